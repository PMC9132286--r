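# donor N at origin, H along +x, acceptor placed at a chosen D-A distance and
# D-H...A angle (degrees, measured at the hydrogen)
dha_model <- function(da_dist, dha_angle) {
  dh <- 1.0
  beta <- dha_angle * pi / 180
  # acceptor at H + t * v with angle(HD, HA) = dha_angle and |DA| = da_dist
  v <- c(-cos(beta), sin(beta), 0)
  cosg <- -cos(beta)
  t <- -dh * cosg + sqrt((dh * cosg)^2 - dh^2 + da_dist^2)
  A <- c(dh, 0, 0) + t * v
  toy_model(data.frame(name = c("N", "H", "O"), element = c("N", "H", "O"),
                       resno = c(1, 1, 2),
                       x = c(0, dh, A[1]), y = c(0, 0, A[2]),
                       z = c(0, 0, A[3])))
}

test_that("geometric criteria are applied inclusively at both boundaries", {
  detect <- function(m) {
    topo <- build_hbond_topology(m)
    detect_hbonds_frame(m, topo)
  }
  expect_equal(nrow(detect(dha_model(3.4, 150))), 1L)   # inside both
  expect_equal(nrow(detect(dha_model(3.6, 150))), 0L)   # too far
  expect_equal(nrow(detect(dha_model(3.4, 119))), 0L)   # too bent
  # boundary inclusivity: criteria set to the pair's exact measured geometry
  # still detect it (<= and >=, not < and >)
  m <- dha_model(3.5, 120)
  topo <- build_hbond_topology(m)
  wide <- detect_hbonds_frame(m, topo, d_max = 3.6, angle_min = 115)
  expect_equal(nrow(wide), 1L)
  expect_equal(wide$distance, 3.5, tolerance = 1e-9)
  expect_equal(wide$angle, 120, tolerance = 1e-6)
  exact <- detect_hbonds_frame(m, topo, d_max = wide$distance,
                               angle_min = wide$angle)
  expect_equal(nrow(exact), 1L)
})

test_that("intra-residue pairs are never reported", {
  m <- dha_model(3.0, 170)
  m$atom$resno <- c(1L, 1L, 1L)  # collapse everything into one residue
  topo <- build_hbond_topology(m)
  expect_equal(nrow(detect_hbonds_frame(m, topo)), 0L)
})

test_that("detection is invariant under global rigid motion", {
  m <- dha_model(3.2, 140)
  topo <- build_hbond_topology(m)
  obs <- detect_hbonds_frame(m, topo)
  m2 <- m
  m2$xyz <- apply_rigid(m$xyz, rotation_matrix(c(1, 1, 0), 67), c(3, -8, 1))
  obs2 <- detect_hbonds_frame(m2, topo)
  expect_equal(obs2$distance, obs$distance, tolerance = 1e-9)
  expect_equal(obs2$angle, obs$angle, tolerance = 1e-6)
})

test_that("occupancy counts bonded frames exactly in round mode", {
  spec <- ensemble_spec(n_residues = 10, n_frames = 100, amplitude = 0.05,
                        base_geometry = "strand", seed = 1,
                        planted_hbonds = data.frame(donor_res = 2,
                                                    acceptor_res = 9,
                                                    occupancy = 60))
  ens <- generate_ensemble(spec)
  topo <- build_hbond_topology(get_frame(ens, 1))
  st <- hbond_occupancy(ens, topo)
  planted <- st[st$donor_resno == 2 & st$acceptor_resno == 9, ]
  expect_equal(planted$occupancy, 60)
  expect_equal(planted$strength, "medium")

  # always-on bond
  spec2 <- ensemble_spec(n_residues = 8, n_frames = 40, amplitude = 0.05,
                         base_geometry = "strand", seed = 2,
                         planted_hbonds = data.frame(donor_res = 2,
                                                     acceptor_res = 7,
                                                     occupancy = 100))
  st2 <- hbond_occupancy(generate_ensemble(spec2),
                         build_hbond_topology(get_frame(generate_ensemble(spec2), 1)))
  expect_equal(st2$occupancy[st2$donor_resno == 2 & st2$acceptor_resno == 7], 100)
})

test_that("Bernoulli-mode occupancy falls within the binomial 99% CI", {
  p <- 0.4; nf <- 1000
  spec <- ensemble_spec(n_residues = 10, n_frames = nf, amplitude = 0.05,
                        base_geometry = "strand", seed = 5,
                        occupancy_mode = "bernoulli",
                        planted_hbonds = data.frame(donor_res = 2,
                                                    acceptor_res = 9,
                                                    occupancy = 100 * p))
  ens <- generate_ensemble(spec)
  st <- hbond_occupancy(ens, build_hbond_topology(get_frame(ens, 1)))
  occ <- st$occupancy[st$donor_resno == 2 & st$acceptor_resno == 9] / 100
  ci <- qbinom(c(0.005, 0.995), nf, p) / nf
  expect_gte(occ, ci[1])
  expect_lte(occ, ci[2])
})

test_that("occupancy is stable under frame reordering", {
  spec <- ensemble_spec(n_residues = 8, n_frames = 50, amplitude = 0.05,
                        base_geometry = "strand", seed = 9,
                        planted_hbonds = data.frame(donor_res = 2,
                                                    acceptor_res = 7,
                                                    occupancy = 40))
  ens <- generate_ensemble(spec)
  topo <- build_hbond_topology(get_frame(ens, 1))
  st1 <- hbond_occupancy(ens, topo)
  ens2 <- ensemble(ens$atom, ens$xyz[rev(seq_len(n_frames(ens))), ])
  st2 <- hbond_occupancy(ens2, topo)
  expect_equal(st1, st2)
})

test_that("strength classes reproduce the published bin boundaries", {
  expect_equal(classify_strength(80), "strong")
  expect_equal(classify_strength(75), "medium")
  expect_equal(classify_strength(50), "weak")
  expect_equal(classify_strength(25), "very_weak")
  expect_equal(classify_strength(10), "unreported")
  expect_equal(classify_strength(0), "unreported")
  expect_error(classify_strength(101), "0, 100")
  expect_error(classify_strength(-1), "0, 100")
  # the four bins partition (10, 100]: every occupancy gets exactly one class
  grid <- seq(10.0001, 100, by = 0.1237)
  cls <- classify_strength(grid)
  expect_true(all(cls %in% c("strong", "medium", "weak", "very_weak")))
  expect_true(all(diff(match(cls, c("very_weak", "weak", "medium", "strong"))) >= 0))
})

test_that("region summaries count unique pairs by strength", {
  st <- data.frame(donor = 1:3, acceptor = 4:6,
                   donor_resno = c(5, 6, 20), donor_atom = "N",
                   acceptor_resno = c(21, 22, 6), acceptor_atom = "O",
                   occupancy = c(80, 60, 30),
                   strength = classify_strength(c(80, 60, 30)),
                   stringsAsFactors = FALSE)
  region <- data.frame(region_id = 1L, start_residue = 5, end_residue = 10)
  counts <- region_hbond_summary(st, region)
  expect_equal(as.integer(counts), c(1L, 1L, 1L, 0L))
  empty <- region_hbond_summary(st[0, ], region)
  expect_equal(as.integer(empty), c(0L, 0L, 0L, 0L))
})

test_that("an extra planted strong bond changes the strong count by one", {
  base_hb <- data.frame(donor_res = 2, acceptor_res = 9, occupancy = 80)
  mut_hb <- rbind(base_hb, data.frame(donor_res = 4, acceptor_res = 10,
                                      occupancy = 90))
  wt <- generate_ensemble(ensemble_spec(n_residues = 12, n_frames = 60,
                                        amplitude = 0.05,
                                        base_geometry = "strand", seed = 13,
                                        planted_hbonds = base_hb))
  mu <- generate_ensemble(ensemble_spec(n_residues = 12, n_frames = 60,
                                        amplitude = 0.05,
                                        base_geometry = "strand", seed = 13,
                                        planted_hbonds = mut_hb))
  region <- data.frame(region_id = 1L, start_residue = 2, end_residue = 5)
  topo_w <- build_hbond_topology(get_frame(wt, 1))
  topo_m <- build_hbond_topology(get_frame(mu, 1))
  cw <- region_hbond_summary(hbond_occupancy(wt, topo_w, min_occupancy = 10),
                             region)
  cm <- region_hbond_summary(hbond_occupancy(mu, topo_m, min_occupancy = 10),
                             region)
  expect_equal(cm[["strong"]] - cw[["strong"]], 1L)
})

test_that("summary differences are signed per class and antisymmetric", {
  mk <- function(v, id = 1L) {
    names(v) <- c("strong", "medium", "weak", "very_weak")
    attr(v, "region_id") <- id
    v
  }
  wt <- mk(c(0, 0, 3, 21)); mut <- mk(c(1, 3, 9, 17))
  d <- diff_hbond_reports(wt, mut)
  expect_equal(unname(d), c(1, 3, 6, -4, 6))
  expect_equal(d[["total"]], 6)
  expect_equal(unname(diff_hbond_reports(mut, wt)), -unname(d))
  expect_equal(unname(diff_hbond_reports(wt, wt)), rep(0, 5))
  expect_error(diff_hbond_reports(wt, mk(c(1, 1, 1, 1), id = 2L)),
               "different regions")
})
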