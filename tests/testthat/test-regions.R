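make_profile <- function(resno, rmsf) {
  out <- data.frame(residue_number = resno, rmsf = rmsf)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

test_that("the flexibility cutoff is the pooled mean over all profiles", {
  p1 <- make_profile(1:3, c(1, 1, 4))
  expect_equal(flexibility_cutoff(p1), 2.0)
  # constant profile: cutoff equals the constant, nothing strictly exceeds it
  pc <- make_profile(1:5, rep(3.3, 5))
  expect_equal(flexibility_cutoff(pc), 3.3)
  expect_length(flag_flexible_residues(pc, flexibility_cutoff(pc)), 0L)

  set.seed(2)
  profs <- lapply(1:3, function(i) make_profile(1:10, runif(10, 0, 6)))
  pooled <- mean(c(profs[[1]]$rmsf, profs[[2]]$rmsf, profs[[3]]$rmsf))
  expect_equal(flexibility_cutoff(profs), pooled)
  expect_equal(flexibility_cutoff(profs, per_model = TRUE),
               vapply(profs, function(p) mean(p$rmsf), numeric(1)))
  expect_error(flexibility_cutoff(list()), "at least one")
})

test_that("flagging uses a strict comparison and matches a brute-force filter", {
  p <- make_profile(1:3, c(1, 1, 4))
  expect_equal(flag_flexible_residues(p, 2), 3L)
  set.seed(31)
  pr <- make_profile(1:50, runif(50, 0, 6))
  cut <- 3.1
  expect_equal(flag_flexible_residues(pr, cut),
               sort(pr$residue_number[pr$rmsf > cut]))
})

test_that("adjacent flagged residues merge into maximal disjoint regions", {
  regs <- merge_into_regions(c(5, 6, 7, 10, 12, 13))
  expect_equal(regs$start_residue, c(5, 10, 12))
  expect_equal(regs$end_residue, c(7, 10, 13))
  expect_equal(regs$region_id, 1:3)
  # regions are disjoint and maximal: no two adjacent regions touch
  expect_true(all(regs$start_residue[-1] > regs$end_residue[-nrow(regs)] + 1))
  # conservation: every flagged, non-excluded residue in exactly one region
  flagged <- c(5, 6, 7, 10, 12, 13)
  covered <- unlist(mapply(seq, regs$start_residue, regs$end_residue))
  expect_setequal(covered, flagged)

  expect_equal(nrow(merge_into_regions(c(820, 825), exclusion = "815-843")), 0L)
  with_excl <- merge_into_regions(c(5, 6, 820), exclusion = "815-843")
  expect_equal(nrow(with_excl), 1L)
})

test_that("re-feeding the published region ranges reproduces the residue counts", {
  reg_tab <- read_region_table(fixture_path("wildtype_flexible_regions.tsv"))
  flags <- unlist(mapply(seq, reg_tab$start_residue, reg_tab$end_residue))
  regs <- merge_into_regions(flags)
  expect_equal(nrow(regs), 12L)
  expect_equal(regs$n_residues, c(14, 23, 11, 14, 6, 10, 6, 9, 11, 20, 11, 6))
})

test_that("region summaries compute mean/sd over the interval and replicates", {
  pc <- make_profile(1:10, rep(2.5, 10))
  s <- summarize_region(pc, 3, 7)
  expect_equal(s$mean_rmsf, 2.5)
  expect_equal(s$sd_rmsf, 0)
  expect_equal(summarize_region(pc, 1, 10)$n_residues, 10L)
  expect_equal(length(seq(48, 70)), 23L)  # region-2 interval width

  set.seed(6)
  p <- make_profile(1:30, runif(30, 1, 5))
  s2 <- summarize_region(p, 11, 20)
  expect_equal(s2$mean_rmsf, mean(p$rmsf[11:20]))
  expect_equal(s2$sd_rmsf, sd(p$rmsf[11:20]))

  reps <- lapply(1:3, function(i) make_profile(1:30, runif(30, 1, 5)))
  s3 <- summarize_region(reps, 11, 20)
  rm_ <- vapply(reps, function(p) mean(p$rmsf[11:20]), numeric(1))
  expect_equal(s3$mean_rmsf, mean(rm_))
  expect_equal(s3$sd_rmsf, sd(rm_))
  expect_error(summarize_region(pc, 8, 12), "missing")
})

test_that("ranking by mean RMSF reproduces the published top five", {
  reg_tab <- read_region_table(fixture_path("wildtype_flexible_regions.tsv"))
  top <- rank_regions(reg_tab, 5)
  expect_setequal(top$region_id, c(2, 3, 4, 8, 11))
  expect_equal(top$region_id[1], 3L)
  expect_equal(top$mean_rmsf[1], 5.5)
  # the published tie at 4.9 A (regions 4 and 11) resolves to the lower id
  tied <- top[top$mean_rmsf == 4.9, ]
  expect_equal(tied$region_id, c(4L, 11L))
  # permutation invariance
  set.seed(4)
  shuffled <- reg_tab[sample(nrow(reg_tab)), ]
  expect_equal(rank_regions(shuffled, 5), top)
  all_sorted <- rank_regions(reg_tab, nrow(reg_tab))
  expect_equal(nrow(all_sorted), 12L)
  expect_true(all(diff(all_sorted$mean_rmsf) <= 0))
  expect_error(rank_regions(reg_tab, 13), "exceeds")
})

test_that("active-site distance is the minimum over all atom pairs", {
  m <- toy_model(data.frame(
    name = c("CA", "CB", "CA", "CA"), element = "C",
    resno = c(1, 1, 2, 3),
    x = c(0, 2, 15.1, 0), y = c(0, 0, 0, 0), z = c(0, 0, 0, 0)))
  expect_equal(active_site_distance(m, 3, 1), 0)     # shared position
  expect_equal(active_site_distance(m, 2, 1), 13.1)  # nearest atom is CB
  expect_error(active_site_distance(m, 9, 1), "not found")

  set.seed(12)
  big <- build_toy_protein(12, "mixed")
  xyz <- matrix(big$xyz, ncol = 3, byrow = TRUE)
  d <- active_site_distance(big, 10, c(1, 2))
  qi <- which(big$atom$resno == 10); ci <- which(big$atom$resno %in% 1:2)
  oracle <- min(apply(xyz[qi, , drop = FALSE], 1, function(a)
    apply(xyz[ci, , drop = FALSE], 1, function(b) sqrt(sum((a - b)^2)))))
  expect_equal(d, oracle)
})

test_that("designability requires strictly more than the distance threshold", {
  m <- toy_model(data.frame(
    name = c("CA", "CA", "CA"), element = "C", resno = 1:3,
    x = c(0, 15.0, 15.1), y = 0, z = 0))
  regs <- merge_into_regions(c(2, 3))
  mask <- designability_mask(m, regs, catalytic_residues = 1, threshold = 15)
  expect_equal(mask$designable, c(FALSE, TRUE))  # 15.0 is not "more than 15"
  empty <- designability_mask(m, merge_into_regions(integer()), 1)
  expect_equal(nrow(empty), 0L)
})
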