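test_that("Kabsch superposition is exact on identical and rigidly moved sets", {
  m <- build_toy_protein(8, "mixed")
  expect_equal(kabsch_superpose(m$xyz, m$xyz)$rmsd, 0, tolerance = 1e-10)
  R <- rotation_matrix(c(1, 2, 3), 73)
  moved <- apply_rigid(m$xyz, R, c(4, -2, 9))
  fit <- kabsch_superpose(moved, m$xyz)
  expect_lt(fit$rmsd, 1e-6)
  expect_lt(max(abs(fit$xyz - m$xyz)), 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches the rotation-grid brute-force oracle", {
  set.seed(5)
  P0 <- matrix(rnorm(12, sd = 2), 4, 3)
  for (case in 1:3) {
    pert <- P0 + matrix(rnorm(12, sd = 0.3), 4, 3)
    moved <- sweep(pert %*% t(rotation_matrix(c(case, 1, 2), 40 * case)),
                   2, c(case, -case, 0.5), "+")
    fit <- kabsch_superpose(as.vector(t(moved)), as.vector(t(P0)))
    oracle <- grid_rmsd_oracle(moved, P0)
    expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
    expect_lte(fit$rmsd, oracle + 1e-6)  # ours is the true minimum
  }
})

test_that("degenerate (collinear) fit selections are rejected", {
  line <- as.vector(t(cbind(1:5, 0, 0)))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("RMSD series removes global rigid motion and matches an independent fit", {
  m <- build_toy_protein(10, "helix")
  ref <- structure_model(m$atom, m$xyz)
  frames <- rbind(m$xyz,
                  m$xyz + rep(c(5, 0, 0), nrow(m$atom)),  # pure translation
                  apply_rigid(m$xyz, rotation_matrix(c(0, 0, 1), 30)))
  ens <- ensemble(m$atom, frames)
  rs <- rmsd_series(ens, ref, selection = "all")
  expect_equal(rs$rmsd, c(0, 0, 0), tolerance = 1e-6)

  set.seed(21)
  noisy <- t(vapply(1:5, function(i) m$xyz + rnorm(length(m$xyz), sd = 0.3),
                    numeric(length(m$xyz))))
  ens2 <- ensemble(m$atom, noisy)
  rs2 <- rmsd_series(ens2, ref, selection = "calpha")
  idx <- which(m$atom$name == "CA")
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  oracle <- vapply(1:5, function(i) {
    bio3d::rmsd(m$xyz, noisy[i, ], a.inds = cols, b.inds = cols, fit = TRUE)
  }, numeric(1))
  expect_equal(rs2$rmsd, oracle, tolerance = 2e-3)  # oracle prints 3 decimals
})

test_that("average structure is the per-atom mean and respects symmetry", {
  m <- build_toy_protein(5, "strand")
  ens <- ensemble(m$atom, rbind(m$xyz, m$xyz, m$xyz))
  expect_equal(average_structure(ens)$xyz, m$xyz)
  d <- rnorm(length(m$xyz), sd = 0.5)
  ens2 <- ensemble(m$atom, rbind(m$xyz + d, m$xyz - d))
  expect_equal(average_structure(ens2)$xyz, m$xyz, tolerance = 1e-12)
})

test_that("iterative superposition converges and has the fixed-point property", {
  m <- build_toy_protein(8, "helix")
  # exact fixed point: radial scalings about a common centroid need no
  # rotation, so the ensemble is already aligned to its average
  ctr <- colMeans(matrix(m$xyz, ncol = 3, byrow = TRUE))
  centered <- m$xyz - rep(ctr, nrow(m$atom))
  aligned <- ensemble(m$atom, rbind(1.02 * centered, 0.98 * centered))
  out <- superpose_ensemble(aligned, selection = "all")
  expect_lt(max(abs(out$xyz - aligned$xyz)), 1e-6)

  # randomly rotated copies of one frame collapse onto a single conformation
  set.seed(3)
  rots <- t(vapply(1:6, function(i)
    apply_rigid(m$xyz, rotation_matrix(rnorm(3), runif(1, 10, 170)),
                rnorm(3, sd = 3)), numeric(length(m$xyz))))
  sup <- superpose_ensemble(ensemble(m$atom, rots), selection = "all")
  spread <- apply(sup$xyz, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-4)
})

test_that("superposition never increases the total RMSD to the average", {
  m <- build_toy_protein(10, "mixed")
  set.seed(9)
  frames <- t(vapply(1:8, function(i)
    apply_rigid(m$xyz + rnorm(length(m$xyz), sd = 0.4),
                rotation_matrix(rnorm(3), runif(1, 0, 180)), rnorm(3, sd = 2)),
    numeric(length(m$xyz))))
  ens <- ensemble(m$atom, frames)
  total_rmsd <- function(e) {
    avg <- colMeans(e$xyz)
    sum(vapply(seq_len(n_frames(e)), function(i)
      sqrt(mean((e$xyz[i, ] - avg)^2)), numeric(1)))
  }
  sup <- superpose_ensemble(ens, selection = "all")
  expect_lte(total_rmsd(sup), total_rmsd(ens) + 1e-9)
})

test_that("centroid selection matches an exhaustive independent scan", {
  m <- build_toy_protein(6, "helix")
  ens <- ensemble(m$atom, rbind(m$xyz, m$xyz, m$xyz))
  expect_equal(select_centroid(ens, selection = "all")$frame_index, 1L)

  set.seed(14)
  frames <- t(vapply(1:50, function(i) m$xyz + rnorm(length(m$xyz), sd = 0.3),
                     numeric(length(m$xyz))))
  ens2 <- superpose_ensemble(ensemble(m$atom, frames), selection = "all")
  win <- 10:40
  got <- select_centroid(ens2, window = win, selection = "all")
  avg <- colMeans(ens2$xyz[win, ])
  oracle_rmsd <- vapply(win, function(i)
    bio3d::rmsd(avg, ens2$xyz[i, ], fit = TRUE), numeric(1))
  expect_equal(got$frame_index, win[which.min(oracle_rmsd)])
})

test_that("a frame equal to the window average is selected as centroid", {
  m <- build_toy_protein(5, "strand")
  d <- rnorm(length(m$xyz), sd = 0.4)
  # frames: X+d, X-d, X  -> average is X, frame 3 coincides with it
  ens <- ensemble(m$atom, rbind(m$xyz + d, m$xyz - d, m$xyz))
  expect_equal(select_centroid(ens, selection = "all")$frame_index, 3L)
})

test_that("RMSF is zero for rigid ensembles and exact for two-point motion", {
  m <- build_toy_protein(6, "helix")
  ens <- ensemble(m$atom, rbind(m$xyz, m$xyz, m$xyz))
  prof <- compute_rmsf(ens, superpose = FALSE)
  expect_true(all(prof$rmsf == 0))

  # one C-alpha alternating between two points 2 A apart -> RMSF exactly 1
  xyz2 <- rbind(m$xyz, m$xyz)
  ca3 <- which(m$atom$name == "CA" & m$atom$resno == 3)
  xyz2[2, 3 * ca3 - 2] <- xyz2[2, 3 * ca3 - 2] + 2.0
  prof2 <- compute_rmsf(ensemble(m$atom, xyz2), superpose = FALSE)
  expect_equal(prof2$rmsf[prof2$residue_number == 3], 1.0, tolerance = 1e-12)
  expect_equal(sum(prof2$rmsf > 0), 1L)
})

test_that("isotropic Gaussian fluctuation recovers sigma * sqrt(3)", {
  spec <- ensemble_spec(n_residues = 10, n_frames = 2000, amplitude = 0.5,
                        base_geometry = "helix", seed = 42)
  prof <- compute_rmsf(generate_ensemble(spec), superpose = FALSE)
  expect_equal(mean(prof$rmsf), 0.5 * sqrt(3), tolerance = 0.05)
  expect_true(all(abs(prof$rmsf - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.05))
})

test_that("RMSF with superposition is invariant under global rigid motion", {
  spec <- ensemble_spec(n_residues = 8, n_frames = 120, amplitude = 0.3,
                        base_geometry = "mixed", seed = 8)
  ens <- generate_ensemble(spec)
  prof <- compute_rmsf(ens, superpose = TRUE)
  R <- rotation_matrix(c(2, -1, 1), 111)
  moved <- t(apply(ens$xyz, 1, apply_rigid, R = R, t = c(10, -5, 2)))
  prof2 <- compute_rmsf(ensemble(ens$atom, moved), superpose = TRUE)
  expect_equal(prof2$rmsf, prof$rmsf, tolerance = 1e-6)
})
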