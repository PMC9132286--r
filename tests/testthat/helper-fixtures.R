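# Shared fixtures and independent oracles used across the suite.

fixture_path <- function(name) {
  system.file("extdata", name, package = "flexiscreen", mustWork = TRUE)
}

# Minimal hand-built model: one atom per row of `df` (name, element, resno,
# x, y, z).
toy_model <- function(df, chain = "A") {
  atom <- data.frame(serial = seq_len(nrow(df)), name = df$name,
                     resname = "ALA", chain = chain, resno = df$resno,
                     element = df$element, stringsAsFactors = FALSE)
  structure_model(atom, as.vector(t(as.matrix(df[, c("x", "y", "z")]))))
}

rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2)); th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

apply_rigid <- function(xyz_flat, R, t = c(0, 0, 0)) {
  m <- matrix(xyz_flat, ncol = 3, byrow = TRUE)
  as.vector(t(sweep(m %*% t(R), 2, t, "+")))
}

# Independent superposition oracle: exhaustive search over rotation space
# (Euler-angle grid, coarse-to-fine), translations removed by centering.
grid_rmsd_oracle <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(b) matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
                           3, 3, byrow = TRUE)
  rmsd_at <- function(a, b, g) {
    R <- rz(a) %*% ry(b) %*% rz(g)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- c(a = 0, b = 0, g = 0); best_v <- rmsd_at(0, 0, 0)
  step <- 15 * pi / 180
  for (a in seq(0, 2 * pi, by = step)) for (b in seq(0, pi, by = step))
    for (g in seq(0, 2 * pi, by = step)) {
      v <- rmsd_at(a, b, g)
      if (v < best_v) { best_v <- v; best <- c(a = a, b = b, g = g) }
    }
  for (refine in c(1.5, 0.15, 0.02)) {
    st <- refine * pi / 180
    rng <- function(x) seq(x - 10 * st, x + 10 * st, by = st)
    for (a in rng(best[["a"]])) for (b in rng(best[["b"]]))
      for (g in rng(best[["g"]])) {
        v <- rmsd_at(a, b, g)
        if (v < best_v) { best_v <- v; best <- c(a = a, b = b, g = g) }
      }
  }
  best_v
}

# Reference DSSP oracle (independent implementation), three-state.
mdtraj_dssp <- function(model) {
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  write_ensemble(ensemble(model$atom, matrix(model$xyz, nrow = 1)), pdb)
  code <- sprintf(
    "import mdtraj as md; t = md.load('%s'); print(''.join(md.compute_dssp(t, simplified=True)[0]))",
    pdb)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  states <- strsplit(trimws(out[length(out)]), "")[[1]]
  unname(c(H = "helix", E = "sheet", C = "coil", N = "coil")[states])
}
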