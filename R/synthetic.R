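# Ideal backbone internal coordinates (Angstrom / degrees)
BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
                b_n_h = 1.01, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                a_c_n_ca = 121.7, a_ca_c_o = 120.8, omega = 180)

PHI_PSI <- list(helix = c(phi = -57, psi = -47),
                strand = c(phi = -140, psi = 135),
                coil = c(phi = -75, psi = 150))

# Place atom d bonded to c with |cd| = bond, angle(b,c,d) = ang (deg) and
# dihedral(a,b,c,d) = dih (deg). Standard internal-to-Cartesian step.
place_atom <- function(a, b, c, bond, ang, dih) {
  th <- ang * pi / 180; ph <- dih * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealised polyalanine backbone
#'
#' Constructs a toy protein (N, H, CA, C, O per residue) from ideal bond
#' lengths/angles and canonical backbone dihedrals: alpha-helix
#' (phi = -57, psi = -47), extended strand (phi = -140, psi = 135) or
#' polyproline-like coil. `"mixed"` concatenates helix, strand and coil
#' segments of roughly equal length. Amide hydrogens are placed 1.01 Angstrom
#' from N along the previous carbonyl's O->C direction.
#'
#' @param n_residues chain length (>= 4).
#' @param base_geometry `"helix"`, `"strand"`, `"coil"` or `"mixed"`.
#' @param start_resno residue number of the first residue.
#' @param chain chain identifier.
#' @return a [structure_model()].
#' @export
build_toy_protein <- function(n_residues,
                              base_geometry = c("helix", "strand", "coil", "mixed"),
                              start_resno = 1L, chain = "A") {
  base_geometry <- match.arg(base_geometry)
  n_residues <- as.integer(n_residues)
  if (n_residues < 4L) stop("n_residues must be at least 4")
  if (base_geometry == "mixed") {
    k <- n_residues %/% 3L
    segs <- c(rep("helix", k), rep("strand", k),
              rep("coil", n_residues - 2L * k))
  } else segs <- rep(base_geometry, n_residues)
  phi <- vapply(segs, function(s) PHI_PSI[[s]][["phi"]], numeric(1))
  psi <- vapply(segs, function(s) PHI_PSI[[s]][["psi"]], numeric(1))
  build_backbone(phi, psi, start_resno = start_resno, chain = chain)
}

# Build a backbone model from per-residue (phi, psi); omega fixed trans.
build_backbone <- function(phi, psi, start_resno = 1L, chain = "A") {
  g <- BB_GEOM
  n <- length(phi)
  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n)[-1L]) {
    N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1L])
    CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  for (i in seq_len(n))
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  for (i in seq_len(n)) {
    if (i == 1L) {
      u1 <- N[1L, ] - CA[1L, ]; u2 <- N[1L, ] - C[1L, ]
      v <- u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2))
    } else {
      v <- C[i - 1L, ] - O[i - 1L, ]
    }
    H[i, ] <- N[i, ] + g$b_n_h * v / sqrt(sum(v^2))
  }
  per_res <- function(i) rbind(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ])
  xyz <- do.call(rbind, lapply(seq_len(n), per_res))
  atom <- data.frame(
    serial = seq_len(5L * n),
    name = rep(c("N", "H", "CA", "C", "O"), n),
    resname = "ALA", chain = chain,
    resno = rep(start_resno + seq_len(n) - 1L, each = 5L),
    element = rep(c("N", "H", "C", "C", "O"), n),
    stringsAsFactors = FALSE)
  structure_model(atom, flatten_coords(xyz))
}

#' Build an idealised two-strand antiparallel beta sheet
#'
#' Two extended strands; the second is the first rotated 180 degrees and
#' rigidly placed by a deterministic grid search maximising the number of
#' inter-strand Kabsch-Sander backbone hydrogen bonds, which realises the
#' antiparallel ladder. Residue numbering leaves a gap between the strands
#' (a chain break, as in a real hairpin whose turn is disordered).
#'
#' @param n_per_strand residues per strand (>= 4).
#' @param numbering_gap residue-number gap between the strands.
#' @return a [structure_model()] with `2 * n_per_strand` residues.
#' @export
build_beta_sheet <- function(n_per_strand = 6L, numbering_gap = 3L) {
  n <- as.integer(n_per_strand)
  s1 <- build_toy_protein(n, "strand")
  x1 <- coords_of(s1$xyz)
  nm <- s1$atom$name; rn <- s1$atom$resno
  idxN <- vapply(seq_len(n), function(r) which(rn == r & nm == "N"), 0L)
  idxO <- vapply(seq_len(n), function(r) which(rn == r & nm == "O"), 0L)
  euler <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3L, 3L, byrow = TRUE)
  }
  place <- function(R0, p) {
    R <- euler(p[1:3]) %*% R0
    sweep(x1 %*% t(R), 2L, p[4:6], "+")
  }
  # narrow-pair hydrogen-bond ladder of an antiparallel sheet: residue i of
  # strand A against residue n+1-i of strand B, N...O distances 2.9 A
  objective <- function(p, R0, parity) {
    x2 <- place(R0, p)
    err <- 0
    for (i in seq_len(n)) {
      if (i %% 2L != parity) next
      j <- n + 1L - i
      d1 <- sqrt(sum((x1[idxN[i], ] - x2[idxO[j], ])^2))
      d2 <- sqrt(sum((x1[idxO[i], ] - x2[idxN[j], ])^2))
      err <- err + (d1 - 2.9)^2 + (d2 - 2.9)^2
    }
    err
  }
  rot0 <- list(diag(c(-1, -1, 1)),   # flip about z
               diag(c(-1, 1, -1)))   # flip about y
  best <- NULL
  for (R0 in rot0) for (parity in 0:1) {
    fit <- stats::optim(c(0, 0, 0, 0, 4.8, 0), objective, R0 = R0,
                        parity = parity, method = "BFGS",
                        control = list(maxit = 500))
    x2 <- place(R0, fit$par)
    nb <- count_intersheet_bonds(s1, x1, x2, n, numbering_gap)
    if (is.null(best) || nb > best$nb ||
        (nb == best$nb && fit$value < best$value))
      best <- list(nb = nb, value = fit$value, x2 = x2)
  }
  assemble_sheet(s1, x1, best$x2, n, numbering_gap)
}

assemble_sheet <- function(s1, x1, x2, n, gap) {
  a2 <- s1$atom
  a2$resno <- a2$resno + n + gap
  a2$serial <- a2$serial + nrow(s1$atom)
  atom <- rbind(s1$atom, a2)
  structure_model(atom, c(flatten_coords(x1), flatten_coords(x2)))
}

count_intersheet_bonds <- function(s1, x1, x2, n, gap) {
  m <- assemble_sheet(s1, x1, x2, n, gap)
  bb <- backbone_frame(m)
  hb <- ks_hbond_matrix(bb)
  first <- seq_len(n); second <- n + seq_len(n)
  sum(hb[first, second]) + sum(hb[second, first])
}

#' Specification for a synthetic conformational ensemble
#'
#' Describes the planted statistical structure of a generated ensemble: the
#' base geometry, per-residue Gaussian fluctuation amplitudes (per-coordinate
#' sd, so the expected C-alpha RMSF is `sd * sqrt(3)`), region-wise amplitude
#' scaling, and hydrogen-bond pairs present in a prescribed fraction of
#' frames.
#'
#' @param n_residues chain length.
#' @param n_frames number of frames.
#' @param amplitude per-coordinate Gaussian sd in Angstrom; scalar or one
#'   value per residue.
#' @param region_scaling optional data.frame with columns `start_residue`,
#'   `end_residue`, `factor` multiplying the amplitude inside each interval.
#' @param planted_hbonds optional data.frame with columns `donor_res`,
#'   `acceptor_res`, `occupancy` (percent of frames in which the pair
#'   satisfies the detection criteria).
#' @param base_geometry forwarded to [build_toy_protein()].
#' @param seed integer seed; the same spec yields a bit-identical ensemble
#'   (R's default Mersenne-Twister generator).
#' @param occupancy_mode `"round"`: exactly `round(occ/100 * n_frames)`
#'   bonded frames; `"bernoulli"`: each frame bonded independently with
#'   probability `occ/100`.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_residues = 30L, n_frames = 200L, amplitude = 0.3,
                          region_scaling = NULL, planted_hbonds = NULL,
                          base_geometry = "mixed", seed = 1L,
                          occupancy_mode = c("round", "bernoulli")) {
  occupancy_mode <- match.arg(occupancy_mode)
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  if (!length(amplitude) %in% c(1L, n_residues))
    stop("amplitude must be scalar or one value per residue")
  if (!is.null(planted_hbonds)) {
    ph <- planted_hbonds
    stopifnot(all(c("donor_res", "acceptor_res", "occupancy") %in% names(ph)))
    if (any(ph$occupancy < 0 | ph$occupancy > 100))
      stop("occupancies must lie in [0, 100]")
    if (any(ph$donor_res == ph$acceptor_res))
      stop("planted bond donor and acceptor must be different residues")
    if (anyDuplicated(ph$acceptor_res))
      stop("conflicting restraints: an acceptor residue appears in more ",
           "than one planted bond")
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 amplitude = amplitude, region_scaling = region_scaling,
                 planted_hbonds = planted_hbonds,
                 base_geometry = base_geometry, seed = as.integer(seed),
                 occupancy_mode = occupancy_mode),
            class = "ensemble_spec")
}

#' Generate a synthetic conformational ensemble with planted structure
#'
#' Frames are the base structure plus independent per-atom Gaussian
#' displacements whose per-coordinate sd is the residue's amplitude (scaled
#' inside any `region_scaling` interval). Planted hydrogen-bond pairs are
#' restrained into criterion-satisfying geometry (donor-acceptor 2.9
#' Angstrom, donor-H...acceptor angle 165 degrees) in the prescribed
#' fraction of frames and pushed outside the criteria (4.5 Angstrom)
#' otherwise. Deterministic per seed. The marginal conformational
#' distribution is the target -- there are no dynamics.
#'
#' @param spec an [ensemble_spec()].
#' @return an [ensemble()].
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  base <- build_toy_protein(spec$n_residues, spec$base_geometry)
  sd_res <- rep(spec$amplitude, length.out = spec$n_residues)
  if (!is.null(spec$region_scaling)) {
    rs <- spec$region_scaling
    for (k in seq_len(nrow(rs))) {
      iv <- seq.int(rs$start_residue[k], rs$end_residue[k])
      if (any(iv < 1L | iv > spec$n_residues))
        stop("region_scaling interval outside the protein")
      sd_res[iv] <- sd_res[iv] * rs$factor[k]
    }
  }
  sd_atom <- sd_res[base$atom$resno]       # every atom of a residue
  sd_col <- rep(sd_atom, each = 3L)
  nf <- spec$n_frames
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  noise <- matrix(rnorm(nf * length(base$xyz)), nrow = nf) *
    matrix(sd_col, nrow = nf, ncol = length(sd_col), byrow = TRUE)
  xyz <- sweep(noise, 2L, base$xyz, "+")
  if (!is.null(spec$planted_hbonds)) {
    ph <- spec$planted_hbonds
    a <- base$atom
    for (k in seq_len(nrow(ph))) {
      di <- which(a$resno == ph$donor_res[k] & a$name == "N")
      hi <- which(a$resno == ph$donor_res[k] & a$name == "H")
      ai <- which(a$resno == ph$acceptor_res[k] & a$name == "O")
      if (!length(di) || !length(hi) || !length(ai))
        stop("planted bond atoms missing for pair ", k)
      n_on <- if (spec$occupancy_mode == "round")
        as.integer(round(ph$occupancy[k] / 100 * nf)) else NA_integer_
      on <- if (spec$occupancy_mode == "round") {
        seq_len(nf) %in% sample.int(nf, n_on)
      } else stats::runif(nf) < ph$occupancy[k] / 100
      for (f in seq_len(nf)) {
        D <- xyz[f, xyz_cols(di)]; H <- xyz[f, xyz_cols(hi)]
        A <- planted_acceptor_pos(D, H, on[f])
        xyz[f, xyz_cols(ai)] <- A
      }
    }
  }
  ensemble(base$atom, xyz)
}

# Acceptor position realising the planted criterion state given donor heavy
# atom D and hydrogen H: bonded frames get |D-A| = 2.9 A at a D-H...A angle
# of 165 deg; unbonded frames put A collinear at |D-A| = 4.5 A.
planted_acceptor_pos <- function(D, H, bonded) {
  u <- H - D; dh <- sqrt(sum(u^2)); u <- u / dh
  if (!bonded) return(D + 4.5 * u)
  e <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- c(u[2] * e[3] - u[3] * e[2], u[3] * e[1] - u[1] * e[3],
         u[1] * e[2] - u[2] * e[1])
  p <- p / sqrt(sum(p^2))
  beta <- 165 * pi / 180
  v <- cos(beta) * (-u) + sin(beta) * p   # direction H -> A
  cosg <- -cos(beta)                       # u . v
  t <- -dh * cosg + sqrt((dh * cosg)^2 - dh^2 + 2.9^2)
  H + t * v
}

#' Generate a wild-type / mutant ensemble pair with a planted rigidity change
#'
#' The mutant is generated from the same specification except that the
#' fluctuation amplitude inside `region` is multiplied by `scale_factor`
#' (and an independent noise stream is used). Since RMSF scales linearly
#' with amplitude, the expected region delta-RMSF is
#' `100 * (scale_factor - 1)` percent.
#'
#' @param spec an [ensemble_spec()] describing the wild type.
#' @param region one row of a `flexible_regions` table (or list with
#'   `start_residue`, `end_residue`).
#' @param scale_factor positive amplitude multiplier (< 1 rigidifies).
#' @return list with elements `wildtype` and `mutant` (each an
#'   [ensemble()]), plus `expected_delta_rmsf` (percent).
#' @export
generate_mutant_pair <- function(spec, region, scale_factor) {
  stopifnot(inherits(spec, "ensemble_spec"), scale_factor > 0)
  iv <- c(region$start_residue[1L], region$end_residue[1L])
  if (iv[1L] < 1L || iv[2L] > spec$n_residues)
    stop("region outside the protein")
  wt <- generate_ensemble(spec)
  extra <- data.frame(start_residue = iv[1L], end_residue = iv[2L],
                      factor = scale_factor)
  mspec <- spec
  mspec$region_scaling <- rbind(spec$region_scaling, extra)
  mspec$seed <- spec$seed + 1L
  mut <- generate_ensemble(mspec)
  list(wildtype = wt, mutant = mut,
       expected_delta_rmsf = 100 * (scale_factor - 1))
}

#' Design-table fixtures for funnel testing
#'
#' `"paper"` mode returns the design score table shipped with the package
#' (the published rhamnosidase design campaign: 68 positions across five
#' flexible regions). `"random"` mode generates a synthetic table with ddG
#' drawn uniformly from `[-8, 4]` REU for stress-testing the selection
#' logic.
#'
#' @param mode `"paper"` or `"random"`.
#' @param seed RNG seed for random mode.
#' @param n_positions number of positions in random mode.
#' @return a `design_table` data.frame.
#' @export
make_design_table_fixture <- function(mode = c("paper", "random"), seed = 1L,
                                      n_positions = 20L) {
  mode <- match.arg(mode)
  if (mode == "paper") {
    path <- system.file("extdata", "design_ddg_table.tsv",
                        package = "flexiscreen", mustWork = TRUE)
    return(read_design_table(path))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  native <- sample(aa, n_positions, replace = TRUE)
  designed <- vapply(native, function(x) sample(setdiff(aa, x), 1L), "")
  out <- data.frame(
    region_id = sort(sample.int(5L, n_positions, replace = TRUE)),
    residue_number = sort(sample.int(800L, n_positions)),
    active_site_distance = round(stats::runif(n_positions, 5, 60), 1L),
    native_aa = native,
    has_interaction_potential = TRUE,
    designed_aa = designed,
    ddG = round(stats::runif(n_positions, -8, 4), 1L),
    stringsAsFactors = FALSE)
  class(out) <- c("design_table", "data.frame")
  out
}
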