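#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model of a backbone C=O ... H-N hydrogen bond:
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
#' distances in Angstrom. A bond is assigned when `E < -0.5` kcal/mol.
#'
#' @param donor named list with 3-vectors `N` and `H` (the N-H group
#'   donating the proton).
#' @param acceptor named list with 3-vectors `C` and `O` (the C=O group
#'   accepting it).
#' @return energy in kcal/mol.
#' @export
backbone_hbond_energy <- function(donor, acceptor) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  r_on <- d(acceptor$O, donor$N); r_ch <- d(acceptor$C, donor$H)
  r_oh <- d(acceptor$O, donor$H); r_cn <- d(acceptor$C, donor$N)
  if (min(r_on, r_ch, r_oh, r_cn) < 1e-2)
    return(0)  # degenerate overlap: not a physical bond geometry
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

KS_BOND_CUTOFF <- -0.5  # kcal/mol

# Per-residue backbone atom bookkeeping for one conformation.
# Returns residue table with xyz for N, CA, C, O, H (H synthesized in the
# Kabsch-Sander convention -- 1.01 A from N along the previous residue's
# O->C direction -- when the file carries none) and chain-break flags.
backbone_frame <- function(model) {
  a <- model$atom
  xyz <- coords_of(model$xyz)
  key <- paste(a$chain, a$resno)
  res_keys <- unique(key)
  n <- length(res_keys)
  get1 <- function(k, nm) {
    i <- which(key == k & a$name == nm & a$element != "H")
    if (length(i)) i[1L] else NA_integer_
  }
  getH <- function(k) {
    i <- which(key == k & a$element == "H" & a$name %in% c("H", "HN", "H1"))
    if (length(i)) i[1L] else NA_integer_
  }
  idx <- data.frame(
    N  = vapply(res_keys, get1, integer(1), nm = "N"),
    CA = vapply(res_keys, get1, integer(1), nm = "CA"),
    C  = vapply(res_keys, get1, integer(1), nm = "C"),
    O  = vapply(res_keys, get1, integer(1), nm = "O"),
    H  = vapply(res_keys, getH, integer(1)))
  coord <- function(col) {
    out <- matrix(NA_real_, n, 3L)
    ok <- !is.na(idx[[col]])
    out[ok, ] <- xyz[idx[[col]][ok], , drop = FALSE]
    out
  }
  bb <- list(N = coord("N"), CA = coord("CA"), C = coord("C"),
             O = coord("O"), H = coord("H"),
             resno = a$resno[match(res_keys, key)],
             chain = a$chain[match(res_keys, key)])
  bb$complete <- !is.na(idx$N) & !is.na(idx$CA) & !is.na(idx$C) & !is.na(idx$O)
  # chain break after residue i: chain change or broken C(i)-N(i+1) bond
  brk <- rep(FALSE, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (bb$chain[i] != bb$chain[i + 1L] || !bb$complete[i] ||
          !bb$complete[i + 1L]) { brk[i] <- TRUE; next }
      if (sqrt(sum((bb$C[i, ] - bb$N[i + 1L, ])^2)) > 2.5) brk[i] <- TRUE
    }
  }
  bb$break_after <- brk
  # synthesize amide H where absent (never for a chain start: no preceding
  # carbonyl to orient it, and prolines genuinely lack one)
  for (i in seq_len(n)) {
    if (!any(is.na(bb$H[i, ]))) next
    if (i == 1L || brk[i - 1L] || !bb$complete[i] || !bb$complete[i - 1L]) next
    v <- bb$C[i - 1L, ] - bb$O[i - 1L, ]
    bb$H[i, ] <- bb$N[i, ] + 1.01 * v / sqrt(sum(v^2))
  }
  bb
}

# Logical matrix hb[i, j]: C=O of residue i accepts a hydrogen bond from the
# N-H of residue j (Kabsch-Sander energy below cutoff). 9 A CA prefilter.
ks_hbond_matrix <- function(bb) {
  n <- length(bb$resno)
  hb <- matrix(FALSE, n, n)
  if (n < 2L) return(hb)
  ca_ok <- !is.na(bb$CA[, 1L])
  for (i in seq_len(n)) {
    if (!bb$complete[i]) next
    for (j in seq_len(n)) {
      if (j == i || abs(j - i) == 1L) next
      if (!bb$complete[j] || any(is.na(bb$H[j, ]))) next
      if (ca_ok[i] && ca_ok[j] &&
          sum((bb$CA[i, ] - bb$CA[j, ])^2) > 81) next
      e <- backbone_hbond_energy(list(N = bb$N[j, ], H = bb$H[j, ]),
                                 list(C = bb$C[i, ], O = bb$O[i, ]))
      hb[i, j] <- e < KS_BOND_CUTOFF
    }
  }
  hb
}

#' Three-state secondary structure of one conformation (simplified DSSP)
#'
#' Backbone hydrogen bonds are assigned by the Kabsch-Sander energy
#' criterion, then the standard pattern rules are applied: two consecutive
#' n-turns (n = 3, 4, 5) define 3/10-, alpha- and pi-helices, and
#' parallel/antiparallel bridge patterns define strand residues. The eight
#' DSSP classes are collapsed to three: helix (H/G/I), sheet (E/B) and coil
#' (everything else, including turns and bends). Priority at overlaps follows
#' DSSP: alpha-helix, then sheet, then 3/10- or pi-helix. Chain breaks
#' restart the pattern search.
#'
#' @param model a [structure_model()] with complete backbone (amide
#'   hydrogens are synthesized when absent).
#' @param frame integer frame label recorded in the output.
#' @return data.frame with `residue_number`, `state`
#'   (`"helix"`/`"sheet"`/`"coil"`), `frame`.
#' @export
assign_secstruct_frame <- function(model, frame = 1L) {
  stopifnot(inherits(model, "structure_model"))
  bb <- backbone_frame(model)
  n <- length(bb$resno)
  if (any(!bb$complete))
    warning("residue(s) with incomplete backbone skipped: ",
            paste(head(bb$resno[!bb$complete], 5L), collapse = ", "))
  hb <- ks_hbond_matrix(bb)
  contiguous <- function(i, j) {
    if (j <= i) return(TRUE)
    !any(bb$break_after[i:(j - 1L)])
  }
  turn_at <- function(i, len) {
    i >= 1L && i + len <= n && contiguous(i, i + len) && hb[i, i + len]
  }
  helix_mask <- function(len) {
    m <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (turn_at(i - 1L, len) && turn_at(i, len))
        m[i:min(n, i + len - 1L)] <- TRUE
    }
    m
  }
  is_H <- helix_mask(4L)
  is_G <- helix_mask(3L)
  is_I <- helix_mask(5L)
  is_E <- rep(FALSE, n)
  hbs <- function(i, j) i >= 1L && j >= 1L && i <= n && j <= n && hb[i, j]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3L) next
      para <- (hbs(i - 1L, j) && hbs(j, i + 1L)) ||
              (hbs(j - 1L, i) && hbs(i, j + 1L))
      anti <- (hbs(i, j) && hbs(j, i)) ||
              (hbs(i - 1L, j + 1L) && hbs(j - 1L, i + 1L))
      if (para || anti) { is_E[i] <- TRUE; is_E[j] <- TRUE }
    }
  }
  state <- rep("coil", n)
  state[is_G | is_I] <- "helix"
  state[is_E] <- "sheet"
  state[is_H] <- "helix"  # alpha-helix outranks sheet at overlaps
  data.frame(residue_number = bb$resno, state = state,
             frame = as.integer(frame), stringsAsFactors = FALSE)
}

#' Secondary-structure content of a region across replicate ensembles
#'
#' Per frame, the fraction of the region's residues in each of the three
#' states; averaged over frames within each replicate, then mean and sd
#' across replicates. The three percentages sum to 100 up to rounding.
#'
#' @param replicates an [ensemble()] or list of replicate ensembles.
#' @param region one row of a `flexible_regions` table.
#' @return one-row data.frame of class `secstruct_summary`: `region_id`,
#'   `pct_sheet`, `sd_sheet`, `pct_helix`, `sd_helix`, `pct_coil`,
#'   `sd_coil`, `n_replicates`.
#' @export
region_secstruct_percentages <- function(replicates, region) {
  if (inherits(replicates, "ensemble")) replicates <- list(replicates)
  if (!length(replicates)) stop("need at least one ensemble")
  rng <- seq.int(region$start_residue[1L], region$end_residue[1L])
  if (!length(rng)) stop("empty region")
  per_rep <- vapply(replicates, function(ens) {
    stopifnot(inherits(ens, "ensemble"))
    acc <- c(sheet = 0, helix = 0, coil = 0)
    nf <- n_frames(ens)
    for (i in seq_len(nf)) {
      ss <- assign_secstruct_frame(get_frame(ens, i), frame = i)
      ss <- ss[ss$residue_number %in% rng, , drop = FALSE]
      if (!nrow(ss)) stop("region residues absent from ensemble")
      for (st in names(acc)) acc[st] <- acc[st] + mean(ss$state == st)
    }
    100 * acc / nf
  }, numeric(3))
  m <- rowMeans(per_rep)
  s <- if (ncol(per_rep) > 1L) apply(per_rep, 1L, sd) else c(0, 0, 0)
  out <- data.frame(region_id = region$region_id[1L],
                    pct_sheet = m[["sheet"]], sd_sheet = s[[1L]],
                    pct_helix = m[["helix"]], sd_helix = s[[2L]],
                    pct_coil = m[["coil"]], sd_coil = s[[3L]],
                    n_replicates = ncol(per_rep))
  class(out) <- c("secstruct_summary", "data.frame")
  out
}
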