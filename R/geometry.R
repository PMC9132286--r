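#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation + translation minimising the RMSD between the
#' selected atoms of `mobile` and `reference`, and applies it to all mobile
#' atoms. The returned RMSD is the least-squares minimum over the fit
#' selection; the transformation is always a proper rotation (no reflection).
#'
#' @param mobile flat coordinate vector (x1,y1,z1,...) of the mobile
#'   structure.
#' @param reference flat coordinate vector of the reference; the fit atoms
#'   must match `mobile`'s in count and order.
#' @param fit_idx integer atom indices used for the fit (default: all atoms).
#'   At least 3 non-collinear atoms are required.
#' @return list with `xyz` (transformed mobile coordinates), `rmsd`
#'   (Angstrom, over the fit atoms), `rotation` (3x3), `translation`
#'   (length 3).
#' @export
kabsch_superpose <- function(mobile, reference, fit_idx = NULL) {
  mob <- coords_of(as.numeric(mobile))
  ref <- coords_of(as.numeric(reference))
  if (is.null(fit_idx)) fit_idx <- seq_len(min(nrow(mob), nrow(ref)))
  fit_idx <- as.integer(fit_idx)
  if (length(fit_idx) < 3L)
    stop("superposition needs at least 3 fit atoms, got ", length(fit_idx))
  P <- mob[fit_idx, , drop = FALSE]
  Q <- ref[fit_idx, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("fit selections differ in atom count")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  # degenerate (collinear/coincident) selections leave the rotation
  # under-determined
  scale0 <- sqrt(mean(rowSums(Pc^2)) * mean(rowSums(Qc^2)))
  if (scale0 <= 0 || sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    stop("degenerate fit selection (collinear or coincident atoms); ",
         "rotation is not uniquely determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(mob, 2L, cp) %*% t(R), 2L, cq, "+")
  rmsd <- sqrt(mean(rowSums((moved[fit_idx, , drop = FALSE] - Q)^2)))
  list(xyz = flatten_coords(moved), rmsd = rmsd, rotation = R,
       translation = as.numeric(cq - R %*% cp))
}

#' RMSD of every frame against a reference structure
#'
#' Each frame is optimally superposed onto the reference (on the selection)
#' before the deviation is measured, so global translation/rotation never
#' contributes.
#'
#' @param ens an [ensemble()].
#' @param reference a [structure_model()] sharing the ensemble topology
#'   (default: first frame).
#' @param selection an [atom_selection()] or mode string.
#' @return data.frame of class `rmsd_series` with columns `frame_index`,
#'   `rmsd` (Angstrom); attribute `reference_label`.
#' @export
rmsd_series <- function(ens, reference = NULL, selection = "calpha") {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(reference)) reference <- get_frame(ens, 1L)
  stopifnot(inherits(reference, "structure_model"))
  idx <- select_atoms(ens$atom, selection)
  if (length(idx) < 3L)
    stop("selection resolves to fewer than 3 atoms")
  rms <- vapply(seq_len(n_frames(ens)), function(i) {
    kabsch_superpose(ens$xyz[i, ], reference$xyz, fit_idx = idx)$rmsd
  }, numeric(1))
  out <- data.frame(frame_index = seq_len(n_frames(ens)), rmsd = rms)
  attr(out, "reference_label") <- paste0("model_", reference$model_id)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Per-atom average structure of an ensemble
#'
#' Coordinates are arithmetic means over frames; meaningful when the frames
#' are mutually superposed (see [superpose_ensemble()]).
#'
#' @param ens an [ensemble()].
#' @return a [structure_model()] (model_id 0).
#' @export
average_structure <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  structure_model(ens$atom, colMeans(ens$xyz), model_id = 0L)
}

#' Iteratively superpose all frames onto their evolving average
#'
#' Standard fixed-point alignment: every frame is Kabsch-fitted to the
#' running average structure, the average is recomputed, and the cycle
#' repeats until the average moves less than `tol` (max per-coordinate shift,
#' Angstrom) or `max_iter` is reached (then a warning is emitted and the last
#' iterate returned). Deterministic.
#'
#' @param ens an [ensemble()].
#' @param selection fit selection ([atom_selection()] or mode string).
#' @param tol convergence tolerance on the average structure (Angstrom).
#' @param max_iter maximum number of alignment sweeps.
#' @return the superposed [ensemble()].
#' @export
superpose_ensemble <- function(ens, selection = "calpha", tol = 1e-4,
                               max_iter = 10L) {
  stopifnot(inherits(ens, "ensemble"))
  idx <- select_atoms(ens$atom, selection)
  if (length(idx) < 3L) stop("selection resolves to fewer than 3 atoms")
  xyz <- ens$xyz
  # seed with the raw average so an already-aligned ensemble is a fixed point
  # on the first sweep; fall back to frame 1 if that average is degenerate
  ref <- colMeans(xyz)
  ok <- tryCatch({ kabsch_superpose(xyz[1L, ], ref, fit_idx = idx); TRUE },
                 error = function(e) FALSE)
  if (!ok) ref <- xyz[1L, ]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nrow(xyz)))
      xyz[i, ] <- kabsch_superpose(xyz[i, ], ref, fit_idx = idx)$xyz
    avg <- colMeans(xyz)
    delta <- max(abs(avg - ref))
    ref <- avg
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 1L)
    warning("ensemble superposition did not converge within ", max_iter,
            " iterations; returning last iterate")
  ensemble(ens$atom, xyz, frame_times = ens$frame_times,
           topology_key = ens$topology_key)
}

#' Select the centroid frame of a trajectory window
#'
#' The centroid is the frame with minimum RMSD (on the selection, after
#' optimal superposition) to the average structure over the window -- the
#' conventional representative conformation of a trajectory segment. Ties are
#' broken by the earliest frame.
#'
#' @param ens an [ensemble()] (window frames should be mutually superposed).
#' @param window integer vector of frame indices (default: all frames).
#' @param selection [atom_selection()] or mode string.
#' @return list with `frame_index` (within the full ensemble) and `model`
#'   (the centroid [structure_model()]).
#' @export
select_centroid <- function(ens, window = NULL, selection = "calpha") {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(window)) window <- seq_len(n_frames(ens))
  window <- as.integer(window)
  if (!length(window)) stop("empty frame window")
  if (any(window < 1L | window > n_frames(ens)))
    stop("window indices outside the ensemble")
  idx <- select_atoms(ens$atom, selection)
  if (length(idx) < 3L) stop("selection resolves to fewer than 3 atoms")
  avg <- colMeans(ens$xyz[window, , drop = FALSE])
  rms <- vapply(window, function(i)
    kabsch_superpose(ens$xyz[i, ], avg, fit_idx = idx)$rmsd, numeric(1))
  best <- window[which.min(rms)]  # which.min takes the first minimum
  list(frame_index = best, model = get_frame(ens, best))
}

#' Per-residue root mean square fluctuation (RMSF)
#'
#' For each residue, RMSF = sqrt(mean over frames and over the residue's
#' selected atoms of the squared displacement from the atom's time-average
#' position). Global rigid motion is removed first by iterative superposition
#' unless `superpose = FALSE` (for pre-aligned frames).
#'
#' @param ens an [ensemble()].
#' @param selection atoms entering the per-residue statistic
#'   ([atom_selection()] or mode string; default C-alpha, the standard
#'   per-residue flexibility convention).
#' @param superpose remove global rigid motion first?
#' @param source_label free-text label stored on the profile.
#' @param tol,max_iter forwarded to [superpose_ensemble()].
#' @return data.frame of class `rmsf_profile` with columns `residue_number`,
#'   `rmsf` (Angstrom, >= 0).
#' @export
compute_rmsf <- function(ens, selection = "calpha", superpose = TRUE,
                         source_label = "", tol = 1e-4, max_iter = 10L) {
  stopifnot(inherits(ens, "ensemble"))
  if (superpose) ens <- superpose_ensemble(ens, selection, tol, max_iter)
  idx <- select_atoms(ens$atom, selection)
  all_res <- unique(ens$atom$resno)
  if (!length(idx)) stop("selection resolves to zero atoms")
  cols <- xyz_cols(idx)
  sub <- ens$xyz[, cols, drop = FALSE]
  dev <- sweep(sub, 2L, colMeans(sub))
  sq <- dev^2
  # per-atom mean squared displacement: sum x/y/z columns, average over frames
  msf_atom <- colMeans(sq[, seq(1L, ncol(sq), by = 3L), drop = FALSE]) +
    colMeans(sq[, seq(2L, ncol(sq), by = 3L), drop = FALSE]) +
    colMeans(sq[, seq(3L, ncol(sq), by = 3L), drop = FALSE])
  res_of_atom <- ens$atom$resno[idx]
  msf_res <- tapply(msf_atom, res_of_atom, mean)
  resno <- as.integer(names(msf_res))
  omitted <- setdiff(all_res, resno)
  if (length(omitted))
    warning("residue(s) absent from selection omitted from RMSF profile: ",
            paste(head(omitted, 10L), collapse = ", "),
            if (length(omitted) > 10L) ", ...")
  out <- data.frame(residue_number = resno, rmsf = as.numeric(sqrt(msf_res)))
  out <- out[order(out$residue_number), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selection") <- if (is.character(selection)) selection else selection$mode
  attr(out, "source_label") <- source_label
  class(out) <- c("rmsf_profile", "data.frame")
  out
}
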