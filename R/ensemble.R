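# Required columns of the atom table shared by all frames of an ensemble.
ATOM_COLS <- c("serial", "name", "resname", "chain", "resno", "element")

#' Construct a single-conformation structure model
#'
#' A `structure_model` is one conformation of a protein: an atom table plus a
#' flat coordinate vector in Angstrom. It is the unit on which per-frame
#' geometry (hydrogen-bond detection, secondary structure, distances) is
#' computed.
#'
#' @param atom data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `element` (one row per atom, file order preserved).
#' @param xyz numeric vector of length `3 * nrow(atom)`, ordered
#'   x1,y1,z1,x2,...
#' @param model_id integer label for the conformation (e.g. MODEL number).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atom, xyz, model_id = 1L) {
  atom <- normalize_atom_table(atom)
  xyz <- as.numeric(xyz)
  if (nrow(atom) < 1L)
    stop("structure_model must contain at least one atom")
  if (length(xyz) != 3L * nrow(atom))
    stop("xyz length (", length(xyz), ") does not match 3 x ", nrow(atom), " atoms")
  if (!all(is.finite(xyz)))
    stop("all coordinates must be finite")
  check_residue_order(atom)
  structure(list(atom = atom, xyz = xyz, model_id = as.integer(model_id)),
            class = "structure_model")
}

#' Construct a conformational ensemble
#'
#' An `ensemble` is an ordered set of frames sharing one topology (identical
#' atom names, residue numbers and chains in identical order). All flexibility
#' (RMSF), deviation (RMSD) and hydrogen-bond occupancy statistics are defined
#' over an ensemble.
#'
#' @param atom shared atom table (see [structure_model()]).
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param frame_times optional numeric vector of frame times (ps), one per
#'   frame.
#' @param topology_key optional identifier for the shared topology.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(atom, xyz, frame_times = NULL, topology_key = NULL) {
  atom <- normalize_atom_table(atom)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one frame")
  if (ncol(xyz) != 3L * nrow(atom))
    stop("xyz has ", ncol(xyz), " columns; expected 3 x ", nrow(atom), " atoms")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  if (!is.null(frame_times) && length(frame_times) != nrow(xyz))
    stop("frame_times length must equal the number of frames")
  check_residue_order(atom)
  if (is.null(topology_key)) {
    topology_key <- paste0("n", nrow(atom), ":",
                           substr(digest_key(atom), 1L, 12L))
  }
  structure(list(atom = atom, xyz = xyz, frame_times = frame_times,
                 topology_key = topology_key),
            class = "ensemble")
}

# Stable short key for an atom table (dependency-free stand-in for a hash).
digest_key <- function(atom) {
  s <- paste(atom$name, atom$resno, atom$chain, collapse = "|")
  # polynomial rolling checksum, returned as hex
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

normalize_atom_table <- function(atom) {
  atom <- as.data.frame(atom, stringsAsFactors = FALSE)
  if (!"chain" %in% names(atom) || all(is.na(atom$chain)) ||
      all(!nzchar(trimws(as.character(atom$chain)))))
    atom$chain <- "A"  # chain-less input: single-chain convention
  atom$chain[is.na(atom$chain) | !nzchar(trimws(atom$chain))] <- "A"
  if (!"serial" %in% names(atom)) atom$serial <- seq_len(nrow(atom))
  if (!"element" %in% names(atom) || any(is.na(atom$element)) ||
      any(!nzchar(trimws(as.character(atom$element))))) {
    ele <- if ("element" %in% names(atom)) trimws(as.character(atom$element)) else
      rep("", nrow(atom))
    miss <- is.na(ele) | !nzchar(ele)
    ele[miss] <- infer_element(atom$name[miss])
    atom$element <- ele
  }
  atom$element <- toupper(trimws(atom$element))
  if (any(!nzchar(atom$element)))
    stop("could not determine element for atoms: ",
         paste(utils::head(atom$name[!nzchar(atom$element)], 5L), collapse = ", "))
  missing_cols <- setdiff(ATOM_COLS, names(atom))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atom$resno <- as.integer(atom$resno)
  atom$serial <- as.integer(atom$serial)
  atom$name <- trimws(as.character(atom$name))
  atom$resname <- trimws(as.character(atom$resname))
  rownames(atom) <- NULL
  atom[ATOM_COLS]
}

# Infer element symbols from PDB atom names ("CA" -> C, "1HB" -> H, "OXT" -> O).
infer_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9'*]", "", toupper(trimws(nm)))
    if (!nzchar(nm)) return("")
    two <- substr(nm, 1L, 2L)
    if (two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")) return(two)
    substr(nm, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

check_residue_order <- function(atom) {
  for (ch in unique(atom$chain)) {
    r <- atom$resno[atom$chain == ch]
    if (any(diff(r) < 0L))
      stop("residue numbers must be non-decreasing within chain ", ch)
  }
  invisible(TRUE)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: ", nrow(x$atom), " atoms, ",
      length(unique(paste(x$atom$chain, x$atom$resno))), " residues, model_id ",
      x$model_id, "\n", sep = "")
  invisible(x)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble: ", n_frames(x), " frames x ", nrow(x$atom), " atoms (",
      length(unique(paste(x$atom$chain, x$atom$resno))), " residues)\n",
      sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  nrow(x$xyz)
}

#' Extract one frame of an ensemble as a structure model
#' @param x an `ensemble`.
#' @param i frame index (1-based).
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "ensemble"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(x)) stop("frame index out of range: ", i)
  structure_model(x$atom, x$xyz[i, ], model_id = i)
}

#' Assemble an ensemble from structure models
#'
#' All models must share the same (name, residue number, chain) sequence.
#' @param models list of `structure_model` objects.
#' @param frame_times optional frame times (ps).
#' @export
ensemble_from_models <- function(models, frame_times = NULL) {
  if (!length(models)) stop("need at least one model")
  a0 <- models[[1L]]$atom
  for (k in seq_along(models)) {
    a <- models[[k]]$atom
    if (nrow(a) != nrow(a0) ||
        !identical(a$name, a0$name) || !identical(a$resno, a0$resno) ||
        !identical(a$chain, a0$chain))
      stop("topology mismatch: model ", k,
           " does not share the atom sequence of model 1")
  }
  xyz <- do.call(rbind, lapply(models, function(m) m$xyz))
  ensemble(a0, xyz, frame_times = frame_times)
}

# Column indices into a flat xyz vector/matrix for atom indices `idx`.
xyz_cols <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

# n x 3 coordinate matrix for selected atoms from a flat xyz vector.
coords_of <- function(xyz, idx = NULL) {
  m <- matrix(xyz, ncol = 3L, byrow = TRUE)
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

# Flatten an n x 3 coordinate matrix back to x1,y1,z1,... order.
flatten_coords <- function(m) as.vector(t(m))

#' Atom selection for superposition and flexibility metrics
#'
#' @param mode one of `"calpha"`, `"backbone"`, `"heavy"`, `"all"`.
#' @param resno optional integer vector restricting the selection to these
#'   residue numbers.
#' @return object of class `atom_selection`.
#' @export
atom_selection <- function(mode = c("calpha", "backbone", "heavy", "all"),
                           resno = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, resno = if (is.null(resno)) NULL else
    as.integer(resno)), class = "atom_selection")
}

# Resolve an atom_selection (or mode string) to atom indices in `atom`.
select_atoms <- function(atom, selection = atom_selection("calpha")) {
  if (is.character(selection)) selection <- atom_selection(selection)
  stopifnot(inherits(selection, "atom_selection"))
  keep <- switch(selection$mode,
    calpha   = atom$name == "CA" & atom$element == "C",
    backbone = atom$name %in% c("N", "CA", "C", "O") & atom$element != "H",
    heavy    = atom$element != "H",
    all      = rep(TRUE, nrow(atom)))
  if (!is.null(selection$resno)) keep <- keep & atom$resno %in% selection$resno
  which(keep)
}
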