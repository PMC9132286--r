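#' Read a (multi-model) PDB file as a conformational ensemble
#'
#' MODEL/ENDMDL blocks become frames; a file without MODEL records yields a
#' one-frame ensemble. All models must share one topology (same atom count and
#' (name, residue, chain) sequence); a mismatch is a topology error. Parsing
#' is delegated to \pkg{bio3d}; a line-level pre-scan reports malformed ATOM
#' records with their line number and ragged MODEL blocks before parsing.
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb-multimodel"` is supported.
#' @return an [ensemble()].
#' @export
read_ensemble <- function(path, format = "pdb-multimodel") {
  format <- match.arg(format, "pdb-multimodel")
  if (!file.exists(path)) stop("file not found: ", path)
  prescan_pdb(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  atom <- data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
                     chain = ifelse(is.na(at$chain), "A", at$chain),
                     resno = at$resno, element = at$elesy,
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1L)
  ensemble(atom, unclass(xyz))
}

# Validate raw PDB text: coordinate fields must parse and all MODEL blocks
# must carry the same number of atom records.
prescan_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  ati <- which(is_atom)
  for (i in ati) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed ATOM record (too short) at line ", i, " of ", path)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinates in ATOM record at line ", i, " of ", path)
  }
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1L) {
    model_id <- findInterval(ati, model_starts)
    counts <- table(model_id[model_id > 0L])
    if (length(unique(as.integer(counts))) > 1L)
      stop("topology error: MODEL blocks in ", path,
           " contain differing atom counts (",
           paste(as.integer(counts), collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Each frame is written as one MODEL/ENDMDL block (standard PDB coordinate
#' precision, 0.001 Angstrom). Inverse of [read_ensemble()] up to that
#' precision.
#'
#' @param ens an [ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  if (n_frames(ens) < 1L) stop("ensemble has no frames")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  a <- ens$atom
  bio3d::write.pdb(file = path, xyz = ens$xyz, resno = a$resno,
                   resid = a$resname, eleno = a$serial, elety = a$name,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Read a design score table (positions, designed mutants, ddG)
#'
#' Expects tab-separated text with columns region, residue number, distance
#' from the active site (Angstrom), native amino acid, interaction-potential
#' flag, designed mutant and ddG (REU, designed minus wild type; negative =
#' predicted stabilising). `-` marks an absent value and is preserved as `NA`,
#' never as zero.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `design_table` with columns `region_id`,
#'   `residue_number`, `active_site_distance`, `native_aa`,
#'   `has_interaction_potential`, `designed_aa`, `ddG`.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, blank.lines.skip = TRUE)
  if (nrow(raw) == 0L)
    return(empty_design_table())
  if (ncol(raw) < 7L)
    stop("design table needs 7 columns (region, residue number, distance, ",
         "native aa, interaction potential, designed mutant, ddG); got ",
         ncol(raw))
  absent <- function(x) trimws(x) == "-" | trimws(x) == ""
  ddg_chr <- trimws(raw[[7L]])
  bad <- !absent(ddg_chr) & is.na(suppressWarnings(as.numeric(ddg_chr)))
  if (any(bad))
    stop("non-numeric ddG value(s): ",
         paste(unique(ddg_chr[bad]), collapse = ", "))
  out <- data.frame(
    region_id = as.integer(raw[[1L]]),
    residue_number = as.integer(raw[[2L]]),
    active_site_distance = as.numeric(raw[[3L]]),
    native_aa = trimws(raw[[4L]]),
    has_interaction_potential = toupper(trimws(raw[[5L]])) %in% c("YES", "TRUE", "1"),
    designed_aa = ifelse(absent(raw[[6L]]), NA_character_, trimws(raw[[6L]])),
    ddG = ifelse(absent(ddg_chr), NA_real_, suppressWarnings(as.numeric(ddg_chr))),
    stringsAsFactors = FALSE)
  if (any(!is.na(out$ddG) & is.na(out$designed_aa)))
    stop("rows with a ddG value must name a designed amino acid")
  if (any(out$active_site_distance < 0, na.rm = TRUE))
    stop("active-site distances must be non-negative")
  class(out) <- c("design_table", "data.frame")
  out
}

empty_design_table <- function() {
  out <- data.frame(region_id = integer(), residue_number = integer(),
                    active_site_distance = numeric(), native_aa = character(),
                    has_interaction_potential = logical(),
                    designed_aa = character(), ddG = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("design_table", "data.frame")
  out
}

#' Read a flexible-region summary table
#'
#' Columns: region id, residue range (`start-end`), number of residues, mean
#' RMSF (Angstrom) and its spread.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `region_table` with columns `region_id`,
#'   `start_residue`, `end_residue`, `n_residues`, `mean_rmsf`, `sd_rmsf`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  rng <- strsplit(gsub("–", "-", trimws(raw[[2L]])), "-", fixed = TRUE)
  start <- vapply(rng, function(x) as.integer(x[1L]), integer(1))
  end <- vapply(rng, function(x) as.integer(x[2L]), integer(1))
  out <- data.frame(region_id = as.integer(raw[[1L]]), start_residue = start,
                    end_residue = end, n_residues = as.integer(raw[[3L]]),
                    mean_rmsf = as.numeric(raw[[4L]]),
                    sd_rmsf = as.numeric(raw[[5L]]),
                    stringsAsFactors = FALSE)
  bad <- out$n_residues != out$end_residue - out$start_residue + 1L
  if (any(bad))
    stop("region table inconsistency: residue count does not match range for ",
         "region(s) ", paste(out$region_id[bad], collapse = ", "))
  class(out) <- c("region_table", "data.frame")
  out
}

#' Read a mutant delta-RMSF table
#'
#' Columns: region, mutant label, then (mean, sem) pairs per temperature
#' stage; `-` marks mutants not simulated at that stage.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `region_id`, `mutant_label`, `mean_500K`,
#'   `sem_500K`, `mean_313K`, `sem_313K` (`NA` where absent).
#' @export
read_delta_rmsf_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  num <- function(x) ifelse(trimws(x) %in% c("-", ""), NA_real_,
                            suppressWarnings(as.numeric(x)))
  out <- data.frame(region_id = as.integer(raw[[1L]]),
                    mutant_label = trimws(raw[[2L]]),
                    mean_500K = num(raw[[3L]]), sem_500K = num(raw[[4L]]),
                    mean_313K = num(raw[[5L]]), sem_313K = num(raw[[6L]]),
                    stringsAsFactors = FALSE)
  class(out) <- c("delta_rmsf_table", "data.frame")
  out
}

#' Reshape one temperature stage of a delta-RMSF table into screening results
#'
#' @param tab a `delta_rmsf_table` from [read_delta_rmsf_table()].
#' @param stage `"500K"` or `"313K"`.
#' @return data.frame in the shape consumed by [screen_stage()]: columns
#'   `mutant_label`, `temperature_label`, `mean_delta_rmsf`, `sem_delta_rmsf`
#'   (rows without a value at that stage dropped).
#' @export
stage_results <- function(tab, stage = c("500K", "313K")) {
  stage <- match.arg(stage)
  mcol <- paste0("mean_", stage); scol <- paste0("sem_", stage)
  keep <- !is.na(tab[[mcol]])
  data.frame(mutant_label = tab$mutant_label[keep],
             temperature_label = stage,
             mean_delta_rmsf = tab[[mcol]][keep],
             sem_delta_rmsf = tab[[scol]][keep],
             region_id = tab$region_id[keep],
             stringsAsFactors = FALSE)
}

#' Build a hydrogen-bond donor/acceptor topology
#'
#' Donors are N/O heavy atoms with at least one covalently bonded hydrogen
#' (bond inferred by an H-to-heavy distance of at most 1.2 Angstrom, since
#' MD-derived PDB files rarely carry CONECT records); one donor entry per
#' (heavy atom, hydrogen) pair. Acceptors are all N/O atoms.
#'
#' @param model a [structure_model()] containing hydrogens.
#' @param bond_max maximum H-to-heavy covalent bond distance (Angstrom).
#' @return object of class `hbond_topology`: list with `donors` (data.frame
#'   `heavy`, `hydrogen`: atom indices) and `acceptors` (atom indices).
#' @export
build_hbond_topology <- function(model, bond_max = 1.2) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atom
  xyz <- coords_of(model$xyz)
  acceptors <- which(a$element %in% c("N", "O"))
  hyd <- which(a$element == "H")
  donors <- data.frame(heavy = integer(), hydrogen = integer())
  if (!length(hyd)) {
    warning("model contains no hydrogens; donor list is empty and ",
            "hydrogen-bond criteria cannot be evaluated")
  } else if (length(acceptors)) {
    for (h in hyd) {
      d2 <- colSums((t(xyz[acceptors, , drop = FALSE]) - xyz[h, ])^2)
      near <- which(d2 <= bond_max^2)
      if (length(near)) {
        heavy <- acceptors[near[which.min(d2[near])]]
        donors <- rbind(donors, data.frame(heavy = heavy, hydrogen = h))
      }
    }
  }
  structure(list(donors = donors, acceptors = acceptors),
            class = "hbond_topology")
}
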