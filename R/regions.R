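#' Pooled RMSF cutoff for calling highly flexible residues
#'
#' The cutoff is the arithmetic mean of all per-residue RMSF values pooled
#' over every supplied profile (e.g. the three replicate models of a
#' protein): residues fluctuating more than the protein-wide average are the
#' flexibility hotspots.
#'
#' @param profiles a single `rmsf_profile` or a list of them.
#' @param per_model if `TRUE`, return one cutoff per profile instead of the
#'   pooled value.
#' @return cutoff in Angstrom (scalar, or vector if `per_model`).
#' @export
flexibility_cutoff <- function(profiles, per_model = FALSE) {
  profiles <- as_profile_list(profiles)
  if (!length(profiles)) stop("need at least one RMSF profile")
  if (per_model) return(vapply(profiles, function(p) mean(p$rmsf), numeric(1)))
  mean(unlist(lapply(profiles, function(p) p$rmsf)))
}

as_profile_list <- function(profiles) {
  if (inherits(profiles, "rmsf_profile") || is.data.frame(profiles))
    profiles <- list(profiles)
  lapply(profiles, function(p) {
    if (!all(c("residue_number", "rmsf") %in% names(p)))
      stop("an RMSF profile needs columns residue_number and rmsf")
    p
  })
}

#' Flag residues whose RMSF strictly exceeds a cutoff
#'
#' Strictly-greater comparison: residues exactly at the cutoff are not
#' flagged.
#'
#' @param profile an `rmsf_profile`.
#' @param cutoff RMSF cutoff (Angstrom).
#' @return sorted integer vector of flagged residue numbers.
#' @export
flag_flexible_residues <- function(profile, cutoff) {
  stopifnot(is.finite(cutoff))
  profile <- as_profile_list(profile)[[1L]]
  sort(unique(profile$residue_number[profile$rmsf > cutoff]))
}

#' Merge flagged residues into contiguous highly flexible regions
#'
#' Maximal runs of consecutive residue numbers become regions; residues
#' falling inside any exclusion interval (e.g. a natively floppy C-terminus)
#' are dropped before merging. Regions are sorted by start residue and get
#' ids 1..n.
#'
#' @param flagged integer vector of flagged residue numbers.
#' @param exclusion optional exclusion intervals: a list of `c(start, end)`
#'   pairs, a two-column matrix, or a string like `"815-843"` (several may be
#'   comma-separated).
#' @param gap maximum numbering gap still treated as adjacent (default 0:
#'   strictly consecutive residues).
#' @return data.frame of class `flexible_regions` with columns `region_id`,
#'   `start_residue`, `end_residue`, `n_residues` (and `mean_rmsf`/`sd_rmsf`
#'   set to `NA` until [summarize_region()] fills them).
#' @export
merge_into_regions <- function(flagged, exclusion = NULL, gap = 0L) {
  flagged <- sort(unique(as.integer(flagged)))
  for (iv in parse_intervals(exclusion))
    flagged <- flagged[flagged < iv[1L] | flagged > iv[2L]]
  if (!length(flagged)) return(empty_regions())
  brk <- c(0L, which(diff(flagged) > gap + 1L), length(flagged))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(k) {
    run <- flagged[(brk[k] + 1L):brk[k + 1L]]
    data.frame(start_residue = run[1L], end_residue = run[length(run)])
  }))
  out <- data.frame(region_id = seq_len(nrow(out)), out,
                    n_residues = out$end_residue - out$start_residue + 1L,
                    mean_rmsf = NA_real_, sd_rmsf = NA_real_)
  class(out) <- c("flexible_regions", "data.frame")
  out
}

empty_regions <- function() {
  out <- data.frame(region_id = integer(), start_residue = integer(),
                    end_residue = integer(), n_residues = integer(),
                    mean_rmsf = numeric(), sd_rmsf = numeric())
  class(out) <- c("flexible_regions", "data.frame")
  out
}

parse_intervals <- function(x) {
  if (is.null(x)) return(list())
  if (is.character(x)) {
    x <- unlist(strsplit(x, ","))
    return(lapply(x, function(s) {
      p <- as.integer(strsplit(trimws(s), "-")[[1L]])
      if (length(p) != 2L || any(is.na(p)) || p[1L] > p[2L])
        stop("cannot parse interval: ", s)
      p
    }))
  }
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) as.integer(x[i, 1:2])))
  if (is.list(x)) return(lapply(x, function(p) as.integer(p[1:2])))
  list(as.integer(x[1:2]))
}

#' Summarise RMSF statistics over a residue interval
#'
#' With a single profile, `mean_rmsf`/`sd_rmsf` are the mean and sd of the
#' per-residue RMSF values inside the interval. With replicate profiles, the
#' mean is taken on the across-replicate mean profile and the sd is the
#' spread of the region mean across replicates (the role the plus/minus
#' values play in a replicate experiment).
#'
#' @param profile an `rmsf_profile` or list of replicate profiles.
#' @param start_residue,end_residue interval bounds (inclusive).
#' @param region_id id to record on the output row.
#' @return one-row data.frame in the [merge_into_regions()] shape.
#' @export
summarize_region <- function(profile, start_residue, end_residue,
                             region_id = 1L) {
  profiles <- as_profile_list(profile)
  rng <- seq.int(start_residue, end_residue)
  region_vals <- lapply(profiles, function(p) {
    miss <- setdiff(rng, p$residue_number)
    if (length(miss))
      stop("residue(s) missing from profile: ", paste(miss, collapse = ", "))
    p$rmsf[match(rng, p$residue_number)]
  })
  if (length(profiles) == 1L) {
    v <- region_vals[[1L]]
    mean_rmsf <- mean(v); sd_rmsf <- if (length(v) > 1L) sd(v) else 0
  } else {
    rep_means <- vapply(region_vals, mean, numeric(1))
    mean_rmsf <- mean(rep_means); sd_rmsf <- sd(rep_means)
  }
  out <- data.frame(region_id = as.integer(region_id),
                    start_residue = as.integer(start_residue),
                    end_residue = as.integer(end_residue),
                    n_residues = length(rng),
                    mean_rmsf = mean_rmsf, sd_rmsf = sd_rmsf)
  class(out) <- c("flexible_regions", "data.frame")
  out
}

#' Rank flexible regions by mean RMSF and keep the top k
#'
#' Descending by `mean_rmsf`; ties broken by the smaller `region_id`
#' (deterministic).
#'
#' @param regions a `flexible_regions` data.frame with `mean_rmsf` filled in.
#' @param k number of regions to keep (`k = 0` yields an empty table).
#' @return the top-k rows, sorted.
#' @export
rank_regions <- function(regions, k = 5L) {
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative")
  if (k > nrow(regions)) stop("k exceeds the number of regions")
  ord <- order(-regions$mean_rmsf, regions$region_id)
  out <- regions[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum distance from a residue to the catalytic residues
#'
#' Minimum over all atom pairs (any atom of the residue x any atom of any
#' catalytic residue), in Angstrom.
#'
#' @param model a [structure_model()].
#' @param residue_number query residue.
#' @param catalytic_residues integer vector of catalytic residue numbers
#'   (e.g. the two catalytic glutamates of a glycoside hydrolase).
#' @return distance in Angstrom.
#' @export
active_site_distance <- function(model, residue_number, catalytic_residues) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- coords_of(model$xyz)
  qi <- which(model$atom$resno == residue_number)
  ci <- which(model$atom$resno %in% catalytic_residues)
  if (!length(qi)) stop("residue ", residue_number, " not found in model")
  miss <- setdiff(catalytic_residues, model$atom$resno)
  if (length(miss))
    stop("catalytic residue(s) not found in model: ",
         paste(miss, collapse = ", "))
  q <- xyz[qi, , drop = FALSE]; cc <- xyz[ci, , drop = FALSE]
  d2 <- outer(rowSums(q^2), rowSums(cc^2), "+") - 2 * q %*% t(cc)
  sqrt(max(0, min(d2)))
}

#' Designability mask: which region residues are far enough from the active
#' site
#'
#' A residue is designable iff its minimum distance to any catalytic residue
#' is strictly greater than `threshold` ("more than" rule: a residue exactly
#' at the threshold is not designable).
#'
#' @param model a [structure_model()].
#' @param regions a `flexible_regions` table (residues of all listed regions
#'   are evaluated).
#' @param catalytic_residues integer vector of catalytic residue numbers.
#' @param threshold distance threshold in Angstrom (default 15).
#' @return data.frame with columns `residue_number`,
#'   `distance_to_active_site`, `designable`.
#' @export
designability_mask <- function(model, regions, catalytic_residues,
                               threshold = 15) {
  res <- unlist(lapply(seq_len(nrow(regions)), function(i)
    seq.int(regions$start_residue[i], regions$end_residue[i])))
  res <- sort(unique(res))
  if (!length(res))
    return(data.frame(residue_number = integer(),
                      distance_to_active_site = numeric(),
                      designable = logical()))
  d <- vapply(res, function(r)
    active_site_distance(model, r, catalytic_residues), numeric(1))
  data.frame(residue_number = res, distance_to_active_site = d,
             designable = d > threshold)
}
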