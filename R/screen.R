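#' Select designed mutants from a design score table
#'
#' Implements the ddG triage rule: for each designed position keep at most
#' one call -- the substitution with the lowest (best) ddG -- and keep it only
#' if ddG < 0 REU (strictly stabilising relative to wild type). Positions
#' whose designed amino acid is absent or equals the native one are skipped.
#' A tie at one position is resolved to the alphabetically first designed
#' amino acid.
#'
#' @param records a `design_table` ([read_design_table()]).
#' @return data.frame of class `mutant_calls` with columns `label` (e.g.
#'   `"N88Q"`), `region_id`, `residue_number`, `native_aa`, `designed_aa`,
#'   `ddG`; one row per selected mutant, in position order.
#' @export
select_designs <- function(records) {
  need <- c("region_id", "residue_number", "native_aa", "designed_aa", "ddG")
  stopifnot(all(need %in% names(records)))
  cand <- records[!is.na(records$designed_aa) &
                    records$designed_aa != records$native_aa &
                    !is.na(records$ddG), , drop = FALSE]
  key <- paste(cand$residue_number, cand$designed_aa)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      v <- cand$ddG[key == k]
      if (length(unique(v)) > 1L)
        stop("conflicting ddG values for the same substitution: ", k)
    }
    cand <- cand[!duplicated(key), , drop = FALSE]
  }
  keep <- do.call(rbind, lapply(split(cand, cand$residue_number), function(g) {
    g <- g[order(g$ddG, g$designed_aa), , drop = FALSE]  # tie -> alphabetical
    g[1L, , drop = FALSE]
  }))
  keep <- keep[!is.na(keep$ddG) & keep$ddG < 0, , drop = FALSE]
  if (is.null(keep) || nrow(keep) == 0L) {
    out <- data.frame(label = character(), region_id = integer(),
                      residue_number = integer(), native_aa = character(),
                      designed_aa = character(), ddG = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    keep <- keep[order(keep$residue_number), , drop = FALSE]
    out <- data.frame(
      label = paste0(keep$native_aa, keep$residue_number, keep$designed_aa),
      region_id = keep$region_id, residue_number = keep$residue_number,
      native_aa = keep$native_aa, designed_aa = keep$designed_aa,
      ddG = keep$ddG, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("mutant_calls", "data.frame")
  out
}

#' Parse a mutant label like "N88Q"
#'
#' @param label character vector of labels (native aa, position, designed aa).
#' @return data.frame with `native_aa`, `residue_number`, `designed_aa`.
#' @export
parse_mutant_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)([A-Z])$", label))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed mutant label(s): ",
                     paste(label[bad], collapse = ", "))
  data.frame(native_aa = vapply(m, `[`, "", 2L),
             residue_number = as.integer(vapply(m, `[`, "", 3L)),
             designed_aa = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Percent change of region-mean RMSF, mutant relative to wild type
#'
#' `100 * (mean RMSF of the mutant over the region - mean RMSF of the wild
#' type over the region) / (mean RMSF of the wild type over the region)`.
#' Negative values mean the designed region became more rigid.
#'
#' @param mutant_profile,wildtype_profile `rmsf_profile`s covering the
#'   region.
#' @param region one row of a `flexible_regions` table (or anything with
#'   `start_residue`/`end_residue`).
#' @param per_residue if `TRUE`, average the per-residue percent changes
#'   instead of taking percent change of the region means.
#' @return delta-RMSF in percent.
#' @export
region_delta_rmsf <- function(mutant_profile, wildtype_profile, region,
                              per_residue = FALSE) {
  rng <- seq.int(region$start_residue[1L], region$end_residue[1L])
  mv <- profile_values(mutant_profile, rng)
  wv <- profile_values(wildtype_profile, rng)
  if (per_residue) {
    if (any(wv == 0)) stop("wild-type RMSF is zero for some region residues")
    return(mean(100 * (mv - wv) / wv))
  }
  wm <- mean(wv)
  if (wm == 0) stop("wild-type region mean RMSF is zero; delta-RMSF undefined")
  100 * (mean(mv) - wm) / wm
}

profile_values <- function(profile, rng) {
  miss <- setdiff(rng, profile$residue_number)
  if (length(miss))
    stop("profile does not cover residue(s): ", paste(miss, collapse = ", "))
  profile$rmsf[match(rng, profile$residue_number)]
}

#' Replicate-averaged delta-RMSF for one mutant/region
#'
#' Replicates are paired index-wise (replicate i of the mutant against
#' replicate i of the wild type); with unequal counts all pairs are used.
#' Reports the mean and the standard error of the per-pair delta-RMSF values.
#'
#' @param mutant_profiles,wildtype_profiles lists of `rmsf_profile`s (one per
#'   replicate simulation).
#' @param region as in [region_delta_rmsf()].
#' @param mutant_label,temperature_label labels carried into the result.
#' @param threshold pass threshold in percent (strict less-than).
#' @return one-row data.frame with `mutant_label`, `temperature_label`,
#'   `mean_delta_rmsf`, `sem_delta_rmsf`, `passes`.
#' @export
replicate_delta_rmsf <- function(mutant_profiles, wildtype_profiles, region,
                                 mutant_label = "", temperature_label = "",
                                 threshold = -10) {
  mutant_profiles <- as_profile_list(mutant_profiles)
  wildtype_profiles <- as_profile_list(wildtype_profiles)
  if (!length(mutant_profiles) || !length(wildtype_profiles))
    stop("need at least one replicate profile on each side")
  if (length(mutant_profiles) == length(wildtype_profiles)) {
    vals <- mapply(function(m, w) region_delta_rmsf(m, w, region),
                   mutant_profiles, wildtype_profiles)
  } else {
    vals <- as.vector(outer(seq_along(mutant_profiles),
                            seq_along(wildtype_profiles),
                            Vectorize(function(i, j)
                              region_delta_rmsf(mutant_profiles[[i]],
                                                wildtype_profiles[[j]],
                                                region))))
  }
  m <- mean(vals)
  sem <- if (length(vals) > 1L) sd(vals) / sqrt(length(vals)) else 0
  data.frame(mutant_label = mutant_label, temperature_label = temperature_label,
             mean_delta_rmsf = m, sem_delta_rmsf = sem,
             passes = m < threshold, stringsAsFactors = FALSE)
}

#' Screen one stage of the delta-RMSF funnel
#'
#' Keeps the mutants whose mean delta-RMSF is strictly below `threshold`
#' (e.g. -10 percent at the high-temperature stage; 0 percent -- i.e. any
#' rigidification -- at the optimum-temperature stage). Input order is
#' preserved. All rows must come from the same temperature stage.
#'
#' @param results data.frame with columns `mutant_label`,
#'   `temperature_label`, `mean_delta_rmsf` (e.g. from
#'   [replicate_delta_rmsf()] or [stage_results()]).
#' @param threshold pass threshold in percent.
#' @return character vector of passing mutant labels.
#' @export
screen_stage <- function(results, threshold = -10) {
  if (!nrow(results)) return(character())
  if (length(unique(results$temperature_label)) > 1L)
    stop("mixed temperature labels in one screening stage: ",
         paste(unique(results$temperature_label), collapse = ", "))
  results$mutant_label[results$mean_delta_rmsf < threshold]
}
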