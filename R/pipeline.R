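#' Configuration for the screening pipeline
#'
#' Holds the funnel parameters (with the published defaults) and the inputs
#' for either run mode. `"fixture"` mode reproduces the selection logic from
#' tabulated inputs alone: a design score table, a delta-RMSF table and a
#' region table. `"full"` mode computes everything from conformational
#' ensembles: per-stage wild-type and mutant ensembles (objects or PDB
#' paths).
#'
#' @param mode `"fixture"` or `"full"`.
#' @param design_table path to (or data.frame of) the design score table.
#' @param delta_rmsf_table path/data.frame of the per-mutant delta-RMSF
#'   table (fixture mode).
#' @param region_table path/data.frame of the flexible-region table (fixture
#'   mode; optional in full mode, where regions are detected from the
#'   wild-type ensembles).
#' @param ensembles full mode: named list, one entry per temperature stage in
#'   screening order; each entry a list with `wildtype` (list of ensembles or
#'   PDB paths) and `mutants` (named list: mutant label -> list of replicate
#'   ensembles/paths).
#' @param stage_thresholds pass thresholds (percent) per stage, in stage
#'   order. Defaults: -10 (high-temperature screen), 0 (any rigidification at
#'   the optimum temperature).
#' @param top_k number of top-ranked regions carried into design.
#' @param catalytic_residues residue numbers of the catalytic residues.
#' @param min_active_site_distance designability threshold (Angstrom,
#'   strict "more than").
#' @param exclusion residue intervals excluded from region calling (e.g. a
#'   floppy C-terminus), as in [merge_into_regions()].
#' @param selection RMSF atom selection mode.
#' @param explain in full mode, add hydrogen-bond and secondary-structure
#'   summaries for the final-stage survivors.
#' @param seed integer seed recorded in the report (and used by any
#'   stochastic step).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("fixture", "full"),
                            design_table = NULL,
                            delta_rmsf_table = NULL,
                            region_table = NULL,
                            ensembles = NULL,
                            stage_thresholds = c("500K" = -10, "313K" = 0),
                            top_k = 5L,
                            catalytic_residues = c(442L, 712L),
                            min_active_site_distance = 15,
                            exclusion = NULL,
                            selection = "calpha",
                            explain = FALSE,
                            seed = 1L) {
  mode <- match.arg(mode)
  fixture_default <- function(x, fname) {
    if (!is.null(x)) return(x)
    system.file("extdata", fname, package = "flexiscreen", mustWork = TRUE)
  }
  if (mode == "fixture") {
    design_table <- fixture_default(design_table, "design_ddg_table.tsv")
    delta_rmsf_table <- fixture_default(delta_rmsf_table,
                                        "mutant_delta_rmsf.tsv")
    region_table <- fixture_default(region_table,
                                    "wildtype_flexible_regions.tsv")
  } else if (is.null(ensembles)) {
    stop("full mode requires per-stage ensembles")
  }
  stopifnot(is.finite(stage_thresholds), is.finite(top_k),
            is.finite(min_active_site_distance))
  structure(list(mode = mode, design_table = design_table,
                 delta_rmsf_table = delta_rmsf_table,
                 region_table = region_table, ensembles = ensembles,
                 stage_thresholds = stage_thresholds, top_k = as.integer(top_k),
                 catalytic_residues = as.integer(catalytic_residues),
                 min_active_site_distance = min_active_site_distance,
                 exclusion = exclusion, selection = selection,
                 explain = isTRUE(explain), seed = as.integer(seed)),
            class = "pipeline_config")
}

as_table <- function(x, reader) if (is.character(x)) reader(x) else x

as_ensemble_input <- function(x) {
  if (inherits(x, "ensemble")) return(x)
  if (is.character(x)) return(read_ensemble(x))
  stop("expected an ensemble or a PDB path")
}

#' Run the full screening funnel
#'
#' Fixture mode: regions are ranked from the region table, designed mutants
#' are selected from the design table (best ddG per position, ddG < 0), and
#' the staged delta-RMSF screen is applied to the delta-RMSF table. Full
#' mode: per-residue RMSF profiles are computed from the stage-1 wild-type
#' ensembles, highly flexible regions are detected and ranked, each mutant's
#' region delta-RMSF is measured against the wild type at every stage, and
#' survivors are carried forward; optional hydrogen-bond and
#' secondary-structure comparisons explain the final calls.
#'
#' Deterministic given inputs and seed; every stage's intermediate is kept on
#' the report.
#'
#' @param config a [pipeline_config()].
#' @return object of class `screening_report`: list with `stages`, `counts`,
#'   `pass` lists, result tables and provenance.
#' @seealso [write_report()]
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- if (config$mode == "fixture") run_fixture_pipeline(config)
            else run_full_pipeline(config)
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("flexiscreen")),
    mode = config$mode, seed = config$seed,
    config_key = digest_key(data.frame(
      name = "cfg", resno = config$seed,
      chain = paste(config$mode, config$top_k,
                    paste(config$stage_thresholds, collapse = ",")))))
  class(report) <- "screening_report"
  report
}

run_fixture_pipeline <- function(config) {
  regions <- as_table(config$region_table, read_region_table)
  designs <- as_table(config$design_table, read_design_table)
  drt <- as_table(config$delta_rmsf_table, read_delta_rmsf_table)
  top <- rank_regions(regions, min(config$top_k, nrow(regions)))
  calls <- select_designs(designs)
  calls <- calls[calls$region_id %in% top$region_id, , drop = FALSE]
  stage_names <- names(config$stage_thresholds)
  if (is.null(stage_names)) stage_names <- paste0("stage", seq_along(config$stage_thresholds))
  stages <- list(); surviving <- calls$label
  for (s in seq_along(config$stage_thresholds)) {
    sres <- stage_results(drt, stage_names[s])
    sres <- sres[sres$mutant_label %in% surviving, , drop = FALSE]
    pass <- screen_stage(sres, config$stage_thresholds[[s]])
    stages[[stage_names[s]]] <- list(threshold = config$stage_thresholds[[s]],
                                     results = sres, pass = pass,
                                     n_in = nrow(sres), n_pass = length(pass))
    surviving <- pass
  }
  list(mode = "fixture",
       regions = regions, top_regions = top, design_calls = calls,
       stages = stages,
       counts = c(n_regions = nrow(regions), n_top_regions = nrow(top),
                  n_design_rows = nrow(designs),
                  n_mutant_calls = nrow(calls),
                  setNames(vapply(stages, function(x) x$n_pass, integer(1)),
                           paste0("n_pass_", names(stages)))),
       final_pass = surviving)
}

run_full_pipeline <- function(config) {
  stage_names <- names(config$ensembles)
  if (is.null(stage_names)) stop("ensembles must be a named per-stage list")
  if (length(config$stage_thresholds) != length(stage_names))
    stop("one threshold per stage is required")
  # stage 1 wild type defines the flexible regions
  st1 <- config$ensembles[[1L]]
  wt1 <- lapply(st1$wildtype, as_ensemble_input)
  wt_profiles <- lapply(wt1, compute_rmsf, selection = config$selection)
  if (!is.null(config$region_table)) {
    regions <- as_table(config$region_table, read_region_table)
  } else {
    cutoff <- flexibility_cutoff(wt_profiles)
    mean_prof <- pool_profiles(wt_profiles)
    flagged <- flag_flexible_residues(mean_prof, cutoff)
    regions <- merge_into_regions(flagged, exclusion = config$exclusion)
    if (nrow(regions))
      regions <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
        summarize_region(wt_profiles, regions$start_residue[i],
                         regions$end_residue[i], region_id = i)))
  }
  top <- rank_regions(regions, min(config$top_k, nrow(regions)))
  stages <- list()
  surviving <- names(config$ensembles[[1L]]$mutants)
  for (s in seq_along(stage_names)) {
    st <- config$ensembles[[s]]
    wt_prof <- lapply(lapply(st$wildtype, as_ensemble_input),
                      compute_rmsf, selection = config$selection)
    rows <- list()
    for (lab in intersect(names(st$mutants), surviving)) {
      pos <- parse_mutant_label(lab)$residue_number
      reg <- top[top$start_residue <= pos & top$end_residue >= pos, ,
                 drop = FALSE]
      if (!nrow(reg)) {
        warning("mutant ", lab, " lies in no ranked flexible region; dropped")
        next
      }
      mut_prof <- lapply(lapply(st$mutants[[lab]], as_ensemble_input),
                         compute_rmsf, selection = config$selection)
      rows[[lab]] <- replicate_delta_rmsf(
        mut_prof, wt_prof, reg[1L, ], mutant_label = lab,
        temperature_label = stage_names[s],
        threshold = config$stage_thresholds[[s]])
    }
    sres <- if (length(rows)) do.call(rbind, rows) else
      data.frame(mutant_label = character(), temperature_label = character(),
                 mean_delta_rmsf = numeric(), sem_delta_rmsf = numeric(),
                 passes = logical())
    rownames(sres) <- NULL
    pass <- screen_stage(sres, config$stage_thresholds[[s]])
    stages[[stage_names[s]]] <- list(threshold = config$stage_thresholds[[s]],
                                     results = sres, pass = pass,
                                     n_in = nrow(sres), n_pass = length(pass))
    surviving <- pass
  }
  report <- list(mode = "full", regions = regions, top_regions = top,
                 stages = stages,
                 counts = c(n_regions = nrow(regions),
                            n_top_regions = nrow(top),
                            setNames(vapply(stages, function(x) x$n_pass,
                                            integer(1)),
                                     paste0("n_pass_", names(stages)))),
                 final_pass = surviving)
  if (config$explain && length(surviving)) {
    last <- config$ensembles[[length(config$ensembles)]]
    wt_ens <- as_ensemble_input(last$wildtype[[1L]])
    wt_topo <- build_hbond_topology(get_frame(wt_ens, 1L))
    explain <- list()
    for (lab in surviving) {
      pos <- parse_mutant_label(lab)$residue_number
      reg <- top[top$start_residue <= pos & top$end_residue >= pos, ,
                 drop = FALSE][1L, ]
      mut_ens <- as_ensemble_input(last$mutants[[lab]][[1L]])
      mut_topo <- build_hbond_topology(get_frame(mut_ens, 1L))
      wt_sum <- region_hbond_summary(
        hbond_occupancy(wt_ens, wt_topo, min_occupancy = 10), reg)
      mut_sum <- region_hbond_summary(
        hbond_occupancy(mut_ens, mut_topo, min_occupancy = 10), reg)
      explain[[lab]] <- list(
        region_id = reg$region_id,
        hbond_wildtype = wt_sum, hbond_mutant = mut_sum,
        hbond_delta = diff_hbond_reports(wt_sum, mut_sum),
        secstruct_wildtype = region_secstruct_percentages(wt_ens, reg),
        secstruct_mutant = region_secstruct_percentages(mut_ens, reg))
    }
    report$explain <- explain
  }
  report
}

# Across-replicate mean RMSF profile (residues common to all replicates).
pool_profiles <- function(profiles) {
  profiles <- as_profile_list(profiles)
  res <- Reduce(intersect, lapply(profiles, function(p) p$residue_number))
  vals <- vapply(profiles, function(p) p$rmsf[match(res, p$residue_number)],
                 numeric(length(res)))
  out <- data.frame(residue_number = res,
                    rmsf = if (length(profiles) == 1L) as.numeric(vals)
                           else rowMeans(vals))
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report (", x$mode, " mode)\n", sep = "")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  for (s in names(x$stages))
    cat("  stage ", s, " (threshold ", x$stages[[s]]$threshold, "%): ",
        x$stages[[s]]$n_in, " in -> ", x$stages[[s]]$n_pass, " pass\n",
        sep = "")
  cat("  final pass:", if (length(x$final_pass))
    paste(x$final_pass, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Serialise a screening report to JSON and TSV tables
#'
#' Writes `report.json` (counts, thresholds, pass lists, provenance) plus one
#' TSV per result table into `dir`. Output is a pure function of the report
#' (no timestamps), so re-running an identical configuration reproduces
#' byte-identical files.
#'
#' @param report a `screening_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "screening_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) write.table(
    df, file.path(dir, paste0(name, ".tsv")), sep = "\t", row.names = FALSE,
    quote = FALSE)
  if (!is.null(report$regions)) tsv(report$regions, "regions")
  if (!is.null(report$top_regions)) tsv(report$top_regions, "top_regions")
  if (!is.null(report$design_calls)) tsv(report$design_calls, "mutant_calls")
  for (s in names(report$stages))
    tsv(report$stages[[s]]$results, paste0("stage_", s))
  js <- list(mode = report$mode, counts = as.list(report$counts),
             stages = lapply(report$stages, function(x)
               list(threshold = x$threshold, n_in = x$n_in,
                    n_pass = x$n_pass, pass = x$pass)),
             final_pass = report$final_pass,
             provenance = report$provenance)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
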