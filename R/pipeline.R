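# deterministic per-stage seed derived from the global seed and stage name,
# so toggling one stage never perturbs another stage's random stream
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 2654435L + h * 97L) %% 2147483647)
}

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one list. Either a
#' generator specification (`specs`) or an input cohort CSV (`cohort_path`,
#' with optional `truth_path`) must be supplied. All stage parameters are
#' serialised into the run manifest so a run can be reproduced from the
#' manifest alone.
#'
#' @param specs list of [group_spec()] objects for the synthetic generator,
#'   or NULL when reading a cohort from disk.
#' @param cohort_path,truth_path input CSVs (used when `specs` is NULL).
#' @param roles factor roles, see [default_roles()].
#' @param k `"elbow"` or an integer number of groups.
#' @param k_max largest k scanned by the elbow.
#' @param missing_rate,rai_weights generator settings, see
#'   [generate_cohort()].
#' @param iterations,pmm_k imputation settings.
#' @param stability_B,stability_scheme resampling settings, see
#'   [resample_stability()].
#' @param n_perm permutations for the Kruskal-Wallis permutation test.
#' @param do_motility simulate trajectories and compute motility metrics.
#' @param n_cells_per_group trajectories per group when `do_motility`.
#' @param lattice_args arguments for [lattice()].
#' @param stop_min_duration,stop_tolerance stop-detection settings, minutes
#'   and micrometres.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(specs = default_group_specs(),
                            cohort_path = NULL, truth_path = NULL,
                            roles = default_roles(),
                            k = "elbow", k_max = 8L,
                            missing_rate = 0.05,
                            rai_weights = c(0.20, 0.25, 0.25, 0.20, 0.10),
                            iterations = 10L, pmm_k = 5L,
                            stability_B = 500L,
                            stability_scheme = c("bootstrap", "subsample90"),
                            n_perm = 1e5,
                            do_motility = FALSE, n_cells_per_group = 25L,
                            lattice_args = list(),
                            stop_min_duration = 3, stop_tolerance = 2) {
  if (is.null(specs) && is.null(cohort_path))
    stop("either a generator spec or a cohort path is required")
  structure(list(specs = specs, cohort_path = cohort_path,
                 truth_path = truth_path, roles = roles, k = k,
                 k_max = as.integer(k_max), missing_rate = missing_rate,
                 rai_weights = rai_weights, iterations = as.integer(iterations),
                 pmm_k = as.integer(pmm_k),
                 stability_B = as.integer(stability_B),
                 stability_scheme = match.arg(stability_scheme,
                                              several.ok = TRUE),
                 n_perm = n_perm, do_motility = isTRUE(do_motility),
                 n_cells_per_group = as.integer(n_cells_per_group),
                 lattice_args = lattice_args,
                 stop_min_duration = stop_min_duration,
                 stop_tolerance = stop_tolerance),
            class = "pipeline_config")
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full stratification pipeline
#'
#' Executes the stage sequence — cohort generation or ingestion, optional
#' trajectory simulation and motility metrics, imputation, FAMD,
#' equal-contribution factor selection, k-medoids grouping, resampling
#' stability, and group statistics — writing one CSV per stage output plus
#' a machine-readable JSON manifest (configuration, seed, per-stage seeds,
#' package and R versions, and an MD5 checksum of every output file) into
#' `output_dir`. Any stage failure aborts with the stage name and cause;
#' outputs written so far are retained next to a `FAILED` marker naming the
#' stage. Identical configuration and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir run directory (created; must be empty or absent).
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @return (invisibly) a list with the `stratification`, the stability
#'   reports, the stats tables, the motility summary (or NULL), and the
#'   manifest path.
#' @export
run_pipeline <- function(config, output_dir, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- character()
  stage <- "init"
  fail <- function(e) {
    writeLines(sprintf("stage %s: %s", stage, conditionMessage(e)),
               file.path(output_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    ## ---- cohort ----
    stage <- "cohort"
    if (!is.null(config$cohort_path)) {
      if (!file.exists(config$cohort_path))
        stop(sprintf("input cohort '%s' not found", config$cohort_path))
      cohort <- read_cohort(config$cohort_path, config$truth_path)
    } else {
      cohort <- generate_cohort(config$specs, config$rai_weights,
                                config$missing_rate,
                                seed = stage_seed(seed, "cohort"))
    }
    files["cohort"] <- write_stage_csv(cohort$table, output_dir, "cohort.csv")
    if (!is.null(cohort$truth))
      files["truth"] <- write_stage_csv(cohort$truth, output_dir,
                                        "cohort_truth.csv")

    ## ---- motility (optional) ----
    motility <- NULL
    if (config$do_motility) {
      stage <- "motility"
      lat <- do.call(lattice, config$lattice_args)
      specs <- if (!is.null(config$specs)) config$specs else
        default_group_specs()
      trajs <- list()
      for (i in seq_along(specs)) {
        sp <- specs[[i]]
        trajs <- c(trajs, simulate_trajectories(
          sp, lat, n_cells = config$n_cells_per_group,
          seed = stage_seed(seed, paste0("motility", i)),
          donor_id = paste0("sim_", sp$label)))
      }
      files["trajectories"] <- file.path(output_dir, "trajectories.csv")
      write_trajectories(trajs, files["trajectories"])
      motility <- summarize_motility(trajs, lat, config$stop_min_duration,
                                     config$stop_tolerance)
      files["motility_cells"] <- write_stage_csv(motility$cells, output_dir,
                                                 "motility_cells.csv")
      files["motility_summary"] <- write_stage_csv(motility$summary,
                                                   output_dir,
                                                   "motility_summary.csv")
    }

    ## ---- impute + famd + select + cluster ----
    stage <- "stratify"
    strat <- stratify_donors(cohort$table, roles = config$roles,
                             k = config$k, k_max = config$k_max,
                             iterations = config$iterations,
                             pmm_k = config$pmm_k,
                             seed = stage_seed(seed, "impute"))
    files["imputed"] <- write_stage_csv(strat$completed, output_dir,
                                        "imputed.csv")
    files["impute_flags"] <- write_stage_csv(
      cbind(donor_id = rownames(strat$imputation$flags),
            strat$imputation$flags),
      output_dir, "impute_flags.csv")
    ft <- strat$famd
    files["scree"] <- write_stage_csv(
      data.frame(dimension = seq_along(ft$eigenvalues),
                 eigenvalue = ft$eigenvalues,
                 variance_pct = ft$variance_pct),
      output_dir, "scree.csv")
    files["contributions"] <- write_stage_csv(
      data.frame(factor = rownames(ft$contrib),
                 dim1_pct = ft$contrib[, 1], dim2_pct = ft$contrib[, 2],
                 dim12_pct = strat$contrib12,
                 threshold_pct = strat$selection$threshold_pct,
                 selected = rownames(ft$contrib) %in%
                   strat$selection$selected),
      output_dir, "contributions.csv")
    files["scores"] <- write_stage_csv(
      data.frame(donor_id = rownames(ft$scores),
                 dim1 = ft$scores[, 1], dim2 = ft$scores[, 2]),
      output_dir, "scores.csv")
    if (!is.null(strat$elbow_curve))
      files["cost_curve"] <- write_stage_csv(strat$elbow_curve, output_dir,
                                             "cost_curve.csv")
    files["assignments"] <- write_stage_csv(
      data.frame(donor_id = names(strat$assignments),
                 group = strat$assignments,
                 medoid = names(strat$assignments) %in%
                   strat$clustering$medoids),
      output_dir, "assignments.csv")

    ## ---- stability ----
    stage <- "stability"
    stability <- list()
    for (sc in config$stability_scheme) {
      rep <- resample_stability(cohort$table, scheme = sc,
                                B = config$stability_B,
                                roles = config$roles, k_ref = strat$k,
                                iterations = config$iterations,
                                pmm_k = config$pmm_k,
                                seed = stage_seed(seed, paste0("stab_", sc)),
                                reference = strat)
      stability[[sc]] <- rep
      freq <- data.frame(donor_id = rownames(rep$freq), rep$freq,
                         appearances = rep$appearances,
                         check.names = FALSE)
      names(freq)[2:(1 + strat$k)] <- paste0("freq_group", seq_len(strat$k))
      files[paste0("stability_", sc)] <- write_stage_csv(
        freq, output_dir, paste0("stability_", sc, ".csv"))
    }
    boot <- stability[[config$stability_scheme[1]]]
    files["stability_summary"] <- write_stage_csv(
      data.frame(scheme = names(stability),
                 B = vapply(stability, `[[`, 0L, "B"),
                 B_used = vapply(stability, `[[`, 0L, "B_used"),
                 dim12_ci_lower = vapply(stability, function(s) s$dim12_ci[1], 0),
                 dim12_ci_upper = vapply(stability, function(s) s$dim12_ci[2], 0),
                 min_modal_frequency = vapply(stability, function(s)
                   min(s$modal$frequency), 0)),
      output_dir, "stability_summary.csv")

    ## ---- stats ----
    stage <- "stats"
    comp <- strat$completed
    cll <- comp[comp$status == "cll", , drop = FALSE]
    grp <- as.character(strat$assignments[cll$donor_id])
    kw <- kruskal_wallis_perm(cll$max_doublings, cll$rai,
                              N = config$n_perm,
                              seed = stage_seed(seed, "stats"))
    t_sex <- ttest2(cll$max_doublings[cll$sex == "M"],
                    cll$max_doublings[cll$sex == "F"])
    t_igvh <- ttest2(cll$max_doublings[cll$igvh == "mutated"],
                     cll$max_doublings[cll$igvh == "unmutated"])
    all_groups <- c(grp, rep("healthy", sum(comp$status == "healthy")))
    healthy <- comp[comp$status == "healthy", , drop = FALSE]
    stats_rows <- list(data.frame(
      test = c("kw_perm_doublings_vs_rai", "ttest_doublings_sex",
               "ttest_doublings_igvh"),
      statistic = c(kw$statistic, t_sex$statistic, t_igvh$statistic),
      p_value = c(kw$p_value, t_sex$p_value, t_igvh$p_value),
      stringsAsFactors = FALSE))
    comparisons <- list()
    for (v in c("max_doublings", "pd1_pct", "alignment_pct", "il2")) {
      gc <- anova_tukey(c(cll[[v]], healthy[[v]]), all_groups)
      comparisons[[v]] <- gc
      stats_rows[[v]] <- data.frame(
        test = paste0("anova_", v, "_by_group"),
        statistic = gc$F, p_value = gc$p_anova, stringsAsFactors = FALSE)
    }
    files["stats"] <- write_stage_csv(do.call(rbind, stats_rows),
                                      output_dir, "stats_summary.csv")
    pairwise <- do.call(rbind, lapply(names(comparisons), function(v)
      cbind(variable = v, comparisons[[v]]$pairwise)))
    files["tukey"] <- write_stage_csv(pairwise, output_dir,
                                      "tukey_pairwise.csv")
    if (nrow(healthy) >= 2) {
      des <- pd1_designation(healthy$pd1_pct, cll$pd1_pct)
      files["pd1"] <- write_stage_csv(
        data.frame(donor_id = cll$donor_id, pd1_pct = cll$pd1_pct,
                   designation = as.character(des),
                   healthy_upper = attr(des, "upper")),
        output_dir, "pd1_designation.csv")
    }

    ## ---- manifest ----
    stage <- "manifest"
    manifest <- list(
      package = "cllstrat",
      version = as.character(utils::packageVersion("cllstrat")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = as.integer(seed),
      config = config_to_manifest(config),
      checksums = as.list(tools::md5sum(unname(files))))
    manifest_path <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(stratification = strat, stability = stability,
                   stats = list(kw_rai = kw, ttest_sex = t_sex,
                                ttest_igvh = t_igvh,
                                comparisons = comparisons),
                   motility = motility, manifest = manifest_path,
                   files = files, output_dir = output_dir))
  }, error = fail)
}

# flatten the config into JSON-serialisable values
config_to_manifest <- function(config) {
  out <- unclass(config)
  out$specs <- lapply(out$specs, unclass)
  out$roles <- out$roles
  out
}
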