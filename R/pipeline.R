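# End-to-end orchestration: classification report, expert sensitivity
# comparison, and simulation study. Each run writes versioned CSV/JSON
# outputs plus a manifest (configuration hash, seed, package version) so a
# rerun with an identical manifest reproduces identical outputs.

write_manifest <- function(out_dir, cfg, extra = list()) {
  manifest <- c(list(
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("alcpolicy")),
    seed = cfg$seed %||% NA
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    abort(sprintf("output directory %s is not empty (use force = TRUE)",
                  out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
}

#' Run the objective classification pipeline
#'
#' Classifies a policy timeline against an economic series, builds the
#' cumulative score series, and writes `tiers.csv`, `score.csv`,
#' `affordability.csv`, a human-readable `summary.txt` listing the criteria
#' fired per event, and a `manifest.json`.
#'
#' @param timeline_path Path to a timeline CSV/JSON (see [read_timeline()]).
#' @param economy_path Path to an economic index CSV (see
#'   [read_economic_series()]).
#' @param out_dir Output directory.
#' @param window A [study_window()]. Default Jan 2000 - Dec 2019.
#' @param threshold Affordability threshold percent. Default 5.
#' @param base_year Economic base year. Default 2010.
#' @param force Overwrite a non-empty output directory. Default `FALSE`.
#' @return Invisibly, a list with `tiers`, `score`, `affordability`,
#'   `manifest`.
#' @export
run_classification <- function(timeline_path, economy_path, out_dir,
                               window = study_window("2000-01", "2019-12"),
                               threshold = 5, base_year = 2010,
                               force = FALSE) {
  if (!file.exists(economy_path)) {
    abort(sprintf("economy file not found: %s", economy_path))
  }
  timeline <- read_timeline(timeline_path)
  econ <- read_economic_series(economy_path, base_year = base_year)
  prepare_out_dir(out_dir, force)

  aff <- affordability_index(econ, base_year = base_year,
                             threshold = threshold)
  tiers <- classify_tiers(timeline, econ, window, threshold = threshold)
  score <- cumulative_score(tiers, window)

  readr::write_csv(tiers, file.path(out_dir, "tiers.csv"))
  readr::write_csv(score, file.path(out_dir, "score.csv"))
  readr::write_csv(aff, file.path(out_dir, "affordability.csv"))

  lines <- c(
    sprintf("Classification of %d policy events, window %s..%s",
            nrow(tiers), format(window$start, "%Y-%m"),
            format(window$end, "%Y-%m")),
    "",
    "Tier 1 (weight 1.0):",
    summary_lines(tiers, "tier1"),
    "",
    "Tier 2 only (weight 0.5):",
    summary_lines(tiers, "tier2_only"),
    "",
    "Specific-population (not scored):",
    summary_lines(tiers, "specific"),
    "",
    "Excluded:",
    summary_lines(tiers, "excluded"),
    "",
    sprintf("Final cumulative score (%s): %.1f",
            format(window$end, "%Y-%m"), dplyr::last(score$score))
  )
  writeLines(lines, file.path(out_dir, "summary.txt"))

  cfg <- list(timeline = timeline, econ = econ,
              window = unclass(window), threshold = threshold,
              base_year = base_year)
  manifest <- write_manifest(out_dir, cfg,
                             extra = list(n_events = nrow(tiers),
                                          final_score = dplyr::last(score$score)))
  invisible(list(tiers = tiers, score = score, affordability = aff,
                 manifest = manifest))
}

summary_lines <- function(tiers, level) {
  rows <- dplyr::filter(tiers, .data$tier == level)
  if (nrow(rows) == 0) return("  (none)")
  sprintf("  %s  %s  [%s]", rows$event_id, format(rows$date),
          rows$criteria_fired)
}

#' Run the expert-rating sensitivity pipeline
#'
#' Aggregates an expert rating table, computes reliability statistics
#' (ICC, pairwise Spearman), selects dates by the mean-rating threshold,
#' compares them with the objective tier selection, and writes
#' `reliability.json` plus a `manifest.json`.
#'
#' @param ratings_path Path to a rating CSV (items in rows, one numeric
#'   column per rater, `event_id` column).
#' @inheritParams run_classification
#' @param rating_threshold Mean-rating selection cutoff. Default 5.
#' @return Invisibly, a list with `reliability`, `selected_dates`,
#'   `concordance`, `manifest`.
#' @export
run_sensitivity <- function(ratings_path, timeline_path, economy_path,
                            out_dir,
                            window = study_window("2000-01", "2019-12"),
                            threshold = 5, rating_threshold = 5,
                            base_year = 2010, force = FALSE) {
  if (!file.exists(ratings_path)) {
    abort(sprintf("ratings file not found: %s", ratings_path))
  }
  ratings <- readr::read_csv(ratings_path, show_col_types = FALSE)
  timeline <- read_timeline(timeline_path)
  econ <- read_economic_series(economy_path, base_year = base_year)
  prepare_out_dir(out_dir, force)

  rel <- icc(ratings)
  sp <- spearman_summary(ratings)
  selected <- select_dates(ratings, timeline, threshold = rating_threshold)
  tiers <- classify_tiers(timeline, econ, window, threshold = threshold)
  conc <- rating_concordance(selected, tiers)

  report <- list(
    icc = as.list(rel),
    spearman = list(median = sp$median, iqr = sp$iqr,
                    n_pairs = nrow(sp$pairs), dropped = sp$dropped_pairs),
    selected_dates = format(selected),
    concordance = list(
      in_both = format(conc$in_both),
      expert_only = format(conc$expert_only),
      criteria_only = format(conc$criteria_only),
      expert_superset = conc$expert_superset
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "reliability.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(ratings = ratings, timeline = timeline, econ = econ,
              window = unclass(window), threshold = threshold,
              rating_threshold = rating_threshold)
  manifest <- write_manifest(out_dir, cfg)
  invisible(list(reliability = rel, spearman = sp, selected_dates = selected,
                 concordance = conc, manifest = manifest))
}

#' Run a simulation study of the ITS estimator
#'
#' Repeatedly simulates outcome series from a [simulation_config()] with
#' fresh noise, refits the segmented regression, and tabulates bias, RMSE,
#' and confidence-interval coverage per intervention effect. Writes
#' `recovery.csv` and `manifest.json` when `out_dir` is given.
#'
#' @param config A [simulation_config()] with at least one intervention.
#' @param n_reps Number of replicates. Default 200.
#' @param ar1 Fit with AR(1) correction. Default `TRUE`.
#' @param out_dir Optional output directory.
#' @param force Overwrite a non-empty output directory. Default `FALSE`.
#' @return A tibble, one row per intervention: `name`, `true_effect`,
#'   `mean_estimate`, `bias`, `mc_se`, `rmse`, `ci_coverage`, `n_reps`.
#' @export
run_simulation_study <- function(config, n_reps = 200, ar1 = TRUE,
                                 out_dir = NULL, force = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  iv <- config$interventions
  if (nrow(iv) == 0) abort("config must contain at least one intervention")
  specs <- intervention_spec(iv$date, shape = iv$shape,
                             lag_months = iv$lag_months)

  rep_seeds <- with_stream_seed(config$seed, "study", {
    sample.int(2^31 - 2, n_reps)
  })
  one_rep <- function(s) {
    cfg <- config
    cfg$seed <- s
    fit <- fit_its(simulate_outcome(cfg), specs, ar1 = ar1)
    eff <- fit$effects
    tibble(name = eff$term, estimate = eff$estimate,
           covered = eff$conf_low <= iv$true_effect &
             iv$true_effect <= eff$conf_high)
  }
  draws <- purrr::map_dfr(rep_seeds, one_rep)
  out <- draws |>
    group_by(.data$name) |>
    summarise(mean_estimate = mean(.data$estimate),
              sd_estimate = sd(.data$estimate),
              ci_coverage = mean(.data$covered), .groups = "drop") |>
    left_join(tibble(name = specs$name, true_effect = iv$true_effect),
              by = "name") |>
    mutate(bias = .data$mean_estimate - .data$true_effect,
           mc_se = .data$sd_estimate / sqrt(n_reps),
           n_reps = n_reps) |>
    select("name", "true_effect", "mean_estimate", "bias", "mc_se",
           "sd_estimate", "ci_coverage", "n_reps")
  out$rmse <- sqrt(out$bias^2 + out$sd_estimate^2 * (n_reps - 1) / n_reps)

  if (!is.null(out_dir)) {
    prepare_out_dir(out_dir, force)
    readr::write_csv(out, file.path(out_dir, "recovery.csv"))
    write_manifest(out_dir, list(config = unclass(config), n_reps = n_reps,
                                 ar1 = ar1, seed = config$seed))
  }
  out
}
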