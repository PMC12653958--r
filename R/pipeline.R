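#' Run the full per-trial contact + failure pipeline over a cohort
#'
#' For every trial: converts the peak medial force to newtons, solves
#' the elastic-foundation contact problem at the trial's flexion angle,
#' derives the damage-driving strain, computes cumulative load, daily
#' loading cycles, time to failure and the lifetime failure
#' probabilities with and without repair; then aggregates trial ->
#' participant -> condition (the repeated-measures order), fits the
#' mixed-effects comparison for each outcome, and averages the failure
#' time series per condition.
#'
#' Trials whose contact solve fails are quarantined (their outcome
#' columns set to `NA`) and reported in `quarantined`, not fatal.
#'
#' @param cohort Cohort data frame from [generate_cohort()] or
#'   [read_cohort()].
#' @param geometry A [knee_geometry()] object.
#' @param material A [cartilage_material()] object.
#' @param params A [failure_params()] object.
#' @param outcomes Outcome columns entered into the summary and the
#'   condition comparison.
#' @param compare Fit the mixed-effects comparisons (default TRUE;
#'   disable for speed in replicate studies).
#' @param curve_step Grid step in years for the condition-average
#'   failure curves (default 0.1; the terminal probabilities are always
#'   computed on the finer `params$time_step` grid).
#' @param contact_tol Contact solver force tolerance in N.
#' @return An object of class `knee_pipeline_result`: `trials`
#'   (augmented per-trial table), `summary` (per-condition mean/SD of
#'   each outcome over participant means), `comparisons` (pairwise
#'   mixed-model contrasts per outcome), `curves` (condition-average
#'   failure-probability time series), `quarantined` (row indices of
#'   failed solves) and `meta` (seed, configuration hash, package
#'   version).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' res <- run_pipeline(cohort)
#' res$summary[res$summary$outcome == "p_terminal", ]
#' }
#' @export
run_pipeline <- function(cohort,
                         geometry = knee_geometry(),
                         material = cartilage_material(),
                         params = failure_params(),
                         outcomes = c("peak_force_bw", "cumulative_load_bw_m",
                                      "peak_stress_mpa", "peak_strain",
                                      "p_terminal"),
                         compare = TRUE,
                         curve_step = 0.1,
                         contact_tol = 0.5) {
  .validate_cohort(cohort)
  mesh <- build_mesh(geometry, material)
  n <- nrow(cohort)

  trials <- cohort
  trials$force_n <- bw_to_newtons(trials$peak_force_bw, trials$body_mass_kg)
  trials$cumulative_load_bw_m <- cumulative_load(trials$mean_stance_force_bw,
                                                 trials$stride_length_m)
  trials$daily_cycles <- daily_loading_cycles(trials$stride_length_m,
                                              params$daily_distance,
                                              params$cycle_count)
  for (col in c("axis_depth_mm", "peak_stress_mpa", "peak_strain",
                "loaded_area_mm2", "stressed_volume_mm3", "t_f_years",
                "p_terminal", "p_terminal_no_repair"))
    trials[[col]] <- NA_real_

  tgrid <- seq(0, params$horizon, by = curve_step)
  curve_mat <- matrix(NA_real_, n, length(tgrid))
  curve_mat_no_rep <- matrix(NA_real_, n, length(tgrid))
  quarantined <- integer(0)

  for (i in seq_len(n)) {
    sol <- tryCatch(
      solve_contact(trials$force_n[i], trials$flexion_angle_deg[i],
                    geometry, material, mesh = mesh, tol = contact_tol),
      error = function(e) e)
    if (inherits(sol, "error")) {
      quarantined <- c(quarantined, i)
      next
    }
    strain <- if (params$strain_input == "peak") sol$peak_strain
      else mean(sol$strain[sol$compression > 0])
    trials$axis_depth_mm[i] <- sol$axis_depth
    trials$peak_stress_mpa[i] <- sol$peak_stress
    trials$peak_strain[i] <- sol$peak_strain
    trials$loaded_area_mm2[i] <- sol$loaded_area
    trials$stressed_volume_mm3[i] <- sol$stressed_volume
    vol <- if (params$volume_rule == "loaded") sol$stressed_volume
      else params$reference_volume
    tf <- time_to_failure(strain, trials$stride_length_m[i], params)
    fr <- p_fail_with_repair(vol, tf, params)
    trials$t_f_years[i] <- tf
    trials$p_terminal[i] <- fr$p_terminal
    trials$p_terminal_no_repair[i] <- fr$p_terminal_no_repair
    idx <- findInterval(tgrid, fr$time)
    curve_mat[i, ] <- fr$p_fail_with_repair[idx]
    curve_mat_no_rep[i, ] <- fr$p_fail[idx]
  }
  if (length(quarantined))
    warning(length(quarantined), " trial(s) quarantined after contact-solver ",
            "failure (rows ", paste(quarantined, collapse = ", "), ")")

  summary_df <- condition_summary(trials, outcomes)
  comparisons <- if (compare) compare_conditions(trials, outcomes) else NULL
  curves <- .condition_curves(trials, tgrid, curve_mat, curve_mat_no_rep)

  structure(
    list(trials = trials,
         summary = summary_df,
         comparisons = comparisons,
         curves = curves,
         quarantined = quarantined,
         meta = list(
           seed = attr(cohort, "cohort_config")$seed,
           config_hash = config_hash(list(geometry = geometry,
                                          material = material,
                                          params = params)),
           package_version = as.character(utils::packageVersion("medialknee")),
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "knee_pipeline_result")
}

.validate_cohort <- function(cohort) {
  required <- c("participant_id", "condition", "body_mass_kg",
                .cohort_features())
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(cohort$peak_force_bw <= 0 | cohort$stride_length_m <= 0 |
                 cohort$body_mass_kg <= 0 |
                 cohort$peak_force_bw < cohort$mean_stance_force_bw |
                 !(as.character(cohort$condition) %in% gait_conditions()))
  if (length(bad))
    stop("cohort schema violation in row(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

.condition_curves <- function(trials, tgrid, curve_mat, curve_mat_no_rep) {
  res <- lapply(gait_conditions(), function(cond) {
    rows <- which(as.character(trials$condition) == cond &
                    !is.na(trials$p_terminal))
    if (!length(rows)) return(NULL)
    # trial -> participant mean -> condition mean at each time point
    pid <- trials$participant_id[rows]
    pm <- rowsum(curve_mat[rows, , drop = FALSE], pid) /
      as.vector(table(pid)[sort(unique(pid))])
    pm_no <- rowsum(curve_mat_no_rep[rows, , drop = FALSE], pid) /
      as.vector(table(pid)[sort(unique(pid))])
    data.frame(condition = cond, time = tgrid,
               p_fail_with_repair = colMeans(pm),
               p_fail_no_repair = colMeans(pm_no))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-condition outcome summary (mean and SD over participant means)
#'
#' Aggregates trial-level outcomes to participant x condition means
#' first, then reports the across-participant mean and SD per condition
#' - the aggregation order of a repeated-measures design.
#'
#' @param trials Per-trial table (e.g. `run_pipeline(...)$trials`).
#' @param outcomes Outcome column names to summarise.
#' @return Long data frame: `outcome`, `condition`, `mean`, `sd`,
#'   `n_participants`.
#' @export
condition_summary <- function(trials, outcomes) {
  stopifnot(all(outcomes %in% names(trials)))
  res <- lapply(outcomes, function(oc) {
    pm <- .participant_condition_means(trials, oc)
    agg_m <- stats::aggregate(value ~ condition, pm, mean)
    agg_s <- stats::aggregate(value ~ condition, pm, stats::sd)
    agg_n <- stats::aggregate(value ~ condition, pm, length)
    data.frame(outcome = oc, condition = as.character(agg_m$condition),
               mean = agg_m$value, sd = agg_s$value,
               n_participants = agg_n$value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pairwise mixed-model comparisons for several outcomes
#'
#' Applies [fit_condition_model()] to each outcome column and binds the
#' contrast tables.
#'
#' @inheritParams condition_summary
#' @param alpha Significance level (default 0.05).
#' @param adjust Multiplicity adjustment (default `"none"`).
#' @return Data frame of class `condition_comparison`.
#' @export
compare_conditions <- function(trials, outcomes, alpha = 0.05,
                               adjust = "none") {
  out <- do.call(rbind, lapply(outcomes, function(oc)
    fit_condition_model(trials, oc, alpha = alpha, adjust = adjust)))
  rownames(out) <- NULL
  class(out) <- c("condition_comparison", "data.frame")
  out
}

#' Stable hash of a configuration object
#'
#' MD5 of the serialised object; used to stamp pipeline outputs so that
#' runs are traceable to their exact configuration.
#'
#' @param x Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' @export
print.knee_pipeline_result <- function(x, ...) {
  cat("Medial knee cartilage pipeline result\n")
  cat(sprintf("  %d trials (%d quarantined) | config %s\n",
              nrow(x$trials), length(x$quarantined),
              substr(x$meta$config_hash, 1, 8)))
  pt <- x$summary[x$summary$outcome == "p_terminal", ]
  if (nrow(pt)) {
    cat("  terminal failure probability with repair (cohort means):\n")
    for (i in seq_len(nrow(pt)))
      cat(sprintf("    %-16s %6.2f%% (SD %.2f%%)\n", pt$condition[i],
                  100 * pt$mean[i], 100 * pt$sd[i]))
  }
  invisible(x)
}
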