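#' Default per-condition feature means for the synthetic cohort
#'
#' One row per gait condition (`neutral`, `toe_in`, `toe_out`,
#' `lateral_insoles`), one column per gait feature.  Values are the
#' cohort means of the study conditions the generator emulates: a
#' 15-participant repeated-measures gait-modification cohort walking at
#' self-selected speed.  Mean stance-phase force is reconstructed as
#' cumulative load times stride length, since cumulative load is defined
#' as mean stance force divided by stride length.  Knee flexion at the
#' instant of peak medial force is not tabulated for this cohort; the
#' default of 18 degrees is typical early-stance flexion at the first
#' peak of the medial contact force in walking.
#'
#' @return A data frame with conditions as row names and feature columns
#'   `peak_force_bw`, `mean_stance_force_bw`, `flexion_angle_deg`,
#'   `stride_length_m`, `velocity_mps`, `cop_offset_mm`,
#'   `foot_progression_deg`.
#' @export
default_condition_means <- function() {
  data.frame(
    peak_force_bw        = c(2.68, 2.51, 2.43, 2.69),
    mean_stance_force_bw = c(0.85 * 1.71, 0.81 * 1.72, 0.80 * 1.74, 0.84 * 1.71),
    flexion_angle_deg    = c(18, 18, 18, 18),
    stride_length_m      = c(1.71, 1.72, 1.74, 1.71),
    velocity_mps         = c(1.54, 1.49, 1.49, 1.56),
    cop_offset_mm        = c(1.39, 8.45, -4.58, -1.03),
    foot_progression_deg = c(3.51, -10.63, 11.95, 2.33),
    row.names = gait_conditions()
  )
}

#' Default per-condition feature standard deviations
#'
#' Companion to [default_condition_means()]; total (cross-sectional)
#' standard deviations, later split into a participant random intercept
#' and trial-to-trial noise by `between_participant_sd_fraction`.
#' Mean stance-force SDs are propagated from the cumulative-load SDs.
#'
#' @return A data frame shaped like [default_condition_means()].
#' @export
default_condition_sds <- function() {
  data.frame(
    peak_force_bw        = c(0.47, 0.46, 0.46, 0.49),
    mean_stance_force_bw = c(0.09 * 1.71, 0.13 * 1.72, 0.09 * 1.74, 0.09 * 1.71),
    flexion_angle_deg    = c(4, 4, 4, 4),
    stride_length_m      = c(0.10, 0.11, 0.12, 0.09),
    velocity_mps         = c(0.11, 0.15, 0.11, 0.12),
    cop_offset_mm        = c(5.12, 8.05, 7.63, 4.25),
    foot_progression_deg = c(5.86, 3.91, 2.25, 3.10),
    row.names = gait_conditions()
  )
}

#' Gait condition labels
#'
#' @return Character vector of the four condition labels in canonical
#'   order: neutral, toe-in, toe-out, lateral wedge insoles.
#' @export
gait_conditions <- function() {
  c("neutral", "toe_in", "toe_out", "lateral_insoles")
}

.cohort_features <- function() {
  c("peak_force_bw", "mean_stance_force_bw", "flexion_angle_deg",
    "stride_length_m", "velocity_mps", "cop_offset_mm",
    "foot_progression_deg")
}

#' Configuration for the synthetic gait cohort generator
#'
#' Bundles sample sizes, per-condition feature means/SDs, the
#' between-participant variance split and body-mass distribution into a
#' validated configuration object consumed by [generate_cohort()].
#'
#' Each feature is generated as
#' `condition mean + participant intercept + trial noise`, where the
#' participant intercept (shared across conditions, which is what makes
#' the design repeated-measures) has SD equal to
#' `between_participant_sd_fraction` times the feature's across-condition
#' mean SD, and the trial noise has SD
#' `sqrt(1 - between_participant_sd_fraction^2)` times the per-condition
#' SD, so the marginal SD approximately reproduces the configured one.
#'
#' @param n_participants Number of participants (default 15).
#' @param n_trials Trials per participant per condition (default 5).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param condition_means,condition_sds Data frames shaped like
#'   [default_condition_means()] / [default_condition_sds()].
#' @param between_participant_sd_fraction Fraction of each feature's SD
#'   attributed to the participant random intercept, in `[0, 1]`
#'   (default 0.7; the source summaries report no within-participant
#'   correlations, so this is an adjustable assumption).
#' @param body_mass_mean_kg,body_mass_sd_kg Body-mass distribution
#'   (defaults 69.31 and 9.92 kg); mass is constant within participant.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 15,
                          n_trials = 5,
                          seed = 1L,
                          condition_means = default_condition_means(),
                          condition_sds = default_condition_sds(),
                          between_participant_sd_fraction = 0.7,
                          body_mass_mean_kg = 69.31,
                          body_mass_sd_kg = 9.92) {
  if (n_participants < 2) stop("'n_participants' must be at least 2")
  if (n_trials < 1) stop("'n_trials' must be at least 1")
  if (between_participant_sd_fraction < 0 || between_participant_sd_fraction > 1)
    stop("'between_participant_sd_fraction' must lie in [0, 1]")
  feats <- .cohort_features()
  for (df in list(condition_means, condition_sds)) {
    if (!all(feats %in% names(df)))
      stop("condition means/SDs must contain columns: ",
           paste(feats, collapse = ", "))
    if (!all(gait_conditions() %in% rownames(df)))
      stop("condition means/SDs must have rows: ",
           paste(gait_conditions(), collapse = ", "))
  }
  if (any(as.matrix(condition_sds[, feats]) < 0))
    stop("all feature SDs must be non-negative")
  if (body_mass_sd_kg < 0) stop("'body_mass_sd_kg' must be non-negative")
  structure(
    list(n_participants = as.integer(n_participants),
         n_trials = as.integer(n_trials),
         seed = as.integer(seed),
         condition_means = condition_means[gait_conditions(), feats],
         condition_sds = condition_sds[gait_conditions(), feats],
         between_participant_sd_fraction = between_participant_sd_fraction,
         body_mass_mean_kg = body_mass_mean_kg,
         body_mass_sd_kg = body_mass_sd_kg),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic gait cohort configuration\n")
  cat(sprintf("  %d participants x %d conditions x %d trials, seed %d\n",
              x$n_participants, nrow(x$condition_means), x$n_trials, x$seed))
  cat(sprintf("  participant-intercept SD fraction: %.2f\n",
              x$between_participant_sd_fraction))
  cat(sprintf("  body mass: %.2f +/- %.2f kg\n",
              x$body_mass_mean_kg, x$body_mass_sd_kg))
  invisible(x)
}

#' Generate a synthetic repeated-measures gait cohort
#'
#' Draws one row per participant x condition x trial with the gait
#' features needed by the contact and failure stages, standing in for a
#' motion-capture plus musculoskeletal-simulation front end.  Features
#' are mutually independent given the participant intercept; Gaussian
#' noise is truncated at physical bounds (positive forces and stride,
#' peak force at least the stance mean) by redrawing offending trials.
#'
#' @param config A [cohort_config()] object.
#' @return A data frame with columns `participant_id`, `condition`,
#'   `trial`, `body_mass_kg` and the seven feature columns of
#'   [default_condition_means()].  `condition` is a factor with levels in
#'   the canonical order.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' aggregate(peak_force_bw ~ condition, cohort, mean)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  np <- config$n_participants
  nt <- config$n_trials
  conds <- gait_conditions()
  feats <- .cohort_features()
  frac <- config$between_participant_sd_fraction

  mass <- stats::rnorm(np, config$body_mass_mean_kg, config$body_mass_sd_kg)
  for (i in seq_len(100)) {
    bad <- mass <= 0
    if (!any(bad)) break
    mass[bad] <- stats::rnorm(sum(bad), config$body_mass_mean_kg,
                              config$body_mass_sd_kg)
  }

  # participant intercepts: SD = fraction x across-condition mean SD
  mean_sds <- colMeans(config$condition_sds)
  intercepts <- sapply(feats, function(f) stats::rnorm(np, 0, frac * mean_sds[f]))
  intercepts <- matrix(intercepts, nrow = np,
                       dimnames = list(NULL, feats))

  grid <- expand.grid(trial = seq_len(nt), condition = conds,
                      participant = seq_len(np),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  noise_frac <- sqrt(1 - frac^2)
  vals <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  for (f in feats) {
    mu <- config$condition_means[grid$condition, f]
    sdv <- noise_frac * config$condition_sds[grid$condition, f]
    vals[, f] <- mu + intercepts[grid$participant, f] + stats::rnorm(n, 0, sdv)
  }

  # truncation at physical bounds by redrawing trial noise of offending rows
  redraw_feats <- c("peak_force_bw", "mean_stance_force_bw", "stride_length_m")
  for (i in seq_len(200)) {
    bad <- vals[, "peak_force_bw"] <= 0 |
      vals[, "mean_stance_force_bw"] <= 0 |
      vals[, "stride_length_m"] <= 0 |
      vals[, "peak_force_bw"] < vals[, "mean_stance_force_bw"]
    if (!any(bad)) break
    for (f in redraw_feats) {
      mu <- config$condition_means[grid$condition[bad], f]
      sdv <- noise_frac * config$condition_sds[grid$condition[bad], f]
      vals[bad, f] <- mu + intercepts[grid$participant[bad], f] +
        stats::rnorm(sum(bad), 0, sdv)
    }
  }
  if (any(bad))
    stop("could not satisfy feature bounds after 200 redraw sweeps; ",
         "check that configured means are compatible with their SDs")

  out <- data.frame(
    participant_id = sprintf("P%02d", grid$participant),
    condition = factor(grid$condition, levels = conds),
    trial = grid$trial,
    body_mass_kg = mass[grid$participant],
    vals,
    stringsAsFactors = FALSE)
  out[order(out$participant_id, out$condition, out$trial), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  attr(out, "cohort_config") <- config
  out
}

#' Synthetic centre-of-pressure trajectory at a prescribed progression angle
#'
#' Builds a straight-line centre-of-pressure (CoP) path from initial
#' contact to toe-off whose heading relative to the anterior axis equals
#' `progression_angle` (positive toe-out, i.e. laterally for a right
#' foot), with optional mediolateral Gaussian noise.  Used as a fixture
#' for checking [foot_progression_angle()] recovery.
#'
#' @param progression_angle Heading in degrees (positive = toe-out).
#' @param stance_duration Stance time in seconds (default 0.7).
#' @param n_samples Number of samples, at least 2 (default 500).
#' @param noise_sd Mediolateral noise SD in mm (default 0).
#' @param seed Optional integer seed for the noise.
#' @param path_length CoP excursion from heel contact to toe-off in mm
#'   (default 200, about 80% of an adult foot length).
#' @return Data frame with columns `time` (s), `x_ml` (mm, positive
#'   lateral) and `y_ap` (mm, positive anterior).
#' @export
generate_cop_trajectory <- function(progression_angle,
                                    stance_duration = 0.7,
                                    n_samples = 500,
                                    noise_sd = 0,
                                    seed = NULL,
                                    path_length = 200) {
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  if (stance_duration <= 0) stop("'stance_duration' must be positive")
  if (!is.null(seed)) set.seed(seed)
  s <- seq(0, 1, length.out = n_samples)
  theta <- progression_angle * pi / 180
  x <- s * path_length * sin(theta)
  y <- s * path_length * cos(theta)
  if (noise_sd > 0) x <- x + stats::rnorm(n_samples, 0, noise_sd)
  data.frame(time = s * stance_duration, x_ml = x, y_ap = y)
}

#' Write / read a cohort table as delimited text
#'
#' Tab-separated, UTF-8, `.` decimal separator, fixed header.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort data frame with `condition` restored as a factor.
#' @export
write_cohort <- function(cohort, path) {
  utf8 <- cohort
  utils::write.table(utf8, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  out$condition <- factor(out$condition, levels = gait_conditions())
  out
}
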