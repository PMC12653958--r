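#' Paired Cohen's d
#'
#' Standardised mean difference for a repeated-measures contrast: the
#' mean of the paired differences divided by the SD of the paired
#' differences.  The within-subject denominator is what makes large
#' effect sizes attainable for mean differences that are small relative
#' to the cross-sectional SD.  Sign follows `a - b`.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Effect size; `0` when the vectors are identical; signed `Inf`
#'   (with a warning) when the differences have zero variance but a
#'   non-zero mean.
#' @examples
#' cohens_d(c(2.7, 2.6, 2.9), c(2.4, 2.5, 2.6))
#' @export
cohens_d <- function(a, b) {
  if (length(a) != length(b))
    stop("'a' and 'b' must be paired vectors of equal length")
  d <- a - b
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(0)
    warning("zero-variance differences with non-zero mean: effect size is infinite")
    return(sign(m) * Inf)
  }
  m / s
}

.participant_condition_means <- function(data, value_col) {
  agg <- stats::aggregate(data[[value_col]],
                          by = list(participant_id = data$participant_id,
                                    condition = data$condition),
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- "value"
  agg$condition <- factor(agg$condition, levels = gait_conditions())
  agg
}

.paired_fallback <- function(pm, pairs_mat, outcome, alpha) {
  wide <- stats::reshape(pm, idvar = "participant_id",
                         timevar = "condition", direction = "wide")
  res <- lapply(seq_len(nrow(pairs_mat)), function(i) {
    a <- wide[[paste0("value.", pairs_mat[i, 1])]]
    b <- wide[[paste0("value.", pairs_mat[i, 2])]]
    diffs <- a - b
    p <- if (stats::sd(diffs) == 0) {
      if (mean(diffs) == 0) 1 else 0
    } else stats::t.test(a, b, paired = TRUE)$p.value
    data.frame(outcome = outcome,
               contrast = paste(pairs_mat[i, 1], "-", pairs_mat[i, 2]),
               estimate = mean(diffs),
               p_value = p,
               cohens_d = suppressWarnings(cohens_d(a, b)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value <= alpha
  out
}

#' Compare an outcome across gait conditions with a mixed-effects model
#'
#' Fits a linear mixed-effects model (REML) on participant x condition
#' means with gait condition as a fixed effect and participant-level
#' random intercepts; the random intercept induces a
#' compound-symmetric within-participant covariance.  All pairwise
#' condition contrasts are extracted with Satterthwaite degrees of
#' freedom, and each is accompanied by a paired Cohen's d computed from
#' the participant means.  Singular or failed fits fall back to paired
#' t-tests with a warning.
#'
#' @param data Data frame with columns `participant_id`, `condition`
#'   and the outcome column; trial-level data are first averaged to
#'   participant x condition means.
#' @param value_col Name of the outcome column.
#' @param alpha Significance level (default 0.05).
#' @param adjust Multiplicity adjustment passed to
#'   `emmeans` (default `"none"`; `"holm"` available).
#' @return Data frame of class `condition_comparison` with one row per
#'   pairwise contrast: `outcome`, `contrast`, `estimate`, `p_value`,
#'   `cohens_d`, `significant`.
#' @export
fit_condition_model <- function(data, value_col, alpha = 0.05,
                                adjust = "none") {
  stopifnot(all(c("participant_id", "condition", value_col) %in% names(data)))
  pm <- .participant_condition_means(data, value_col)
  conds <- levels(droplevels(pm$condition))
  if (length(conds) < 2) stop("at least 2 conditions are required")
  if (length(unique(pm$participant_id)) < 2)
    stop("at least 2 participants are required")
  pairs_mat <- t(utils::combn(conds, 2))

  # degenerate case: no variance at all
  if (stats::sd(pm$value) == 0) {
    out <- data.frame(outcome = value_col,
                      contrast = paste(pairs_mat[, 1], "-", pairs_mat[, 2]),
                      estimate = 0, p_value = 1, cohens_d = 0,
                      significant = FALSE, stringsAsFactors = FALSE)
    class(out) <- c("condition_comparison", "data.frame")
    return(out)
  }

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(value ~ condition + (1 | participant_id),
                                    data = pm, REML = TRUE)),
    error = function(e) NULL)
  singular <- is.null(fit) ||
    isTRUE(tryCatch(lme4::isSingular(fit, tol = 1e-6), error = function(e) TRUE))
  if (is.null(fit)) {
    warning("mixed-model fit failed; falling back to paired t-tests")
    out <- .paired_fallback(pm, pairs_mat, value_col, alpha)
    class(out) <- c("condition_comparison", "data.frame")
    return(out)
  }
  if (singular)
    warning("mixed-model fit is singular (participant variance at the boundary); ",
            "contrasts reported from the fitted model")

  em <- emmeans::emmeans(fit, "condition", lmer.df = "satterthwaite")
  ctr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = adjust))
  # emmeans orders pairwise contrasts as combn over factor levels
  wide <- stats::reshape(pm, idvar = "participant_id",
                         timevar = "condition", direction = "wide")
  d_vals <- vapply(seq_len(nrow(pairs_mat)), function(i) {
    suppressWarnings(cohens_d(wide[[paste0("value.", pairs_mat[i, 1])]],
                              wide[[paste0("value.", pairs_mat[i, 2])]]))
  }, numeric(1))
  out <- data.frame(outcome = value_col,
                    contrast = paste(pairs_mat[, 1], "-", pairs_mat[, 2]),
                    estimate = ctr$estimate,
                    p_value = ctr$p.value,
                    cohens_d = d_vals,
                    stringsAsFactors = FALSE)
  out$significant <- out$p_value <= alpha
  class(out) <- c("condition_comparison", "data.frame")
  out
}
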