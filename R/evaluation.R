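#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly drawn
#' presence outscores a randomly drawn absence, with ties counted half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, same length.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold table of sensitivity, specificity and TSS
#'
#' One row per threshold `t` in `{0, step, ..., 1}`; the prediction is
#' positive iff `score >= t` (inclusive, matching the RIO >= threshold
#' mapping convention).  TSS = sensitivity + specificity - 1.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores in [0, 1].
#' @param step threshold grid step, 0 < step <= 0.5 (default 0.01, the
#'   reporting precision of two-decimal operating thresholds).
#' @return data.frame of class `threshold_table` with columns
#'   `threshold`, `sensitivity`, `specificity`, `tss`.
#' @export
threshold_table <- function(labels, scores, step = 0.01) {
  if (!is.numeric(step) || step <= 0 || step > 0.5) stop("invalid step")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  # round so grid values equal their decimal literals (0.58 == 0.58)
  thresholds <- round(seq(0, 1, by = step), 9)
  if (thresholds[length(thresholds)] < 1) thresholds <- c(thresholds, 1)
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pos <- scores >= thresholds[i]
    sens[i] <- sum(pos & labels == 1) / n1
    spec[i] <- sum(!pos & labels == 0) / n0
  }
  structure(data.frame(threshold = thresholds, sensitivity = sens,
                       specificity = spec, tss = sens + spec - 1),
            class = c("threshold_table", "data.frame"))
}

#' Select the operating threshold
#'
#' Sensitivity-specificity sum maximization: the tabulated threshold
#' maximizing sensitivity + specificity, ties broken toward the smaller
#' threshold.  Being an argmax over the table rows it coincides with
#' exhaustive search by construction.
#'
#' @param table `threshold_table`.
#' @return the selected threshold.
#' @export
select_threshold <- function(table) {
  if (nrow(table) == 0) stop("empty threshold table")
  s <- table$sensitivity + table$specificity
  table$threshold[which.max(s)]  # first maximum = smallest threshold
}

#' True skill statistic
#'
#' @param sensitivity,specificity rates in [0, 1] (vectors allowed).
#' @return sensitivity + specificity - 1.
#' @export
tss <- function(sensitivity, specificity) sensitivity + specificity - 1

#' Validate the model on independent testing points
#'
#' Summarizes the RIOs of held-out testing records: median and a seeded
#' percentile-bootstrap 95% confidence interval of the median (1,000
#' resamples).
#'
#' @param rio numeric RIO vector, or a scored `point_table` with an
#'   `rio` column.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list of class `validation_summary`: `rio`, `median`,
#'   `ci_lower`, `ci_upper`, `n_test`.
#' @export
validate_on_test <- function(rio, n_boot = 1000, seed = 1) {
  if (is.data.frame(rio)) {
    if (!"rio" %in% names(rio)) stop("point table has no 'rio' column")
    rio <- rio$rio
  }
  rio <- rio[!is.na(rio)]
  if (length(rio) == 0) stop("empty test set")
  stopifnot(all(rio >= 0 & rio <= 1))
  meds <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    stats::median(sample(rio, replace = TRUE)), 0))
  ci <- unname(stats::quantile(meds, c(0.025, 0.975)))
  structure(list(rio = rio, median = stats::median(rio),
                 ci_lower = ci[1], ci_upper = ci[2], n_test = length(rio)),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("validation_summary: n = %d, median RIO %.3f (95%% CI %.3f-%.3f)\n",
              x$n_test, x$median, x$ci_lower, x$ci_upper))
  invisible(x)
}
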