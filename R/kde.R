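#' Rule-of-thumb Gaussian KDE bandwidth
#'
#' `h = 1.06 * delta * n^(-1/5)`, where `delta` is the sample standard
#' deviation (n - 1 denominator) of the values. Set
#' `population_sd = TRUE` to use the population standard deviation
#' (n denominator) instead.
#'
#' @param values Numeric vector, length >= 2, with positive variance.
#' @param population_sd Use the n-denominator standard deviation.
#' @return Bandwidth `h > 0`.
#' @examples
#' kde_bandwidth(c(0, 2))  # 1.06 * sqrt(2) * 2^(-0.2)
#' @export
kde_bandwidth <- function(values, population_sd = FALSE) {
  n <- length(values)
  if (n < 2L) stop("at least two values are required for a bandwidth")
  delta <- stats::sd(values)
  if (population_sd) delta <- delta * sqrt((n - 1) / n)
  if (delta == 0) stop("degenerate group: zero variance")
  1.06 * delta * n^(-1 / 5)
}

#' Fit a one-group Gaussian KDE
#'
#' Stores a group's training distances together with the rule-of-thumb
#' bandwidth from [kde_bandwidth()].
#'
#' @param values Training distances, length >= 2, positive variance.
#' @param group Optional label (e.g. `"Self/short"`), kept for reporting.
#' @param population_sd Passed to [kde_bandwidth()].
#' @return An object of class `kde_model` with fields `values`, `h`, `n`,
#'   `group`.
#' @export
kde_model <- function(values, group = NULL, population_sd = FALSE) {
  h <- tryCatch(kde_bandwidth(values, population_sd),
                error = function(e) stop(
                  conditionMessage(e),
                  if (!is.null(group)) paste0(" in group ", group),
                  call. = FALSE))
  structure(list(values = as.numeric(values), h = h,
                 n = length(values), group = group),
            class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("Gaussian KDE%s: n = %d, bandwidth h = %.5g\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              x$n, x$h))
  invisible(x)
}

#' Evaluate a KDE density
#'
#' The Gaussian kernel sum
#' `f(d) = (1 / (n h sqrt(2 pi))) * sum_i exp(-(d - X_i)^2 / (2 h^2))`.
#'
#' @param model A [kde_model()].
#' @param d Numeric vector of evaluation points.
#' @return Densities, same length as `d`.
#' @export
kde_density <- function(model, d) {
  stopifnot(inherits(model, "kde_model"))
  vapply(d, function(x)
    sum(exp(-(x - model$values)^2 / (2 * model$h^2))) /
      (model$n * model$h * sqrt(2 * pi)),
    numeric(1))
}

log_kde_density <- function(model, d) {
  # log-sum-exp over kernels for far-tail stability
  vapply(d, function(x) {
    z <- -(x - model$values)^2 / (2 * model$h^2)
    m <- max(z)
    m + log(sum(exp(z - m))) -
      log(model$n * model$h * sqrt(2 * pi))
  }, numeric(1))
}

#' Likelihood ratio of a distance
#'
#' The evidence that two samples share a source individual:
#' `LR = f_Self(d) / f_MZT(d)`, the ratio of the Self-group KDE density to
#' the MZT-group KDE density at the observed distance. Densities are
#' computed in log space and floored at 1e-300 before division, so the
#' ratio is always finite and positive.
#'
#' @param self_model,mzt_model [kde_model()] fits of the Self and MZT
#'   training distances for one time-interval class.
#' @param d Numeric vector of distances.
#' @return Likelihood ratios (> 0), same length as `d`.
#' @export
likelihood_ratio <- function(self_model, mzt_model, d) {
  floor_log <- log(1e-300)
  ls <- pmax(log_kde_density(self_model, d), floor_log)
  lm <- pmax(log_kde_density(mzt_model, d), floor_log)
  exp(ls - lm)
}

#' Youden-optimal LR threshold
#'
#' Scans candidate thresholds (midpoints of consecutive distinct values in
#' the pooled sorted LRs, plus one candidate below the minimum and one
#' above the maximum) under the rule "classify as Self iff LR >
#' threshold", and returns the threshold maximizing the Youden index
#' `YI = Sen + Spe - 1`. Ties are broken toward the smallest threshold.
#' Because the optimum is attained on an open interval between two
#' adjacent observed LRs, the bounding values are also reported.
#'
#' @param self_lrs,mzt_lrs Non-empty numeric vectors of LRs for Self and
#'   MZT pairs.
#' @return A list: `threshold` (midpoint of the optimal interval), `lower`
#'   and `upper` (the observed LRs bounding it), `sensitivity`,
#'   `specificity`, `youden`.
#' @examples
#' best_youden_threshold(c(2, 3), c(0.5, 1.5))  # threshold 1.75, YI = 1
#' @export
best_youden_threshold <- function(self_lrs, mzt_lrs) {
  if (!length(self_lrs) || !length(mzt_lrs))
    stop("both Self and MZT groups must be non-empty")
  pooled <- sort(unique(c(self_lrs, mzt_lrs)))
  lowers <- c(pooled[1L] / 2, pooled)
  uppers <- c(pooled, pooled[length(pooled)] * 2)
  cands <- (lowers + uppers) / 2
  best <- NULL
  for (i in seq_along(cands)) {
    sen <- mean(self_lrs > cands[i])
    spe <- mean(mzt_lrs <= cands[i])
    yi <- sen + spe - 1
    if (is.null(best) || yi > best$youden + 1e-12)
      best <- list(threshold = cands[i], lower = lowers[i],
                   upper = uppers[i], sensitivity = sen,
                   specificity = spe, youden = yi)
  }
  best
}

#' Diagnostic evaluation at a threshold
#'
#' Applies the decision rule "Self iff LR > threshold" and reports
#' sensitivity (fraction of Self pairs confirmed as Self), specificity
#' (fraction of MZT pairs confirmed as MZT), the Youden index
#' `YI = Sen + Spe - 1`, and the misjudged pairs.
#'
#' @param pairs Data frame with columns `sample_a`, `sample_b`,
#'   `relationship` (`"Self"`/`"MZT"`) and `lr`.
#' @param threshold Positive LR threshold.
#' @return A list of class `mzt_diagnostics`: `threshold`, `sensitivity`,
#'   `specificity`, `youden`, `n_self`, `n_mzt`, and `misjudged` (character
#'   vector of `"A--B"` pair ids).
#' @export
evaluate_decision <- function(pairs, threshold) {
  stopifnot(threshold > 0)
  is_self <- pairs$relationship == "Self"
  if (!any(is_self) || !any(!is_self))
    stop("both Self and MZT pairs are required for diagnostics")
  call_self <- pairs$lr > threshold
  sen <- mean(call_self[is_self])
  spe <- mean(!call_self[!is_self])
  wrong <- (is_self & !call_self) | (!is_self & call_self)
  structure(list(threshold = threshold, sensitivity = sen,
                 specificity = spe, youden = sen + spe - 1,
                 n_self = sum(is_self), n_mzt = sum(!is_self),
                 misjudged = paste(pairs$sample_a[wrong],
                                   pairs$sample_b[wrong], sep = "--")),
            class = "mzt_diagnostics")
}

#' @export
print.mzt_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Threshold %.4g: Sen %.4f, Spe %.4f, YI %.4f (%d Self, %d MZT)\n",
    x$threshold, x$sensitivity, x$specificity, x$youden, x$n_self,
    x$n_mzt))
  if (length(x$misjudged))
    cat("  misjudged:", paste(x$misjudged, collapse = ", "), "\n")
  else cat("  misjudged: none\n")
  invisible(x)
}
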