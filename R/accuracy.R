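#' Binomial audit sample-size design
#'
#' Number of audit samples needed to estimate an error proportion at a
#' given two-sided confidence level and confidence-interval half-width,
#' using the normal-approximation design formula
#' `ceil(z^2 p0 (1 - p0) / half_width^2)` with the worst-case `p0 = 0.5`
#' unless stated otherwise.
#'
#' @param confidence two-sided confidence level (default 0.90).
#' @param half_width confidence-interval half-width (default 0.10).
#' @param p0 design proportion (default 0.5, the conservative maximum).
#' @return integer sample size.
#' @examples
#' required_sample_size(0.90, 0.10) # 68
#' @export
required_sample_size <- function(confidence = 0.90, half_width = 0.10, p0 = 0.5) {
  stopifnot(confidence > 0, confidence < 1, half_width > 0, half_width <= 0.5,
            p0 >= 0, p0 <= 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling(z^2 * p0 * (1 - p0) / half_width^2))
}

#' Draw a seeded audit sample
#'
#' Uniform sampling without replacement, deterministic for a given seed.
#'
#' @param ids candidate ids.
#' @param n sample size (`n <= length(ids)`).
#' @param seed integer RNG seed.
#' @return character vector of sampled ids.
#' @export
draw_audit_samples <- function(ids, n, seed) {
  if (n > length(ids)) {
    stop(sprintf("cannot sample %d from %d ids", n, length(ids)))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(ids, n, replace = FALSE)
}

#' Estimate an error rate with a Clopper-Pearson interval
#'
#' Exact (conservative) binomial interval from beta-quantile inversion of
#' the binomial tail equations.
#'
#' @param x number of errors found.
#' @param n sample size.
#' @param confidence two-sided confidence level (default 0.90).
#' @return a [rate_estimate()].
#' @export
estimate_rate <- function(x, n, confidence = 0.90) {
  stopifnot(n >= 1, x >= 0, x <= n, confidence > 0, confidence < 1)
  alpha <- 1 - confidence
  lo <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  rate_estimate(x, n, ci_low = lo, ci_high = hi, method = "clopper-pearson")
}

#' Construct a rate estimate
#'
#' Holds an observed error proportion with confidence bounds. Use
#' [estimate_rate()] to compute Clopper-Pearson bounds; this constructor
#' also accepts externally supplied interval endpoints (e.g. previously
#' published audit intervals) for downstream accuracy arithmetic.
#'
#' @param x errors found; @param n sample size.
#' @param ci_low,ci_high interval endpoints (proportions).
#' @param method label of the interval method.
#' @return an object of class `rate_estimate` with fields `x`, `n`, `rate`,
#'   `ci_low`, `ci_high`, `method`.
#' @export
rate_estimate <- function(x, n, ci_low, ci_high, method = "supplied") {
  stopifnot(n >= 1, x >= 0, x <= n,
            ci_low >= 0, ci_high <= 1, ci_low <= ci_high)
  rate <- x / n
  structure(list(x = as.integer(x), n = as.integer(n), rate = rate,
                 ci_low = ci_low, ci_high = ci_high, method = method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate %d/%d = %.4f [%.5f, %.5f] (%s)>\n",
              x$x, x$n, x$rate, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

round1 <- function(x) round(x, 1)

#' Overall accuracy from false-negative and false-positive audits
#'
#' Combines two audit rate estimates into a percentage accuracy with
#' bounds: `accuracy = 100 - fn% - fp%` where each percentage rate is first
#' rounded to one decimal (the convention used when quoting audit rates to
#' one decimal); the lower bound subtracts the rounded upper interval
#' endpoints, the upper bound the rounded lower endpoints. Unrounded
#' variants are returned alongside.
#'
#' @param fn,fp `rate_estimate`s for the false-negative and false-positive
#'   audits.
#' @return an object of class `accuracy_summary` with `accuracy_pct`,
#'   `lower_pct`, `upper_pct` and `_raw` unrounded counterparts.
#' @export
accuracy_summary <- function(fn, fp) {
  stopifnot(inherits(fn, "rate_estimate"), inherits(fp, "rate_estimate"))
  acc <- 100 - round1(100 * fn$rate) - round1(100 * fp$rate)
  lower <- 100 - round1(100 * fn$ci_high) - round1(100 * fp$ci_high)
  upper <- 100 - round1(100 * fn$ci_low) - round1(100 * fp$ci_low)
  structure(list(
    fn = fn, fp = fp,
    accuracy_pct = acc, lower_pct = lower, upper_pct = upper,
    accuracy_pct_raw = 100 * (1 - fn$rate - fp$rate),
    lower_pct_raw = 100 * (1 - fn$ci_high - fp$ci_high),
    upper_pct_raw = 100 * (1 - fn$ci_low - fp$ci_low)
  ), class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("<accuracy_summary: %.1f%% [%.1f%%, %.1f%%]>\n",
              x$accuracy_pct, x$lower_pct, x$upper_pct))
  invisible(x)
}

#' Extrapolate an error count from a rate bound
#'
#' @param rate_bound error-rate bound (proportion).
#' @param population number of entities the rate applies to.
#' @return `round(rate_bound * population)` as an integer.
#' @export
extrapolate_error_count <- function(rate_bound, population) {
  stopifnot(rate_bound >= 0, rate_bound <= 1, population >= 0)
  as.integer(round(rate_bound * population))
}

#' Evaluate predicted correspondences against ground truth
#'
#' Exact analogue of a manual audit, enabled by synthetic ground truth:
#' counts true/false positives and false negatives and derives precision
#' and recall.
#'
#' @param predicted a `correspondence_set` (or data frame with `a_id`,
#'   `b_id`, optionally filtered by `entity_type`).
#' @param truth a `ground_truth` object from [derive_views()].
#' @param entity_type `"compound"` or `"reaction"`.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall` (`precision`
#'   is `NA` when nothing was predicted).
#' @export
evaluate_correspondences <- function(predicted, truth,
                                     entity_type = c("compound", "reaction")) {
  entity_type <- match.arg(entity_type)
  if (!is.null(predicted$entity_type)) {
    predicted <- predicted[predicted$entity_type == entity_type, , drop = FALSE]
  }
  true_pairs <- if (entity_type == "compound") truth$compound_pairs else truth$reaction_pairs
  pred_key <- paste(predicted$a_id, predicted$b_id, sep = "\r")
  true_key <- paste(true_pairs$a_id, true_pairs$b_id, sep = "\r")
  tp <- length(intersect(pred_key, true_key))
  fp <- length(setdiff(pred_key, true_key))
  fn <- length(setdiff(true_key, pred_key))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}
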