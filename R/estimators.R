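new_hr_estimate <- function(log_hr, se, alpha, method, flags = character()) {
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(log_hr = log_hr, se = se, hr = exp(log_hr),
                 ci_low = if (is.na(se)) NA_real_ else exp(log_hr - z * se),
                 ci_high = if (is.na(se)) NA_real_ else exp(log_hr + z * se),
                 alpha = alpha, method = method, flags = flags),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  HR = %.4f  (log HR = %.4f", x$hr, x$log_hr))
  if (!is.na(x$se))
    cat(sprintf(", SE = %.4f)\n  %g%% CI: %.4f to %.4f\n",
                x$se, 100 * (1 - x$alpha), x$ci_low, x$ci_high))
  else cat(")\n  no variance estimator available\n")
  if (length(x$flags)) cat("  note:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Closed-form partial MLE of the common hazard ratio
#'
#' In a pair-stratified Cox model the partial likelihood depends on the
#' data only through the comparable-pair counts `G` and `H`, and its
#' maximizer is simply `G/H`.  The observed Fisher information evaluated
#' at the maximum gives the variance estimator `1/G + 1/H` for
#' `log(G/H)`, from which a Wald confidence interval on the log scale is
#' formed.  The result is numerically identical to an iteratively fitted
#' pair-stratified Cox model with Breslow tie handling.
#'
#' @param counts a `pair_counts` object from [tabulate_pairs] or
#'   [pair_counts].
#' @param alpha complement of the confidence level (default 0.05 for a
#'   95% interval).
#' @return An object of class `hr_estimate` with fields `log_hr`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `alpha`, `method`.
#' @examples
#' common_hr_pmle(pair_counts(n1 = 198, n2 = 135))
#' @export
common_hr_pmle <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "pair_counts"))
  G <- counts$G; H <- counts$H
  if (G == 0 && H == 0)
    stop("no comparable pairs: G = H = 0, common HR is not estimable",
         call. = FALSE)
  if (H == 0)
    stop("boundary estimate: H = 0, common HR estimate diverges to +Inf",
         call. = FALSE)
  if (G == 0)
    stop("boundary estimate: G = 0, common HR estimate diverges to 0",
         call. = FALSE)
  new_hr_estimate(log_hr = log(G / H), se = sqrt(1 / G + 1 / H),
                  alpha = alpha, method = "Stratified PMLE (G/H)")
}

#' Stratified log-rank test for matched pairs
#'
#' The score test of no exposure effect in the pair-stratified Cox model
#' reduces to \eqn{(G - H)^2 / (G + H)}, the matched-pair analogue of
#' McNemar's statistic, asymptotically chi-squared with 1 df under the
#' null of common hazard ratio 1.
#'
#' @inheritParams common_hr_pmle
#' @return A `pair_test` object with fields `statistic`, `df`, `p_value`,
#'   `name`.
#' @examples
#' stratified_logrank(pair_counts(n1 = 198, n2 = 135))
#' @export
stratified_logrank <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  G <- counts$G; H <- counts$H
  if (G + H == 0)
    stop("no comparable pairs: stratified log-rank statistic undefined",
         call. = FALSE)
  stat <- (G - H)^2 / (G + H)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 name = "Stratified log-rank (matched pairs)"),
            class = "pair_test")
}

#' McNemar's test on event indicators only
#'
#' Binary-outcome analogue of [stratified_logrank]: censoring and event
#' ordering are ignored and the classical discordant-pair statistic
#' \eqn{(B - C)^2/(B + C)} is computed, where `B` counts pairs with an
#' exposed-only event and `C` pairs with an unexposed-only event.  Use
#' only when follow-up is complete or equal within pairs; with censoring,
#' [stratified_logrank] is the appropriate test.
#'
#' @param pairs a [pair_data] object.
#' @return A `pair_test` object.
#' @export
mcnemar_test <- function(pairs) {
  validate_pair_data(pairs)
  B <- sum(pairs$y1 == 1 & pairs$y0 == 0)
  C <- sum(pairs$y1 == 0 & pairs$y0 == 1)
  if (B + C == 0)
    stop("no discordant pairs: McNemar statistic undefined", call. = FALSE)
  stat <- (B - C)^2 / (B + C)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 name = "McNemar (event indicators only)"),
            class = "pair_test")
}

#' @export
print.pair_test <- function(x, ...) {
  cat(x$name, "\n")
  cat(sprintf("  chi-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Matched-pair concordance statistic for censored time-to-event data
#'
#' Among comparable pairs (those whose shorter-time member had the
#' event), the proportion in which that member belongs to the
#' higher-hazard arm estimates the matched-pair concordance
#' \eqn{C = \max(G, H)/(G + H)}.  Its odds \eqn{C/(1 - C)} equal
#' \eqn{\max(G/H, H/G)}, i.e. the common hazard ratio (or its
#' reciprocal when the hazard ratio is below 1), which gives the common
#' HR a discrimination interpretation.  The estimate remains consistent
#' when censoring is independent of the event time conditional on the
#' pair and exposure, even when the censoring rates differ by exposure.
#'
#' @inheritParams common_hr_pmle
#' @return A `pair_cstat` object with fields `c` and `direction`
#'   (`"exposed"` if the exposed arm has shorter times, `"unexposed"`
#'   otherwise, `"none"` when G = H).
#' @examples
#' pair_c_statistic(pair_counts(n1 = 198, n2 = 135))
#' @export
pair_c_statistic <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  G <- counts$G; H <- counts$H
  if (G + H == 0)
    stop("no comparable pairs: C-statistic undefined", call. = FALSE)
  structure(list(c = max(G, H) / (G + H),
                 direction = if (G > H) "exposed" else if (H > G) "unexposed" else "none"),
            class = "pair_cstat")
}

#' @export
print.pair_cstat <- function(x, ...) {
  cat(sprintf("Matched-pair C-statistic: %.4f (odds %.4f)\n",
              x$c, x$c / (1 - x$c)))
  cat("  favored arm:", x$direction, "\n")
  invisible(x)
}

#' Mantel-Haenszel rate ratio for matched pairs
#'
#' Point estimator
#' \deqn{\widehat{HR}_{MH} = \frac{\sum_k Y_{k1} X_{k0}/(X_{k0}+X_{k1})}
#'                                {\sum_k Y_{k0} X_{k1}/(X_{k0}+X_{k1})}}
#' treating each pair as a two-cell rate table with person-time
#' denominators.  It approximates the conditional-Poisson MLE
#' ([poisson_cmle]) near hazard ratio 1.  No variance estimator is
#' returned.
#'
#' @param pairs a [pair_data] object.
#' @param alpha kept for interface symmetry; the interval is `NA`.
#' @return An `hr_estimate` with `se = NA` (point estimate only).
#' @export
mh_rate_ratio <- function(pairs, alpha = 0.05) {
  validate_pair_data(pairs)
  num <- sum(pairs$y1 * pairs$x0 / (pairs$x0 + pairs$x1))
  den <- sum(pairs$y0 * pairs$x1 / (pairs$x0 + pairs$x1))
  if (num == 0 && den == 0)
    stop("no events in any pair: rate ratio undefined", call. = FALSE)
  if (den == 0)
    stop("boundary estimate: no unexposed events, rate ratio diverges",
         call. = FALSE)
  flags <- if (num == 0) "no exposed events: estimate at boundary 0" else character()
  est <- new_hr_estimate(log_hr = log(num / den), se = NA_real_, alpha = alpha,
                         method = "Mantel-Haenszel rate ratio", flags = flags)
  est
}

#' Conditional-Poisson MLE of the common hazard ratio
#'
#' Under a stratified Poisson (constant-rate) model, conditioning on the
#' total number of events in each pair yields a binomial likelihood whose
#' maximizer solves the estimating equation
#' \deqn{\sum_k \frac{Y_{k1} X_{k0} - HR \cdot Y_{k0} X_{k1}}
#'                    {X_{k0} + HR \cdot X_{k1}} = 0.}
#' The estimating function is strictly decreasing in HR wherever it is
#' defined, so the root is unique; it is found by bracketed
#' root-finding on the log(HR) axis, expanding the initial bracket
#' \eqn{[-10, 10]} if needed.
#'
#' @param pairs a [pair_data] object.
#' @param alpha kept for interface symmetry; no variance estimator is
#'   provided, so the interval is `NA`.
#' @param tol absolute convergence tolerance on log(HR).
#' @return An `hr_estimate` with `se = NA` (point estimate only).
#' @export
poisson_cmle <- function(pairs, alpha = 0.05, tol = 1e-10) {
  validate_pair_data(pairs)
  if (!any(pairs$y1 == 1))
    stop("boundary estimate: no exposed events, CMLE root at 0", call. = FALSE)
  if (!any(pairs$y0 == 1))
    stop("boundary estimate: no unexposed events, CMLE diverges", call. = FALSE)
  ee <- function(log_hr) {
    hr <- exp(log_hr)
    sum((pairs$y1 * pairs$x0 - hr * pairs$y0 * pairs$x1) /
          (pairs$x0 + hr * pairs$x1))
  }
  lo <- -10; hi <- 10
  while (ee(lo) < 0 && lo > -40) lo <- lo - 10
  while (ee(hi) > 0 && hi < 40) hi <- hi + 10
  if (ee(lo) < 0 || ee(hi) > 0)
    stop("conditional-Poisson estimating equation has no sign change in ",
         "[exp(-40), exp(40)]", call. = FALSE)
  root <- stats::uniroot(ee, lower = lo, upper = hi, tol = tol)
  new_hr_estimate(log_hr = root$root, se = NA_real_, alpha = alpha,
                  method = "Conditional-Poisson MLE")
}
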