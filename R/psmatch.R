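#' Estimate propensity scores by logistic regression
#'
#' Fits a maximum-likelihood logistic model of exposure on the supplied
#' covariate columns (via iteratively reweighted least squares) and
#' returns the fitted exposure probabilities.  Any covariate transforms
#' (e.g. `exp(-0.12 * nodes)`, quadratic terms) are the caller's
#' responsibility: the model is linear in whatever columns it is given.
#'
#' @param data data.frame with an exposure column and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param exposure name of the 0/1 exposure column.
#' @return Numeric vector of propensity scores in (0, 1), one per row,
#'   with the fitted coefficients in attribute `"coefficients"`.
#' @export
fit_propensity <- function(data, covariates, exposure = "exposure") {
  miss <- setdiff(c(exposure, covariates), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  y <- data[[exposure]]
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop("exposure must be 0/1 with both groups nonempty", call. = FALSE)
  X <- as.matrix(data[, covariates, drop = FALSE])
  if (any(!is.finite(X))) stop("covariates must be finite", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- covariates[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                        family = stats::binomial())
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)", call. = FALSE)
  if (length(covariates) && max(abs(fit$coefficients[-1])) > 15)
    stop("separation: logistic coefficients diverging", call. = FALSE)
  structure(as.numeric(fit$fitted.values),
            coefficients = stats::setNames(fit$coefficients,
                                           c("(Intercept)", covariates)))
}

#' Caliper pair-matching on the propensity score, without replacement
#'
#' Greedy nearest-neighbor matching of exposed to unexposed subjects on
#' the propensity-score scale.  The caliper equals
#' `caliper_sd_fraction` times the standard deviation of the scores in
#' the unexposed (reference) group.  Exposed subjects are processed in
#' descending score order (hardest-to-match first); each takes the
#' nearest still-unmatched control within the caliper, with ties broken
#' by subject id.  The procedure is deterministic.
#'
#' @param scores numeric propensity scores in (0, 1).
#' @param exposure 0/1 exposure vector aligned with `scores`.
#' @param ids optional subject identifiers (default positional).
#' @param caliper_sd_fraction caliper width as a fraction of the
#'   reference-group score SD (default 0.2).
#' @return Object of class `match_result`: `pairs` (data.frame with
#'   `exposed_id`, `unexposed_id`, `ps_distance`), `n_matched`,
#'   `caliper`, `unmatched_exposed`, `unmatched_unexposed`.
#' @export
caliper_match <- function(scores, exposure, ids = NULL,
                          caliper_sd_fraction = 0.2) {
  stopifnot(length(scores) == length(exposure))
  if (any(scores <= 0 | scores >= 1))
    stop("scores must lie strictly in (0, 1)", call. = FALSE)
  if (!all(exposure %in% c(0, 1)))
    stop("exposure must be 0/1", call. = FALSE)
  if (is.null(ids)) ids <- seq_along(scores)
  ref_sd <- stats::sd(scores[exposure == 0])
  if (!is.finite(ref_sd) || ref_sd == 0)
    stop("degenerate caliper: reference-group scores have zero spread",
         call. = FALSE)
  caliper <- caliper_sd_fraction * ref_sd

  ei <- which(exposure == 1)
  ui <- which(exposure == 0)
  # descending score, ties by id, fully deterministic
  ei <- ei[order(-scores[ei], ids[ei])]
  avail <- rep(TRUE, length(ui))
  u_scores <- scores[ui]
  res_e <- res_u <- res_d <- vector("list", length(ei))
  n_matched <- 0L
  for (e in ei) {
    d <- abs(u_scores - scores[e])
    d[!avail] <- Inf
    if (all(is.infinite(d))) next
    best <- min(d)
    if (best > caliper) next
    cand <- which(d == best)
    pick <- cand[order(ids[ui][cand])][1]
    avail[pick] <- FALSE
    n_matched <- n_matched + 1L
    res_e[[n_matched]] <- ids[e]
    res_u[[n_matched]] <- ids[ui][pick]
    res_d[[n_matched]] <- best
  }
  matched_e <- unlist(res_e[seq_len(n_matched)])
  matched_u <- unlist(res_u[seq_len(n_matched)])
  pairs <- if (n_matched > 0)
    data.frame(exposed_id = matched_e, unexposed_id = matched_u,
               ps_distance = unlist(res_d[seq_len(n_matched)]))
  else data.frame(exposed_id = character(), unexposed_id = character(),
                  ps_distance = numeric())
  structure(list(pairs = pairs, n_matched = n_matched, caliper = caliper,
                 unmatched_exposed = setdiff(ids[exposure == 1], matched_e),
                 unmatched_unexposed = setdiff(ids[exposure == 0], matched_u)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Caliper match: %d pairs (caliper %.5f)\n",
              x$n_matched, x$caliper))
  cat(sprintf("  unmatched: %d exposed, %d unexposed\n",
              length(x$unmatched_exposed), length(x$unmatched_unexposed)))
  invisible(x)
}

#' Build a matched-pair cohort from a covariate table
#'
#' Convenience pipeline for the full application recipe: fit the
#' propensity model, caliper-match without replacement, and return the
#' matched cohort as a [pair_data] object using the carried-through
#' `time` and `event` columns.
#'
#' @inheritParams fit_propensity
#' @inheritParams caliper_match
#' @param id,time,event column names of the subject id, follow-up time
#'   and event indicator.
#' @return A list with `cohort` (a [pair_data] object), `match`
#'   (the `match_result`) and `scores`.
#' @export
ps_match_cohort <- function(data, covariates, exposure = "exposure",
                            id = "subject_id", time = "time", event = "event",
                            caliper_sd_fraction = 0.2) {
  miss <- setdiff(c(id, time, event), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  scores <- fit_propensity(data, covariates, exposure = exposure)
  m <- caliper_match(scores, data[[exposure]], ids = data[[id]],
                     caliper_sd_fraction = caliper_sd_fraction)
  ie <- match(m$pairs$exposed_id, data[[id]])
  iu <- match(m$pairs$unexposed_id, data[[id]])
  cohort <- pair_data(pair_id = paste0(m$pairs$exposed_id, ":",
                                       m$pairs$unexposed_id),
                      x1 = data[[time]][ie], y1 = data[[event]][ie],
                      x0 = data[[time]][iu], y0 = data[[event]][iu])
  list(cohort = cohort, match = m, scores = scores)
}
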