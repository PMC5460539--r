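# Breslow partial-likelihood machinery.
#
# All risk-set sums are computed vectorized: rows are sorted by
# (stratum, time); within a stratum the sum over {j : t_j >= t_i} of a
# quantity v_j is a reverse cumulative sum read at the first index of the
# (stratum, time) tie group, so tied subjects share one risk set.  The
# risk set at t contains every subject with observed time >= t, which
# places subjects censored at t at risk for events at t.

# evaluate Breslow log partial likelihood, gradient, information (and
# optionally per-subject score residuals) at beta, on pre-sorted data
.cox_eval <- function(beta, env, residuals = FALSE) {
  X <- env$X; w <- env$w; d <- env$d
  eta <- drop(X %*% beta)
  r <- w * exp(eta)
  p <- ncol(X)

  # risk-set sums S0 (scalar), S1 (p), S2 (p x p upper triangle)
  rX <- X * r
  # sum over {tie_first[i] .. grp_last[i]} = cs[grp_last] - cs[tie_first - 1]
  risk_sum <- function(v) {
    cs <- cumsum(v)
    cs[env$grp_last] - c(0, cs)[env$tie_first]
  }
  S0 <- risk_sum(r)
  S1 <- matrix(0, env$n, p)
  for (j in seq_len(p)) S1[, j] <- risk_sum(rX[, j])
  xbar <- S1 / S0

  dw <- d * w
  loglik <- sum(dw * eta) - sum(dw * log(S0))
  grad <- colSums(dw * (X - xbar))

  info <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in j:p) {
    S2jk <- risk_sum(rX[, j] * X[, k])
    v <- sum(dw * (S2jk / S0 - xbar[, j] * xbar[, k]))
    info[j, k] <- v; info[k, j] <- v
  }

  out <- list(loglik = loglik, grad = grad, info = info)
  if (residuals) {
    # score residuals: d_i (x_i - xbar(t_i)) - r_i * sum_{t_d <= t_i} of
    # (x_i - xbar(t_d)) dLambda0(t_d), cumulated within stratum over
    # event times up to and including t_i
    inc0 <- dw / S0                  # dLambda0 mass carried by each event row
    A <- cumsum(inc0)
    A <- A[env$tie_last] - c(0, A)[env$grp_first]
    B <- matrix(0, env$n, p)
    for (j in seq_len(p)) {
      bj <- cumsum(inc0 * xbar[, j])
      B[, j] <- bj[env$tie_last] - c(0, bj)[env$grp_first]
    }
    U <- d * (X - xbar) - (r / w) * (X * A - B)
    out$score_resid <- w * U
  }
  out
}

.cox_prepare <- function(time, status, X, strata, weights) {
  n <- length(time)
  s <- if (is.null(strata)) rep(1L, n) else as.integer(factor(strata))
  ord <- order(s, time)
  time <- time[ord]; status <- status[ord]; s <- s[ord]
  X <- X[ord, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, n) else weights[ord]

  new_grp <- c(TRUE, s[-1] != s[-n])
  idx <- seq_len(n)
  # nearest group boundary: forward fill uses a prefix cummax over start
  # markers, backward fill a suffix cummin over end markers
  last_of <- function(is_end) as.integer(rev(cummin(rev(ifelse(is_end, idx, Inf)))))
  grp_last <- last_of(c(new_grp[-1], TRUE))
  grp_first <- as.integer(cummax(ifelse(new_grp, idx, 0L)))
  new_tie <- new_grp | c(TRUE, time[-1] != time[-n])
  tie_first <- as.integer(cummax(ifelse(new_tie, idx, 0L)))
  tie_last <- last_of(c(new_tie[-1], TRUE))

  list(n = n, time = time, d = status, X = X, w = w, s = s, ord = ord,
       grp_last = grp_last, grp_first = grp_first,
       tie_first = tie_first, tie_last = tie_last)
}

#' Fit a Cox proportional hazards model by Breslow partial likelihood
#'
#' Newton-Raphson maximization of the (optionally stratified and
#' case-weighted) Breslow partial likelihood, with model-based standard
#' errors from the inverse observed information and, when a cluster
#' column is supplied, a cluster-robust sandwich variance built from
#' score residuals summed within clusters (no small-sample correction).
#'
#' On matched-pair data fitted with `strata` equal to the pair
#' identifier and the exposure indicator as the single covariate, the
#' returned coefficient equals `log(G/H)` of [common_hr_pmle] and the
#' inverse information equals `1/G + 1/H`, exactly.
#'
#' @param data data.frame in long (one row per subject) format.
#' @param covariates character vector of covariate column names.
#' @param time,event names of the follow-up-time and event-indicator
#'   columns (defaults `"time"`, `"event"`).
#' @param strata optional name of a stratum column (e.g. the pair id).
#' @param cluster optional name of a cluster column for the robust
#'   sandwich variance (e.g. the pair id in an unstratified fit).
#' @param weights optional name of a positive case-weight column.
#' @param init initial coefficient vector (default zeros).
#' @param tol convergence tolerance on the max-norm of the gradient.
#' @param max_iter maximum Newton-Raphson iterations.
#' @return An object of class `cox_pl_fit`: list with `beta`,
#'   `se_model`, `var_model`, `se_robust`/`var_robust` (when `cluster`
#'   given), `loglik` (at init and at solution), `iterations`,
#'   `converged`, `score_at_null`, `info_at_null`, `n`, `n_events`.
#' @examples
#' ph <- pairs_to_long(fixture_cohort("one_per_type"))
#' fit_cox(ph, covariates = "exposure", strata = "pair_id")
#' @export
fit_cox <- function(data, covariates, time = "time", event = "event",
                    strata = NULL, cluster = NULL, weights = NULL,
                    init = NULL, tol = 1e-8, max_iter = 50) {
  need <- c(time, event, covariates, strata, cluster, weights)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  tt <- as.numeric(data[[time]]); dd <- as.numeric(data[[event]])
  if (any(!is.finite(tt) | tt <= 0)) stop("times must be positive", call. = FALSE)
  if (any(!dd %in% c(0, 1))) stop("event indicator must be 0/1", call. = FALSE)
  if (sum(dd) == 0) stop("no events: partial likelihood is flat", call. = FALSE)
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  ww <- if (is.null(weights)) NULL else as.numeric(data[[weights]])
  if (!is.null(ww) && any(ww <= 0)) stop("weights must be positive", call. = FALSE)

  env <- .cox_prepare(tt, dd, X, if (is.null(strata)) NULL else data[[strata]], ww)
  p <- ncol(X)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)

  at0 <- .cox_eval(rep(0, p), env)
  cur <- if (all(beta == 0)) at0 else .cox_eval(beta, env)
  loglik0 <- if (all(beta == 0)) at0$loglik else .cox_eval(rep(0, p), env)$loglik
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e)
      stop("singular information matrix: covariates collinear within ",
           "contributing risk sets", call. = FALSE))
    new_beta <- beta + step
    nxt <- .cox_eval(new_beta, env)
    halvings <- 0L
    while ((!is.finite(nxt$loglik) || nxt$loglik < cur$loglik) && halvings < 20L) {
      step <- step / 2; halvings <- halvings + 1L
      new_beta <- beta + step
      nxt <- .cox_eval(new_beta, env)
    }
    beta <- new_beta; cur <- nxt
    if (any(abs(beta) > 15))
      stop("separation: |coefficient| exceeded 15 on the log scale ",
           "(monotone likelihood)", call. = FALSE)
  }
  if (!converged && max(abs(cur$grad)) < tol) converged <- TRUE
  if (!converged)
    stop("Newton-Raphson did not converge in ", max_iter,
         " iterations (last max gradient ", format(max(abs(cur$grad))), ")",
         call. = FALSE)

  var_model <- solve(cur$info)
  fit <- list(beta = stats::setNames(beta, covariates),
              var_model = var_model,
              se_model = stats::setNames(sqrt(diag(var_model)), covariates),
              loglik = c(init = loglik0, final = cur$loglik),
              iterations = iter, converged = converged,
              score_at_null = at0$grad, info_at_null = at0$info,
              n = env$n, n_events = sum(env$d), ties = "breslow")
  if (!is.null(cluster)) {
    ev <- .cox_eval(beta, env, residuals = TRUE)
    cl <- as.factor(data[[cluster]])[env$ord]
    Uc <- rowsum(ev$score_resid, cl)
    meat <- crossprod(Uc)
    var_robust <- var_model %*% meat %*% var_model
    fit$var_robust <- var_robust
    fit$se_robust <- stats::setNames(sqrt(diag(var_robust)), covariates)
  }
  class(fit) <- "cox_pl_fit"
  fit
}

#' @export
print.cox_pl_fit <- function(x, ...) {
  cat("Cox partial-likelihood fit (Breslow ties),", x$n, "subjects,",
      x$n_events, "events\n")
  tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta),
                    se = x$se_model, check.names = FALSE)
  if (!is.null(x$se_robust)) tab$`robust se` <- x$se_robust
  print(tab)
  cat(sprintf("log partial likelihood: %.4f (null %.4f), %d iterations\n",
              x$loglik[["final"]], x$loglik[["init"]], x$iterations))
  invisible(x)
}

#' Score test of no covariate effect in a Cox model
#'
#' Evaluates the partial-likelihood score and information at coefficient
#' zero and returns the quadratic-form statistic
#' \eqn{U(0)^\top I(0)^{-1} U(0)}, chi-squared with `p` df under the
#' null.  For pair-stratified data with a single binary exposure this is
#' algebraically \eqn{(G-H)^2/(G+H)}, the stratified log-rank test; for
#' unstratified two-group data it is the classical log-rank statistic.
#'
#' @inheritParams fit_cox
#' @return A `pair_test` object with `statistic`, `df`, `p_value`.
#' @export
score_test_null <- function(data, covariates, time = "time", event = "event",
                            strata = NULL, weights = NULL) {
  tt <- as.numeric(data[[time]]); dd <- as.numeric(data[[event]])
  if (sum(dd) == 0) stop("no events: score test undefined", call. = FALSE)
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  ww <- if (is.null(weights)) NULL else as.numeric(data[[weights]])
  env <- .cox_prepare(tt, dd, X, if (is.null(strata)) NULL else data[[strata]], ww)
  at0 <- .cox_eval(rep(0, ncol(X)), env)
  stat <- drop(crossprod(at0$grad, solve(at0$info, at0$grad)))
  structure(list(statistic = stat, df = ncol(X),
                 p_value = stats::pchisq(stat, df = ncol(X), lower.tail = FALSE),
                 name = "Partial-likelihood score test at beta = 0"),
            class = "pair_test")
}
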