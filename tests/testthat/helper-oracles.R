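# Shared fixtures and independent oracles for the test suite.  The
# oracles deliberately use naive per-pair loops and brute-force scans so
# they share no code path with the vectorized implementations.

# random matched-pair cohort; round_digits > 0 induces tied times
rand_cohort <- function(n, seed, cens_rate = 0.7, round_digits = NULL) {
  set.seed(seed)
  t1 <- rexp(n, 1.3); t0 <- rexp(n, 1)
  u1 <- rexp(n, cens_rate); u0 <- rexp(n, cens_rate)
  x1 <- pmin(t1, u1); x0 <- pmin(t0, u0)
  y1 <- as.numeric(x1 == t1); y0 <- as.numeric(x0 == t0)
  if (!is.null(round_digits)) {
    x1 <- round(x1, round_digits) + 10^(-round_digits - 2)
    x0 <- round(x0, round_digits) + 10^(-round_digits - 2)
  }
  pair_data(pair_id = seq_len(n), x1 = x1, y1 = y1, x0 = x0, y0 = y0)
}

# comparable-pair counts from the definition, one pair at a time:
# G counts pairs whose shorter-observed-time member is the exposed one
# and had the event (ties: event precedes censoring; double events at
# one time count once in each of G and H)
brute_force_GH <- function(pairs) {
  G <- H <- 0L
  for (i in seq_len(nrow(pairs))) {
    x1 <- pairs$x1[i]; y1 <- pairs$y1[i]
    x0 <- pairs$x0[i]; y0 <- pairs$y0[i]
    if (x1 == x0 && y1 == 1 && y0 == 1) { G <- G + 1L; H <- H + 1L; next }
    exposed_first <- x1 < x0 || (x1 == x0 && y1 == 1)
    if (exposed_first && y1 == 1) G <- G + 1L
    if (!exposed_first && y0 == 1) H <- H + 1L
  }
  list(G = G, H = H)
}

# direct double-loop Breslow log partial likelihood (no sorting tricks)
loglik_breslow_oracle <- function(beta, time, event, x, strata = NULL) {
  if (is.null(strata)) strata <- rep(1, length(time))
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    at_risk <- strata == strata[i] & time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# reference greedy caliper matcher following the documented order
greedy_match_reference <- function(scores, exposure, ids, caliper) {
  exp_idx <- which(exposure == 1)
  exp_idx <- exp_idx[order(-scores[exp_idx], ids[exp_idx])]
  un_idx <- which(exposure == 0)
  taken <- logical(length(un_idx))
  out <- NULL
  for (e in exp_idx) {
    best_j <- NA; best_d <- Inf
    for (j in seq_along(un_idx)) {
      if (taken[j]) next
      d <- abs(scores[un_idx[j]] - scores[e])
      if (d < best_d ||
          (d == best_d && !is.na(best_j) &&
           order(ids[un_idx[c(j, best_j)]])[1] == 1)) {
        best_d <- d; best_j <- j
      }
    }
    if (!is.na(best_j) && best_d <= caliper) {
      taken[best_j] <- TRUE
      out <- rbind(out, data.frame(exposed_id = ids[e],
                                   unexposed_id = ids[un_idx[best_j]],
                                   ps_distance = best_d))
    }
  }
  out
}

# swap exposure labels within every pair
swap_exposure <- function(pairs) {
  pair_data(pair_id = pairs$pair_id, x1 = pairs$x0, y1 = pairs$y0,
            x0 = pairs$x1, y0 = pairs$y1)
}
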