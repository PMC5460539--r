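#' Construct a matched-pair survival data set
#'
#' A matched-pair cohort is stored one row per pair, holding the observed
#' follow-up time and event indicator of the exposed member (`x1`, `y1`)
#' and of the unexposed member (`x0`, `y0`).  This is the atom of all
#' closed-form estimation in the package.
#'
#' @param pair_id vector of unique pair identifiers.
#' @param x1,x0 positive follow-up times of the exposed / unexposed member.
#' @param y1,y0 event indicators (0 = censored, 1 = event).
#' @return A `data.frame` of class `pair_data` with columns
#'   `pair_id`, `x1`, `y1`, `x0`, `y0`.
#' @examples
#' pair_data(pair_id = 1:2, x1 = c(0.5, 2), y1 = c(1, 0),
#'           x0 = c(0.9, 1), y0 = c(1, 1))
#' @export
pair_data <- function(pair_id, x1, y1, x0, y0) {
  out <- data.frame(pair_id = pair_id, x1 = as.numeric(x1), y1 = as.numeric(y1),
                    x0 = as.numeric(x0), y0 = as.numeric(y0),
                    stringsAsFactors = FALSE)
  validate_pair_data(out)
  class(out) <- c("pair_data", "data.frame")
  out
}

validate_pair_data <- function(pairs) {
  req <- c("pair_id", "x1", "y1", "x0", "y0")
  miss <- setdiff(req, names(pairs))
  if (length(miss))
    stop("pair data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(pairs$pair_id))
    stop("duplicate pair_id: ",
         paste(unique(pairs$pair_id[duplicated(pairs$pair_id)]), collapse = ", "),
         call. = FALSE)
  bad_t <- !is.finite(pairs$x1) | !is.finite(pairs$x0) | pairs$x1 <= 0 | pairs$x0 <= 0
  if (any(bad_t))
    stop("nonpositive or non-finite follow-up time in pair(s): ",
         paste(pairs$pair_id[bad_t], collapse = ", "), call. = FALSE)
  bad_y <- !(pairs$y1 %in% c(0, 1)) | !(pairs$y0 %in% c(0, 1))
  if (any(bad_y))
    stop("non-binary event indicator in pair(s): ",
         paste(pairs$pair_id[bad_y], collapse = ", "), call. = FALSE)
  invisible(pairs)
}

#' Classify matched pairs into the nine observable pair types
#'
#' Each pair is assigned one of nine codes according to which member's
#' observed time is shorter and whether that member (and the later one)
#' experienced the event:
#' \describe{
#'   \item{1}{exposed event first, unexposed event later}
#'   \item{2}{unexposed event first, exposed event later}
#'   \item{3}{exposed event first, unexposed censored later}
#'   \item{4}{unexposed event first, exposed censored later}
#'   \item{5}{exposed censored first, unexposed event later}
#'   \item{6}{unexposed censored first, exposed event later}
#'   \item{7}{exposed censored first, unexposed censored later}
#'   \item{8}{unexposed censored first, exposed censored later}
#'   \item{9}{both censored simultaneously at the end of follow-up `tau`}
#' }
#' Types 1 and 3 contribute a factor exp(b)/(1 + exp(b)) to the
#' pair-stratified partial likelihood, types 2 and 4 contribute
#' 1/(1 + exp(b)), and types 5--9 contribute nothing.
#'
#' Tie conventions: an event and a censoring recorded at the same time are
#' ordered event-before-censoring, so the event holder counts as the
#' shorter-time member (type 3 or 4).  Two censorings at the same time
#' before `tau` are coded 7.  Two events at the same time receive the
#' distinguished code 0; under the Breslow tie approximation such a pair
#' contributes like one type-1 plus one type-2 pair.
#'
#' @param pairs a [pair_data] object (or data.frame with its columns).
#' @param tau end of follow-up; `Inf` (default) means no administrative
#'   censoring, in which case type 9 never occurs.
#' @return integer vector of codes, 0--9, one per pair.
#' @export
classify_pairs <- function(pairs, tau = Inf) {
  validate_pair_data(pairs)
  if (is.finite(tau) && any(pairs$x1 > tau | pairs$x0 > tau))
    stop("follow-up time exceeds tau", call. = FALSE)
  x1 <- pairs$x1; y1 <- pairs$y1; x0 <- pairs$x0; y0 <- pairs$y0
  # break event-vs-censoring ties by placing events first
  first_exposed  <- x1 < x0 | (x1 == x0 & y1 == 1 & y0 == 0)
  first_unexposed <- x0 < x1 | (x1 == x0 & y0 == 1 & y1 == 0)
  code <- integer(nrow(pairs))
  tied_events <- x1 == x0 & y1 == 1 & y0 == 1
  code[tied_events] <- 0L
  code[first_exposed  & y1 == 1 & y0 == 1] <- 1L
  code[first_unexposed & y1 == 1 & y0 == 1] <- 2L
  code[first_exposed  & y1 == 1 & y0 == 0] <- 3L
  code[first_unexposed & y0 == 1 & y1 == 0] <- 4L
  code[first_exposed  & y1 == 0 & y0 == 1] <- 5L
  code[first_unexposed & y0 == 0 & y1 == 1] <- 6L
  code[first_exposed  & y1 == 0 & y0 == 0] <- 7L
  code[first_unexposed & y0 == 0 & y1 == 0] <- 8L
  both_cens_tied <- x1 == x0 & y1 == 0 & y0 == 0
  at_tau <- is.finite(tau) & x1 == tau & x0 == tau
  code[both_cens_tied] <- 7L          # exposed listed first by convention
  code[both_cens_tied & at_tau] <- 9L
  code
}

#' @rdname classify_pairs
#' @param x1,x0,y1,y0 a single pair's times and event indicators.
#' @export
classify_pair <- function(x1, y1, x0, y0, tau = Inf) {
  classify_pairs(pair_data(pair_id = "p", x1 = x1, y1 = y1, x0 = x0, y0 = y0),
                 tau = tau)
}

#' Reduce a matched-pair cohort to its pair-type counts and (G, H)
#'
#' Tabulates the pair-type codes of [classify_pairs] and computes the two
#' sufficient statistics of the pair-stratified partial likelihood:
#' `G`, the number of pairs in which the exposed member has the shorter
#' observed time and experienced an event, and `H`, the analogous count
#' for the unexposed member.  A within-pair tied-event pair (code 0)
#' increments both `G` and `H` by one (Breslow convention).
#'
#' `G` and `H` depend on the data only through the within-pair ordering of
#' observed times and the event indicators, so they are invariant under
#' any strictly increasing transformation of the time axis.
#'
#' @inheritParams classify_pairs
#' @return An object of class `pair_counts`: a list with integer fields
#'   `n1`--`n9`, `n_tied_events`, `G`, `H` and `n_total`.
#' @examples
#' ph <- fixture_cohort("one_per_type")
#' tabulate_pairs(ph, tau = 10)
#' @export
tabulate_pairs <- function(pairs, tau = Inf) {
  code <- classify_pairs(pairs, tau = tau)
  n <- vapply(0:9, function(k) sum(code == k), integer(1))
  names(n) <- paste0("n", 0:9)
  counts <- as.list(n[paste0("n", 1:9)])
  counts$n_tied_events <- n[["n0"]]
  counts$G <- counts$n1 + counts$n3 + counts$n_tied_events
  counts$H <- counts$n2 + counts$n4 + counts$n_tied_events
  counts$n_total <- length(code)
  class(counts) <- "pair_counts"
  counts
}

#' Assemble pair-type counts directly
#'
#' Constructor for a `pair_counts` object from known type counts, for use
#' when only the counts (not subject-level data) are available.
#'
#' @param n1,n2,n3,n4,n5,n6,n7,n8,n9 nonnegative pair-type counts.
#' @param n_tied_events number of pairs with both events at the same time.
#' @return A `pair_counts` object; see [tabulate_pairs].
#' @examples
#' pair_counts(n1 = 100, n2 = 60, n3 = 98, n4 = 75)  # G = 198, H = 135
#' @export
pair_counts <- function(n1 = 0, n2 = 0, n3 = 0, n4 = 0, n5 = 0, n6 = 0,
                        n7 = 0, n8 = 0, n9 = 0, n_tied_events = 0) {
  counts <- list(n1 = n1, n2 = n2, n3 = n3, n4 = n4, n5 = n5, n6 = n6,
                 n7 = n7, n8 = n8, n9 = n9, n_tied_events = n_tied_events)
  if (any(unlist(counts) < 0) || any(unlist(counts) != round(unlist(counts))))
    stop("pair-type counts must be nonnegative integers", call. = FALSE)
  counts <- lapply(counts, as.integer)
  counts$G <- counts$n1 + counts$n3 + counts$n_tied_events
  counts$H <- counts$n2 + counts$n4 + counts$n_tied_events
  counts$n_total <- sum(unlist(counts[paste0("n", 1:9)])) + counts$n_tied_events
  class(counts) <- "pair_counts"
  counts
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("Matched-pair type counts (", x$n_total, " pairs)\n", sep = "")
  tab <- unlist(x[paste0("n", 1:9)])
  print(tab)
  if (x$n_tied_events > 0)
    cat("tied-event pairs (counted in both G and H):", x$n_tied_events, "\n")
  cat("G =", x$G, " H =", x$H,
      " (comparable pairs: shorter-time member had the event)\n")
  invisible(x)
}

#' @export
as.data.frame.pair_counts <- function(x, ...) {
  data.frame(type = c(1:9, "tied_events"),
             count = c(unlist(x[paste0("n", 1:9)]), x$n_tied_events))
}
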