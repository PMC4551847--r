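#' Number of spline knots from the number of time points
#'
#' The knot count grows slowly with the number of distinct measured time
#' points `T`: `K = max(5, min(floor(T/4), 40))`. With few time points the
#' floor of 5 keeps the basis flexible; the cap of 40 bounds the cost for
#' densely sampled series.
#'
#' @param n_times integer, number of distinct observed time points (>= 2).
#' @return integer knot count.
#' @export
#' @examples
#' knot_count(6)   # 5
#' knot_count(24)  # 6
#' knot_count(200) # 40
knot_count <- function(n_times) {
  n_times <- as.integer(n_times)
  if (is.na(n_times) || n_times < 2)
    stop("need at least 2 distinct time points")
  max(5L, min(n_times %/% 4L, 40L))
}

#' Construct a truncated-line spline basis
#'
#' Places `K` knots at equally spaced empirical quantiles (probabilities
#' k/(K+1), k = 1..K, type-7 interpolation) of the observed time values,
#' replicate multiplicity included. Duplicate knot values -- unavoidable
#' when `K` is close to the number of distinct times -- are collapsed, so
#' the returned basis may have fewer than `K` knots.
#'
#' @param times numeric vector of all observed time values.
#' @param K knot count; defaults to [knot_count()] of the number of
#'   distinct values in `times`.
#' @return object of class `spline_basis`: list with `knots` (sorted,
#'   de-duplicated) and `K` (the requested count before de-duplication).
#' @export
spline_basis <- function(times, K = NULL) {
  times <- times[is.finite(times)]
  n_distinct <- length(unique(times))
  if (is.null(K)) K <- knot_count(n_distinct)
  probs <- seq_len(K) / (K + 1)
  knots <- unname(stats::quantile(times, probs = probs, type = 7))
  knots <- sort(unique(knots))
  structure(list(knots = knots, K = K), class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("Truncated-line spline basis: K =", x$K, "requested,",
      length(x$knots), "distinct knot(s) at\n  ",
      paste(signif(x$knots, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the truncated-line basis
#'
#' Component `k` of the basis at time `t` is `(t - kappa_k)_+`, i.e.
#' `t - kappa_k` where positive and 0 otherwise: zero left of the knot,
#' linear with unit slope to its right. Sums of these terms (plus an
#' intercept and slope) give continuous piecewise-linear curves with
#' breakpoints at the knots.
#'
#' @param t numeric vector of evaluation times.
#' @param knots sorted knot positions, or a `spline_basis`.
#' @return length(t) x length(knots) matrix.
#' @export
truncated_line_basis <- function(t, knots) {
  if (inherits(knots, "spline_basis")) knots <- knots$knots
  Z <- outer(t, knots, "-")
  Z[Z < 0] <- 0
  Z
}
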