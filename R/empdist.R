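#' Discrete empirical distributions over nonnegative counts
#'
#' `empdist()` builds a discrete distribution on a set of nonnegative integer
#' support points; `fit_empirical()` fits one from observed counts by relative
#' frequency. These objects carry the (empirical) probability mass and
#' cumulative distribution functions used throughout the newsvendor solvers.
#'
#' @param support Nonnegative integer support points (duplicates are merged).
#' @param probability Nonnegative weights, same length as `support`; they are
#'   normalised to sum to one.
#' @return An object of class `empdist`: a list with sorted integer `support`,
#'   `probability` summing to 1, and the cumulative `cdf`.
#' @examples
#' d <- fit_empirical(c(0, 1, 2, 3))
#' pmf(d, 2)
#' cdf(d, 2)
#' e_min(d, 2) # E[min(D, 2)]
#' @export
empdist <- function(support, probability) {
  support <- check_counts(support, "support")
  if (!is.numeric(probability) || length(probability) != length(support)) {
    abort("`probability` must be numeric and match `support` in length.")
  }
  if (anyNA(probability) || any(probability < 0)) {
    abort("`probability` must be nonnegative.")
  }
  tot <- sum(probability)
  if (tot <= 0) abort("`probability` must have positive total mass.")
  agg <- rowsum(probability / tot, group = support)
  support <- as.integer(rownames(agg))
  probability <- as.numeric(agg)
  ord <- order(support)
  structure(
    list(
      support = support[ord],
      probability = probability[ord],
      cdf = cumsum(probability[ord])
    ),
    class = "empdist"
  )
}

#' @rdname empdist
#' @param samples Observed nonnegative integer counts (at least one).
#' @export
fit_empirical <- function(samples) {
  samples <- check_counts(samples, "samples")
  tab <- table(samples)
  empdist(as.integer(names(tab)), as.numeric(tab))
}

#' @export
print.empdist <- function(x, ...) {
  cat("<empdist> on {", min(x$support), "..", max(x$support), "}, ",
      length(x$support), " support points, mean ",
      format(mean(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname empdist
#' @param d An `empdist` object.
#' @param x,q Integer evaluation points (vectorised).
#' @export
pmf <- function(d, x) {
  stopifnot(inherits(d, "empdist"))
  p <- d$probability[match(x, d$support)]
  ifelse(is.na(p), 0, p)
}

#' @rdname empdist
#' @export
cdf <- function(d, q) {
  stopifnot(inherits(d, "empdist"))
  idx <- findInterval(q, d$support)
  ifelse(idx == 0, 0, d$cdf[pmax(idx, 1L)])
}

# P(D > j), vectorised
surv <- function(d, j) 1 - cdf(d, j)

#' @export
mean.empdist <- function(x, ...) sum(x$support * x$probability)

#' Expected served demand under a quota
#'
#' `e_min(d, Q)` returns `E[min(D, Q)]` for a discrete distribution, computed
#' exactly via the tail-sum identity `E[min(D, Q)] = sum_{j=0}^{Q-1} P(D > j)`.
#' `e_min_vec(d, Qmax)` returns the whole vector for quotas `0..Qmax`.
#'
#' @param d An [empdist] object.
#' @param Q Nonnegative integer quota.
#' @param Qmax Largest quota of interest.
#' @export
e_min <- function(d, Q) {
  stopifnot(inherits(d, "empdist"))
  check_scalar_number(Q, "Q", lower = 0)
  if (Q == 0) return(0)
  sum(surv(d, seq_len(Q) - 1L))
}

#' @rdname e_min
#' @export
e_min_vec <- function(d, Qmax) {
  stopifnot(inherits(d, "empdist"))
  check_scalar_number(Qmax, "Qmax", lower = 0)
  c(0, cumsum(surv(d, 0:max(Qmax - 1L, 0L))))[1:(Qmax + 1L)]
}
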