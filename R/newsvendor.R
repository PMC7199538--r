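#' Two-class bed-allocation problem instance
#'
#' A single-period problem: `K` beds are split between an urgent class
#' (quota `Q1`, adjusted per-unit revenue `r1`) and a regular class (quota
#' `Q2 = K - Q1`, revenue `r2`). The adjusted revenues fold the equity
#' priority of urgent patients into the monetary reward, so the model
#' assumes `r1 > r2`; violating that is allowed but flagged with a warning.
#'
#' @param K Total bed capacity (nonnegative integer).
#' @param r1 Adjusted per-unit revenue of an urgent admission (> 0).
#' @param r2 Adjusted per-unit revenue of a regular admission (> 0).
#' @return An object of class `two_class_problem`.
#' @examples
#' two_class_problem(K = 140, r1 = 3, r2 = 1)
#' @export
two_class_problem <- function(K, r1 = 3, r2 = 1) {
  check_scalar_number(K, "K", lower = 0)
  if (K != floor(K)) abort("`K` must be an integer.")
  check_scalar_number(r1, "r1", lower = 1e-12)
  check_scalar_number(r2, "r2", lower = 1e-12)
  if (r1 <= r2) {
    warn("Expected r1 > r2 (urgent priority); proceeding with r1 <= r2.")
  }
  structure(list(K = as.integer(K), r1 = r1, r2 = r2),
            class = "two_class_problem")
}

#' @export
print.two_class_problem <- function(x, ...) {
  cat("<two_class_problem> K =", x$K, " r1 =", x$r1, " r2 =", x$r2, "\n")
  invisible(x)
}

new_allocation <- function(Q1, objective, method, n_used, prob,
                           objective_curve = NULL) {
  structure(
    list(Q1 = as.integer(Q1), Q2 = prob$K - as.integer(Q1),
         objective = objective, method = method, n_used = n_used,
         K = prob$K, r1 = prob$r1, r2 = prob$r2,
         objective_curve = objective_curve),
    class = "bed_allocation"
  )
}

#' @export
print.bed_allocation <- function(x, ...) {
  cat("<bed_allocation> [", x$method, "] Q1 =", x$Q1, " Q2 =", x$Q2,
      " objective =", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' @export
tidy.bed_allocation <- function(x, ...) {
  tibble(Q1 = x$Q1, Q2 = x$Q2, objective = x$objective,
         method = x$method, n_used = x$n_used)
}

#' @export
glance.bed_allocation <- function(x, ...) {
  tibble(objective = x$objective, method = x$method, K = x$K,
         r1 = x$r1, r2 = x$r2, n_used = x$n_used)
}

#' Expected adjusted revenue of an allocation
#'
#' Computes `r1 * E[min(D1, Q1)] + r2 * E[min(D2, K - Q1)]` exactly for
#' discrete demand distributions, using the tail-sum identity
#' `E[min(D, Q)] = sum_{j=0}^{Q-1} P(D > j)`.
#'
#' @param Q1 Urgent quota, an integer in `[0, K]`.
#' @param distX,distY [empdist] demand distributions of the urgent and
#'   regular class.
#' @param prob A [two_class_problem].
#' @return The expected adjusted revenue (scalar).
#' @export
expected_adjusted_revenue <- function(Q1, distX, distY, prob) {
  stopifnot(inherits(prob, "two_class_problem"))
  check_scalar_number(Q1, "Q1", lower = 0, upper = prob$K)
  if (Q1 != floor(Q1)) abort("`Q1` must be an integer.")
  prob$r1 * e_min(distX, Q1) + prob$r2 * e_min(distY, prob$K - Q1)
}

# full objective curve over Q1 = 0..K
revenue_curve <- function(distX, distY, prob) {
  K <- prob$K
  v1 <- prob$r1 * e_min_vec(distX, K)
  v2 <- prob$r2 * e_min_vec(distY, K)
  v1 + rev(v2)
}

#' Exact single-period solver
#'
#' Maximizes the expected adjusted revenue over the integer urgent quota
#' `Q1 in {0, ..., K}` by exhaustive sweep; the first-order crossing
#' condition `r1 * P(D1 >= q) = r2 * P(D2 >= K - q)` of the continuous
#' analysis is exposed as a verification predicate via
#' [balance_condition()], not used for the search. Among tied maximizers the
#' smallest `Q1` is returned (conservative toward the regular class).
#'
#' @inheritParams expected_adjusted_revenue
#' @return A `bed_allocation` with `Q1`, `Q2`, `objective` and the full
#'   `objective_curve`.
#' @examples
#' dX <- fit_empirical(c(0, 1, 2, 3, 4))
#' dY <- fit_empirical(c(0, 1, 2, 3, 4))
#' solve_exact(dX, dY, two_class_problem(K = 4, r1 = 3, r2 = 1))
#' @export
solve_exact <- function(distX, distY, prob) {
  stopifnot(inherits(prob, "two_class_problem"),
            inherits(distX, "empdist"), inherits(distY, "empdist"))
  obj <- revenue_curve(distX, distY, prob)
  q1 <- which.max(obj) - 1L # which.max returns the first (smallest) maximizer
  new_allocation(q1, obj[q1 + 1L], "exact", NA_integer_, prob,
                 objective_curve = obj)
}

#' Verify the discrete optimality (balance) condition
#'
#' For a candidate quota the continuous first-order condition
#' `r1 * P(D1 >= q) = r2 * P(D2 >= K - q)` is generally unattainable with
#' step CDFs; the discrete analogue is that the smallest `q` at which
#' `r1 * P(D1 >= q+1) <= r2 * P(D2 >= K - q)` flips holds at the optimum,
#' and that whenever `r1 > r2` the optimum leans urgent:
#' `P(D2 >= K - Q1) >= P(D1 >= Q1)`.
#'
#' @param sol A `bed_allocation` from one of the solvers.
#' @inheritParams expected_adjusted_revenue
#' @return A list with logicals `crossing_ok` and `lean_urgent_ok`, and the
#'   crossing quota `q_cross`.
#' @export
balance_condition <- function(sol, distX, distY, prob) {
  K <- prob$K
  q <- 0:K
  # marginal value of moving bed q+1 from regular to urgent
  gain1 <- prob$r1 * surv(distX, q) # P(D1 > q) = P(D1 >= q + 1)
  loss2 <- prob$r2 * surv(distY, K - q - 1) # P(D2 >= K - q)
  flip <- which(gain1 <= loss2) # first q where adding urgent stops paying
  q_cross <- if (length(flip)) q[flip[1]] else K
  list(
    crossing_ok = abs(sol$Q1 - q_cross) <= 1L,
    lean_urgent_ok = surv(distY, K - sol$Q1 - 1L) >= surv(distX, sol$Q1 - 1L) - 1e-12,
    q_cross = q_cross
  )
}

#' Sample-average-approximation solver
#'
#' Replaces the expectations with sample averages over observed demand
#' histories and sweeps the integer quota:
#' `max_Q1 (1/n) sum_i [r1 * min(D1_i, Q1) + r2 * min(D2_i, K - Q1)]`.
#' Equivalent to [solve_exact()] applied to [fit_empirical()] of each sample
#' (the samples need not be paired or of equal length).
#'
#' @param samples1,samples2 Nonempty vectors of observed urgent/regular
#'   daily counts.
#' @inheritParams expected_adjusted_revenue
#' @return A `bed_allocation` (`method = "saa"`).
#' @export
solve_saa <- function(samples1, samples2, prob) {
  stopifnot(inherits(prob, "two_class_problem"))
  samples1 <- check_counts(samples1, "samples1")
  samples2 <- check_counts(samples2, "samples2")
  K <- prob$K
  qs <- 0:K
  obj <- vapply(qs, function(q) {
    prob$r1 * mean(pmin(samples1, q)) + prob$r2 * mean(pmin(samples2, K - q))
  }, numeric(1))
  q1 <- which.max(obj) - 1L
  new_allocation(q1, obj[q1 + 1L], "saa",
                 min(length(samples1), length(samples2)), prob,
                 objective_curve = obj)
}
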