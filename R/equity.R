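#' State of the revenue-plus-equity admission model
#'
#' `W1`, `W2` are the urgent/regular waiting censuses, `B1`, `B2` the
#' urgent/regular inpatient censuses, and `X` the bed slack: positive `X`
#' is idle standard capacity (holding beds), negative `X` means corridor
#' "extra" beds are in use. The conservation identity `B1 + B2 + X = K`
#' holds at all times.
#'
#' @param W1,W2,B1,B2 Nonnegative integers.
#' @param X Integer slack (may be negative).
#' @export
equity_state <- function(W1, W2, B1, B2, X) {
  for (nm in c("W1", "W2", "B1", "B2")) {
    v <- get(nm)
    check_scalar_number(v, nm, lower = 0)
  }
  check_scalar_number(X, "X")
  structure(list(W1 = as.integer(W1), W2 = as.integer(W2),
                 B1 = as.integer(B1), B2 = as.integer(B2),
                 X = as.integer(X)),
            class = "equity_state")
}

#' Parameters of the revenue-plus-equity model
#'
#' Revenues, waiting-cost rates, the extra-bed penalty, capacity and the
#' admission-control coefficients. Defaults: the urgent adjusted revenue is
#' 1.25 times the regular one; urgent waiting costs twice regular waiting
#' per day; `K = 140` standard beds. The revenue and cost levels are in
#' relative monetary units and are freely rescalable.
#'
#' @param r1,r2 Adjusted per-admission revenues (`r1 > r2`).
#' @param rho1,rho2 Per-day waiting costs (`rho1 > rho2`).
#' @param b Extra-bed penalty per bed-day.
#' @param K Total standard beds.
#' @param alpha Waiting-mix coefficient (>= 0): scales how strongly the
#'   urgent share of the waiting list drives the urgent quota.
#' @param beta Length-5 weekday reservation ratios in `[0, 1]`
#'   (Monday..Friday); larger `beta_k` shrinks the urgent quota on day `k`.
#' @param xi Reservation proportion in `[0, 1]`: the fraction of predicted
#'   capacity withheld from today's admissions.
#' @export
equity_params <- function(r1 = 125, r2 = 100, rho1 = 2, rho2 = 1, b = 500,
                          K = 140, alpha = 1, beta = rep(0, 5), xi = 0) {
  check_scalar_number(r1, "r1", lower = 1e-12)
  check_scalar_number(r2, "r2", lower = 1e-12)
  check_scalar_number(rho1, "rho1", lower = 0)
  check_scalar_number(rho2, "rho2", lower = 0)
  check_scalar_number(b, "b", lower = 0)
  check_scalar_number(K, "K", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 0)
  check_scalar_number(xi, "xi", lower = 0, upper = 1)
  if (length(beta) != 5L || any(beta < 0) || any(beta > 1)) {
    abort("`beta` must be five weekday ratios in [0, 1].")
  }
  structure(list(r1 = r1, r2 = r2, rho1 = rho1, rho2 = rho2, b = b,
                 K = as.integer(K), alpha = alpha, beta = as.numeric(beta),
                 xi = xi),
            class = "equity_params")
}

#' Predicted available capacity for the day
#'
#' `K_t = max(0, X + round(B1 * gamma_hat1 + B2 * gamma_hat2))`: current
#' slack plus the expected number of discharges under plug-in predictions
#' of the class discharge fractions.
#'
#' @param state An [equity_state()].
#' @param gamma_hat1,gamma_hat2 Predicted discharge fractions in `[0, 1]`.
#' @return A nonnegative integer capacity prediction.
#' @export
predict_capacity <- function(state, gamma_hat1, gamma_hat2) {
  stopifnot(inherits(state, "equity_state"))
  check_scalar_number(gamma_hat1, "gamma_hat1", lower = 0, upper = 1)
  check_scalar_number(gamma_hat2, "gamma_hat2", lower = 0, upper = 1)
  as.integer(max(0, state$X + round(state$B1 * gamma_hat1 +
                                      state$B2 * gamma_hat2)))
}

#' Urgent admission quota
#'
#' The day's urgent quota under the reservation rule: of the predicted
#' capacity `K_t`, a proportion `xi` is reserved; the rest is steered to the
#' urgent class by the waiting-list mix and the weekday reservation ratio:
#' `Q1 = min(W1, floor((1 - xi) K_t * alpha * W1 / (W1 + W2) *
#' (1 - beta_wd)))`, and `Q1 = 0` when the waiting list is empty. The cap at
#' `W1` keeps the waiting census nonnegative.
#'
#' @param state An [equity_state()].
#' @param K_t Predicted capacity (nonnegative integer).
#' @param params An [equity_params()].
#' @param weekday Integer 1..5.
#' @return A nonnegative integer quota.
#' @export
urgent_quota <- function(state, K_t, params, weekday) {
  stopifnot(inherits(state, "equity_state"), inherits(params, "equity_params"))
  check_scalar_number(K_t, "K_t", lower = 0)
  check_scalar_number(weekday, "weekday", lower = 1, upper = 5)
  Wtot <- state$W1 + state$W2
  if (Wtot == 0) return(0L)
  raw <- (1 - params$xi) * K_t * params$alpha * (state$W1 / Wtot) *
    (1 - params$beta[weekday])
  min(state$W1, int_floor(raw))
}

#' One day of the revenue-plus-equity admission model
#'
#' Computes the day's quotas, revenue, waiting cost and extra-bed cost, and
#' advances the state. The urgent quota comes from [urgent_quota()]; the
#' regular quota fills the remaining unreserved capacity,
#' `Q2 = min(W2, floor((1 - xi) K_t) - Q1)`, so the reservation identity
#' `K_t - Q1 - Q2 = xi * K_t` holds whenever both queues are long. Class
#' discharges `round(B γ)` are integers; the slack update
#' `X' = X + discharges - E - Q1 - Q2` conserves `B1 + B2 + X = K` exactly.
#' Costs: waiting `O = rho1 (W1 - Q1) + rho2 (W2 - Q2)`; extra beds
#' `P = b * [(E + Q1 + Q2) - (X + discharges)]^+`.
#'
#' @param state An [equity_state()].
#' @param params An [equity_params()].
#' @param exog One trace day: a list/row with `D1`, `D2`, `E`, `gamma1`,
#'   `gamma2`, `weekday`, and optionally `day`.
#' @param gamma_hat Optional length-2 plug-in discharge-fraction predictions
#'   for [predict_capacity()]; defaults to the day's realised fractions.
#' @return A list with the next `state` and a named-list `ledger` of the
#'   day's quantities (`K_t`, `K_t0`, `Q1`, `Q2`, `R_t`, `O_t`, `P_t`,
#'   `extra_beds`, `holding_beds` and the pre-decision censuses).
#' @export
step_equity <- function(state, params, exog, gamma_hat = NULL) {
  stopifnot(inherits(state, "equity_state"), inherits(params, "equity_params"))
  if (is.null(gamma_hat)) gamma_hat <- c(exog$gamma1, exog$gamma2)
  K_t <- predict_capacity(state, gamma_hat[1], gamma_hat[2])
  wd <- as.integer(exog$weekday)
  Q1 <- urgent_quota(state, K_t, params, wd)
  usable <- int_floor((1 - params$xi) * K_t)
  Q2 <- min(state$W2, max(0L, usable - Q1))
  d1 <- as.integer(round(state$B1 * exog$gamma1))
  d2 <- as.integer(round(state$B2 * exog$gamma2))
  admitted <- exog$E + Q1 + Q2
  freed <- state$X + d1 + d2
  extra <- pos(admitted - freed)
  R_t <- params$r1 * Q1 + params$r2 * Q2
  O_t <- params$rho1 * (state$W1 - Q1) + params$rho2 * (state$W2 - Q2)
  P_t <- params$b * extra
  nxt <- equity_state(
    W1 = state$W1 - Q1 + exog$D1,
    W2 = state$W2 - Q2 + exog$D2,
    B1 = state$B1 - d1 + Q1 + exog$E,
    B2 = state$B2 - d2 + Q2,
    X = state$X + d1 + d2 - exog$E - Q1 - Q2
  )
  if (nxt$W1 < 0 || nxt$W2 < 0) abort("Internal error: negative waiting census.")
  ledger <- list(
    day = if (!is.null(exog$day)) as.integer(exog$day) else NA_integer_,
    weekday = wd, K_t = K_t, K_t0 = as.integer(K_t - Q1 - Q2),
    Q1 = as.integer(Q1), Q2 = as.integer(Q2),
    R_t = R_t, O_t = O_t, P_t = P_t,
    extra_beds = as.integer(extra), holding_beds = as.integer(pos(nxt$X)),
    W1 = state$W1, W2 = state$W2, B1 = state$B1, B2 = state$B2, X = state$X
  )
  list(state = nxt, ledger = ledger)
}

#' Evaluate the admission policy over a full trace
#'
#' Sequentially applies [step_equity()] along a [gen_hospital_trace()] (or
#' equivalent) and returns the time-averaged objective
#' `f = (1/T) sum_t (R_t - O_t - P_t)` together with its unaveraged total
#' and the full daily ledger. Capacity predictions use the plug-in
#' historical mean discharge fractions of the trace.
#'
#' @param trace A `hospital_trace`.
#' @param params An [equity_params()].
#' @return An object of class `equity_run`: list with `f` (time average),
#'   `f_total` (sum), and the `ledger` tibble.
#' @export
run_horizon <- function(trace, params) {
  stopifnot(inherits(trace, "hospital_trace"), inherits(params, "equity_params"))
  if (nrow(trace) < 1L) abort("`trace` must contain at least one day.")
  init <- attr(trace, "init_state")
  K <- attr(trace, "K")
  if (init$B1 + init$B2 + init$X != K) {
    abort("Inconsistent trace: B1 + B2 + X must equal K initially.")
  }
  gamma_hat <- c(mean(trace$gamma1), mean(trace$gamma2))
  state <- equity_state(init$W1, init$W2, init$B1, init$B2, init$X)
  rows <- vector("list", nrow(trace))
  days <- as.list(as_tibble(trace)) # column access once, rows as lists below
  for (i in seq_len(nrow(trace))) {
    exog <- list(day = days$day[i], weekday = days$weekday[i],
                 D1 = days$D1[i], D2 = days$D2[i], E = days$E[i],
                 gamma1 = days$gamma1[i], gamma2 = days$gamma2[i])
    step <- step_equity(state, params, exog, gamma_hat = gamma_hat)
    rows[[i]] <- step$ledger
    state <- step$state
  }
  ledger <- dplyr::bind_rows(rows)
  daily <- ledger$R_t - ledger$O_t - ledger$P_t
  structure(list(f = mean(daily), f_total = sum(daily), ledger = ledger,
                 params = params, final_state = state),
            class = "equity_run")
}

#' @export
print.equity_run <- function(x, ...) {
  cat("<equity_run> T =", nrow(x$ledger),
      " f =", format(x$f, digits = 6),
      " (total", format(x$f_total, digits = 6), ")\n")
  invisible(x)
}

#' @export
tidy.equity_run <- function(x, ...) x$ledger

#' @export
glance.equity_run <- function(x, ...) {
  p <- x$params
  tibble(f = x$f, f_total = x$f_total, T = nrow(x$ledger),
         xi = p$xi, alpha = p$alpha, b = p$b,
         mean_extra = mean(x$ledger$extra_beds),
         mean_holding = mean(x$ledger$holding_beds))
}

#' Sensitivity sweep over the control variables
#'
#' Evaluates [run_horizon()] over a grid of reservation proportions `xi`
#' and waiting-mix coefficients `alpha`, with one weekday-ratio vector
#' `beta` per `alpha` column. The `beta` columns can be supplied explicitly
#' (`beta_mode = "fixed"`, recycling `params$beta` if `beta_list` is
#' `NULL`), drawn at random (`"random"`, seeded), or a coordinate-wise grid
#' for one weekday at a time (`"grid"`).
#'
#' @param trace A `hospital_trace`.
#' @param params Baseline [equity_params()].
#' @param xi_grid,alpha_grid Control grids.
#' @param beta_mode `"fixed"`, `"random"` or `"grid"`.
#' @param beta_list Optional list of length-5 `beta` vectors, one per
#'   `alpha` value (recycled if shorter).
#' @param seed Seed for `beta_mode = "random"`.
#' @return An object of class `equity_sweep`: a tibble with columns `xi`,
#'   `alpha`, `beta_id`, `f`, `f_total`, with the per-column `beta`
#'   vectors in attribute `betas` and the maximizing controls in attribute
#'   `argmax`.
#' @export
sweep_controls <- function(trace, params = equity_params(),
                           xi_grid = seq(0, 1, 0.1),
                           alpha_grid = seq(0, 1, 0.1),
                           beta_mode = c("fixed", "random", "grid"),
                           beta_list = NULL, seed = 1L) {
  beta_mode <- match.arg(beta_mode)
  if (length(xi_grid) == 0L || length(alpha_grid) == 0L) {
    abort("Control grids must be nonempty.")
  }
  n_a <- length(alpha_grid)
  betas <- switch(beta_mode,
    fixed = {
      if (is.null(beta_list)) beta_list <- list(params$beta)
      rep(beta_list, length.out = n_a)
    },
    random = with_seed_if(seed, purrr::map(seq_len(n_a),
                                           function(i) stats::runif(5))),
    grid = purrr::map(seq_len(n_a), function(i) {
      b <- rep(0, 5); b[(i - 1L) %% 5L + 1L] <- (i - 1L) %/% 5L * 0.5; clip01(b)
    })
  )
  grid <- tidyr::expand_grid(xi = xi_grid, a_idx = seq_len(n_a))
  res <- purrr::pmap_dfr(grid, function(xi, a_idx) {
    p <- params
    p$xi <- xi
    p$alpha <- alpha_grid[a_idx]
    p$beta <- betas[[a_idx]]
    run <- run_horizon(trace, p)
    tibble(xi = xi, alpha = alpha_grid[a_idx], beta_id = a_idx,
           f = run$f, f_total = run$f_total)
  })
  best <- res[which.max(res$f), ]
  out <- structure(res, betas = betas,
                   argmax = list(xi = best$xi, alpha = best$alpha,
                                 beta = betas[[best$beta_id]], f = best$f),
                   class = c("equity_sweep", class(res)))
  out
}

#' Sensitivity sweep over the extra-bed cost rate
#'
#' Evaluates the objective over a grid of extra-bed penalties `b` and
#' reservation proportions `xi`, holding `alpha` and `beta` fixed at the
#' supplied `params` (typically the controls-sweep optimum), and reports
#' the maximizing `xi` for each `b` (smallest in case of ties).
#'
#' @param trace A `hospital_trace`.
#' @param params An [equity_params()] with the fixed `alpha`, `beta`.
#' @param b_grid Extra-bed penalty grid.
#' @param xi_grid Reservation grid.
#' @return An object of class `cost_sweep`: a tibble with columns `b`,
#'   `xi`, `f`, `f_total`, with the `xi*(b)` curve in attribute `xi_star`.
#' @export
sweep_cost <- function(trace, params = equity_params(),
                       b_grid = seq(500, 1500, 100),
                       xi_grid = seq(0, 1, 0.1)) {
  if (length(b_grid) == 0L || length(xi_grid) == 0L) {
    abort("Grids must be nonempty.")
  }
  grid <- tidyr::expand_grid(b = b_grid, xi = xi_grid)
  res <- purrr::pmap_dfr(grid, function(b, xi) {
    p <- params
    p$b <- b
    p$xi <- xi
    run <- run_horizon(trace, p)
    tibble(b = b, xi = xi, f = run$f, f_total = run$f_total)
  })
  xi_star <- res |>
    dplyr::group_by(b) |>
    dplyr::slice_max(f, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(b, xi_star = xi, f_star = f)
  structure(res, xi_star = xi_star, class = c("cost_sweep", class(res)))
}

#' Per-weekday summaries of a daily ledger
#'
#' Groups a [run_horizon()] ledger by weekday and summarises the extra-bed
#' and holding-bed counts and the urgent/regular admission shares
#' (mean and quartiles), suitable for boxplot-style reporting.
#'
#' @param ledger A ledger tibble with columns `weekday`, `extra_beds`,
#'   `holding_beds`, `Q1`, `Q2`.
#' @return A tibble with one row per weekday and metric.
#' @export
weekday_summaries <- function(ledger) {
  ledger <- as_tibble(ledger)
  if (nrow(ledger) < 1L) abort("`ledger` must be nonempty.")
  tot <- ledger$Q1 + ledger$Q2
  ledger$q1_share <- ifelse(tot > 0, ledger$Q1 / tot, NA_real_)
  ledger$q2_share <- ifelse(tot > 0, ledger$Q2 / tot, NA_real_)
  ledger |>
    dplyr::select(weekday, extra_beds, holding_beds, q1_share, q2_share) |>
    tidyr::pivot_longer(-weekday, names_to = "metric") |>
    dplyr::group_by(weekday, metric) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean = mean(value, na.rm = TRUE),
      q25 = unname(quantile(value, 0.25, na.rm = TRUE)),
      median = unname(quantile(value, 0.5, na.rm = TRUE)),
      q75 = unname(quantile(value, 0.75, na.rm = TRUE)),
      .groups = "drop"
    )
}
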