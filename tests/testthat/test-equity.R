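test_that("capacity prediction is slack plus expected discharges", {
  expect_identical(predict_capacity(equity_state(0, 0, 0, 0, 0), 0.5, 0.5), 0L)
  st <- equity_state(10, 10, 100, 40, -5)
  expect_identical(predict_capacity(st, 0.1, 0.25), 15L)
  st2 <- equity_state(0, 0, 100, 40, -40)
  expect_identical(predict_capacity(st2, 0.1, 0.1), 0L) # floored at zero
})

test_that("urgent quota follows the reservation and weekday rule", {
  prm <- equity_params(xi = 0, alpha = 1, beta = rep(0, 5))
  st <- equity_state(W1 = 30, W2 = 30, B1 = 50, B2 = 80, X = 10)
  expect_identical(urgent_quota(st, 20L, prm, 1), 10L) # half the queue is urgent
  expect_identical(urgent_quota(equity_state(0, 30, 50, 80, 10), 20L, prm, 1), 0L)
  expect_identical(urgent_quota(st, 20L, equity_params(xi = 1), 3), 0L)
  # weekday ratio shrinks the quota: (1 - 0.5) halves it
  prm_b <- equity_params(xi = 0, alpha = 1, beta = c(0, 0.5, 0, 0, 0))
  expect_identical(urgent_quota(st, 20L, prm_b, 2), 5L)
  # cap at the urgent waiting census
  st_small <- equity_state(W1 = 2, W2 = 2, B1 = 50, B2 = 80, X = 10)
  expect_identical(urgent_quota(st_small, 20L, prm, 5), 2L)
})

test_that("full reservation shuts down admissions and leaves pure waiting cost", {
  prm <- equity_params(xi = 1, rho1 = 2, rho2 = 1)
  st <- equity_state(W1 = 7, W2 = 11, B1 = 60, B2 = 70, X = 10)
  ex <- list(day = 1L, weekday = 2L, D1 = 3L, D2 = 5L, E = 0L,
             gamma1 = 0.1, gamma2 = 0.1)
  step <- step_equity(st, prm, ex)
  expect_identical(step$ledger$Q1, 0L)
  expect_identical(step$ledger$Q2, 0L)
  expect_equal(step$ledger$R_t, 0)
  expect_equal(step$ledger$O_t, 2 * 7 + 1 * 11)
})

test_that("daily step matches the spreadsheet oracle on a fixture trace", {
  prm <- equity_params(xi = 0.2, alpha = 0.8, beta = c(0, 0.6, 0.6, 0.1, 0.9))
  tr <- gen_hospital_trace(5, seed = 29)
  init <- attr(tr, "init_state")
  state <- equity_state(init$W1, init$W2, init$B1, init$B2, init$X)
  gh <- c(mean(tr$gamma1), mean(tr$gamma2))
  for (i in 1:5) {
    ex <- as.list(tr[i, ])
    want <- oracle_equity_step(state$W1, state$W2, state$B1, state$B2, state$X,
                               ex$D1, ex$D2, ex$E, ex$gamma1, ex$gamma2,
                               ex$weekday, prm, gh[1], gh[2])
    got <- step_equity(state, prm, ex, gamma_hat = gh)
    expect_identical(got$ledger$K_t, as.integer(want$K_t))
    expect_identical(got$ledger$Q1, as.integer(want$Q1))
    expect_identical(got$ledger$Q2, as.integer(want$Q2))
    expect_equal(got$ledger$R_t, want$R_t)
    expect_equal(got$ledger$O_t, want$O_t)
    expect_equal(got$ledger$P_t, want$P_t)
    expect_identical(got$state$B1, as.integer(want$B1n))
    expect_identical(got$state$B2, as.integer(want$B2n))
    expect_identical(got$state$X, as.integer(want$Xn))
    expect_identical(got$state$W1, as.integer(want$W1n))
    state <- got$state
  }
})

test_that("bed conservation holds exactly after every step", {
  withr::with_seed(61, {
    prm <- equity_params()
    K <- prm$K
    state <- equity_state(50, 250, 30, 105, K - 135)
    for (i in 1:2000) {
      ex <- list(day = i, weekday = sample(1:5, 1),
                 D1 = rpois(1, 2), D2 = rpois(1, 10), E = rpois(1, 2),
                 gamma1 = runif(1, 0, 0.3), gamma2 = runif(1, 0, 0.3))
      state <- step_equity(state, prm, ex)$state
      expect_identical(state$B1 + state$B2 + state$X, K)
    }
  })
})

test_that("quota feasibility and slack complementarity hold along a run", {
  tr <- gen_hospital_trace(193, seed = 7)
  led <- run_horizon(tr, equity_params(xi = 0.1))$ledger
  expect_true(all(led$Q1 <= led$W1))
  expect_true(all(led$Q2 <= led$W2))
  expect_true(all(led$Q1 + led$Q2 <= led$K_t))
  expect_true(all(led$K_t0 >= 0))
  # a day never uses corridor beds and idles standard beds at once
  expect_true(all(!(led$extra_beds > 0 & led$holding_beds > 0)))
})

test_that("degenerate single-day horizon with no demand and full reservation is costless", {
  cfg <- trace_config(W1_0 = 0, W2_0 = 0, mu1 = 0, mu2 = 0, sd1 = 0, sd2 = 0,
                      E_mean = 0)
  tr <- gen_hospital_trace(1, config = cfg, seed = 2)
  run <- run_horizon(tr, equity_params(xi = 1, b = 0))
  expect_equal(run$f, 0)
})

test_that("the objective is affine in the extra-bed cost with the ledger slope", {
  tr <- gen_hospital_trace(100, seed = 19)
  prm0 <- equity_params(b = 0)
  r0 <- run_horizon(tr, prm0)
  r1 <- run_horizon(tr, equity_params(b = 1))
  slope <- r1$f - r0$f
  expect_equal(slope, -mean(r0$ledger$extra_beds), tolerance = 1e-9)
  r700 <- run_horizon(tr, equity_params(b = 700))
  expect_equal(r700$f, r0$f + 700 * slope, tolerance = 1e-6)
})

test_that("with full reservation the objective ignores alpha and beta", {
  tr <- gen_hospital_trace(60, seed = 3)
  f_vals <- vapply(list(
    equity_params(xi = 1, alpha = 0, beta = rep(0, 5)),
    equity_params(xi = 1, alpha = 1, beta = c(0, 0.6, 0.6, 0.1, 0.9)),
    equity_params(xi = 1, alpha = 0.5, beta = rep(1, 5))
  ), function(p) run_horizon(tr, p)$f, numeric(1))
  expect_equal(f_vals[1], f_vals[2], tolerance = 1e-12)
  expect_equal(f_vals[1], f_vals[3], tolerance = 1e-12)
  expect_true(all(run_horizon(tr, equity_params(xi = 1))$ledger$R_t == 0))
})

test_that("control sweep returns its own argmax and singleton grids collapse", {
  tr <- gen_hospital_trace(60, seed = 13)
  prm <- equity_params()
  single <- sweep_controls(tr, prm, xi_grid = 0.2, alpha_grid = 0.5)
  expect_identical(nrow(as.data.frame(single)), 1L)
  p_single <- equity_params(xi = 0.2, alpha = 0.5)
  expect_equal(single$f, run_horizon(tr, p_single)$f)

  sw <- sweep_controls(tr, prm, xi_grid = seq(0, 1, 0.25),
                       alpha_grid = seq(0, 1, 0.5), beta_mode = "random",
                       seed = 4)
  am <- attr(sw, "argmax")
  expect_equal(am$f, max(sw$f))
  got <- dplyr::filter(as_tibble(sw), xi == am$xi, alpha == am$alpha)
  expect_true(am$f %in% got$f)
})

test_that("cost sweep rows are affine in b and the optimal reservation rises with b", {
  tr <- gen_hospital_trace(100, seed = 19)
  prm <- equity_params(alpha = 1, beta = rep(0, 5))
  cs <- sweep_cost(tr, prm, b_grid = c(0, 400, 800, 1200),
                   xi_grid = seq(0, 0.6, 0.2))
  tbl <- as_tibble(cs)
  for (x in unique(tbl$xi)) {
    fx <- dplyr::arrange(dplyr::filter(tbl, xi == x), b)
    slopes <- diff(fx$f) / diff(fx$b)
    expect_lt(max(slopes) - min(slopes), 1e-6) # shared slope per row
  }
  xs <- attr(cs, "xi_star")
  expect_true(all(diff(xs$xi_star) >= 0))
  # b = 0 column equals the plain run without extra-bed penalty
  f00 <- dplyr::filter(tbl, b == 0, xi == 0)$f
  expect_equal(f00, run_horizon(tr, equity_params(alpha = 1, beta = rep(0, 5),
                                                  b = 0, xi = 0))$f)
})

test_that("weekday summaries partition the horizon and aggregate single days", {
  tr <- gen_hospital_trace(193, seed = 5)
  led <- run_horizon(tr, equity_params())$ledger
  ws <- weekday_summaries(led)
  counts <- dplyr::summarise(dplyr::group_by(ws, weekday),
                             n = dplyr::first(n_days))
  expect_identical(sum(counts$n), 193L)

  one <- weekday_summaries(led[3, ])
  expect_identical(nrow(one), 4L) # one weekday, four metrics
  expect_equal(dplyr::filter(one, metric == "extra_beds")$mean,
               led$extra_beds[3])
})

test_that("extra-bed usage declines as more capacity is reserved", {
  tr <- gen_hospital_trace(100, seed = 37)
  extras <- vapply(c(0, 0.5, 1), function(x) {
    mean(run_horizon(tr, equity_params(xi = x))$ledger$extra_beds)
  }, numeric(1))
  expect_true(all(diff(extras) <= 0))
})
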