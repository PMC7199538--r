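test_that("zero demand scale forces an all-zero series", {
  s <- gen_sinusoidal_demand(5, tau = 3, mu = 0, sigma = 0, seed = 1)
  expect_identical(s$count, rep(0L, 5))
  expect_identical(s$weekday, 1:5)
})

test_that("demand counts follow the cyclical formula with the drawn noise", {
  z <- withr::with_seed(17, rnorm(6, mean = 1, sd = 0.1))
  s <- gen_sinusoidal_demand(6, tau = 3, mu = 10, sigma = 1, seed = 17)
  expect_identical(s$count,
                   as.integer(floor(pmax(0, abs(sin(1:6 / 3)) * 10 + z))))
  # weekday cycles 1..5,1..
  expect_identical(s$weekday[6], 1L)
})

test_that("long-run demand mean agrees with a Monte-Carlo oracle", {
  T_n <- 1e4
  s <- gen_sinusoidal_demand(T_n, tau = 3, mu = 3, sigma = 1, seed = 23)
  # independent oracle: 100 fresh noise draws per day of the same formula
  oracle <- withr::with_seed(71, {
    reps <- 100
    m <- 0
    for (r in seq_len(reps)) {
      z <- rnorm(T_n, 1, 0.1)
      m <- m + mean(floor(pmax(0, abs(sin(seq_len(T_n) / 3)) * 3 + z)))
    }
    m / reps
  })
  se <- sd(s$count) / sqrt(T_n)
  expect_lt(abs(mean(s$count) - oracle), 3 * se + 0.01)
})

test_that("demand generator validates the horizon and is seed-deterministic", {
  expect_error(gen_sinusoidal_demand(0, 3, 3, 1), "T_horizon")
  expect_identical(gen_sinusoidal_demand(50, 3, 3, 1, seed = 4),
                   gen_sinusoidal_demand(50, 3, 3, 1, seed = 4))
})

test_that("released beds are bounded by the occupied census", {
  expect_identical(gen_released_beds(0, t = 3, seed = 1), 0L)
  expect_error(gen_released_beds(-1, t = 1), "B_t")
  withr::with_seed(2, {
    for (i in 1:200) {
      B <- sample(0:60, 1)
      eps <- gen_released_beds(B, t = sample(1:100, 1))
      expect_true(eps >= 0 && eps <= B)
    }
  })
})

test_that("released beds reproduce the clipped-fraction formula exactly", {
  # dual implementation with the same seeded normal draw
  for (tt in c(1, 5, 9.424778, 13)) { # includes t = 3*pi where |sin(t/6)| = 1
    z <- withr::with_seed(99, rnorm(1))
    frac <- min(1, max(0, abs(sin(tt / 6)) * (0.5 + 0.2 * z)))
    expect_identical(gen_released_beds(100, t = tt, seed = 99),
                     as.integer(floor(frac * 100 + 1e-9)))
  }
})

test_that("mean release fraction agrees with a Monte-Carlo oracle", {
  obs <- vapply(1:2000, function(t) gen_released_beds(40, t, seed = 1000 + t),
                integer(1)) / 40
  oracle <- withr::with_seed(5, {
    t_rep <- rep(1:2000, each = 50)
    z <- rnorm(length(t_rep))
    frac <- pmin(1, pmax(0, abs(sin(t_rep / 6)) * (0.5 + 0.2 * z)))
    mean(floor(frac * 40) / 40)
  })
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - oracle), 3 * se + 0.005)
})

test_that("feature history hits the configured urgent share and is reproducible", {
  h1 <- gen_feature_history(1, seed = 3)
  expect_true(h1$D1 >= 0 && h1$D2 >= 0)
  expect_error(gen_feature_history(0), "n")

  h <- gen_feature_history(5000, seed = 8)
  share <- sum(h$D1) / sum(h$D1 + h$D2)
  expect_lt(abs(share - 0.24), 0.03)
  expect_identical(h, gen_feature_history(5000, seed = 8))
})

test_that("hospital trace satisfies its invariants and weekday cycling", {
  tr <- gen_hospital_trace(11, seed = 6)
  expect_s3_class(tr, "hospital_trace")
  expect_identical(tr$weekday[6], tr$weekday[1])
  expect_true(all(tr$D1 >= 0 & tr$D2 >= 0 & tr$E >= 0))
  expect_true(all(tr$gamma1 >= 0 & tr$gamma1 <= 1))
  expect_true(all(tr$gamma2 >= 0 & tr$gamma2 <= 1))
  init <- attr(tr, "init_state")
  expect_identical(init$B1 + init$B2 + init$X, as.integer(attr(tr, "K")))

  expect_error(gen_hospital_trace(5, config = trace_config(B1_0 = 10)),
               "B1_0")
  expect_identical(gen_hospital_trace(30, seed = 2),
                   gen_hospital_trace(30, seed = 2))
})

test_that("trace generator is calibrated to its waiting-census target", {
  tr <- gen_hospital_trace(193, seed = 11)
  led <- run_horizon(tr, equity_params())$ledger
  waiting <- mean(led$W1 + led$W2)
  expect_gt(waiting, 300)
  expect_lt(waiting, 380)
  urgent_share <- mean(led$W1 / (led$W1 + led$W2))
  expect_gt(urgent_share, 0.10)
  expect_lt(urgent_share, 0.28)
  # near-100% utilisation of the 140 standard beds
  expect_gt(mean(led$B1 + led$B2), 130)
})
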