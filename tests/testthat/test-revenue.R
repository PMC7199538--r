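test_that("one-period transition reproduces direct substitutions", {
  # both queues long: protection shares bind, 6/4 split of 10 beds
  st <- revenue_state(B = 30, X = 10, W1 = 10, W2 = 10)
  step <- transition(st, alpha = 0.6, eps = 0, D1 = 0, D2 = 0)
  expect_identical(step$Q1, 6L)
  expect_identical(step$Q2, 4L)
  expect_equal(step$reward, 3 * 6 + 1 * 4)

  # empty system: nothing admitted, released beds become slack
  st0 <- revenue_state(B = 12, X = 3)
  step0 <- transition(st0, alpha = 0.6, eps = 5, D1 = 0, D2 = 0)
  expect_identical(step0$Q1 + step0$Q2, 0L)
  expect_equal(step0$reward, 0)
  expect_identical(step0$state$X, 8L)
  expect_identical(step0$state$B, 7L)

  expect_error(transition(st0, 0.5, eps = 13, D1 = 0, D2 = 0), "eps")
  expect_error(transition(st0, 1.2, eps = 0, D1 = 0, D2 = 0), "alpha")
})

test_that("fuzzed transitions match the independently coded oracle", {
  withr::with_seed(55, {
    ok <- TRUE
    conserved <- TRUE
    for (i in 1:10000) {
      B <- sample(0:40, 1); X <- sample(0:15, 1)
      W1 <- sample(0:20, 1); W2 <- sample(0:30, 1)
      st <- revenue_state(B, X, W1, W2)
      alpha <- sample(seq(0, 1, 0.05), 1)
      eps <- if (B > 0) sample(0:B, 1) else 0
      D1 <- sample(0:8, 1); D2 <- sample(0:12, 1)
      got <- transition(st, alpha, eps, D1, D2)
      want <- oracle_transition(B, X, W1, W2, alpha, eps, D1, D2)
      ok <- ok && got$state$B == want$B && got$state$X == want$X &&
        got$state$W1 == want$W1 && got$state$W2 == want$W2 &&
        got$reward == want$reward
      conserved <- conserved && (got$state$B + got$state$X <= B + X)
      if (!ok) break
    }
    expect_true(ok)           # next states identical to the oracle
    expect_true(conserved)    # beds are never created
  })
})

test_that("fixed-ratio policy estimates the mean release fraction", {
  h <- tibble::tibble(eps = c(3, 6, 9), B = c(10, 20, 30))
  expect_equal(policy_fa(h, 0.6)$tau_bar, 0.3)
  h2 <- tibble::tibble(eps = c(2, 3, 4), B = c(10, 10, 10))
  expect_equal(policy_fa(h2, 0.5)$tau_bar, mean(c(0.2, 0.3, 0.4)))
  h3 <- tibble::tibble(eps = c(2, 0), B = c(10, 0))
  expect_message(fa <- policy_fa(h3, 0.5), "B = 0")
  expect_equal(fa$tau_bar, 0.2)
  # the fixed fraction does not depend on the state
  st_a <- revenue_state(5, 0, 9, 0)
  st_b <- revenue_state(20, 7, 0, 50)
  expect_equal(bedalloc:::decide_alpha(fa, st_a, 1, 1),
               bedalloc:::decide_alpha(fa, st_b, 2, 2))
})

test_that("KO policy is deterministic and prefers urgent under scarcity", {
  h <- tibble::tibble(weekday = rep(1:5, 10), eps = rep(2L, 50),
                      B = rep(20L, 50), D1 = rep(6L, 50), D2 = rep(9L, 50))
  ko1 <- policy_ko(h)
  ko2 <- policy_ko(h)
  st <- revenue_state(B = 20, X = 0, W1 = 30, W2 = 30)
  a1 <- bedalloc:::decide_alpha(ko1, st, 1, 1)
  expect_identical(a1, bedalloc:::decide_alpha(ko2, st, 1, 1))
  # capacity far below urgent backlog: all protection to the urgent class
  expect_identical(a1, 1)
})

test_that("episodes are seed-deterministic with a consistent reward ledger", {
  gen <- revenue_gen_params()
  ep1 <- run_episode(50, 15, function(s, t, w) 0.6, gen, seed = 31)
  ep2 <- run_episode(50, 15, function(s, t, w) 0.6, gen, seed = 31)
  expect_identical(ep1$ledger, ep2$ledger)
  expect_equal(ep1$ledger$reward,
               3 * ep1$ledger$Q1 + 1 * ep1$ledger$Q2)
  expect_equal(ep1$total_reward, sum(ep1$ledger$reward))

  # zero demand, single period
  g0 <- revenue_gen_params(mu1 = 0, mu2 = 0, sigma1 = 0, sigma2 = 0)
  e0 <- run_episode(1, 5, function(s, t, w) 0.5, g0, seed = 1)
  expect_equal(e0$total_reward, 0)
})

test_that("episode states remain nonnegative with occupancy bounded by capacity", {
  ep <- run_episode(200, 12, function(s, t, w) 0.37, seed = 13)
  led <- ep$ledger
  expect_true(all(led$B >= 0 & led$X >= 0 & led$W1 >= 0 & led$W2 >= 0))
  expect_true(all(led$B + led$X <= 12))
})

test_that("mean episode reward is nondecreasing in capacity", {
  rewards <- vapply(c(4, 8, 16), function(K) {
    mean(vapply(1:30, function(j) {
      run_episode(40, K, function(s, t, w) 0.6, seed = 700 + j)$total_reward
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rewards) > 0))
})

test_that("the capacity sweep is reproducible and KO never trails FA materially", {
  tab1 <- evaluate_improvement(c(3, 8), n_instances = 40, seed = 5)
  tab2 <- evaluate_improvement(c(3, 8), n_instances = 40, seed = 5)
  expect_identical(tab1, tab2)
  expect_true(all(tab1$ko_reward >= tab1$fa_reward - 3 * tab1$se * tab1$fa_reward / 100))
  expect_named(tab1, c("K", "ko_reward", "fa_reward", "improvement_pct", "se"))
})
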