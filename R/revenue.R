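#' Multiperiod admission state (revenue model)
#'
#' State of the two-class admission system with random bed release:
#' `B` occupied beds, `X` unoccupied beds, and waiting censuses `W1`
#' (urgent), `W2` (regular).
#'
#' @param B,X,W1,W2 Nonnegative integers.
#' @export
revenue_state <- function(B, X = 0, W1 = 0, W2 = 0) {
  for (nm in c("B", "X", "W1", "W2")) {
    v <- get(nm)
    check_scalar_number(v, nm, lower = 0)
    if (v != floor(v)) abort(sprintf("`%s` must be an integer.", nm))
  }
  structure(list(B = as.integer(B), X = as.integer(X),
                 W1 = as.integer(W1), W2 = as.integer(W2)),
            class = "revenue_state")
}

# integer split of `total` beds by ratio alpha, remainder bed to the urgent
# class (beds are indivisible and r1 > r2)
alloc_caps <- function(alpha, total) {
  cap1 <- int_floor(alpha * total)
  cap2 <- int_floor((1 - alpha) * total)
  cap1 <- cap1 + (total - cap1 - cap2)
  list(cap1 = cap1, cap2 = cap2)
}

# protection-level admissions with within-period spillover: each class is
# admitted up to its protected share first; beds left protected for a class
# whose queue has emptied serve the other class the same day, urgent first.
# Vectorised over equal-length inputs.
admit_spill <- function(alpha, total, dem1, dem2) {
  caps <- alloc_caps(alpha, total)
  Q1 <- pmin(caps$cap1, dem1)
  Q2 <- pmin(caps$cap2, dem2)
  left <- total - Q1 - Q2
  a1 <- pmin(left, dem1 - Q1)
  Q1 <- Q1 + a1
  Q2 <- Q2 + pmin(left - a1, dem2 - Q2)
  list(Q1 = Q1, Q2 = Q2)
}

#' One-period transition of the revenue model
#'
#' Applies the admission dynamics for one period: the scheduler protects a
#' fraction `alpha` of the available capacity `X + eps` (unoccupied beds
#' plus beds released during the period) for the urgent class and the rest
#' for the regular class. Protections are floored to whole beds with the
#' remainder bed going to the urgent class. Each class is admitted up to
#' its protection level, `Q1 = min(cap1, W1 + D1)`,
#' `Q2 = min(cap2, W2 + D2)`; beds protected for a class whose queue has
#' emptied serve the other class the same day (urgent first), so capacity
#' idles only when both queues are exhausted. The state then updates as
#' `B' = (B - eps + Q1 + Q2)^+`, `W1' = W1 + D1 - Q1`,
#' `W2' = W2 + D2 - Q2`, `X' = (X + eps - Q1 - Q2)^+`, and the period
#' reward is `r1 Q1 + r2 Q2`.
#'
#' @param state A [revenue_state()].
#' @param alpha Urgent allocation fraction in `[0, 1]`.
#' @param eps Beds released this period, `0 <= eps <= B`.
#' @param D1,D2 New urgent/regular arrivals (nonnegative integers).
#' @param r1,r2 Adjusted per-unit revenues.
#' @return A list with the next `state`, `Q1`, `Q2` and `reward`.
#' @export
transition <- function(state, alpha, eps, D1, D2, r1 = 3, r2 = 1) {
  stopifnot(inherits(state, "revenue_state"))
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  check_scalar_number(eps, "eps", lower = 0)
  if (eps > state$B) abort("`eps` cannot exceed the occupied census `B`.")
  check_scalar_number(D1, "D1", lower = 0)
  check_scalar_number(D2, "D2", lower = 0)
  total <- state$X + eps
  adm <- admit_spill(alpha, total, state$W1 + D1, state$W2 + D2)
  Q1 <- adm$Q1
  Q2 <- adm$Q2
  nxt <- revenue_state(
    B = pos(state$B - eps + Q1 + Q2),
    X = pos(total - Q1 - Q2),
    W1 = state$W1 + D1 - Q1,
    W2 = state$W2 + D2 - Q2
  )
  list(state = nxt, Q1 = as.integer(Q1), Q2 = as.integer(Q2),
       reward = r1 * Q1 + r2 * Q2)
}

#' Generator parameters for the revenue-model experiments
#'
#' Demand cycles and scales of the sinusoidal two-class arrival processes
#' and the adjusted revenues used by the multiperiod benchmark. The demand
#' scales `mu1 = 3`, `mu2 = 9` keep the urgent share of mean demand near
#' one quarter.
#'
#' @param tau1,tau2 Demand cycle lengths (days).
#' @param sigma1,sigma2 Demand noise scales.
#' @param mu1,mu2 Demand scales (urgent, regular).
#' @param r1,r2 Adjusted per-unit revenues.
#' @export
revenue_gen_params <- function(tau1 = 3, tau2 = 3, sigma1 = 1, sigma2 = 1,
                               mu1 = 3, mu2 = 9, r1 = 3, r2 = 1) {
  as.list(environment())
}

#' Fixed-ratio allocation policy
#'
#' The benchmark policy: a constant urgent fraction `alpha0` every period,
#' with the released-bed process summarised by the mean release fraction
#' `tau_bar = mean(eps_t / B_t)` over the training history (days with
#' `B_t = 0` are excluded, with a message). The capacity estimate
#' `X_t + tau_bar * B_t` is the planning value the fixed policy would quote;
#' the realised transition always uses the actual release.
#'
#' @param history A training episode ledger (from [run_episode()]) with
#'   columns `eps` and `B`.
#' @param alpha0 The fixed urgent fraction in `[0, 1]`.
#' @return A policy object of class `fa_policy`.
#' @export
policy_fa <- function(history, alpha0 = 0.6) {
  history <- as_tibble(history)
  if (nrow(history) < 1L) abort("`history` must be nonempty.")
  check_scalar_number(alpha0, "alpha0", lower = 0, upper = 1)
  ok <- history$B > 0
  if (any(!ok)) {
    inform(sprintf("policy_fa: excluded %d day(s) with B = 0 from tau_bar.",
                   sum(!ok)))
  }
  tau_bar <- if (any(ok)) mean(history$eps[ok] / history$B[ok]) else 0
  structure(list(alpha0 = alpha0, tau_bar = tau_bar), class = "fa_policy")
}

#' Kernel-optimization allocation policy
#'
#' A one-step-lookahead policy: for the current state it forms
#' day-of-week kernel-weighted empirical distributions of the release
#' fraction and the two demand streams from the training history, and
#' returns the `alpha` on a grid maximizing the one-step expected reward
#' `E[r1 Q1 + r2 Q2]` by exhaustive enumeration over the weighted support.
#' Ties are broken toward the largest `alpha` (urgent priority).
#'
#' @param history A training episode ledger with columns `weekday`, `eps`,
#'   `B`, `D1`, `D2`.
#' @param spec A [kernel_spec()] for the weekday feature (one-hot encoded).
#' @param alpha_grid Candidate fractions in `[0, 1]`.
#' @param r1,r2 Adjusted per-unit revenues.
#' @return A policy object of class `ko_policy`.
#' @export
policy_ko <- function(history, spec = kernel_spec(), alpha_grid = seq(0, 1, 0.05),
                      r1 = 3, r2 = 1) {
  history <- as_tibble(history)
  if (nrow(history) < 1L) abort("`history` must be nonempty.")
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    abort("`alpha_grid` must lie in [0, 1].")
  }
  wd_hist <- tibble(weekday = factor(history$weekday, levels = 1:5))
  # precompute one weight vector per weekday
  weights <- purrr::map(1:5, function(k) {
    nw_weights(tibble(weekday = factor(k, levels = 1:5)), wd_hist, spec)
  })
  frac <- ifelse(history$B > 0, history$eps / history$B, 0)
  structure(list(weights = weights, frac = frac,
                 D1 = history$D1, D2 = history$D2,
                 alpha_grid = sort(alpha_grid), r1 = r1, r2 = r2),
            class = "ko_policy")
}

decide_alpha <- function(policy, state, t, weekday) {
  UseMethod("decide_alpha")
}

#' @export
decide_alpha.fa_policy <- function(policy, state, t, weekday) {
  policy$alpha0
}

#' @export
decide_alpha.ko_policy <- function(policy, state, t, weekday) {
  w <- policy$weights[[weekday]]
  eps_hat <- int_floor(policy$frac * state$B)
  total <- state$X + eps_hat
  dem1 <- state$W1 + policy$D1
  dem2 <- state$W2 + policy$D2
  best_alpha <- policy$alpha_grid[1]
  best_val <- -Inf
  for (a in policy$alpha_grid) {
    adm <- admit_spill(a, total, dem1, dem2)
    val <- sum(w * (policy$r1 * adm$Q1 + policy$r2 * adm$Q2))
    if (val >= best_val - 1e-9) { # ties go to the largest alpha
      best_alpha <- a
      best_val <- max(best_val, val)
    }
  }
  best_alpha
}

#' Simulate one admission episode
#'
#' Draws the exogenous processes (two sinusoidal demand streams and the
#' cyclical release fractions) from `seed`, applies the policy's `alpha`
#' each period and the one-period [transition()], and returns the full
#' per-period ledger. The exogenous draws depend only on `seed` and the
#' generator parameters, so two policies run under the same seed face
#' common random numbers. The episode starts from a fully occupied ward
#' (`B = K_total`, `X = 0`, empty queues) unless `init` is given.
#'
#' @param T_horizon Number of periods (>= 1).
#' @param K_total Total bed capacity (>= 1).
#' @param policy An `fa_policy`, `ko_policy`, or a function
#'   `(state, t, weekday) -> alpha`.
#' @param gen A [revenue_gen_params()] list.
#' @param seed Integer seed for the exogenous draws.
#' @param init Optional [revenue_state()] initial state.
#' @return An object of class `bed_episode`: list with the per-period
#'   `ledger` tibble and `total_reward`.
#' @export
run_episode <- function(T_horizon, K_total, policy, gen = revenue_gen_params(),
                        seed = 1L, init = NULL) {
  check_scalar_number(T_horizon, "T_horizon", lower = 1)
  check_scalar_number(K_total, "K_total", lower = 1)
  draws <- with_seed_if(seed, list(
    z1 = rnorm(T_horizon), z2 = rnorm(T_horizon), zf = rnorm(T_horizon)
  ))
  t_seq <- seq_len(T_horizon)
  D1 <- count_floor(abs(sin(t_seq / gen$tau1)) * gen$mu1 +
                      gen$sigma1 * (1 + 0.1 * draws$z1))
  D2 <- count_floor(abs(sin(t_seq / gen$tau2)) * gen$mu2 +
                      gen$sigma2 * (1 + 0.1 * draws$z2))
  frac <- release_fraction(t_seq, draws$zf)
  state <- if (is.null(init)) revenue_state(B = K_total) else init
  wd_seq <- workday_of(t_seq)
  out <- matrix(0, nrow = T_horizon, ncol = 11)
  is_fun <- is.function(policy)
  B <- state$B; X <- state$X; W1 <- state$W1; W2 <- state$W2
  for (t in t_seq) {
    wd <- wd_seq[t]
    eps <- int_floor(frac[t] * B)
    st <- list(B = B, X = X, W1 = W1, W2 = W2)
    alpha <- if (is_fun) policy(st, t, wd) else decide_alpha(policy, st, t, wd)
    total <- X + eps
    adm <- admit_spill(alpha, total, W1 + D1[t], W2 + D2[t])
    Q1 <- adm$Q1
    Q2 <- adm$Q2
    out[t, ] <- c(alpha, eps, D1[t], D2[t], Q1, Q2,
                  gen$r1 * Q1 + gen$r2 * Q2, B, X, W1, W2)
    B <- max(0, B - eps + Q1 + Q2)
    W1 <- W1 + D1[t] - Q1
    W2 <- W2 + D2[t] - Q2
    X <- max(0, total - Q1 - Q2)
  }
  state <- revenue_state(B = B, X = X, W1 = W1, W2 = W2)
  ledger <- tibble(
    t = t_seq, weekday = wd_seq, alpha = out[, 1], eps = as.integer(out[, 2]),
    D1 = as.integer(out[, 3]), D2 = as.integer(out[, 4]),
    Q1 = as.integer(out[, 5]), Q2 = as.integer(out[, 6]), reward = out[, 7],
    B = as.integer(out[, 8]), X = as.integer(out[, 9]),
    W1 = as.integer(out[, 10]), W2 = as.integer(out[, 11])
  )
  structure(list(ledger = ledger, total_reward = sum(ledger$reward),
                 K_total = as.integer(K_total), final_state = state),
            class = "bed_episode")
}

#' @export
print.bed_episode <- function(x, ...) {
  cat("<bed_episode> T =", nrow(x$ledger), " K =", x$K_total,
      " total reward =", format(x$total_reward, digits = 6), "\n")
  invisible(x)
}

#' @export
tidy.bed_episode <- function(x, ...) x$ledger

#' @export
glance.bed_episode <- function(x, ...) {
  tibble(total_reward = x$total_reward, T = nrow(x$ledger), K = x$K_total)
}

#' Capacity sweep comparing kernel-optimization against fixed-ratio
#'
#' For each capacity `K`: simulates a 50-period training episode under the
#' fixed fraction `alpha0`, fits the fixed-ratio and kernel-optimization
#' policies on it, then evaluates both on `n_instances` fresh episodes of
#' horizon `T_horizon` under common random numbers, and reports the mean
#' rewards and the relative improvement `(KO - FA) / FA * 100`. If the mean
#' fixed-ratio reward is zero the improvement is reported as `NA`.
#'
#' @param K_range Capacities to sweep.
#' @param n_instances Evaluation episodes per capacity.
#' @param T_horizon Evaluation horizon (training uses `train_T`).
#' @param seed Master seed; training and every instance derive their own
#'   sub-seed from it.
#' @param gen A [revenue_gen_params()] list.
#' @param alpha0 Training/benchmark fixed fraction.
#' @param train_T Training-episode length.
#' @param alpha_grid Grid for the kernel-optimization policy.
#' @return A tibble with columns `K`, `ko_reward`, `fa_reward`,
#'   `improvement_pct`, `se` (standard error of the improvement, via the
#'   paired differences).
#' @export
evaluate_improvement <- function(K_range, n_instances = 500, T_horizon = 50,
                                 seed = 1L, gen = revenue_gen_params(),
                                 alpha0 = 0.6, train_T = 50,
                                 alpha_grid = seq(0, 1, 0.05)) {
  check_scalar_number(n_instances, "n_instances", lower = 1)
  purrr::map_dfr(K_range, function(K) {
    train <- run_episode(train_T, K, function(state, t, wd) alpha0,
                         gen, seed = derive_seed(seed, K, 0))
    fa <- policy_fa(train$ledger, alpha0)
    ko <- policy_ko(train$ledger, alpha_grid = alpha_grid,
                    r1 = gen$r1, r2 = gen$r2)
    rewards <- purrr::map_dfr(seq_len(n_instances), function(j) {
      s <- derive_seed(seed, K, j)
      tibble(
        fa = run_episode(T_horizon, K, fa, gen, seed = s)$total_reward,
        ko = run_episode(T_horizon, K, ko, gen, seed = s)$total_reward
      )
    })
    fa_mean <- mean(rewards$fa)
    ko_mean <- mean(rewards$ko)
    if (fa_mean > 0) {
      imp <- (ko_mean - fa_mean) / fa_mean * 100
      se <- sd(rewards$ko - rewards$fa) / sqrt(n_instances) / fa_mean * 100
    } else {
      imp <- NA_real_
      se <- NA_real_
    }
    tibble(K = K, ko_reward = ko_mean, fa_reward = fa_mean,
           improvement_pct = imp, se = se)
  })
}
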