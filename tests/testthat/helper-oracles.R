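# Independent oracles used by the unit and acceptance tests. These are
# deliberately written from scratch (enumeration / direct substitution),
# not by calling the package internals they check.

# expected adjusted revenue by exhaustive enumeration of all demand pairs,
# evaluating the piecewise case table of the single-period revenue
oracle_revenue_enum <- function(Q1, distX, distY, K, r1, r2) {
  val <- 0
  for (i in seq_along(distX$support)) {
    for (j in seq_along(distY$support)) {
      x <- distX$support[i]
      y <- distY$support[j]
      rev <- if (x >= Q1 && y >= K - Q1) {
        r1 * Q1 + r2 * (K - Q1)
      } else if (x >= Q1 && y < K - Q1) {
        r1 * Q1 + r2 * y
      } else if (x < Q1 && y >= K - Q1) {
        r1 * x + r2 * (K - Q1)
      } else {
        r1 * x + r2 * y
      }
      val <- val + rev * distX$probability[i] * distY$probability[j]
    }
  }
  val
}

# brute-force sweep of the urgent quota using the enumeration oracle;
# smallest maximizer
oracle_bruteforce_q1 <- function(distX, distY, K, r1, r2) {
  objs <- vapply(0:K, function(q) oracle_revenue_enum(q, distX, distY, K, r1, r2),
                 numeric(1))
  list(Q1 = which.max(objs) - 1L, objective = max(objs), curve = objs)
}

# a random discrete demand distribution with support inside 0..10, built
# from counts so that an exhaustive sample reproducing it exists
random_counts <- function(n = 40, max_support = 10) {
  sample(0:max_support, n, replace = TRUE, prob = stats::runif(max_support + 1))
}

# independently coded one-period transition of the revenue model
# (protection levels with same-day spillover, urgent first)
oracle_transition <- function(B, X, W1, W2, alpha, eps, D1, D2, r1 = 3, r2 = 1) {
  total <- X + eps
  p1 <- floor(alpha * total + 1e-9)
  p2 <- floor((1 - alpha) * total + 1e-9)
  p1 <- p1 + (total - p1 - p2) # leftover whole bed protects urgent
  d1 <- W1 + D1
  d2 <- W2 + D2
  q1 <- min(p1, d1)
  q2 <- min(p2, d2)
  spare <- total - q1 - q2
  if (spare > 0 && d1 > q1) {
    extra <- min(spare, d1 - q1); q1 <- q1 + extra; spare <- spare - extra
  }
  if (spare > 0 && d2 > q2) {
    q2 <- q2 + min(spare, d2 - q2)
  }
  list(B = max(0, B - eps + q1 + q2), X = max(0, total - q1 - q2),
       W1 = d1 - q1, W2 = d2 - q2, Q1 = q1, Q2 = q2,
       reward = r1 * q1 + r2 * q2)
}

# independently coded day of the revenue-plus-equity model ("spreadsheet"
# oracle): direct substitution into the quota rule, costs and transitions
oracle_equity_step <- function(W1, W2, B1, B2, X, D1, D2, E, g1, g2,
                               wd, prm, gh1, gh2) {
  Kt <- max(0, X + round(B1 * gh1 + B2 * gh2))
  Wtot <- W1 + W2
  Q1 <- if (Wtot == 0) 0 else {
    min(W1, floor((1 - prm$xi) * Kt * prm$alpha * W1 / Wtot *
                    (1 - prm$beta[wd]) + 1e-9))
  }
  Q2 <- min(W2, max(0, floor((1 - prm$xi) * Kt + 1e-9) - Q1))
  d1 <- round(B1 * g1)
  d2 <- round(B2 * g2)
  extra <- max(0, (E + Q1 + Q2) - (X + d1 + d2))
  list(
    K_t = Kt, Q1 = Q1, Q2 = Q2,
    R_t = prm$r1 * Q1 + prm$r2 * Q2,
    O_t = prm$rho1 * (W1 - Q1) + prm$rho2 * (W2 - Q2),
    P_t = prm$b * extra, extra_beds = extra,
    W1n = W1 - Q1 + D1, W2n = W2 - Q2 + D2,
    B1n = B1 - d1 + Q1 + E, B2n = B2 - d2 + Q2,
    Xn = X + d1 + d2 - E - Q1 - Q2
  )
}

# small waiting-list fixture written in code (no stored data)
make_waitlist_fixture <- function(n = 10, seed = 42) {
  withr::with_seed(seed, {
    cert <- as.Date("2024-01-01") + sample(0:20, n, replace = TRUE)
    wait <- sample(0:30, n, replace = TRUE)
    adm <- cert + wait
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      gender = sample(c("M", "F"), n, replace = TRUE),
      admission_certificate_date = cert,
      arrival_date = adm - sample(0:1, n, replace = TRUE),
      admission_date = adm,
      diagnosis = sample(c("kidney cancer", "renal cyst"), n, replace = TRUE),
      disease_type = sample(c("urgent", "regular"), n, replace = TRUE),
      insurance_type = sample(c("social", "none"), n, replace = TRUE),
      waiting_time = as.numeric(wait),
      dual_referral = sample(c("yes", "no"), n, replace = TRUE)
    )
  })
}
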