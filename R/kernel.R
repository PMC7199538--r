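#' Kernel specification for feature-weighted estimation
#'
#' @param kernel `"gaussian"` (default) or `"uniform"`.
#' @param bandwidth Either a positive number (used for every feature
#'   dimension after centering) or `"silverman"` to apply Silverman's
#'   rule-of-thumb per dimension: `h_j = sd_j * (4 / ((p + 2) n))^(1/(p+4))`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kernel = c("gaussian", "uniform"),
                        bandwidth = "silverman") {
  kernel <- match.arg(kernel)
  if (is.numeric(bandwidth)) {
    check_scalar_number(bandwidth, "bandwidth", lower = 1e-12)
  } else if (!identical(bandwidth, "silverman")) {
    abort('`bandwidth` must be a positive number or "silverman".')
  }
  structure(list(kernel = kernel, bandwidth = bandwidth),
            class = "kernel_spec")
}

# one-hot encode non-numeric columns (categorical weekday features get a
# Hamming-style distance); numeric columns pass through
encode_features <- function(df) {
  df <- as_tibble(df)
  cols <- purrr::map(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      m <- outer(f, levels(f), `==`) * 1
      colnames(m) <- paste0(nm, "_", levels(f))
    }
    m
  })
  do.call(cbind, cols)
}

resolve_bandwidths <- function(X, spec) {
  p <- ncol(X)
  n <- nrow(X)
  if (is.numeric(spec$bandwidth)) return(rep(spec$bandwidth, p))
  sds <- apply(X, 2, sd)
  sds[!is.finite(sds) | sds < 1e-12] <- 1
  h <- sds * (4 / ((p + 2) * max(n, 2)))^(1 / (p + 4))
  pmax(h, 1e-8)
}

#' Nadaraya-Watson kernel weights
#'
#' Weights `w_i = K_h(x_new - x_i) / sum_j K_h(x_new - x_j)` over a feature
#' history. Distances are computed per dimension scaled by the bandwidth;
#' the Gaussian kernel is `exp(-d^2 / 2)`, the uniform kernel is `1{d <= 1}`.
#' If every kernel value underflows to zero the weights fall back to uniform
#' with a warning (class `bedalloc_uniform_fallback`).
#'
#' @param x_new A numeric feature vector (or one-row matrix/data frame).
#' @param history_x A numeric matrix or data frame of historical feature
#'   vectors, one row per observation. Non-numeric columns are one-hot
#'   encoded (and `x_new` must then be a data frame row with the same
#'   columns).
#' @param spec A [kernel_spec()].
#' @return A nonnegative weight vector summing to one.
#' @examples
#' nw_weights(0, matrix(c(0, 1, 2)), kernel_spec(bandwidth = 1))
#' @export
nw_weights <- function(x_new, history_x, spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.data.frame(history_x)) {
    stopifnot(is.data.frame(x_new))
    both <- encode_features(dplyr::bind_rows(as_tibble(x_new), as_tibble(history_x)))
    x_new <- both[1, , drop = TRUE]
    history_x <- both[-1, , drop = FALSE]
  } else {
    history_x <- as.matrix(history_x)
    x_new <- as.numeric(x_new)
  }
  n <- nrow(history_x)
  if (n < 1L) abort("`history_x` must contain at least one observation.")
  if (length(x_new) != ncol(history_x)) {
    abort("`x_new` must have one value per feature column.")
  }
  h <- resolve_bandwidths(history_x, spec)
  d2 <- colSums((t(history_x) - x_new)^2 / h^2)
  k <- switch(spec$kernel,
              gaussian = exp(-d2 / 2),
              uniform = as.numeric(d2 <= 1))
  tot <- sum(k)
  if (!is.finite(tot) || tot <= 0) {
    warn("All kernel values are zero; falling back to uniform weights.",
         class = "bedalloc_uniform_fallback")
    return(rep(1 / n, n))
  }
  k / tot
}

#' Feature-based kernel-optimization solver
#'
#' Maximizes the Nadaraya-Watson estimate of the conditional expected
#' adjusted revenue at a new feature vector:
#' `max_Q1 sum_i w_i [r1 * min(D1_i, Q1) + r2 * min(D2_i, K - Q1)]`
#' with weights from [nw_weights()]. With equal weights this reduces
#' exactly to [solve_saa()] on the pooled history.
#'
#' @param history A data frame with demand columns `D1`, `D2` and one or
#'   more feature columns.
#' @param x_new A one-row data frame with the same feature columns as
#'   `history` (demand columns are ignored if present).
#' @param prob A [two_class_problem].
#' @param spec A [kernel_spec()].
#' @param features Character vector naming the feature columns; default all
#'   columns except `D1`, `D2`, `t` and `count`.
#' @return A `bed_allocation` (`method = "ko"`).
#' @export
solve_ko <- function(history, x_new, prob, spec = kernel_spec(),
                     features = NULL) {
  stopifnot(inherits(prob, "two_class_problem"))
  history <- as_tibble(history)
  if (nrow(history) < 1L) abort("`history` must be nonempty.")
  if (!all(c("D1", "D2") %in% names(history))) {
    abort("`history` must contain columns `D1` and `D2`.")
  }
  if (is.null(features)) {
    features <- setdiff(names(history), c("D1", "D2", "t", "count"))
  }
  if (length(features) == 0L) abort("No feature columns identified.")
  w <- nw_weights(as_tibble(x_new)[, features, drop = FALSE],
                  history[, features, drop = FALSE], spec)
  obj <- ko_objective_curve(history$D1, history$D2, w, prob)
  q1 <- which.max(obj) - 1L
  new_allocation(q1, obj[q1 + 1L], "ko", nrow(history), prob,
                 objective_curve = obj)
}

# weighted objective over Q1 = 0..K
ko_objective_curve <- function(D1, D2, w, prob) {
  K <- prob$K
  vapply(0:K, function(q) {
    prob$r1 * sum(w * pmin(D1, q)) + prob$r2 * sum(w * pmin(D2, K - q))
  }, numeric(1))
}

#' Learning curve of the kernel-optimization solver
#'
#' Runs [solve_ko()] on growing prefixes of a demand history and reports the
#' chosen urgent quota and an objective value per sample size. By default the
#' objective is the in-sample kernel-weighted estimate at the optimum; if
#' `holdout` (a list with vectors `D1`, `D2` of fresh demand draws at
#' `x_new`) is supplied, each prefix's quota is instead scored out-of-sample
#' on the holdout by sample average, which measures how allocation quality
#' improves with the amount of data.
#'
#' @inheritParams solve_ko
#' @param n_grid Increasing sample sizes, each at most `nrow(history)`.
#' @param holdout Optional list with components `D1` and `D2`.
#' @return A tibble with columns `n`, `Q1`, `objective`.
#' @export
ko_learning_curve <- function(history, x_new, prob, spec = kernel_spec(),
                              n_grid, holdout = NULL) {
  history <- as_tibble(history)
  n_grid <- as.integer(n_grid)
  if (any(diff(n_grid) <= 0)) abort("`n_grid` must be strictly increasing.")
  if (max(n_grid) > nrow(history)) {
    abort("`n_grid` may not exceed the history length.")
  }
  purrr::map_dfr(n_grid, function(n) {
    sol <- solve_ko(history[seq_len(n), , drop = FALSE], x_new, prob, spec)
    objective <- if (is.null(holdout)) {
      sol$objective
    } else {
      prob$r1 * mean(pmin(holdout$D1, sol$Q1)) +
        prob$r2 * mean(pmin(holdout$D2, prob$K - sol$Q1))
    }
    tibble(n = n, Q1 = sol$Q1, objective = objective)
  })
}
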