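# shared numeric helpers

# clamp to [0, 1]
clip01 <- function(x) pmin(1, pmax(0, x))

# positive part
pos <- function(x) pmax(0, x)

# floor with a tolerance so that e.g. 0.7 * 10 = 6.999999... floors to 7
int_floor <- function(x) as.integer(floor(x + 1e-9))

# counts are never negative: clamp at zero, then floor
count_floor <- function(x) int_floor(pmax(0, x))

# weekday on a 5-day (Monday..Friday) workweek calendar
workday_of <- function(t) as.integer((t - 1L) %% 5L + 1L)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_counts <- function(x, name) {
  if (length(x) == 0L) abort(sprintf("`%s` must contain at least one value.", name))
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must be nonnegative integer counts.", name))
  }
  invisible(as.integer(x))
}

# deterministic sub-seed derivation so parallel generator streams do not
# perturb each other; result stays below 2^31 - 1
derive_seed <- function(seed, ...) {
  ks <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (k in ks) x <- (x * 7919 + 104729 * (as.numeric(k) + 1)) %% 2147483647
  as.integer(x)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
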