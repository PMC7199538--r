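waitlist_columns <- c("patient_id", "gender", "admission_certificate_date",
                      "arrival_date", "admission_date", "diagnosis",
                      "disease_type", "insurance_type", "waiting_time",
                      "dual_referral")

#' Read a patient waiting-list CSV
#'
#' Reads per-patient waiting-list records (one row per admission request)
#' with columns `patient_id, gender, admission_certificate_date,
#' arrival_date, admission_date, diagnosis, disease_type, insurance_type,
#' waiting_time, dual_referral`. Dates are ISO-8601. Validation is total:
#' every row is either accepted or collected in a rejects report (attribute
#' `rejects`, also via [rejected_records()]) with a reason; nothing is
#' silently dropped. A row is rejected when its admission date precedes its
#' arrival date, its waiting time is negative, or its waiting time
#' disagrees with `admission_date - admission_certificate_date` when all
#' three are present.
#'
#' @param path Path to the CSV file.
#' @return A tibble of accepted records (class `waiting_list`) with the
#'   rejected rows and reasons in attribute `rejects`.
#' @export
read_waiting_list <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(waitlist_columns, header)
  if (length(missing)) {
    abort(paste0("Waiting-list file is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    gender = readr::col_character(),
    admission_certificate_date = readr::col_date(),
    arrival_date = readr::col_date(),
    admission_date = readr::col_date(),
    diagnosis = readr::col_character(),
    disease_type = readr::col_character(),
    insurance_type = readr::col_character(),
    waiting_time = readr::col_double(),
    dual_referral = readr::col_character()
  ))
  reason <- rep(NA_character_, nrow(raw))
  both_dates <- !is.na(raw$arrival_date) & !is.na(raw$admission_date)
  bad_order <- both_dates & raw$admission_date < raw$arrival_date
  reason[bad_order] <- "admission_date precedes arrival_date"
  bad_wait <- !is.na(raw$waiting_time) & raw$waiting_time < 0
  reason[is.na(reason) & bad_wait] <- "negative waiting_time"
  wt_known <- !is.na(raw$waiting_time) & !is.na(raw$admission_date) &
    !is.na(raw$admission_certificate_date)
  implied <- as.numeric(raw$admission_date - raw$admission_certificate_date)
  bad_consistency <- wt_known & raw$waiting_time != implied
  reason[is.na(reason) & bad_consistency] <-
    "waiting_time inconsistent with certificate/admission dates"
  accepted <- raw[is.na(reason), , drop = FALSE]
  rejects <- raw[!is.na(reason), , drop = FALSE]
  rejects$reason <- reason[!is.na(reason)]
  structure(accepted, rejects = rejects,
            class = c("waiting_list", class(accepted)))
}

#' @rdname read_waiting_list
#' @param records A `waiting_list` tibble.
#' @export
rejected_records <- function(records) {
  attr(records, "rejects") %||% tibble()
}

#' Write waiting-list records to CSV
#'
#' @param records A tibble with the waiting-list columns.
#' @param path Output path.
#' @export
write_waiting_list <- function(records, path) {
  readr::write_csv(as_tibble(records)[, waitlist_columns], path)
  invisible(path)
}

#' Aggregate patient-level records to a daily hospital trace
#'
#' Builds the per-day inputs of the multiperiod pipeline from patient-level
#' waiting-list records: `D1`/`D2` count admission certificates per day by
#' class (via `urgent_types`), `E` counts same-day admissions
#' (`arrival_date == admission_date`), and the initial waiting censuses are
#' reconstructed by date-interval membership (a request waits on day `d`
#' when `certificate <= d` and `admission > d` or is absent). Discharge
#' fractions are not observable in a waiting list, so weekday profiles from
#' `config` are attached. Records dated outside the calendar are excluded
#' with a warning giving the count.
#'
#' @param records A `waiting_list` tibble (accepted records).
#' @param calendar A sorted `Date` vector of workdays defining the horizon.
#' @param urgent_types Values of `disease_type` mapped to the urgent class.
#' @param config A [trace_config()] supplying `K`, the initial censuses and
#'   the discharge profiles.
#' @return A `hospital_trace`.
#' @export
aggregate_to_trace <- function(records, calendar,
                               urgent_types = "urgent",
                               config = trace_config()) {
  records <- as_tibble(records)
  if (!inherits(calendar, "Date") || length(calendar) < 1L) {
    abort("`calendar` must be a nonempty Date vector.")
  }
  calendar <- sort(calendar)
  cert <- records$admission_certificate_date
  outside <- !is.na(cert) & (cert < min(calendar) | cert > max(calendar))
  if (any(outside)) {
    warn(sprintf("aggregate_to_trace: excluded %d record(s) dated outside the calendar.",
                 sum(outside)))
    records <- records[!outside, , drop = FALSE]
    cert <- records$admission_certificate_date
  }
  urgent <- records$disease_type %in% urgent_types
  t_seq <- seq_along(calendar)
  wd <- workday_of(t_seq)
  D1 <- vapply(calendar, function(d) sum(urgent & !is.na(cert) & cert == d), 0L)
  D2 <- vapply(calendar, function(d) sum(!urgent & !is.na(cert) & cert == d), 0L)
  same_day <- !is.na(records$arrival_date) & !is.na(records$admission_date) &
    records$arrival_date == records$admission_date
  E <- vapply(calendar, function(d) {
    sum(same_day & records$admission_date == d)
  }, 0L)
  d0 <- calendar[1]
  waiting0 <- !is.na(cert) & cert <= d0 &
    (is.na(records$admission_date) | records$admission_date > d0)
  W1_0 <- sum(waiting0 & urgent)
  W2_0 <- sum(waiting0 & !urgent)
  cfg <- config
  new_hospital_trace(
    tibble(day = t_seq, weekday = wd, D1 = as.integer(D1), D2 = as.integer(D2),
           E = as.integer(E),
           gamma1 = cfg$gamma1_profile[wd], gamma2 = cfg$gamma2_profile[wd]),
    init_state = list(W1 = as.integer(W1_0), W2 = as.integer(W2_0),
                      B1 = as.integer(cfg$B1_0), B2 = as.integer(cfg$B2_0),
                      X = as.integer(cfg$X_0)),
    K = cfg$K
  )
}

#' Trace CSV + JSON sidecar round trip
#'
#' `write_trace()` writes the per-day columns
#' `day,weekday,D1,D2,E,gamma1,gamma2` to CSV and the initial state and `K`
#' to a JSON sidecar (`<path>.json`); `read_trace()` reads them back.
#'
#' @param trace A `hospital_trace`.
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "hospital_trace"))
  readr::write_csv(as_tibble(trace), path)
  meta <- list(init_state = attr(trace, "init_state"), K = attr(trace, "K"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  days <- readr::read_csv(path, col_types = readr::cols(
    day = readr::col_integer(), weekday = readr::col_integer(),
    D1 = readr::col_integer(), D2 = readr::col_integer(),
    E = readr::col_integer(),
    gamma1 = readr::col_double(), gamma2 = readr::col_double()
  ))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_hospital_trace(days, init_state = as.list(meta$init_state), K = meta$K)
}

config_sections <- function() {
  list(
    demand = names(formals(revenue_gen_params)),
    release = character(0),
    trace = names(formals(trace_config)),
    newsvendor = c("K", "r1", "r2"),
    equity = names(formals(equity_params)),
    run = c("seed", "T", "out")
  )
}

#' Read and validate a YAML run configuration
#'
#' Accepts the sections `demand`, `release`, `trace`, `newsvendor`,
#' `equity` and `run`; unknown sections or keys are rejected with an error
#' naming them. Returns the configuration with defaults merged in.
#'
#' @param path Path to a YAML file.
#' @return A named list of validated sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  sections <- config_sections()
  unknown <- setdiff(names(cfg), names(sections))
  if (length(unknown)) {
    abort(paste0("Unknown config section(s): ", paste(unknown, collapse = ", ")))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), sections[[sec]])
    if (length(bad)) {
      abort(paste0("Unknown key(s) in section `", sec, "`: ",
                   paste(bad, collapse = ", ")))
    }
  }
  defaults <- list(
    demand = revenue_gen_params(),
    release = list(),
    trace = trace_config(),
    newsvendor = list(K = 140L, r1 = 3, r2 = 1),
    equity = unclass(equity_params()),
    run = list(seed = 1L, T = 193L, out = ".")
  )
  for (sec in names(cfg)) {
    defaults[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  defaults
}

#' Deterministic CSV/JSON report writer
#'
#' Writes sweep/run results with a stable byte layout: data frames go to
#' CSV with numeric columns rounded to 6 significant digits; lists go to
#' JSON with sorted keys and 6 significant digits. Identical inputs produce
#' byte-identical files.
#'
#' @param results A data frame or a named list.
#' @param path Output path (`.csv` or `.json` decides the format when the
#'   type is ambiguous).
#' @export
write_report <- function(results, path) {
  if (is.data.frame(results)) {
    out <- as_tibble(results) |>
      dplyr::mutate(dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
    readr::write_csv(out, path)
  } else if (is.list(results)) {
    ord <- order(names(results))
    jsonlite::write_json(results[ord], path, auto_unbox = TRUE, digits = 6,
                         pretty = TRUE)
  } else {
    abort("`results` must be a data frame or a named list.")
  }
  invisible(path)
}

#' Controls-sweep table in wide layout
#'
#' Reshapes an [sweep_controls()] result into the conventional sensitivity
#' layout: one row per reservation proportion `xi`, one column per `alpha`
#' (plus the five `beta` weekday rows on top when `include_beta` is TRUE).
#'
#' @param sweep An `equity_sweep`.
#' @param include_beta Prepend the per-column `beta` vectors as rows.
#' @return A tibble in wide layout.
#' @export
controls_table <- function(sweep, include_beta = TRUE) {
  stopifnot(inherits(sweep, "equity_sweep"))
  wide <- as_tibble(sweep) |>
    dplyr::select(xi, alpha, f) |>
    dplyr::mutate(alpha = paste0("alpha_", alpha)) |>
    tidyr::pivot_wider(names_from = alpha, values_from = f) |>
    dplyr::mutate(row = paste0("f_xi_", xi), .before = 1) |>
    dplyr::select(-xi)
  if (include_beta) {
    betas <- attr(sweep, "betas")
    beta_rows <- purrr::map_dfr(1:5, function(k) {
      vals <- purrr::map_dbl(betas, k)
      row <- tibble(row = paste0("beta_", k))
      for (j in seq_along(vals)) row[[names(wide)[j + 1L]]] <- vals[j]
      row
    })
    wide <- dplyr::bind_rows(beta_rows, wide)
  }
  wide
}

`%||%` <- function(x, y) if (is.null(x)) y else x
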