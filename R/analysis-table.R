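#' Build the participant-by-variable analysis table
#'
#' Scores EQ-5D-3L profiles to utilities, PAID items to 0-100 totals,
#' aggregates health-service and prescription costs by section and window,
#' and applies the 10-14 month validity window to the 12-month outcomes.
#' The result is the aggregated-level table that the imputation and
#' inference stages operate on: one row per participant, with explicit `NA`
#' where a questionnaire or section is missing.
#'
#' @param trial A `trial_data` object.
#' @param unit_costs A [unit_cost_table()].
#' @param value_set An `eq5d_value_set`.
#' @return A tibble with id, centre, arm, baseline covariates, the nine
#'   section costs, `eq5d_0/3/12`, `paid_0/3/12`, assessment months,
#'   `valid_12m`, and auxiliary `eq5d_12_aux`/`paid_12_aux` columns carrying
#'   out-of-window 12-month measurements (usable as imputation predictors
#'   only).
#' @export
build_analysis_table <- function(trial, unit_costs = unit_cost_table(),
                                 value_set = eq5d_value_set()) {
  p <- trial$participants
  eq_dims <- c("mo", "sc", "ua", "pd", "ad")
  out <- p |>
    dplyr::select(dplyr::all_of(c("id", "center", "arm", "age", "sex",
                                  "cvd_history", "smoking",
                                  "diabetes_duration", "month_0", "month_3",
                                  "month_12")))
  for (tp in c("0", "3", "12")) {
    prof <- as.matrix(p[, paste0("eq_", eq_dims, "_", tp)])
    u <- rep(NA_real_, nrow(p))
    ok <- complete.cases(prof)
    if (any(ok)) u[ok] <- eq5d_utility(prof[ok, , drop = FALSE], value_set)
    out[[paste0("eq5d_", tp)]] <- u

    items <- as.matrix(p[, sprintf("paid_q%02d_%s", 1:20, tp)])
    pd <- rep(NA_real_, nrow(p))
    okp <- complete.cases(items)
    if (any(okp)) pd[okp] <- paid_score(items[okp, , drop = FALSE])$total
    out[[paste0("paid_", tp)]] <- pd
  }
  costs <- aggregate_costs(trial, unit_costs)
  out <- dplyr::left_join(out, costs, by = "id")
  out <- apply_validity_window(out)
  # out-of-window 12-month measurements: invalid as outcomes, kept as
  # auxiliary predictors; the outcome columns are set missing there
  out$eq5d_12_aux <- ifelse(!out$valid_12m & !is.na(out$eq5d_12),
                            out$eq5d_12, NA_real_)
  out$paid_12_aux <- ifelse(!out$valid_12m & !is.na(out$paid_12),
                            out$paid_12, NA_real_)
  out$eq5d_12 <- out$eq5d_12_outcome
  out$paid_12 <- out$paid_12_outcome
  out$eq5d_12_outcome <- out$paid_12_outcome <- NULL
  out
}

# the aggregated variables subject to imputation, in a canonical order
imputable_variables <- function() {
  c(paste0("cost_", rep(c("nurse", "presc", "self"), each = 3), "_",
           rep(c("pre", "m0_3", "m3_12"), times = 3)),
    "paid_0", "paid_3", "paid_12", "eq5d_0", "eq5d_3", "eq5d_12",
    "diabetes_duration")
}

# baseline covariates entering every prediction model (binary as indicators)
imputation_covariates <- function() {
  c("age", "sex", "cvd_history", "smoking")
}
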