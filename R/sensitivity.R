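#' ICER as a function of the number of users
#'
#' One-way sensitivity analysis of the cost-effectiveness ratio to scale:
#' the fixed annual operating cost is spread over `n_users` (up to the
#' server capacity) while the per-user training and facilitation costs, the
#' incremental healthcare cost and the incremental QALY observed in the
#' trial are held fixed (the implicit assumption being that effects on
#' health-service use and QALYs generalize).
#'
#' `ICER(n) = (fixed/n + per-user variable + delta healthcare cost) / delta QALY`
#'
#' @param cost_model An [intervention_cost_model()].
#' @param delta_healthcare_cost Adjusted incremental healthcare cost (GBP):
#'   the adjusted incremental total cost minus the per-participant
#'   intervention cost (e.g. 111 - 263 = -152 in rounded-component mode).
#' @param delta_qaly Adjusted incremental QALY (non-zero).
#' @param n_grid User counts to evaluate; default log-spaced over
#'   \[1, capacity\] plus all integers 50-500 so the break-even region is
#'   resolved.
#' @param rounding Component rounding mode.
#' @return A tibble of class `scaling_result` with `n_users`,
#'   `cost_per_user`, `incremental_cost`, `icer`.
#' @export
icer_vs_users <- function(cost_model, delta_healthcare_cost, delta_qaly,
                          n_grid = NULL, rounding = c("rounded", "unrounded")) {
  rounding <- match.arg(rounding)
  if (delta_qaly == 0) abort("delta_qaly must be non-zero")
  if (is.null(n_grid)) {
    n_grid <- sort(unique(c(
      round(exp(seq(log(1), log(cost_model$capacity), length.out = 250))),
      50:500
    )))
  }
  if (any(n_grid < 1) || any(n_grid > cost_model$capacity)) {
    abort(paste0("n_grid must lie within [1, capacity = ",
                 cost_model$capacity, "]"))
  }
  # the fixed share is kept continuous so the curve is strictly monotone;
  # rounding (when requested) applies to the per-user variable components,
  # as in the reported per-participant breakdown
  v <- if (rounding == "rounded") {
    round_gbp(cost_model$per_user_training) +
      round_gbp(cost_model$per_user_facilitation)
  } else {
    cost_model$per_user_training + cost_model$per_user_facilitation
  }
  cpu <- cost_model$fixed_annual / n_grid + v
  out <- tibble::tibble(
    n_users = n_grid,
    cost_per_user = cpu,
    incremental_cost = cpu + delta_healthcare_cost,
    icer = (cpu + delta_healthcare_cost) / delta_qaly
  )
  attr(out, "delta_qaly") <- delta_qaly
  attr(out, "delta_healthcare_cost") <- delta_healthcare_cost
  class(out) <- c("scaling_result", class(out))
  out
}

#' Break-even number of users
#'
#' The user count at which the incremental total cost crosses zero, i.e. the
#' root of `fixed/n + per-user variable + delta healthcare cost = 0`. A root
#' exists only when healthcare savings exceed the per-user variable cost. In
#' rounded-component mode the per-user variable cost is the sum of the
#' rounded training and facilitation components and the healthcare
#' difference is used as passed (conventionally a whole-pound figure).
#'
#' @inheritParams icer_vs_users
#' @return A list with `exact_root`, `breakeven_n` (nearest whole user) and
#'   `exists`; when no root lies in \[1, capacity\], `exists` is `FALSE` and
#'   the roots are `NA` (never fabricated).
#' @examples
#' m <- default_cost_model()
#' breakeven_users(m, -152)$breakeven_n  # 363
#' @export
breakeven_users <- function(cost_model, delta_healthcare_cost,
                            rounding = c("rounded", "unrounded")) {
  rounding <- match.arg(rounding)
  v <- if (rounding == "rounded") {
    round_gbp(cost_model$per_user_training) +
      round_gbp(cost_model$per_user_facilitation)
  } else {
    cost_model$per_user_training + cost_model$per_user_facilitation
  }
  denom <- -(v + delta_healthcare_cost)
  if (denom <= 0) {
    return(list(exact_root = NA_real_, breakeven_n = NA_integer_,
                exists = FALSE,
                reason = "healthcare savings do not exceed the per-user variable cost"))
  }
  root <- cost_model$fixed_annual / denom
  if (root < 1 || root > cost_model$capacity) {
    if (cost_model$fixed_annual == 0) {
      # cost-saving from the first user
      return(list(exact_root = 0, breakeven_n = 1L, exists = TRUE))
    }
    return(list(exact_root = NA_real_, breakeven_n = NA_integer_,
                exists = FALSE,
                reason = "root outside [1, capacity]"))
  }
  list(exact_root = root, breakeven_n = as.integer(round_gbp(root)),
       exists = TRUE)
}

#' Complete-case re-analysis
#'
#' Applies the complete-case filter and runs the same adjusted-model (and
#' optionally bootstrap) machinery on the retained participants, for
#' contrast with the multiply-imputed primary analysis.
#'
#' @param data Analysis table (incomplete).
#' @param cost_model,rounding As in [analyze_imputed()].
#' @param required Required-variable set for [cca_filter()].
#' @param quiet Suppress singular-fit warnings.
#' @return A `cea_fit` with a `retention` element.
#' @export
run_cca_analysis <- function(data, cost_model = default_cost_model(),
                             rounding = "rounded",
                             required = c(imputation_covariates(),
                                          imputable_variables()),
                             quiet = FALSE) {
  cc <- cca_filter(data, required)
  if (length(unique(cc$center)) < 2L) {
    abort("fewer than 2 centres survive the complete-case filter")
  }
  fit <- analyze_imputed(cc, cost_model, rounding, quiet = quiet)
  fit$retention <- attr(cc, "retention")
  fit$analysis <- "complete_case"
  fit
}
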