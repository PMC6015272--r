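#' Unit-cost table for health-service contacts
#'
#' National average unit costs (GBP, 2014 prices) per consultation or
#' episode. VAT, salary on-costs and overheads are already embedded in the
#' published figures, so they are never applied a second time here.
#'
#' @param path CSV with columns `service_type`, `unit_cost`, `source`;
#'   defaults to the packaged 2014 table.
#' @return A tibble of class `unit_cost_table`.
#' @export
unit_cost_table <- function(path = tc_extdata("unit_costs_2014.csv")) {
  tab <- tibble::as_tibble(read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
  stopifnot(all(c("service_type", "unit_cost") %in% names(tab)))
  if (any(tab$unit_cost < 0)) abort("unit costs must be non-negative")
  if (anyDuplicated(tab$service_type)) abort("duplicate service_type in unit-cost table")
  class(tab) <- c("unit_cost_table", class(tab))
  tab
}

# round half up to whole pounds (currency convention; base round() is
# round-half-even)
round_gbp <- function(x) floor(x + 0.5)

#' Cost health-service use counts by section
#'
#' Multiplies each contact count by its national unit cost and sums within
#' each (participant, window, section). Costs are summarised at the
#' aggregated section level: if any individual service count inside a
#' section is missing, the whole section cost is missing, since a partial
#' sum would understate true use.
#'
#' @param use Long tibble of counts with columns `id`, `window`, `section`,
#'   `service_type`, `count` (`NA` = not recorded).
#' @param unit_costs A [unit_cost_table()].
#' @return Tibble with `id`, `window`, `section`, `cost` (GBP or `NA`).
#' @examples
#' uc <- unit_cost_table()
#' use <- tibble::tibble(
#'   id = 1, window = "m0_3", section = "nurse_services",
#'   service_type = c("gp_surgery", "a_and_e"), count = c(2, 1)
#' )
#' cost_service_use(use, uc) # 2 x 38 + 167 = 243
#' @export
cost_service_use <- function(use, unit_costs = unit_cost_table()) {
  stopifnot(is.data.frame(use),
            all(c("id", "window", "section", "service_type", "count") %in% names(use)))
  unknown <- setdiff(unique(use$service_type), unit_costs$service_type)
  if (length(unknown) > 0) {
    abort(paste0("no unit cost for service type(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(use$count < 0, na.rm = TRUE)) abort("service-use counts must be non-negative")
  if (any(use$count %% 1 != 0, na.rm = TRUE)) abort("service-use counts must be whole numbers")
  use |>
    dplyr::left_join(unit_costs[, c("service_type", "unit_cost")],
                     by = "service_type") |>
    dplyr::group_by(.data$id, .data$window, .data$section) |>
    # sum() with na.rm = FALSE implements the missing-section rule
    dplyr::summarise(cost = sum(.data$count * .data$unit_cost), .groups = "drop")
}

#' Cost current prescriptions over a follow-up window
#'
#' Prescriptions are assumed chronic and issued monthly, so each current
#' item's monthly cost is multiplied by the number of months the collection
#' window covers (12 for the pre-baseline year, 3 for 0-3 months, 9 for 3-12
#' months). A blank prescription record is missing data unless the record
#' explicitly states that no medication was prescribed, in which case the
#' cost is zero.
#'
#' @param items Tibble with `id`, `timepoint` (0, 3 or 12), `monthly_cost`
#'   (GBP per item per month); one row per current item.
#' @param status Tibble with `id`, `timepoint`, `presc_status` in
#'   `c("recorded", "none", "missing")` covering every participant-timepoint.
#' @return Tibble `id`, `timepoint`, `window`, `months`, `cost` (GBP or `NA`).
#' @export
cost_prescriptions <- function(items, status) {
  stopifnot(all(c("id", "timepoint", "presc_status") %in% names(status)))
  win <- prescription_windows()
  bad <- setdiff(unique(status$timepoint), win$timepoint)
  if (length(bad) > 0) {
    abort(paste0("unknown prescription timepoint(s): ", paste(bad, collapse = ", ")))
  }
  sums <- items |>
    dplyr::group_by(.data$id, .data$timepoint) |>
    dplyr::summarise(monthly_total = sum(.data$monthly_cost), .groups = "drop")
  status |>
    dplyr::left_join(sums, by = c("id", "timepoint")) |>
    dplyr::left_join(win, by = "timepoint") |>
    dplyr::mutate(cost = dplyr::case_when(
      presc_status == "none" ~ 0,
      presc_status == "missing" ~ NA_real_,
      is.na(monthly_total) ~ NA_real_,  # "recorded" but no items listed
      TRUE ~ monthly_total * months
    )) |>
    dplyr::select("id", "timepoint", "window", "months", "cost")
}

prescription_windows <- function() {
  tibble::tibble(
    timepoint = c(0, 3, 12),
    window = c("pre", "m0_3", "m3_12"),
    months = c(12, 3, 9)
  )
}

#' Annual staff costs of maintaining and delivering the intervention
#'
#' Each activity is costed as hours per occasion x occasions per year x
#' hourly rate, rounded to whole pounds. The packaged schedule also carries
#' the reported annual figure per row (`printed_cost`); a few reported rows
#' differ slightly from any single annualization convention, so the reported
#' figures are authoritative for totals and `mode = "printed"` is the
#' default. The returned audit columns expose the relative disagreement, and
#' rows off by more than `flag_tol` are flagged.
#'
#' @param schedule Tibble (or path to CSV) with columns `activity`, `rate`,
#'   `hours_per_occasion`, `occasions_per_year`, `printed_cost`; defaults to
#'   the packaged schedule.
#' @param mode `"printed"` (use reported row values) or `"formula"`.
#' @param flag_tol Relative-difference threshold for the audit flag (0.02).
#' @return Tibble with per-activity `formula_cost`, `printed_cost`, selected
#'   `cost`, `rel_diff`, `flagged`; the total is `sum(cost)`.
#' @export
staff_activity_costs <- function(schedule = tc_extdata("staff_activity_schedule.csv"),
                                 mode = c("printed", "formula"),
                                 flag_tol = 0.02) {
  mode <- match.arg(mode)
  if (is.character(schedule)) {
    schedule <- tibble::as_tibble(read.csv(schedule, comment.char = "#",
                                           stringsAsFactors = FALSE))
  }
  req <- c("activity", "rate", "hours_per_occasion", "occasions_per_year",
           "printed_cost")
  stopifnot(all(req %in% names(schedule)))
  if (any(schedule$rate < 0)) abort("hourly rates must be non-negative")
  schedule |>
    dplyr::mutate(
      formula_cost = round_gbp(.data$hours_per_occasion *
                                 .data$occasions_per_year * .data$rate),
      rel_diff = abs(.data$formula_cost - .data$printed_cost) / .data$printed_cost,
      flagged = .data$rel_diff > flag_tol,
      cost = if (mode == "printed") .data$printed_cost else .data$formula_cost
    )
}

#' Annual infrastructure (hardware, software, hosting) costs
#'
#' @param path CSV with `item`, `annual_cost`; defaults to the packaged file.
#' @return Tibble; total is `sum(annual_cost)`.
#' @export
infrastructure_costs <- function(path = tc_extdata("infrastructure_costs.csv")) {
  tab <- tibble::as_tibble(read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
  stopifnot(all(c("item", "annual_cost") %in% names(tab)))
  if (any(tab$annual_cost < 0)) abort("infrastructure costs must be non-negative")
  tab
}

#' Intervention cost model: fixed annual plus per-user components
#'
#' The operating cost of the web programme (staff plus infrastructure) is
#' fixed per year up to the server capacity; nurse training and nurse-led
#' facilitation (registration session plus booklet) accrue per user. The
#' control arm incurs no intervention cost.
#'
#' @param fixed_annual Fixed annual operating cost (GBP/year).
#' @param per_user_training Training cost per user (GBP); held constant as
#'   user numbers grow (conservative).
#' @param per_user_facilitation Facilitation cost per user (GBP).
#' @param capacity Maximum concurrent users the infrastructure supports.
#' @param trial_n Users over whom fixed costs were spread in the trial.
#' @return A list of class `intervention_cost_model`.
#' @export
intervention_cost_model <- function(fixed_annual,
                                    per_user_training,
                                    per_user_facilitation,
                                    capacity = 10000,
                                    trial_n = 185) {
  vals <- c(fixed_annual, per_user_training, per_user_facilitation)
  if (any(vals < 0)) abort("cost components must be non-negative")
  if (capacity < trial_n) abort("capacity must be at least trial_n")
  structure(
    list(fixed_annual = fixed_annual,
         per_user_training = per_user_training,
         per_user_facilitation = per_user_facilitation,
         capacity = capacity, trial_n = trial_n),
    class = "intervention_cost_model"
  )
}

#' Default intervention cost model from the packaged cost schedules
#'
#' Fixed annual cost = reported staff total + infrastructure total
#' (41,796 GBP/year). Training: 3,785 GBP of trainer and nurse time plus 78
#' GBP of printed materials across the 185 intervention-arm participants.
#' Facilitation: 20 minutes of practice-nurse time (one third of the 44
#' GBP hourly consultation rate) plus a 0.95 GBP booklet per user.
#'
#' @param trial_n Intervention-arm size used to spread training costs (185).
#' @param capacity Server capacity (10,000 users).
#' @return An [intervention_cost_model()].
#' @export
default_cost_model <- function(trial_n = 185, capacity = 10000) {
  staff <- sum(staff_activity_costs(mode = "printed")$cost)
  infra <- sum(infrastructure_costs()$annual_cost)
  training_total <- 3785 + 78
  intervention_cost_model(
    fixed_annual = staff + infra,
    per_user_training = training_total / trial_n,
    per_user_facilitation = 44 / 3 + 0.95,
    capacity = capacity,
    trial_n = trial_n
  )
}

#' Intervention cost per user at a given scale
#'
#' Fixed annual cost spread over `n_users`, plus the per-user training and
#' facilitation components. In `"rounded"` mode each component is rounded to
#' the nearest pound before summation (matching how per-participant
#' components are conventionally reported); `"unrounded"` sums exactly.
#'
#' @param model An [intervention_cost_model()].
#' @param n_users Number of active users (1 to `model$capacity`).
#' @param rounding `"rounded"` (default) or `"unrounded"`.
#' @return Tibble with the three components and `cost_per_user` (GBP).
#' @examples
#' m <- default_cost_model()
#' intervention_cost_per_user(m, 185)$cost_per_user # 226 + 21 + 16 = 263
#' @export
intervention_cost_per_user <- function(model, n_users,
                                       rounding = c("rounded", "unrounded")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(model, "intervention_cost_model"))
  if (any(n_users < 1) || any(n_users > model$capacity)) {
    abort(paste0("n_users must lie in [1, capacity = ", model$capacity, "]"))
  }
  fixed_pp <- model$fixed_annual / n_users
  train <- rep_len(model$per_user_training, length(n_users))
  facil <- rep_len(model$per_user_facilitation, length(n_users))
  if (rounding == "rounded") {
    fixed_pp <- round_gbp(fixed_pp)
    train <- round_gbp(train)
    facil <- round_gbp(facil)
  }
  tibble::tibble(
    n_users = n_users,
    fixed_component = fixed_pp,
    training_component = train,
    facilitation_component = facil,
    cost_per_user = fixed_pp + train + facil
  )
}

#' Aggregate a trial dataset's health-service costs by section and window
#'
#' Runs [cost_service_use()] and [cost_prescriptions()] over a generated (or
#' imported) trial dataset and returns the participant-by-variable aggregated
#' cost table that the imputation and inference stages consume: one column
#' per (section, window), in GBP, `NA` where the section is missing.
#'
#' @param trial A `trial_data` object (see [generate_trial()]) or a list with
#'   `service_use`, `prescription_items`, `prescription_status` tibbles.
#' @param unit_costs A [unit_cost_table()].
#' @return Tibble keyed by `id` with columns
#'   `cost_<section>_<window>` for sections `nurse`/`presc`/`self` and
#'   windows `pre`/`m0_3`/`m3_12`, plus `cost_baseline` (pre-window total)
#'   and `cost_trial` (0-12 month total, `NA` if any component missing).
#' @export
aggregate_costs <- function(trial, unit_costs = unit_cost_table()) {
  svc <- cost_service_use(trial$service_use, unit_costs) |>
    dplyr::mutate(var = paste0(
      "cost_", ifelse(.data$section == "nurse_services", "nurse", "self"),
      "_", .data$window
    )) |>
    dplyr::select("id", "var", "cost")
  presc <- cost_prescriptions(trial$prescription_items,
                              trial$prescription_status) |>
    dplyr::mutate(var = paste0("cost_presc_", .data$window)) |>
    dplyr::select("id", "var", "cost")
  wide <- dplyr::bind_rows(svc, presc) |>
    tidyr::pivot_wider(names_from = "var", values_from = "cost")
  cols <- paste0("cost_", rep(c("nurse", "presc", "self"), each = 3), "_",
                 rep(c("pre", "m0_3", "m3_12"), times = 3))
  for (cl in setdiff(cols, names(wide))) wide[[cl]] <- NA_real_
  wide |>
    dplyr::mutate(
      cost_baseline = .data$cost_nurse_pre + .data$cost_presc_pre +
        .data$cost_self_pre,
      cost_trial = .data$cost_nurse_m0_3 + .data$cost_presc_m0_3 +
        .data$cost_self_m0_3 + .data$cost_nurse_m3_12 +
        .data$cost_presc_m3_12 + .data$cost_self_m3_12
    ) |>
    dplyr::select(dplyr::all_of(c("id", cols, "cost_baseline", "cost_trial")))
}
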