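#' Configuration for the synthetic trial generator
#'
#' Defines the study conditions the generator emulates: a 374-participant,
#' two-arm, 21-centre trial of a web-based diabetes self-management
#' programme, with EQ-5D-3L, PAID and aggregated health-service costs
#' observed at baseline, 3 and 12 months. Defaults reproduce the published
#' arm-level summary statistics; the embedded baseline-adjusted incremental
#' effects are set through `effect_targets` and the baseline-to-follow-up
#' regression slopes, so the full pipeline can be exercised as a
#' parameter-recovery experiment.
#'
#' Follow-up means in the intervention arm are derived from
#' `effect_targets`: for an outcome with baseline arm difference `d0`,
#' shared baseline slope `b` and target adjusted difference `delta`, the
#' 12-month arm difference is set so that `delta = d12 - b * d0` (for QALYs,
#' through the trapezoidal AUC weights 0.125/0.5/0.375). The cost target is
#' the *total* adjusted incremental cost, so the embedded healthcare
#' difference is `effect_targets["cost"] - intervention_cost_pp`.
#'
#' @param n_per_arm Target arm sizes (the total is what the generator uses;
#'   realized arm sizes come from the blocked randomization).
#' @param n_centers Number of recruitment centres.
#' @param block_sizes Permuted-block sizes (all even).
#' @param effect_targets Named vector: adjusted incremental total `cost`
#'   (GBP), `qaly`, and `paid` (12-month difference) to embed.
#' @param intervention_cost_pp Per-participant intervention cost added in the
#'   intervention arm by the analysis stage (default 263).
#' @param baseline,cost,utility,paid,center_sd,assessment,missingness Lists
#'   of distribution parameters; see Details in the package vignette. Any
#'   element supplied overrides the default of the same name.
#' @param seed Integer; drives a per-operation seed sequence recorded in the
#'   generated object's metadata.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = c(185, 189),
                         n_centers = 21,
                         block_sizes = c(2, 4, 6),
                         effect_targets = c(cost = 111, qaly = 0.020, paid = -1.9),
                         intervention_cost_pp = 263,
                         baseline = list(),
                         cost = list(),
                         utility = list(),
                         paid = list(),
                         center_sd = list(),
                         assessment = list(),
                         missingness = list(),
                         seed = 1L) {
  if (any(block_sizes %% 2 != 0) || any(block_sizes < 2)) {
    abort("block sizes must all be even and >= 2")
  }
  defaults <- list(
    baseline = list(
      age_mean = c(64.9, 64.7), age_sd = c(9.5, 9.1),
      p_male = 0.69, p_cvd = 0.25, p_smoking = 0.15,
      duration_mean = c(7.8, 8.2), duration_sd = c(5.7, 6.1)
    ),
    cost = list(
      baseline_mean = c(1792, 2084),   # intervention, control (GBP/year)
      control_trial_mean = 2067,
      baseline_cv = 0.86, innovation_cv = 0.95,
      slope = 0.339,                    # baseline -> trial-period regression
      section_split = c(nurse = 0.55, presc = 0.30, self = 0.15),
      window_split = c(m0_3 = 0.25, m3_12 = 0.75)
    ),
    utility = list(
      baseline_mean = c(0.793, 0.766),
      control_mean = c(0.766, 0.786, 0.736),  # months 0, 3, 12
      m3_diff = 0.025,                  # intervention - control at 3 months
      sd = rbind(intervention = c(0.232, 0.186, 0.218),
                 control = c(0.207, 0.229, 0.250)),
      slope = 0.587
    ),
    paid = list(
      baseline_mean = c(18.1, 19.9),
      control_mean = c(19.9, 17.3, 17.6),
      m3_diff = -1.6,
      sd = rbind(intervention = c(16.8, 16.0, 15.5),
                 control = c(16.5, 16.0, 15.2)),
      slope = 0.667
    ),
    center_sd = list(cost = 150, utility = 0.02, paid = 2),
    assessment = list(m3_mean = 3.2, m3_sd = 0.4,
                      m12_mean = 12.3, m12_sd = 0.8, m12_range = c(9, 16)),
    missingness = list(
      q3 = c(0.23, 0.20), q12 = c(0.30, 0.29),  # intervention, control
      q12_given_q3_missing = 0.5,
      nurse_section = 0.02, duration = 0.011,
      mar_gamma = 0.3, mar = TRUE
    )
  )
  merge_list <- function(def, user) {
    for (nm in names(user)) def[[nm]] <- user[[nm]]
    def
  }
  cfg <- list(
    n_per_arm = n_per_arm, n_centers = n_centers, block_sizes = block_sizes,
    effect_targets = effect_targets,
    intervention_cost_pp = intervention_cost_pp,
    baseline = merge_list(defaults$baseline, baseline),
    cost = merge_list(defaults$cost, cost),
    utility = merge_list(defaults$utility, utility),
    paid = merge_list(defaults$paid, paid),
    center_sd = merge_list(defaults$center_sd, center_sd),
    assessment = merge_list(defaults$assessment, assessment),
    missingness = merge_list(defaults$missingness, missingness),
    seed = as.integer(seed)
  )
  validate_trial_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_trial_config <- function(cfg) {
  probs <- c(cfg$baseline$p_male, cfg$baseline$p_cvd, cfg$baseline$p_smoking,
             cfg$missingness$q3, cfg$missingness$q12,
             cfg$missingness$nurse_section, cfg$missingness$duration)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(cfg$utility$baseline_mean < -0.594 | cfg$utility$baseline_mean > 1) ||
      any(cfg$utility$control_mean < -0.594 | cfg$utility$control_mean > 1)) {
    abort("utility means must lie in [-0.594, 1]")
  }
  if (any(cfg$paid$baseline_mean < 0 | cfg$paid$baseline_mean > 100)) {
    abort("PAID means must lie in [0, 100]")
  }
  if (any(c(cfg$baseline$age_sd, cfg$baseline$duration_sd,
            cfg$utility$sd, cfg$paid$sd) < 0)) {
    abort("standard deviations must be non-negative")
  }
  invisible(cfg)
}

# derive per-arm mean structure for follow-ups from the effect targets
derived_means <- function(cfg) {
  b_u <- cfg$utility$slope
  d0_u <- cfg$utility$baseline_mean[1] - cfg$utility$baseline_mean[2]
  # target adjusted QALY = 0.5 * d3 + 0.375 * d12 - 0.875 * b * d0
  d3_u <- cfg$utility$m3_diff
  d12_u <- (cfg$effect_targets[["qaly"]] + 0.875 * b_u * d0_u - 0.5 * d3_u) / 0.375
  util_int <- c(cfg$utility$baseline_mean[1],
                cfg$utility$control_mean[2] + d3_u,
                cfg$utility$control_mean[3] + d12_u)
  util_ctl <- cfg$utility$control_mean

  b_p <- cfg$paid$slope
  d0_p <- cfg$paid$baseline_mean[1] - cfg$paid$baseline_mean[2]
  d12_p <- cfg$effect_targets[["paid"]] + b_p * d0_p
  paid_int <- c(cfg$paid$baseline_mean[1],
                cfg$paid$control_mean[2] + cfg$paid$m3_diff,
                cfg$paid$control_mean[3] + d12_p)
  paid_ctl <- cfg$paid$control_mean

  b_c <- cfg$cost$slope
  d0_c <- cfg$cost$baseline_mean[1] - cfg$cost$baseline_mean[2]
  d1_c <- (cfg$effect_targets[["cost"]] - cfg$intervention_cost_pp) + b_c * d0_c
  cost_trial <- c(cfg$cost$control_trial_mean + d1_c, cfg$cost$control_trial_mean)

  list(
    utility = rbind(intervention = util_int, control = util_ctl),
    paid = rbind(intervention = paid_int, control = paid_ctl),
    cost_baseline = cfg$cost$baseline_mean,
    cost_trial = cost_trial
  )
}

#' Assign arms by permuted blocks stratified by centre
#'
#' Within each centre, participants are assigned in randomly permuted blocks
#' whose sizes are drawn from `block_sizes`; every completed block is exactly
#' balanced, so within-centre imbalance never exceeds half the largest block.
#'
#' @param data Tibble with a `center` column (no missing values).
#' @param block_sizes Even block sizes to draw from.
#' @param seed Integer seed (assignment is deterministic given the seed).
#' @return `data` with an `arm` factor column (`intervention`/`control`).
#' @export
block_randomize <- function(data, block_sizes = c(2, 4, 6), seed = 1L) {
  stopifnot(is.data.frame(data), "center" %in% names(data))
  if (anyNA(data$center)) abort("every participant must have a known center")
  if (any(block_sizes %% 2 != 0)) abort("block sizes must be even")
  set.seed(as.integer(seed))
  arms <- character(nrow(data))
  for (ctr in unique(data$center)) {
    idx <- which(data$center == ctr)
    assigned <- character(0)
    while (length(assigned) < length(idx)) {
      bs <- if (length(block_sizes) == 1L) block_sizes else sample(block_sizes, 1L)
      block <- sample(rep(c("intervention", "control"), bs / 2))
      assigned <- c(assigned, block)
    }
    arms[idx] <- assigned[seq_along(idx)]
  }
  data$arm <- factor(arms, levels = c("control", "intervention"))
  data
}

# --- latent-scale calibration helpers -------------------------------------

# expected value of a normal variate snapped to the nearest point of `grid`
snapped_normal_mean <- function(mu, sd, grid) {
  if (sd == 0) return(grid[which.min(abs(grid - mu))])
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  p <- diff(c(0, pnorm(mids, mu, sd), 1))
  sum(grid * p)
}

# latent mean such that the snapped mean equals `target`
calibrate_snap_mean <- function(target, sd, grid) {
  if (sd == 0) return(target)
  uniroot(function(mu) snapped_normal_mean(mu, sd, grid) - target,
          interval = c(target - 1, target + 1), extendInt = "yes",
          tol = 1e-8)$root
}

snap_to_grid <- function(x, grid) {
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  grid[findInterval(x, mids) + 1L]
}

rgamma_mean_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

# distribute a 0-80 raw PAID sum over 20 items capped at 4
allocate_paid_items <- function(raw_sum, n_items = 20L, item_max = 4L) {
  raw_sum <- max(0L, min(n_items * item_max, as.integer(raw_sum)))
  items <- as.integer(rmultinom(1L, raw_sum, rep(1, n_items)))
  while (any(items > item_max)) {
    over <- which(items > item_max)
    excess <- sum(items[over] - item_max)
    items[over] <- item_max
    room <- which(items < item_max)
    add <- as.integer(rmultinom(1L, excess, rep(1, length(room))))
    items[room] <- items[room] + add
  }
  items
}

# service types and relative cost weights per section
nurse_service_weights <- function() {
  c(gp_surgery = 0.28, gp_telephone = 0.05, nurse_surgery = 0.12,
    clinical_test = 0.05, outpatient = 0.25, day_case = 0.08,
    a_and_e = 0.07, inpatient = 0.10)
}
self_service_weights <- function() {
  c(walk_in_clinic = 0.14, podiatrist = 0.16, optometry = 0.12,
    physiotherapy = 0.18, counselling_primary = 0.10,
    dietician = 0.16, occupational_therapy = 0.14)
}

# unbiased integer counts whose expected cost equals `target`
stochastic_counts <- function(target, weights, unit_costs) {
  lam <- target * weights / unit_costs
  base <- floor(lam)
  as.integer(base + rbinom(length(lam), 1L, lam - base))
}

#' Generate a complete synthetic trial dataset
#'
#' Draws centres, covariates, blocked arm assignment, per-section
#' health-service counts and prescriptions (gamma section totals realized as
#' unbiased integer counts), EQ-5D-3L profiles sampled on the 243-state
#' tariff grid so their utilities match the target arm moments, PAID item
#' responses whose rescaled sums match the target moments, and jittered
#' assessment months. The dataset is complete; apply [impose_missingness()]
#' to obtain realistic missing-data patterns.
#'
#' @param config A [trial_config()].
#' @param value_set Tariff used to build the utility grid.
#' @return A list of class `trial_data` with tibbles `participants`,
#'   `service_use`, `prescription_items`, `prescription_status`, the latent
#'   `truth` table (pre-discretization section costs, utilities and PAID
#'   totals, for calibration experiments), the config echo and the seed trail.
#' @export
generate_trial <- function(config = trial_config(),
                           value_set = eq5d_value_set()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  op_seeds <- sample.int(.Machine$integer.max, 8L)
  n <- sum(config$n_per_arm)
  K <- config$n_centers
  means <- derived_means(config)
  if (any(means$cost_trial - config$cost$slope * means$cost_baseline <= 0)) {
    abort("infeasible cost parameters: trial-period mean must exceed slope x baseline mean")
  }

  # centres of uneven size, each with at least 2 participants
  set.seed(op_seeds[1])
  w <- runif(K, 0.4, 1.6)
  sizes <- 2L + as.integer(rmultinom(1L, n - 2L * K, w))
  center <- factor(rep(paste0("C", sprintf("%02d", seq_len(K))), times = sizes))
  participants <- tibble::tibble(id = seq_len(n), center = center)

  participants <- block_randomize(participants, config$block_sizes,
                                  seed = op_seeds[2])
  arm_idx <- ifelse(participants$arm == "intervention", 1L, 2L)
  n_int <- sum(arm_idx == 1L)

  # baseline covariates
  set.seed(op_seeds[3])
  bl <- config$baseline
  participants <- participants |>
    dplyr::mutate(
      age = rnorm(n, bl$age_mean[arm_idx], bl$age_sd[arm_idx]),
      sex = rbinom(n, 1L, bl$p_male),                  # 1 = male
      cvd_history = rbinom(n, 1L, bl$p_cvd),
      smoking = rbinom(n, 1L, bl$p_smoking),
      diabetes_duration = rgamma_mean_cv(
        n, 1, 1)) # placeholder, filled below per arm
  dur <- numeric(n)
  for (a in 1:2) {
    ii <- which(arm_idx == a)
    dur[ii] <- rgamma_mean_cv(length(ii), bl$duration_mean[a],
                              bl$duration_sd[a] / bl$duration_mean[a])
  }
  participants$diabetes_duration <- dur

  # centre effects (shared across windows/timepoints within an outcome)
  set.seed(op_seeds[4])
  ce_cost <- rnorm(K, 0, config$center_sd$cost)
  ce_util <- rnorm(K, 0, config$center_sd$utility)
  ce_paid <- rnorm(K, 0, config$center_sd$paid)
  ci <- as.integer(participants$center)

  # --- costs: correlated totals, split to sections/windows ----------------
  # The trial-period total is built on the REALIZED (costed) baseline, not
  # the latent one, so the baseline-adjustment slope is not attenuated by
  # the integer count discretization.
  set.seed(op_seeds[5])
  cc <- config$cost
  nw <- nurse_service_weights(); sw <- self_service_weights()
  uc <- unit_cost_table()
  ucv <- setNames(uc$unit_cost, uc$service_type)
  svc_weights <- list(nurse = nw, self = sw)
  sec <- cc$section_split / sum(cc$section_split)
  wsp <- cc$window_split / sum(cc$window_split)

  # realize one (window x section) cell of counts for all participants
  realize_counts <- function(targets, window, key) {
    wts <- svc_weights[[key]]
    cnt <- t(vapply(targets, stochastic_counts, integer(length(wts)),
                    weights = wts, unit_costs = ucv[names(wts)]))
    tibble::tibble(
      id = rep(participants$id, each = length(wts)),
      window = window,
      section = ifelse(key == "nurse", "nurse_services", "self_report"),
      service_type = rep(names(wts), times = n),
      count = as.integer(t(cnt))
    )
  }

  c0 <- numeric(n)
  for (a in 1:2) {
    ii <- which(arm_idx == a)
    c0[ii] <- rgamma_mean_cv(length(ii), means$cost_baseline[a],
                             cc$baseline_cv)
  }
  c0 <- pmax(0, c0 + ce_cost[ci])
  su_nurse_pre <- realize_counts(c0 * sec[["nurse"]], "pre", "nurse")
  su_self_pre <- realize_counts(c0 * sec[["self"]], "pre", "self")
  presc_pre_target <- c0 * sec[["presc"]]
  realized_svc0 <- vapply(
    split((su_nurse_pre$count * ucv[su_nurse_pre$service_type]),
          su_nurse_pre$id)[as.character(participants$id)], sum, numeric(1)) +
    vapply(split((su_self_pre$count * ucv[su_self_pre$service_type]),
                 su_self_pre$id)[as.character(participants$id)], sum, numeric(1))
  c0_real <- realized_svc0 + presc_pre_target

  c1 <- numeric(n)
  for (a in 1:2) {
    ii <- which(arm_idx == a)
    innov <- rgamma_mean_cv(length(ii),
                            means$cost_trial[a] -
                              cc$slope * means$cost_baseline[a],
                            cc$innovation_cv)
    c1[ii] <- cc$slope * c0_real[ii] + innov
  }
  c1 <- pmax(0, c1 + ce_cost[ci])
  su_nurse_03 <- realize_counts(c1 * wsp[["m0_3"]] * sec[["nurse"]], "m0_3", "nurse")
  su_self_03 <- realize_counts(c1 * wsp[["m0_3"]] * sec[["self"]], "m0_3", "self")
  su_nurse_312 <- realize_counts(c1 * wsp[["m3_12"]] * sec[["nurse"]], "m3_12", "nurse")
  su_self_312 <- realize_counts(c1 * wsp[["m3_12"]] * sec[["self"]], "m3_12", "self")
  service_use <- dplyr::bind_rows(su_nurse_pre, su_self_pre, su_nurse_03,
                                  su_self_03, su_nurse_312, su_self_312)
  sect_targets <- tibble::tibble(
    id = rep(participants$id, times = 3L),
    window = rep(c("pre", "m0_3", "m3_12"), each = n),
    section_key = "presc",
    target = c(presc_pre_target, c1 * wsp[["m0_3"]] * sec[["presc"]],
               c1 * wsp[["m3_12"]] * sec[["presc"]])
  )

  # prescriptions: current items whose monthly total reproduces the target
  presc <- sect_targets |>
    dplyr::filter(.data$section_key == "presc") |>
    dplyr::left_join(prescription_windows(), by = "window")
  presc$monthly_total <- presc$target / presc$months
  items_list <- vector("list", nrow(presc))
  status <- character(nrow(presc))
  for (i in seq_len(nrow(presc))) {
    mt <- presc$monthly_total[i]
    if (mt < 0.5) { status[i] <- "none"; items_list[[i]] <- numeric(0); next }
    status[i] <- "recorded"
    j <- 1L + rpois(1L, 2.5)
    shares <- stats::rexp(j); shares <- shares / sum(shares)
    items_list[[i]] <- round(mt * shares, 2)
  }
  prescription_status <- tibble::tibble(
    id = presc$id, timepoint = presc$timepoint, presc_status = status
  )
  prescription_items <- tibble::tibble(
    id = rep(presc$id, lengths(items_list)),
    timepoint = rep(presc$timepoint, lengths(items_list)),
    item = unlist(lapply(lengths(items_list), function(k) {
      if (k > 0) paste0("med_", seq_len(k)) else character(0)
    })),
    monthly_cost = unlist(items_list)
  )

  # --- EQ-5D utilities on the tariff grid ---------------------------------
  set.seed(op_seeds[6])
  profs <- eq5d_profiles(value_set)
  grid <- sort(unique(profs$utility))
  prof_by_u <- split(profs$state, profs$utility)
  um <- means$utility; usd <- config$utility$sd
  b_u <- config$utility$slope
  csd_u <- config$center_sd$utility
  lat_u <- matrix(NA_real_, n, 3)
  for (a in 1:2) {
    ii <- which(arm_idx == a)
    sd_tot0 <- sqrt(usd[a, 1]^2 + csd_u^2)
    mu0 <- calibrate_snap_mean(um[a, 1], sd_tot0, grid)
    z0 <- rnorm(length(ii), mu0, usd[a, 1]) + ce_util[ci[ii]]
    lat_u[ii, 1] <- z0
    for (t in 2:3) {
      sd_e2 <- usd[a, t]^2 - b_u^2 * usd[a, 1]^2
      if (sd_e2 < 0) abort("utility SDs incompatible with baseline slope")
      sd_tot <- sqrt(usd[a, t]^2 + csd_u^2)
      mut <- calibrate_snap_mean(um[a, t], sd_tot, grid)
      lat_u[ii, t] <- mut + b_u * (z0 - ce_util[ci[ii]] - mu0) +
        rnorm(length(ii), 0, sqrt(sd_e2)) + ce_util[ci[ii]]
    }
  }
  snapped <- apply(lat_u, 2, snap_to_grid, grid = grid)
  states <- apply(snapped, 2, function(col) {
    vapply(col, function(u) {
      cands <- prof_by_u[[as.character(u)]]
      if (length(cands) == 1L) cands else sample(cands, 1L)
    }, character(1))
  })
  for (t in 1:3) {
    tp <- c("0", "3", "12")[t]
    lev <- do.call(rbind, strsplit(states[, t], ""))
    for (d in 1:5) {
      participants[[paste0("eq_", c("mo", "sc", "ua", "pd", "ad")[d], "_", tp)]] <-
        as.integer(lev[, d])
    }
  }

  # --- PAID items ---------------------------------------------------------
  set.seed(op_seeds[7])
  pm <- means$paid; psd <- config$paid$sd
  b_p <- config$paid$slope
  csd_p <- config$center_sd$paid
  # PAID totals live on the 0-100 grid with 1.25 spacing (20 items x 0:4
  # rescaled); calibrating on that grid removes discretization bias
  paid_grid <- seq(0, 100, by = 1.25)
  lat_p <- matrix(NA_real_, n, 3)
  for (a in 1:2) {
    ii <- which(arm_idx == a)
    sd_tot0 <- sqrt(psd[a, 1]^2 + csd_p^2)
    mu0 <- calibrate_snap_mean(pm[a, 1], sd_tot0, paid_grid)
    z0 <- rnorm(length(ii), mu0, psd[a, 1]) + ce_paid[ci[ii]]
    lat_p[ii, 1] <- z0
    for (t in 2:3) {
      sd_e2 <- psd[a, t]^2 - b_p^2 * psd[a, 1]^2
      if (sd_e2 < 0) abort("PAID SDs incompatible with baseline slope")
      sd_tot <- sqrt(psd[a, t]^2 + csd_p^2)
      mut <- calibrate_snap_mean(pm[a, t], sd_tot, paid_grid)
      lat_p[ii, t] <- mut + b_p * (z0 - ce_paid[ci[ii]] - mu0) +
        rnorm(length(ii), 0, sqrt(sd_e2)) + ce_paid[ci[ii]]
    }
  }
  raw <- round(pmin(pmax(lat_p, 0), 100) / 1.25)
  for (t in 1:3) {
    tp <- c("0", "3", "12")[t]
    item_mat <- t(vapply(raw[, t], allocate_paid_items, integer(20)))
    colnames(item_mat) <- sprintf("paid_q%02d_%s", 1:20, tp)
    participants <- dplyr::bind_cols(participants, tibble::as_tibble(item_mat))
  }

  # --- assessment months --------------------------------------------------
  set.seed(op_seeds[8])
  as_cfg <- config$assessment
  participants$month_0 <- 0
  participants$month_3 <- rnorm(n, as_cfg$m3_mean, as_cfg$m3_sd)
  m12 <- rnorm(n, as_cfg$m12_mean, as_cfg$m12_sd)
  participants$month_12 <- pmin(pmax(m12, as_cfg$m12_range[1]),
                                as_cfg$m12_range[2])

  truth <- tibble::tibble(
    id = participants$id, arm = participants$arm,
    cost_baseline = c0_real, cost_trial = c1,
    utility_0 = snapped[, 1], utility_3 = snapped[, 2], utility_12 = snapped[, 3],
    paid_0 = raw[, 1] * 1.25, paid_3 = raw[, 2] * 1.25, paid_12 = raw[, 3] * 1.25
  )

  structure(
    list(participants = participants, service_use = service_use,
         prescription_items = prescription_items,
         prescription_status = prescription_status,
         truth = truth, config = config,
         seeds = list(global = config$seed, operations = op_seeds),
         missingness_imposed = FALSE),
    class = "trial_data"
  )
}

#' Impose questionnaire-level missingness on a complete trial dataset
#'
#' Self-report questionnaires (EQ-5D, PAID, self-report service use and the
#' assessment date) go missing as a unit at 3 and 12 months, at per-arm rates
#' configured in `config$missingness`. When `mar = TRUE`, non-response
#' depends on baseline distress (observed, never missing), so the mechanism
#' is missing-at-random by construction: the probability never involves the
#' value being removed. Non-response at 12 months is positively associated
#' with non-response at 3 months (drop-out). Nurse-recorded sections
#' (services and prescriptions) go missing independently at a small rate per
#' window, and diabetes duration is missing for a small fraction at baseline.
#'
#' @param trial A complete `trial_data` from [generate_trial()].
#' @param config Optional `trial_config` whose missingness settings override
#'   the one echoed in `trial`.
#' @return The `trial_data` with `NA` markers set and
#'   `missingness_imposed = TRUE`.
#' @export
impose_missingness <- function(trial, config = trial$config) {
  stopifnot(inherits(trial, "trial_data"))
  mc <- config$missingness
  rates <- c(mc$q3, mc$q12, mc$nurse_section, mc$duration)
  if (any(rates < 0 | rates > 1)) abort("missingness rates must lie in [0, 1]")
  set.seed(config$seed + 104729L)  # distinct stream from generation

  p <- trial$participants
  n <- nrow(p)
  arm_idx <- ifelse(p$arm == "intervention", 1L, 2L)
  paid0 <- rowSums(p[, sprintf("paid_q%02d_0", 1:20)]) * 1.25
  z <- if (sd(paid0) > 0) as.numeric(scale(paid0)) else rep(0, n)

  # per-arm logistic non-response with intercept calibrated to the marginal
  miss_prob <- function(rate, gamma, zz) {
    if (rate <= 0) return(rep(0, length(zz)))
    if (rate >= 1) return(rep(1, length(zz)))
    if (!mc$mar || gamma == 0) return(rep(rate, length(zz)))
    a <- uniroot(function(a) mean(plogis(a + gamma * zz)) - rate,
                 interval = c(-20, 20))$root
    plogis(a + gamma * zz)
  }

  m3 <- m12 <- logical(n)
  for (a in 1:2) {
    ii <- which(arm_idx == a)
    p3 <- miss_prob(mc$q3[a], mc$mar_gamma, z[ii])
    m3[ii] <- runif(length(ii)) < p3
    # split the 12-month marginal between prior non-responders and responders
    r12 <- mc$q12[a]
    p_g_miss <- mc$q12_given_q3_missing
    p_g_obs <- pmax(0, pmin(1, (r12 - p_g_miss * mc$q3[a]) / (1 - mc$q3[a])))
    p12 <- ifelse(m3[ii], p_g_miss,
                  miss_prob(p_g_obs, mc$mar_gamma, z[ii]))
    m12[ii] <- runif(length(ii)) < p12
  }

  blank_questionnaire <- function(p, tp, miss) {
    cols <- c(paste0("eq_", c("mo", "sc", "ua", "pd", "ad"), "_", tp),
              sprintf("paid_q%02d_%s", 1:20, tp), paste0("month_", tp))
    for (cl in cols) p[[cl]][miss] <- NA
    p
  }
  p <- blank_questionnaire(p, "3", m3)
  p <- blank_questionnaire(p, "12", m12)
  p$diabetes_duration[runif(n) < mc$duration] <- NA

  # self-report service sections travel with their questionnaire
  su <- trial$service_use
  key_miss <- tibble::tibble(
    id = rep(p$id, 2L),
    window = rep(c("m0_3", "m3_12"), each = n),
    q_missing = c(m3, m12)
  )
  su <- su |>
    dplyr::left_join(key_miss, by = c("id", "window")) |>
    dplyr::mutate(count = ifelse(.data$section == "self_report" &
                                   !is.na(.data$q_missing) & .data$q_missing,
                                 NA_integer_, .data$count)) |>
    dplyr::select(-"q_missing")

  # nurse-recorded sections: independent section-level missingness
  nurse_miss <- tibble::tibble(
    id = rep(p$id, 3L),
    window = rep(c("pre", "m0_3", "m3_12"), each = n),
    svc_missing = runif(3L * n) < mc$nurse_section,
    presc_missing = runif(3L * n) < mc$nurse_section
  )
  su <- su |>
    dplyr::left_join(nurse_miss[, c("id", "window", "svc_missing")],
                     by = c("id", "window")) |>
    dplyr::mutate(count = ifelse(.data$section == "nurse_services" &
                                   .data$svc_missing, NA_integer_, .data$count)) |>
    dplyr::select(-"svc_missing")
  ps <- trial$prescription_status |>
    dplyr::left_join(prescription_windows()[, c("timepoint", "window")],
                     by = "timepoint") |>
    dplyr::left_join(nurse_miss[, c("id", "window", "presc_missing")],
                     by = c("id", "window")) |>
    dplyr::mutate(presc_status = ifelse(.data$presc_missing, "missing",
                                        .data$presc_status)) |>
    dplyr::select("id", "timepoint", "presc_status")

  trial$participants <- p
  trial$service_use <- su
  trial$prescription_status <- ps
  trial$missingness_imposed <- TRUE
  trial$missingness_mechanism <- if (mc$mar) "MAR (depends on baseline distress only)" else "MCAR"
  trial
}

#' Write a generated trial to a wide CSV with a JSON metadata sidecar
#'
#' One row per participant; service-use counts and monthly prescription
#' totals are spread to columns; missing values are written as empty cells.
#' The sidecar records the config echo and every seed used.
#'
#' @param trial A `trial_data`.
#' @param path Output CSV path; the sidecar is written to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  svc_wide <- trial$service_use |>
    dplyr::mutate(var = paste0("svc_", .data$window, "_", .data$service_type)) |>
    dplyr::select("id", "var", "count") |>
    tidyr::pivot_wider(names_from = "var", values_from = "count")
  presc_tot <- trial$prescription_items |>
    dplyr::group_by(.data$id, .data$timepoint) |>
    dplyr::summarise(monthly = sum(.data$monthly_cost), .groups = "drop")
  presc_wide <- trial$prescription_status |>
    dplyr::left_join(presc_tot, by = c("id", "timepoint")) |>
    dplyr::mutate(
      monthly = dplyr::case_when(
        presc_status == "missing" ~ NA_real_,
        presc_status == "none" ~ 0,
        is.na(monthly) ~ 0,
        TRUE ~ monthly
      )
    ) |>
    tidyr::pivot_wider(
      names_from = "timepoint",
      values_from = c("presc_status", "monthly"),
      names_glue = "presc_{.value}_{timepoint}"
    )
  wide <- trial$participants |>
    dplyr::left_join(svc_wide, by = "id") |>
    dplyr::left_join(presc_wide, by = "id")
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(
      generator = "trialcea synthetic_trial",
      version = as.character(utils::packageVersion("trialcea")),
      seeds = trial$seeds,
      missingness_imposed = trial$missingness_imposed,
      n = nrow(trial$participants),
      config = unclass(trial$config)
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Simulate a trial end to end (generate, impose missingness, write)
#'
#' @param config A [trial_config()].
#' @param path Optional CSV output path (with JSON sidecar).
#' @param missingness Impose the configured missingness (default `TRUE`).
#' @return The `trial_data`, invisibly if `path` is given.
#' @export
simulate_trial <- function(config = trial_config(), path = NULL,
                           missingness = TRUE) {
  trial <- generate_trial(config)
  if (missingness) trial <- impose_missingness(trial)
  if (!is.null(path)) {
    write_trial_csv(trial, path)
    return(invisible(trial))
  }
  trial
}
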