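#' Derive per-participant economic endpoints on a completed dataset
#'
#' Adds `qaly` (trapezoidal area under the utility curve), `total_cost`
#' (health-service costs over the trial year plus the per-participant
#' intervention cost in the intervention arm) and `cost_baseline` to a
#' completed (no-missing) analysis table.
#'
#' @param data Completed analysis table (one imputation copy, or complete
#'   cases).
#' @param cost_model An [intervention_cost_model()]; the per-participant
#'   intervention cost is evaluated at `cost_model$trial_n` users.
#' @param rounding Component rounding mode passed to
#'   [intervention_cost_per_user()].
#' @return The table with `qaly`, `intervention_cost`, `total_cost` added.
#' @export
derive_endpoints <- function(data, cost_model = default_cost_model(),
                             rounding = c("rounded", "unrounded")) {
  rounding <- match.arg(rounding)
  pp <- intervention_cost_per_user(cost_model, cost_model$trial_n,
                                   rounding)$cost_per_user
  healthcare <- with(data, cost_nurse_m0_3 + cost_presc_m0_3 + cost_self_m0_3 +
                       cost_nurse_m3_12 + cost_presc_m3_12 + cost_self_m3_12)
  data |>
    dplyr::mutate(
      qaly = qaly_auc(.data$eq5d_0, .data$eq5d_3, .data$eq5d_12),
      cost_baseline = .data$cost_nurse_pre + .data$cost_presc_pre +
        .data$cost_self_pre,
      intervention_cost = ifelse(.data$arm == "intervention", pp, 0),
      total_cost = healthcare + .data$intervention_cost
    )
}

#' Baseline-adjusted incremental estimate from one completed dataset
#'
#' Fits a linear mixed model with the 12-month endpoint as dependent
#' variable, fixed effects for randomized group, age, sex, cardiovascular
#' history, smoking, diabetes duration and the corresponding baseline
#' endpoint, and a random intercept per recruitment centre. No interaction
#' or time-dependent terms. If the random-intercept fit is singular (zero
#' estimated centre variance) or fails, the model falls back to a
#' fixed-intercept least-squares fit with a warning; in that degenerate case
#' the two estimators coincide.
#'
#' @param data Completed dataset with `arm`, `center`, covariates, `outcome`
#'   and `baseline` columns present.
#' @param outcome,baseline Column names of the endpoint and its baseline
#'   counterpart (e.g. `"total_cost"`/`"cost_baseline"`, `"qaly"`/`"eq5d_0"`,
#'   `"paid_12"`/`"paid_0"`).
#' @param quiet Suppress the singular-fit warning (used inside resampling
#'   loops).
#' @return A list with `estimate` (intervention minus control), `variance`,
#'   `se`, and `method` (`"lmm"` or `"ols"`).
#' @export
fit_adjusted_difference <- function(data, outcome, baseline, quiet = FALSE) {
  stopifnot(all(c("arm", "center", outcome, baseline) %in% names(data)))
  if (length(unique(data$center)) < 2L) {
    abort("at least 2 centres are required for the adjusted analysis")
  }
  covs <- c("age", "sex", "cvd_history", "smoking", "diabetes_duration")
  fml <- as.formula(paste(
    outcome, "~ arm +", paste(covs, collapse = " + "), "+", baseline,
    "+ (1 | center)"
  ))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    if (!quiet) {
      warn("singular random-centre fit; falling back to fixed-intercept model")
    }
    ols <- lm(as.formula(paste(
      outcome, "~ arm +", paste(covs, collapse = " + "), "+", baseline
    )), data = data)
    est <- coef(ols)[["armintervention"]]
    v <- vcov(ols)["armintervention", "armintervention"]
    return(list(estimate = est, variance = v, se = sqrt(v), method = "ols"))
  }
  est <- lme4::fixef(fit)[["armintervention"]]
  v <- as.matrix(vcov(fit))["armintervention", "armintervention"]
  list(estimate = est, variance = v, se = sqrt(v), method = "lmm")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point = mean of the per-imputation estimates; total variance =
#' mean within-imputation variance + (1 + 1/m) x between-imputation
#' variance; the confidence interval uses the t reference with the standard
#' multiple-imputation degrees of freedom.
#'
#' @param estimates,variances Numeric vectors of length m.
#' @param conf_level Confidence level (0.95).
#' @return Tibble with `estimate`, `se`, `conf_low`, `conf_high`, `m`, `df`,
#'   and the variance components.
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 1L) abort("at least one imputation is required")
  stopifnot(length(variances) == m)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- if (m > 1L) var(estimates) else 0
  total <- ubar + (1 + 1 / m) * b
  df <- if (m > 1L && b > 0) {
    (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2
  } else {
    Inf
  }
  half <- qt(1 - (1 - conf_level) / 2, df) * sqrt(total)
  tibble::tibble(
    estimate = qbar, se = sqrt(total),
    conf_low = qbar - half, conf_high = qbar + half,
    m = m, df = df, within = ubar, between = b
  )
}

#' Incremental cost-effectiveness ratio
#'
#' Ratio of incremental cost to incremental effect, with the plane quadrant
#' reported alongside, since a bare negative ratio is ambiguous (it can mean
#' dominance or domination).
#'
#' @param delta_cost,delta_effect Incremental cost (GBP) and effect.
#' @return Tibble with `icer`, `quadrant` (`NE`/`SE`/`NW`/`SW`),
#'   `interpretation`, and `defined` (`FALSE` when the effect difference is
#'   exactly zero, in which case `icer` is `NA`).
#' @examples
#' icer(111, 0.020)  # 5550 GBP per QALY, NE quadrant
#' @export
icer <- function(delta_cost, delta_effect) {
  quad <- dplyr::case_when(
    delta_effect > 0 & delta_cost > 0 ~ "NE",
    delta_effect > 0 & delta_cost <= 0 ~ "SE",
    delta_effect <= 0 & delta_cost > 0 ~ "NW",
    TRUE ~ "SW"
  )
  interp <- c(
    NE = "more effective, costlier (ratio vs willingness to pay)",
    SE = "dominant: more effective, less costly",
    NW = "dominated: less effective, costlier",
    SW = "less effective, less costly"
  )[quad]
  tibble::tibble(
    delta_cost = delta_cost, delta_effect = delta_effect,
    icer = ifelse(delta_effect == 0, NA_real_, delta_cost / delta_effect),
    quadrant = quad, interpretation = unname(interp),
    defined = delta_effect != 0
  )
}

#' Analyze an imputed (or complete) dataset: pooled adjusted incrementals
#'
#' For each imputation copy, derives the endpoints, fits the three adjusted
#' models (total cost, QALY, 12-month PAID), then pools by Rubin's rules and
#' forms the ICERs from the pooled incrementals.
#'
#' @param imputed An `imputed_data` (long, `.imp` column) or a single
#'   completed analysis table.
#' @param cost_model An [intervention_cost_model()].
#' @param rounding Component rounding mode for the intervention cost.
#' @param quiet Suppress singular-fit warnings.
#' @return A list of class `cea_fit`: `incrementals` (tibble, one row per
#'   endpoint), `icers` (tibble), `m`, `methods` used.
#' @export
analyze_imputed <- function(imputed, cost_model = default_cost_model(),
                            rounding = "rounded", quiet = FALSE) {
  if (!".imp" %in% names(imputed)) imputed$.imp <- 1L
  specs <- list(
    cost = c(outcome = "total_cost", baseline = "cost_baseline"),
    qaly = c(outcome = "qaly", baseline = "eq5d_0"),
    paid = c(outcome = "paid_12", baseline = "paid_0")
  )
  copies <- split(tibble::as_tibble(imputed), imputed$.imp)
  fits <- purrr::map(copies, function(cp) {
    cp <- derive_endpoints(cp, cost_model, rounding)
    purrr::map(specs, function(s) {
      fit_adjusted_difference(cp, s[["outcome"]], s[["baseline"]],
                              quiet = quiet)
    })
  })
  pooled <- purrr::imap(specs, function(s, nm) {
    est <- vapply(fits, function(f) f[[nm]]$estimate, numeric(1))
    v <- vapply(fits, function(f) f[[nm]]$variance, numeric(1))
    pool_rubin(est, v)
  })
  incrementals <- dplyr::bind_rows(pooled, .id = "endpoint")
  ic <- dplyr::bind_rows(
    qaly = icer(incrementals$estimate[incrementals$endpoint == "cost"],
                incrementals$estimate[incrementals$endpoint == "qaly"]),
    paid = icer(incrementals$estimate[incrementals$endpoint == "cost"],
                -incrementals$estimate[incrementals$endpoint == "paid"]),
    .id = "effect"
  )
  structure(
    list(incrementals = incrementals, icers = ic,
         m = length(copies),
         methods = vapply(fits[[1]], function(f) f$method, character(1))),
    class = "cea_fit"
  )
}

#' Nonparametric bootstrap of paired incremental cost and effects
#'
#' Resamples participants with replacement, stratified by randomized group,
#' from the original (possibly incomplete) analysis table. Each replicate is
#' singly imputed (a fresh stochastic chained-equation PMM pass) and the
#' three adjusted models are fitted, yielding one paired
#' (delta cost, delta QALY, delta PAID) draw; pairing is preserved because
#' cost and effects come from the same resample. Ordinary least squares
#' (`use_lmm = FALSE`, the default here) keeps large replicate counts
#' tractable; with zero centre variance the two estimators coincide.
#'
#' @param data Analysis table (incomplete allowed).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; the cloud is reproducible given (seed, B).
#' @param cost_model,rounding Passed to [derive_endpoints()].
#' @param imp_spec [imputation_spec()] used per replicate (its `m` is forced
#'   to 1); when `data` is already complete the imputation pass is skipped.
#' @param use_lmm Fit random-centre models per replicate (slower).
#' @return A tibble of class `boot_cloud` with columns `replicate`,
#'   `delta_cost`, `delta_qaly`, `delta_paid`; attributes `B` and `seed`.
#' @export
bootstrap_cloud <- function(data, B = 5000L, seed = 1L,
                            cost_model = default_cost_model(),
                            rounding = "rounded",
                            imp_spec = imputation_spec(cycles = 5L),
                            use_lmm = FALSE) {
  if (B < 1L) abort("B must be at least 1")
  vars <- intersect(c(imputable_variables(),
                      imputation_covariates()), names(data))
  needs_imp <- anyNA(data[, vars])
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, B)
  by_arm <- split(seq_len(nrow(data)), data$arm)
  specs <- list(
    cost = c("total_cost", "cost_baseline"),
    qaly = c("qaly", "eq5d_0"),
    paid = c("paid_12", "paid_0")
  )
  one_rep <- function(b) {
    set.seed(rep_seeds[b])
    idx <- unlist(lapply(by_arm, function(ii) sample(ii, length(ii),
                                                     replace = TRUE)))
    d <- data[idx, ]
    d$id <- seq_len(nrow(d))
    if (needs_imp) {
      sp <- imp_spec
      sp$m <- 1L
      sp$seed <- rep_seeds[b]
      d <- tibble::as_tibble(mice_pmm(d, sp))
      d$.imp <- NULL
    }
    d <- derive_endpoints(d, cost_model, rounding)
    ests <- vapply(specs, function(s) {
      if (use_lmm) {
        fit_adjusted_difference(d, s[1], s[2], quiet = TRUE)$estimate
      } else {
        covs <- c("age", "sex", "cvd_history", "smoking", "diabetes_duration")
        fml <- as.formula(paste(s[1], "~ arm +",
                                paste(covs, collapse = " + "), "+", s[2]))
        coef(lm(fml, data = d))[["armintervention"]]
      }
    }, numeric(1))
    c(delta_cost = ests[["cost"]], delta_qaly = ests[["qaly"]],
      delta_paid = ests[["paid"]])
  }
  mat <- t(vapply(seq_len(B), one_rep, numeric(3)))
  out <- tibble::tibble(
    replicate = seq_len(B),
    delta_cost = mat[, "delta_cost"],
    delta_qaly = mat[, "delta_qaly"],
    delta_paid = mat[, "delta_paid"]
  )
  attr(out, "B") <- B
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("boot_cloud", class(out))
  out
}

#' Quadrant summary of a cost-effectiveness plane cloud
#'
#' Proportions of replicates in each quadrant of the (delta effect, delta
#' cost) plane. Boundary convention: a replicate with delta effect exactly 0
#' counts to the "not more effective" (west) side, and delta cost exactly 0
#' to the "not costlier" (south) side; under continuous data these are
#' measure-zero.
#'
#' @param cloud A `boot_cloud` (or any tibble with `delta_cost` and an
#'   effect column).
#' @param effect Which effect axis: `"qaly"` or `"paid"` (PAID improvements
#'   are sign-flipped so that east always means more effective).
#' @return Tibble with quadrant, n and proportion (summing to 1).
#' @export
ce_plane_summary <- function(cloud, effect = c("qaly", "paid")) {
  effect <- match.arg(effect)
  de <- if (effect == "qaly") cloud$delta_qaly else -cloud$delta_paid
  dc <- cloud$delta_cost
  quad <- dplyr::case_when(
    de > 0 & dc > 0 ~ "NE",
    de > 0 & dc <= 0 ~ "SE",
    de <= 0 & dc > 0 ~ "NW",
    TRUE ~ "SW"
  )
  tibble::tibble(quadrant = c("NE", "SE", "NW", "SW")) |>
    dplyr::left_join(
      tibble::tibble(quadrant = quad) |> dplyr::count(.data$quadrant),
      by = "quadrant"
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  proportion = .data$n / length(de))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of bootstrap replicates with positive net monetary
#' benefit, `wtp x delta effect - delta cost > 0`. At `wtp = 0` this is the
#' fraction of cost-saving replicates; as `wtp` grows it approaches the
#' fraction of effect-positive replicates. The curve is defined for the QALY
#' effect; there is no accepted willingness-to-pay scale per PAID unit, so a
#' PAID CEAC is reported as unavailable.
#'
#' @param cloud A `boot_cloud`.
#' @param wtp_grid Willingness-to-pay values (GBP per QALY), all >= 0;
#'   default 0 to 50,000 in steps of 500 (which includes the conventional
#'   20,000 and 30,000 thresholds).
#' @param effect Only `"qaly"` is supported.
#' @return A tibble of class `ceac_curve` with `wtp` and `probability`.
#' @export
ceac <- function(cloud, wtp_grid = seq(0, 50000, by = 500),
                 effect = "qaly") {
  if (!identical(effect, "qaly")) {
    abort(paste0("CEAC is only defined for the QALY effect: there is no ",
                 "accepted willingness-to-pay threshold per PAID unit"))
  }
  if (nrow(cloud) == 0L) abort("empty bootstrap cloud")
  if (any(wtp_grid < 0)) abort("willingness-to-pay values must be >= 0")
  prob <- vapply(wtp_grid, function(lambda) {
    mean(lambda * cloud$delta_qaly - cloud$delta_cost > 0)
  }, numeric(1))
  out <- tibble::tibble(wtp = wtp_grid, probability = prob)
  class(out) <- c("ceac_curve", class(out))
  out
}
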