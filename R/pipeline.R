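#' Run the full within-trial cost-effectiveness analysis
#'
#' Orchestrates the pipeline on a participant-level trial dataset: costing
#' and outcome scoring ([build_analysis_table()]), multiple imputation
#' ([mice_pmm()]), pooled adjusted incrementals and ICERs
#' ([analyze_imputed()]), bootstrap uncertainty ([bootstrap_cloud()]),
#' CE-plane quadrants and the acceptability curve ([ceac()]). Every seed and
#' stage row count is recorded in the returned object, and identical inputs
#' with identical seeds reproduce the result exactly.
#'
#' @param trial A `trial_data` object, or an analysis table already built.
#' @param m Number of imputations (default 30).
#' @param B Bootstrap replicates (default 5000; set lower for quick runs,
#'   `0` to skip the bootstrap).
#' @param seed Integer seed driving imputation and bootstrap.
#' @param cost_model An [intervention_cost_model()].
#' @param rounding Intervention-cost component rounding mode.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param analysis `"primary"` (multiple imputation) or `"complete_case"`.
#' @param unit_costs,value_set Passed to [build_analysis_table()] when
#'   `trial` is a `trial_data`.
#' @param quiet Suppress singular-fit warnings.
#' @return A list of class `cea_result`: `fit` (the pooled `cea_fit`),
#'   `cloud`, `plane`, `ceac`, `counts`, `seeds`, and the call settings.
#' @export
run_cea <- function(trial, m = 30L, B = 5000L, seed = 1L,
                    cost_model = default_cost_model(),
                    rounding = "rounded",
                    wtp_grid = seq(0, 50000, by = 500),
                    analysis = c("primary", "complete_case"),
                    unit_costs = unit_cost_table(),
                    value_set = eq5d_value_set(),
                    quiet = TRUE) {
  analysis <- match.arg(analysis)
  tab <- if (inherits(trial, "trial_data")) {
    build_analysis_table(trial, unit_costs, value_set)
  } else {
    trial
  }
  counts <- list(participants = nrow(tab),
                 centers = length(unique(tab$center)),
                 per_arm = table(tab$arm))
  wtp_grid <- sort(unique(c(wtp_grid, 20000, 30000)))

  if (analysis == "complete_case") {
    fit <- run_cca_analysis(tab, cost_model, rounding, quiet = quiet)
    base <- cca_filter(tab)
  } else {
    spec <- imputation_spec(m = m, seed = seed)
    imputed <- mice_pmm(tab, spec)
    fit <- analyze_imputed(imputed, cost_model, rounding, quiet = quiet)
    fit$analysis <- "multiple_imputation"
    base <- tab
  }

  cloud <- plane <- curve <- NULL
  if (B > 0L) {
    cloud <- bootstrap_cloud(base, B = B, seed = seed + 1L,
                             cost_model = cost_model, rounding = rounding)
    plane <- ce_plane_summary(cloud)
    curve <- ceac(cloud, wtp_grid)
  }
  structure(
    list(fit = fit, cloud = cloud, plane = plane, ceac = curve,
         counts = counts,
         seeds = list(seed = seed, imputation = seed, bootstrap = seed + 1L),
         settings = list(m = m, B = B, rounding = rounding,
                         analysis = analysis)),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Within-trial cost-effectiveness analysis (",
      x$settings$analysis, ")\n", sep = "")
  cat("  participants:", x$counts$participants,
      "in", x$counts$centers, "centres\n")
  cat("  imputations m =", x$fit$m, "; bootstrap B =",
      if (is.null(x$cloud)) 0 else attr(x$cloud, "B"), "\n\n")
  cat("Adjusted incremental estimates (intervention - control):\n")
  print(as.data.frame(x$fit$incrementals[, c("endpoint", "estimate", "se",
                                             "conf_low", "conf_high")]),
        row.names = FALSE, digits = 4)
  cat("\nICERs:\n")
  print(as.data.frame(x$fit$icers[, c("effect", "icer", "quadrant")]),
        row.names = FALSE, digits = 5)
  if (!is.null(x$ceac)) {
    p20 <- x$ceac$probability[x$ceac$wtp == 20000]
    p30 <- x$ceac$probability[x$ceac$wtp == 30000]
    cat(sprintf("\nP(cost-effective): %.0f%% at 20,000/QALY; %.0f%% at 30,000/QALY\n",
                100 * p20, 100 * p30))
  }
  invisible(x)
}

#' Bivariate-normal synthetic bootstrap cloud
#'
#' Builds a `boot_cloud` directly from first and second moments of the
#' incremental (cost, QALY) distribution, without any trial data. Useful for
#' closed-form cross-checks of the CE-plane and CEAC machinery: for a
#' bivariate normal cloud the CEAC has the closed form
#' `P(wtp x dE - dC > 0) = pnorm((wtp mu_E - mu_C) / sd(wtp dE - dC))`.
#'
#' @param n Number of replicates.
#' @param mean_cost,mean_qaly Means of the incremental cost and QALY.
#' @param sd_cost,sd_qaly Standard deviations.
#' @param correlation Correlation between the two (default 0).
#' @param seed Integer seed.
#' @return A `boot_cloud` tibble.
#' @export
normal_cloud <- function(n, mean_cost, mean_qaly, sd_cost, sd_qaly,
                         correlation = 0, seed = 1L) {
  set.seed(as.integer(seed))
  z1 <- rnorm(n)
  z2 <- correlation * z1 + sqrt(1 - correlation^2) * rnorm(n)
  out <- tibble::tibble(
    replicate = seq_len(n),
    delta_cost = mean_cost + sd_cost * z1,
    delta_qaly = mean_qaly + sd_qaly * z2,
    delta_paid = rep(NA_real_, n)
  )
  attr(out, "B") <- n
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("boot_cloud", class(out))
  out
}

#' Closed-form CEAC for a bivariate-normal incremental distribution
#'
#' @param wtp Willingness-to-pay values.
#' @inheritParams normal_cloud
#' @return Numeric vector of probabilities.
#' @export
ceac_normal <- function(wtp, mean_cost, mean_qaly, sd_cost, sd_qaly,
                        correlation = 0) {
  vapply(wtp, function(l) {
    mu <- l * mean_qaly - mean_cost
    s <- sqrt(l^2 * sd_qaly^2 + sd_cost^2 - 2 * l * correlation * sd_qaly * sd_cost)
    if (s == 0) as.numeric(mu > 0) else pnorm(mu / s)
  }, numeric(1))
}
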