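#' Specification for chained-equation predictive-mean-matching imputation
#'
#' @param m Number of imputed datasets (default 30, chosen to match the
#'   rule of thumb that the imputation count should be at least the
#'   percentage of missing information, here bounded by 30%).
#' @param k_donors Donor-pool size for predictive mean matching (5).
#' @param variables Aggregated variables to impute, in any order; the visit
#'   order used is ascending missingness.
#' @param covariates Complete baseline covariates entering every prediction
#'   model.
#' @param aux Auxiliary predictor columns (mean-filled, never imputed), e.g.
#'   out-of-window 12-month measurements.
#' @param by_arm Impute separately by randomized group (default `TRUE`).
#' @param cycles Chained-equation cycles per imputation (10).
#' @param seed Integer seed.
#' @return A list of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 30L, k_donors = 5L,
                            variables = imputable_variables(),
                            covariates = imputation_covariates(),
                            aux = c("eq5d_12_aux", "paid_12_aux"),
                            by_arm = TRUE, cycles = 10L, seed = 1L) {
  if (m < 1L) abort("m must be at least 1")
  if (k_donors < 1L) abort("k_donors must be at least 1")
  structure(
    list(m = as.integer(m), k_donors = as.integer(k_donors),
         variables = variables, covariates = covariates, aux = aux,
         by_arm = isTRUE(by_arm), cycles = as.integer(cycles),
         seed = as.integer(seed)),
    class = "imputation_spec"
  )
}

# Least-squares fit with a posterior parameter draw, tolerating rank
# deficiency. Observed cases are predicted with the ML coefficients; missing
# cases with coefficients drawn from their posterior (sigma^2 from the
# scaled inverse-chi-square, beta | sigma^2 normal), which propagates
# estimation uncertainty into the between-imputation variance.
ls_predict_draw <- function(X, y, newX) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  ok <- !is.na(beta)
  beta[!ok] <- 0
  df <- max(1L, length(y) - fit$rank)
  ssr <- sum(fit$residuals^2)
  sigma2_star <- ssr / stats::rchisq(1L, df)
  beta_star <- beta
  R <- tryCatch(chol(crossprod(X[, ok, drop = FALSE]) +
                       diag(1e-10, sum(ok))),
                error = function(e) NULL)
  if (!is.null(R)) {
    beta_star[ok] <- beta[ok] +
      backsolve(R, rnorm(sum(ok))) * sqrt(sigma2_star)
  }
  list(pred_obs = drop(X %*% beta), pred_mis = drop(newX %*% beta_star))
}

# one chained-equation pass over a single arm's data, in place
pmm_chain <- function(dat, pred_cols, k_donors, cycles, miss_idx) {
  ord <- names(sort(vapply(miss_idx, length, integer(1))))
  for (cyc in seq_len(cycles)) {
    for (v in ord) {
      mis <- miss_idx[[v]]
      if (length(mis) == 0L) next
      obs <- setdiff(seq_len(nrow(dat)), mis)
      rhs <- setdiff(pred_cols, v)
      X <- cbind(1, as.matrix(dat[obs, rhs]))
      newX <- cbind(1, as.matrix(dat[mis, rhs, drop = FALSE]))
      pr <- ls_predict_draw(X, dat[[v]][obs], newX)
      pred_obs <- pr$pred_obs
      pred_mis <- pr$pred_mis
      yobs <- dat[[v]][obs]
      k <- min(k_donors, length(obs))
      dat[[v]][mis] <- vapply(pred_mis, function(pm) {
        d <- abs(pred_obs - pm)
        # seeded uniform jitter breaks donor-distance ties
        donors <- order(d + runif(length(d)) * 1e-9)[seq_len(k)]
        yobs[donors[sample.int(k, 1L)]]
      }, numeric(1))
    }
  }
  dat
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Missing aggregated variables (section costs, PAID totals, utilities,
#' diabetes duration) are imputed separately by randomized group. Each
#' variable is regressed on all other aggregated variables, the complete
#' baseline covariates and any auxiliary predictors; each missing cell is
#' filled with the observed value of a donor drawn at random from the
#' `k_donors` observed cases whose predicted means lie nearest the predicted
#' mean of the missing case. Imputed values therefore always lie in the
#' observed support of the same arm. Variables are visited in order of
#' ascending missingness; initial fills are random draws from the observed
#' values.
#'
#' @param data Analysis table from [build_analysis_table()] (must contain an
#'   `arm` column when `spec$by_arm`).
#' @param spec An [imputation_spec()].
#' @return An object of class `imputed_data`: a long tibble with an `.imp`
#'   column (1..m), observed cells identical across copies; the spec and the
#'   per-copy seeds are attached as attributes.
#' @export
mice_pmm <- function(data, spec = imputation_spec()) {
  stopifnot(is.data.frame(data), inherits(spec, "imputation_spec"))
  vars <- intersect(spec$variables, names(data))
  covs <- intersect(spec$covariates, names(data))
  aux <- intersect(spec$aux, names(data))
  groups <- if (spec$by_arm) split(seq_len(nrow(data)), data$arm) else
    list(all = seq_len(nrow(data)))

  # pre-flight: enough complete donors per variable per arm
  for (g in names(groups)) {
    for (v in vars) {
      n_obs <- sum(!is.na(data[[v]][groups[[g]]]))
      if (n_obs < spec$k_donors) {
        abort(paste0("too few observed values of '", v, "' in arm '", g,
                     "' (", n_obs, " < k_donors = ", spec$k_donors, ")"))
      }
    }
  }

  set.seed(spec$seed)
  copy_seeds <- sample.int(.Machine$integer.max, spec$m)
  copies <- vector("list", spec$m)
  for (im in seq_len(spec$m)) {
    set.seed(copy_seeds[im])
    filled <- data
    # auxiliary predictors: mean-fill within arm, never imputed
    for (a in aux) {
      for (g in names(groups)) {
        ii <- groups[[g]]
        mu <- mean(filled[[a]][ii], na.rm = TRUE)
        if (is.nan(mu)) mu <- 0
        filled[[a]][ii][is.na(filled[[a]][ii])] <- mu
      }
    }
    for (g in names(groups)) {
      ii <- groups[[g]]
      sub <- filled[ii, c(vars, covs, aux)]
      miss_idx <- lapply(stats::setNames(vars, vars),
                         function(v) which(is.na(sub[[v]])))
      for (v in vars) {       # random initial fill from observed values
        mis <- miss_idx[[v]]
        if (length(mis) > 0L) {
          obs_vals <- sub[[v]][!is.na(sub[[v]])]
          sub[[v]][mis] <- sample(obs_vals, length(mis), replace = TRUE)
        }
      }
      sub <- pmm_chain(sub, c(vars, covs, aux), spec$k_donors,
                       spec$cycles, miss_idx)
      for (v in vars) filled[[v]][ii] <- sub[[v]]
    }
    filled$.imp <- im
    copies[[im]] <- filled
  }
  out <- dplyr::bind_rows(copies)
  attr(out, "spec") <- spec
  attr(out, "copy_seeds") <- copy_seeds
  class(out) <- c("imputed_data", class(out))
  out
}

#' Complete-case filter
#'
#' Retains exactly the rows with no missing value in any required variable
#' and reports per-arm retention.
#'
#' @param data Analysis table.
#' @param required Character vector of required variable names; defaults to
#'   the full set needed for the adjusted analysis (baseline covariates,
#'   all section costs, both health outcomes at all timepoints).
#' @return The retained subset, with a `retention` attribute (tibble of
#'   per-arm n, retained and fraction).
#' @export
cca_filter <- function(data,
                       required = c(imputation_covariates(),
                                    imputable_variables())) {
  stopifnot(all(required %in% names(data)))
  keep <- complete.cases(data[, required])
  retained <- data[keep, ]
  if ("arm" %in% names(data)) {
    ret <- data |>
      dplyr::mutate(.keep_row = keep) |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(n = dplyr::n(), retained = sum(.data$.keep_row),
                       fraction = mean(.data$.keep_row), .groups = "drop")
  } else {
    ret <- tibble::tibble(arm = "all", n = nrow(data), retained = sum(keep),
                          fraction = mean(keep))
  }
  attr(retained, "retention") <- ret
  retained
}
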