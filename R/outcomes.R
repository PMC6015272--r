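#' Score the Problem Areas in Diabetes (PAID) questionnaire
#'
#' The 20 items are each scored 0-4; the raw 0-80 sum is rescaled by 1.25
#' onto a 0-100 scale. Lower scores mean less diabetes-related distress; a
#' score of 40 or more indicates significant distress.
#'
#' @param items Numeric vector of the 20 item responses (each in 0:4), or a
#'   matrix/data frame with 20 columns, one row per respondent.
#' @return A tibble with `total` (0-100), `n_items`, and `significant_distress`
#'   (`total >= 40`).
#' @examples
#' paid_score(rep(0, 20))$total # 0
#' paid_score(rep(4, 20))$total # 100
#' @export
paid_score <- function(items) {
  m <- if (is.matrix(items) || is.data.frame(items)) {
    as.matrix(items)
  } else {
    matrix(as.numeric(items), nrow = 1L)
  }
  if (ncol(m) != 20L) {
    abort("PAID has exactly 20 items")
  }
  if (anyNA(m) || !all(m %in% 0:4)) {
    abort("PAID item responses must all be in {0, 1, 2, 3, 4}")
  }
  total <- rowSums(m) * 1.25
  tibble::tibble(
    total = unname(total),
    n_items = 20L,
    significant_distress = unname(total) >= 40
  )
}

#' QALYs over 12 months by area under the utility curve
#'
#' Trapezoidal area under the utility trajectory measured at 0, 3 and 12
#' months: 0.25 years x mean(u0, u3) + 0.75 years x mean(u3, u12). No
#' discounting is applied, the horizon being a single year.
#'
#' @param u0,u3,u12 Utilities at 0, 3 and 12 months (vectors recycle
#'   together). All must be present: imputation of missing utilities happens
#'   upstream of QALY computation, so a missing value here signals a
#'   pipeline-order violation and is an error.
#' @return Numeric QALY vector, bounded by the utility range.
#' @examples
#' qaly_auc(0.793, 0.811, 0.793) # 0.802
#' qaly_auc(1, 1, 1)             # 1
#' @export
qaly_auc <- function(u0, u3, u12) {
  n <- max(length(u0), length(u3), length(u12))
  u0 <- rep_len(u0, n); u3 <- rep_len(u3, n); u12 <- rep_len(u12, n)
  if (anyNA(u0) || anyNA(u3) || anyNA(u12)) {
    abort(paste0(
      "missing utility passed to qaly_auc(); utilities must be complete ",
      "(impute before computing QALYs)"
    ))
  }
  0.25 * (u0 + u3) / 2 + 0.75 * (u3 + u12) / 2
}

#' Flag 12-month outcomes collected outside the validity window
#'
#' Twelve-month PAID and EQ-5D responses collected outside the pre-specified
#' 10-14 month window (inclusive on both ends) are invalid as 12-month
#' outcomes, but are retained in the data so they can still serve as
#' auxiliary predictors during imputation.
#'
#' @param data A participant-level tibble containing `month_12` (months from
#'   randomization to the 12-month assessment; `NA` when the questionnaire
#'   was never returned).
#' @param window Closed validity interval in months, default `c(10, 14)`.
#' @return `data` with a logical `valid_12m` column (`NA` month -> `FALSE`)
#'   and, for each of `eq5d_12`/`paid_12` present, an `*_outcome` column equal
#'   to the original where valid and `NA` otherwise (the original column is
#'   kept for use as an imputation predictor).
#' @export
apply_validity_window <- function(data, window = c(10, 14)) {
  stopifnot(is.data.frame(data), "month_12" %in% names(data),
            length(window) == 2L, window[1] <= window[2])
  out <- dplyr::mutate(
    data,
    valid_12m = !is.na(.data$month_12) &
      .data$month_12 >= window[1] & .data$month_12 <= window[2]
  )
  for (v in intersect(c("eq5d_12", "paid_12"), names(out))) {
    out[[paste0(v, "_outcome")]] <- ifelse(out$valid_12m, out[[v]], NA_real_)
  }
  out
}
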