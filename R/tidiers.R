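#' Tidy a pooled cost-effectiveness fit
#'
#' @param x A `cea_fit` from [analyze_imputed()] or [run_cca_analysis()].
#' @param ... Unused.
#' @return A tibble with one row per endpoint: estimate, standard error,
#'   confidence bounds, imputation count and degrees of freedom.
#' @export
tidy.cea_fit <- function(x, ...) {
  x$incrementals
}

#' @rdname tidy.cea_fit
#' @export
glance.cea_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    analysis = if (is.null(x$analysis)) "multiple_imputation" else x$analysis,
    icer_qaly = x$icers$icer[x$icers$effect == "qaly"],
    icer_paid = x$icers$icer[x$icers$effect == "paid"]
  )
}

#' Tidy a full cost-effectiveness analysis result
#'
#' @param x A `cea_result` from [run_cea()].
#' @param ... Unused.
#' @return The pooled incrementals tibble (see [tidy.cea_fit()]).
#' @export
tidy.cea_result <- function(x, ...) tidy(x$fit)

#' @rdname tidy.cea_result
#' @export
glance.cea_result <- function(x, ...) {
  g <- glance(x$fit)
  if (!is.null(x$ceac)) {
    g$p_ce_20k <- x$ceac$probability[x$ceac$wtp == 20000]
    g$p_ce_30k <- x$ceac$probability[x$ceac$wtp == 30000]
  }
  g$B <- if (is.null(x$cloud)) 0L else attr(x$cloud, "B")
  g
}
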