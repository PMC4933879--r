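#' Tidy a darpkin fit
#'
#' Broom-style one-row-per-parameter summary of any fitted object in the
#' package (`titration_fit`, `monoexp_fit`, `kobs_line_fit`, `langmuir_fit`,
#' `plateau_fit`).
#'
#' @param x A `darpkin_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.darpkin_fit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(x$se[names(x$estimates)]))
}

#' Glance at a darpkin fit
#'
#' One-row model-level summary: estimates as columns plus fit diagnostics.
#'
#' @param x A `darpkin_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @exportS3Method generics::glance
glance.darpkin_fit <- function(x, ...) {
  est <- as.list(x$estimates)
  names(est) <- names(x$estimates)
  dplyr::bind_cols(
    as_tibble(est),
    tibble(residual_rms = x$residual_rms, n = x$n,
           converged = isTRUE(x$converged), cov_ok = isTRUE(x$cov_ok))
  )
}

#' @exportS3Method generics::glance
glance.titration_fit <- function(x, ...) {
  out <- glance.darpkin_fit(x)
  out$kd_nM <- to_nM(out$kd)
  out$saturation_warning <- isTRUE(x$saturation_warning)
  out
}

#' @exportS3Method generics::glance
glance.langmuir_fit <- function(x, ...) {
  out <- glance.darpkin_fit(x)
  out$kd <- x$kd_table$kd
  out$kd_nM <- to_nM(out$kd)
  out$koff_window_warning <- isTRUE(x$koff_window_warning)
  out
}

#' Human-readable rate-constant table
#'
#' Formats a [kd_from_rates()] row (or several) in conventional reporting
#' units: nM for dissociation constants, 1/s and 1/(M s) for rates.
#'
#' @param rates Tibble from [kd_from_rates()], optionally with a `variant`
#'   column.
#' @return Tibble with formatted columns.
#' @export
format_rate_table <- function(rates) {
  rates |>
    dplyr::mutate(
      k_off_per_s = sprintf("%.3g +/- %.2g", .data$k_off, .data$k_off_se),
      k_on_per_M_s = sprintf("%.3g +/- %.2g", .data$k_on, .data$k_on_se),
      kd_nM = sprintf("%.3g +/- %.2g", to_nM(.data$kd), to_nM(.data$kd_se))
    ) |>
    dplyr::select(dplyr::any_of("variant"), "k_off_per_s", "k_on_per_M_s",
                  "kd_nM")
}

#' Confidence intervals for darpkin fits
#'
#' Wald intervals on the asymptotic standard errors, using Student-t
#' quantiles at the fit's residual degrees of freedom — the appropriate
#' nominal interval for the small designs these experiments use (a k_obs
#' line has only a handful of concentrations).
#'
#' @param object A `darpkin_fit`.
#' @param parm Parameters to include (default all).
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `lower`, `upper`.
#' @exportS3Method stats::confint
confint.darpkin_fit <- function(object, parm = NULL, level = 0.95, ...) {
  terms <- parm %||% names(object$estimates)
  q <- stats::qt(1 - (1 - level) / 2, df = max(object$dof %||% Inf, 1))
  est <- object$estimates[terms]
  se <- object$se[terms]
  tibble(term = terms, estimate = unname(est),
         lower = unname(est - q * se), upper = unname(est + q * se))
}
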