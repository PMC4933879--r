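#' Classify a signal ratio into an affinity category
#'
#' Off-rate ELISA screens rank variants by the ratio of their signal to the
#' parent binder's signal under rebinding-trap (competitor) conditions. The
#' bands are: `low` for ratios below 2 (indistinguishable from the parent),
#' `medium` for 3- to 6-fold, `high` for 8-fold and above. The bands do not
#' tile the positive line; ratios falling in the gaps `[2, 3)` and `(6, 8)`
#' are reported as `indeterminate` rather than forced into a neighbour.
#'
#' @param ratio Numeric vector of signal ratios, >= 0.
#' @return Factor with levels `low`, `medium`, `high`, `indeterminate`.
#' @examples
#' classify_affinity(c(1, 2.5, 4, 7, 10))
#' @export
classify_affinity <- function(ratio) {
  if (!is.numeric(ratio) || anyNA(ratio) || any(!is.finite(ratio))) {
    abort("`ratio` must be finite and numeric")
  }
  if (any(ratio < 0)) abort("signal ratios cannot be negative")
  out <- dplyr::case_when(
    ratio < 2 ~ "low",
    ratio >= 3 & ratio <= 6 ~ "medium",
    ratio >= 8 ~ "high",
    TRUE ~ "indeterminate"
  )
  factor(out, levels = c("low", "medium", "high", "indeterminate"))
}

#' Rank an ELISA panel against its reference binder
#'
#' Computes, for every variant, the replicate mean and standard deviation of
#' the competitor-condition signal, its ratio to the reference variant's
#' mean, and the affinity category from [classify_affinity()]. Ratios under
#' the buffer condition (no rebinding trap), which differentiate binders far
#' less, are reported as auxiliary columns.
#'
#' @param panel Long data frame with columns `variant`, `condition`
#'   (`"buffer"` / `"competitor"`), `replicate`, `signal`, as produced by
#'   [sim_elisa_panel()] or [read_elisa_csv()].
#' @param reference Reference variant id; defaults to the `"reference"`
#'   attribute.
#' @return Tibble with one row per variant: `variant`, `mean_signal`,
#'   `sd_signal`, `ratio`, `category`, `buffer_ratio`; a summary count per
#'   category is attached as attribute `"category_counts"`.
#' @export
rank_panel <- function(panel, reference = attr(panel, "reference")) {
  needed <- c("variant", "condition", "signal")
  if (!all(needed %in% names(panel))) {
    abort("`panel` must contain columns variant, condition, replicate, signal")
  }
  if (is.null(reference)) abort("`reference` variant id is required")
  if (!reference %in% panel$variant) {
    abort(sprintf("reference variant '%s' not present in the panel", reference))
  }
  if (!"competitor" %in% panel$condition) {
    abort("competitor-condition signals are required for off-rate ranking")
  }
  stats_tbl <- panel |>
    dplyr::group_by(.data$variant, .data$condition) |>
    dplyr::summarise(mean_signal = mean(.data$signal),
                     sd_signal = sd(.data$signal), .groups = "drop")
  comp <- dplyr::filter(stats_tbl, .data$condition == "competitor")
  buff <- dplyr::filter(stats_tbl, .data$condition == "buffer")
  ref_sig <- comp$mean_signal[comp$variant == reference]
  if (ref_sig <= 0) abort("reference competitor-condition signal is zero")
  ref_buff <- if (nrow(buff)) buff$mean_signal[buff$variant == reference]
              else NA_real_
  out <- comp |>
    dplyr::transmute(.data$variant, .data$mean_signal, .data$sd_signal,
                     ratio = .data$mean_signal / ref_sig,
                     category = classify_affinity(.data$ratio)) |>
    dplyr::left_join(
      buff |> dplyr::transmute(.data$variant,
                               buffer_ratio = .data$mean_signal /
                                 (ref_buff %||% NA_real_)),
      by = "variant")
  attr(out, "reference") <- reference
  attr(out, "category_counts") <- table(out$category)
  out
}
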