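#' Diagnostic plot for a titration fit
#'
#' Measured signal changes against total ligand concentration (log scale)
#' with the fitted depletion isotherm overlaid.
#'
#' @param object A `titration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.titration_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(conc = exp(seq(log(max(min(d$conc[d$conc > 0]),
                                          1e-12)),
                                log(max(d$conc)), length.out = 200)))
  grid$dfluo <- isotherm_response(grid$conc, object$estimates[["kd"]],
                                  object$estimates[["fmax"]],
                                  object$probe_conc)
  ggplot2::ggplot(d, ggplot2::aes(x = to_nM(.data$conc), y = .data$dfluo)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration (nM)",
                  y = expression(Delta * "Fluo (a.u.)"),
                  title = sprintf("K[D] = %.3g nM",
                                  to_nM(object$estimates[["kd"]]))) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot for a mono-exponential fit
#'
#' @param object A `monoexp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.monoexp_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(time = seq(min(d$time), max(d$time), length.out = 300))
  grid$signal <- exponential_response(grid$time,
                                      object$estimates[["baseline"]],
                                      object$estimates[["amplitude"]],
                                      object$estimates[["k_obs"]],
                                      object$direction)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)",
                  title = sprintf("%s, k[obs] = %.3g 1/s", object$direction,
                                  object$estimates[["k_obs"]])) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot for a global Langmuir fit
#'
#' Sensorgrams coloured by analyte concentration with the fitted model
#' overlaid.
#'
#' @param object A `langmuir_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.langmuir_fit <- function(object, ...) {
  d <- purrr::map2_dfr(object$data, object$concs,
                       ~ tibble(conc = .y, time = .x$time,
                                response = .x$response))
  fitgrid <- purrr::map2_dfr(object$data, seq_along(object$concs),
    function(cv, i) {
      t <- seq(min(cv$time), max(cv$time), length.out = 300)
      tibble(conc = object$concs[i], time = t,
             response = sensorgram_response(
               t, object$estimates[["k_on"]], object$estimates[["k_off"]],
               object$estimates[["r_max"]], object$concs[i],
               object$t_assoc_end,
               baseline = object$per_curve$offset[i]))
    })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$response,
                                  colour = factor(to_nM(.data$conc)))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_line(data = fitgrid) +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  colour = "analyte (nM)") +
    ggplot2::theme_minimal()
}

#' Bar chart of an ELISA affinity ranking
#'
#' @param ranked Output of [rank_panel()].
#' @return A ggplot object.
#' @export
plot_elisa_ranking <- function(ranked) {
  ggplot2::ggplot(ranked,
                  ggplot2::aes(x = stats::reorder(.data$variant,
                                                  .data$ratio),
                               y = .data$ratio, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(2, 3, 6, 8), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "signal ratio to reference",
                  fill = "affinity") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
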