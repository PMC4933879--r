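#' Fit 1:1 Langmuir kinetics to a sensorgram set
#'
#' Estimates \eqn{k_{on}}, \eqn{k_{off}} and \eqn{R_{max}} from association/
#' dissociation response curves using the closed-form Langmuir expressions
#' ([sensorgram_response()]) under the flow-cell assumption of constant
#' analyte concentration (no depletion; the ODE oracle validates this
#' assumption, see the package vignette). Two modes:
#'
#' * `"global"` (default): one \eqn{(k_{on}, k_{off}, R_{max})} shared across
#'   all curves, plus a constant per-curve baseline offset — the standard
#'   global Langmuir analysis of a concentration series;
#' * `"per_curve"`: each curve fitted independently.
#'
#' Parameters are optimised on the log scale (they are positive rates), with
#' Levenberg-Marquardt damping; standard errors come from the Jacobian at
#' the optimum and are transported back to the natural scale.
#'
#' @param data Long data frame with columns `conc` (mol/L), `time` (s) and
#'   `response` (RU); the association window end is taken from the
#'   `"t_assoc"` attribute or `t_assoc_end`.
#' @param mode `"global"` or `"per_curve"`.
#' @param t_assoc_end End of the association phase, s.
#' @return For `"global"`: a `langmuir_fit` (also `darpkin_fit`) with
#'   estimates `k_on`, `k_off`, `r_max`, the derived `kd` row from
#'   [kd_from_rates()] (`$kd_table`), per-curve residual rms, per-curve
#'   plateau flags (association phase reached 99 percent of \eqn{R_{eq}}),
#'   and a `koff_window_warning` when the dissociation window is shorter
#'   than \eqn{0.2/k_{off}} (too short to determine the off-rate). For
#'   `"per_curve"`: a tibble with one row of estimates per concentration.
#' @examples
#' fit <- sim_sensorgram_set(1.9e6, 0.0025, r_max = 120, seed = 5) |>
#'   fit_langmuir()
#' glance(fit)
#' @export
fit_langmuir <- function(data, mode = c("global", "per_curve"),
                         t_assoc_end = attr(data, "t_assoc")) {
  mode <- match.arg(mode)
  if (is.null(data$conc) || is.null(data$time) || is.null(data$response)) {
    abort("`data` must contain columns `conc`, `time`, `response`")
  }
  if (is.null(t_assoc_end)) {
    abort("association window end is required (`t_assoc_end` or attribute)")
  }
  curves <- split(data[c("time", "response")], data$conc)
  concs <- as.numeric(names(curves))
  if (mode == "global" && length(curves) < 3) {
    abort("global Langmuir fitting needs at least 3 analyte concentrations")
  }
  if (mode == "per_curve") {
    out <- purrr::map2_dfr(curves, concs, function(cv, ci) {
      f <- langmuir_engine(list(cv), ci, t_assoc_end)
      tibble(conc = ci, k_on = f$estimates[["k_on"]],
             k_off = f$estimates[["k_off"]], r_max = f$estimates[["r_max"]],
             kd = f$estimates[["k_off"]] / f$estimates[["k_on"]],
             residual_rms = f$residual_rms)
    })
    return(out)
  }
  langmuir_engine(curves, concs, t_assoc_end)
}

# shared residual-based engine; `curves` is a list of data frames
langmuir_engine <- function(curves, concs, t_assoc_end) {
  flat <- all(purrr::map_dbl(curves, ~ sd(.x$response)) <
                1e-10 * max(1, max(abs(unlist(purrr::map(curves, "response"))))))
  if (flat) abort("flat sensorgrams: nothing to fit")

  # initial values: k_off from the log-linear dissociation tail of the
  # strongest curve; k_obs per curve from a mono-exponential association fit
  top <- curves[[which.max(concs)]]
  diss <- top[top$time > t_assoc_end, , drop = FALSE]
  koff0 <- 0.01
  if (nrow(diss) > 5) {
    pos <- diss$response > 0.05 * max(diss$response)
    if (sum(pos) > 3) {
      sl <- unname(coef(lm(log(diss$response[pos]) ~ diss$time[pos]))[2])
      if (is.finite(sl) && sl < 0) koff0 <- -sl
    }
  }
  kobs0 <- purrr::map_dbl(curves, function(cv) {
    assoc <- cv[cv$time <= t_assoc_end, , drop = FALSE]
    f <- tryCatch(suppressWarnings(fit_monoexponential(
      tibble(time = assoc$time, signal = assoc$response), "rise")),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$estimates[["k_obs"]]
  })
  kon0 <- if (sum(is.finite(kobs0)) >= 2) {
    sl <- unname(coef(lm(kobs0 ~ concs))[2])
    if (is.finite(sl) && sl > 0) sl else 1e5
  } else 1e5
  rmax0 <- max(purrr::map_dbl(curves, ~ max(.x$response))) /
    max(max(concs) / (max(concs) + koff0 / kon0), 0.1)

  n_cur <- length(curves)
  y_all <- unlist(purrr::map(curves, "response"), use.names = FALSE)
  resid_fun <- function(p) {
    k_on <- exp(p[1]); k_off <- exp(p[2]); r_max <- exp(p[3])
    offs <- if (length(p) > 3) p[-(1:3)] else rep(0, n_cur)
    pred <- unlist(purrr::map2(curves, seq_len(n_cur), function(cv, i) {
      sensorgram_response(cv$time, k_on, k_off, r_max, concs[i],
                          t_assoc_end, baseline = offs[i])
    }), use.names = FALSE)
    pred - y_all
  }
  p0 <- c(log(kon0), log(koff0), log(rmax0), rep(0, n_cur))
  opt <- minpack.lm::nls.lm(p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-12, ptol = 1e-12))
  if (opt$info == 0 || opt$info == 9) {
    abort(sprintf("Langmuir fit did not converge (nls.lm info = %d)",
                  opt$info))
  }
  p <- opt$par
  est <- c(k_on = exp(p[1]), k_off = exp(p[2]), r_max = exp(p[3]))

  # asymptotic covariance on the log scale -> delta method to natural scale
  se <- rep(NA_real_, 3)
  cov_ok <- FALSE
  vc <- tryCatch(vcov(opt), error = function(e) NULL)
  if (!is.null(vc)) {
    se_log <- sqrt(pmax(diag(vc)[1:3], 0))
    se <- unname(est) * se_log
    cov_ok <- all(is.finite(se))
  }
  names(se) <- names(est)

  per_curve <- purrr::map2_dfr(curves, seq_len(n_cur), function(cv, i) {
    pred <- sensorgram_response(cv$time, est[["k_on"]], est[["k_off"]],
                                est[["r_max"]], concs[i], t_assoc_end,
                                baseline = p[3 + i])
    k_obs <- est[["k_on"]] * concs[i] + est[["k_off"]]
    tibble(conc = concs[i], offset = p[3 + i],
           residual_rms = sqrt(mean((cv$response - pred)^2)),
           plateau_reached = (1 - exp(-k_obs * t_assoc_end)) >= 0.99)
  })
  t_dissoc <- max(purrr::map_dbl(curves, ~ max(.x$time))) - t_assoc_end
  koff_window_warning <- t_dissoc < 0.2 / est[["k_off"]]
  if (koff_window_warning) {
    warn("dissociation window shorter than 0.2/k_off: k_off poorly determined")
  }
  structure(list(estimates = est, se = se,
                 kd_table = kd_from_rates(est[["k_off"]], est[["k_on"]],
                                          se[["k_off"]], se[["k_on"]]),
                 per_curve = per_curve, residual_rms =
                   sqrt(mean(opt$fvec^2)),
                 n = length(y_all), dof = length(y_all) - length(p),
                 converged = TRUE, cov_ok = cov_ok,
                 koff_window_warning = koff_window_warning,
                 t_assoc_end = t_assoc_end, data = curves, concs = concs),
            class = c("langmuir_fit", "darpkin_fit"))
}

#' Extract plateau responses from a sensorgram set
#'
#' The plateau of each association phase is taken as the mean response over
#' the last 10 percent of the association window; a curve still rising by
#' more than 1 percent of its level across that stretch is flagged.
#'
#' @param data Long sensorgram data frame (`conc`, `time`, `response`).
#' @param t_assoc_end End of the association window, s.
#' @return Tibble with `conc`, `plateau`, `still_rising`.
#' @export
extract_plateaus <- function(data, t_assoc_end = attr(data, "t_assoc")) {
  if (is.null(t_assoc_end)) abort("association window end is required")
  data |>
    dplyr::filter(.data$time <= t_assoc_end) |>
    dplyr::group_by(.data$conc) |>
    dplyr::group_modify(function(d, key) {
      last <- d[d$time >= 0.9 * t_assoc_end, , drop = FALSE]
      prev <- d[d$time >= 0.8 * t_assoc_end & d$time < 0.9 * t_assoc_end, ,
                drop = FALSE]
      plateau <- mean(last$response)
      rising <- nrow(prev) > 0 &&
        (plateau - mean(prev$response)) > 0.01 * abs(plateau)
      tibble(plateau = plateau, still_rising = rising)
    }) |>
    dplyr::ungroup()
}

#' Equilibrium dissociation constant from plateau responses
#'
#' Fits the binding hyperbola \eqn{R_{eq} = R_{max} C / (K_D + C)} to plateau
#' response versus analyte concentration — the equilibrium analysis used
#' when the kinetic fit of a sensorgram set is poor. When the responses show
#' no curvature over the tested range (fitted \eqn{K_D} far above the
#' largest concentration) the \eqn{K_D} is not determined and an error is
#' raised.
#'
#' @param series Data frame with columns `conc` (mol/L) and `plateau` (RU),
#'   at least 3 concentrations.
#' @param kinetic_kd Optional externally determined kinetic \eqn{K_D} for an
#'   agreement report.
#' @return A `plateau_fit` (also `darpkin_fit`) with estimates `kd`, `r_max`
#'   and, when `kinetic_kd` is given, an `agreement` tibble from
#'   [kd_consistency()].
#' @export
plateau_kd <- function(series, kinetic_kd = NULL) {
  conc <- series$conc
  plateau <- series$plateau
  if (is.null(conc) || is.null(plateau)) {
    abort("`series` must contain columns `conc` and `plateau`")
  }
  if (length(conc) < 3) {
    abort("plateau analysis needs at least 3 concentrations")
  }
  check_numeric(conc, "conc", positive = TRUE)
  if (any(plateau < 0)) abort("plateau responses must be non-negative")
  rmax0 <- max(plateau) * 1.2
  kd0 <- conc[which.min(abs(plateau - rmax0 / 2))]
  df <- data.frame(conc = conc, plateau = plateau)
  fit <- tryCatch(
    minpack.lm::nlsLM(plateau ~ r_max * conc / (kd + conc), data = df,
                      start = list(r_max = rmax0, kd = kd0),
                      lower = c(1e-12, 1e-18),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  linear_r2 <- suppressWarnings(summary(lm(plateau ~ conc))$r.squared)
  if (is.null(fit)) {
    if (is.finite(linear_r2) && linear_r2 > 0.99) {
      abort("responses are linear in concentration: K_D above tested range")
    }
    abort("plateau hyperbola fit failed to converge")
  }
  est <- coef(fit)
  if (est[["kd"]] > 10 * max(conc)) {
    abort("responses are linear in concentration: K_D above tested range")
  }
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  cov_ok <- !is.null(se) && all(is.finite(se))
  if (!cov_ok) se <- setNames(rep(NA_real_, 2), names(est))
  out <- structure(list(estimates = c(kd = est[["kd"]],
                                      r_max = est[["r_max"]]),
                        se = c(kd = unname(se[["kd"]]),
                               r_max = unname(se[["r_max"]])),
                        residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                        n = length(conc), dof = length(conc) - 2,
                        converged = TRUE, cov_ok = cov_ok,
                        data = tibble(conc = conc, plateau = plateau),
                        nls = fit),
                   class = c("plateau_fit", "darpkin_fit"))
  if (!is.null(kinetic_kd)) {
    out$agreement <- kd_consistency(est[["kd"]], kinetic_kd)
  }
  out
}
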