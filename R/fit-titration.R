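#' Fit the tight-binding isotherm to a titration
#'
#' Nonlinear least-squares estimation of the dissociation constant and
#' saturation signal from a labelled-probe titration, with the probe
#' concentration fixed from metadata. The quadratic depletion isotherm has a
#' notoriously flat likelihood surface once the probe is in excess of
#' \eqn{K_D} (the tight-binding regime), so the Levenberg-Marquardt optimiser
#' is multi-started from three \eqn{K_D} initialisations: a crossing-point
#' heuristic (the ligand concentration at half-saturation, corrected for
#' depletion by subtracting half the probe concentration), and 0.1x / 10x
#' that value. The best converged start by residual sum of squares wins.
#'
#' @param data Data frame with the titration points; columns `conc` (total
#'   ligand, mol/L) and `dfluo` (signal change, a.u.) by default.
#' @param probe_conc Labelled-probe concentration, mol/L. Defaults to the
#'   `"probe_conc"` attribute that [sim_titration()] and
#'   [read_titration_csv()] attach.
#' @param conc_col,response_col Column names.
#' @param bootstrap Also compute residual-resampling bootstrap standard
#'   errors (seeded, `n_boot` refits); stored as `boot_se`. The default
#'   standard errors are always the asymptotic (covariance-based) ones.
#' @param n_boot,boot_seed Bootstrap resamples and seed.
#' @return An object of class `titration_fit` (also `darpkin_fit`): use
#'   [tidy()] for per-parameter estimates and standard errors, [glance()] for
#'   a one-row summary, [autoplot()] for a diagnostic plot. Fields include
#'   `estimates` (`kd`, `fmax`), `se`, `residual_rms`, `n`, `converged`,
#'   `cov_ok`, and `saturation_warning` (`TRUE` when the strongest measured
#'   signal is below 60 percent of the fitted saturation level, i.e. the
#'   plateau was not reached).
#' @examples
#' fit <- sim_titration(kd = from_nM(127), probe_conc = from_nM(100),
#'                      noise_sd = 0.01, seed = 7) |> fit_titration()
#' glance(fit)
#' @export
fit_titration <- function(data, probe_conc = attr(data, "probe_conc"),
                          conc_col = "conc", response_col = "dfluo",
                          bootstrap = FALSE, n_boot = 500, boot_seed = 1) {
  conc <- data[[conc_col]]
  y <- data[[response_col]]
  if (is.null(conc) || is.null(y)) {
    abort(sprintf("`data` must contain columns `%s` and `%s`",
                  conc_col, response_col))
  }
  if (is.null(probe_conc)) {
    abort("`probe_conc` is required (argument or attribute)")
  }
  check_numeric(conc, "conc", non_negative = TRUE)
  check_numeric(probe_conc, "probe_conc", positive = TRUE, scalar = TRUE)
  if (length(conc) < 4) abort("a titration fit needs at least 4 points")

  degenerate <- sd(y) < .Machine$double.eps * max(1, abs(mean(y))) ||
    max(y) <= 0
  fmax0 <- max(y) * 1.05
  kd0 <- if (fmax0 > 0) {
    half <- fmax0 / 2
    ord <- order(conc)
    cross <- suppressWarnings(
      approx(y[ord], conc[ord], xout = half, ties = mean)$y)
    if (is.na(cross)) cross <- stats::median(conc)
    max(cross - probe_conc / 2, cross / 10, probe_conc / 100, 1e-15)
  } else {
    probe_conc
  }

  df <- data.frame(conc = conc, y = y)
  one_fit <- function(kd_start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ isotherm_response(conc, kd, fmax, probe_conc),
        data = df,
        start = list(kd = kd_start, fmax = max(fmax0, 1e-12)),
        lower = c(1e-18, 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fits <- if (degenerate) list() else {
    purrr::compact(purrr::map(c(kd0, 0.1 * kd0, 10 * kd0), one_fit))
  }
  new_fit <- function(est, se, rms, converged, cov_ok, fit = NULL) {
    structure(list(estimates = est, se = se, probe_conc = probe_conc,
                   residual_rms = rms, n = length(y), dof = length(y) - 2,
                   converged = converged,
                   cov_ok = cov_ok, data = tibble(conc = conc, dfluo = y),
                   saturation_warning = FALSE, nls = fit),
              class = c("titration_fit", "darpkin_fit"))
  }
  if (length(fits) == 0) {
    return(new_fit(c(kd = NA_real_, fmax = NA_real_),
                   c(kd = NA_real_, fmax = NA_real_),
                   NA_real_, converged = FALSE, cov_ok = FALSE))
  }
  best <- fits[[which.min(purrr::map_dbl(fits, stats::deviance))]]
  est <- coef(best)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e) NULL)
  cov_ok <- !is.null(se) && all(is.finite(se))
  if (!cov_ok) se <- c(kd = NA_real_, fmax = NA_real_)
  out <- new_fit(setNames(est, c("kd", "fmax")),
                 setNames(se, c("kd", "fmax")),
                 sqrt(mean(stats::residuals(best)^2)),
                 converged = best$convInfo$isConv %||% TRUE,
                 cov_ok = cov_ok, fit = best)
  if (is.finite(est[["fmax"]]) && max(y) < 0.6 * est[["fmax"]]) {
    out$saturation_warning <- TRUE
    warn("titration does not reach 60% of the fitted saturation signal; K_D is poorly constrained")
  }
  if (bootstrap) {
    pred <- y - stats::residuals(best)
    res <- stats::residuals(best)
    boots <- with_stream_seed(boot_seed, "titration_boot", {
      vapply(seq_len(n_boot), function(b) {
        yb <- pred + sample(res, replace = TRUE)
        fb <- tryCatch(
          minpack.lm::nlsLM(
            yb ~ isotherm_response(conc, kd, fmax, probe_conc),
            data = data.frame(conc = conc, yb = yb),
            start = as.list(setNames(est, c("kd", "fmax"))),
            lower = c(1e-18, 1e-12),
            control = minpack.lm::nls.lm.control(maxiter = 100)),
          error = function(e) NULL)
        if (is.null(fb)) c(NA_real_, NA_real_) else unname(coef(fb))
      }, numeric(2))
    })
    out$boot_se <- c(kd = sd(boots[1, ], na.rm = TRUE),
                     fmax = sd(boots[2, ], na.rm = TRUE))
    out$n_boot <- n_boot
  }
  out
}

#' @export
print.darpkin_fit <- function(x, ...) {
  cat(sprintf("<%s> converged: %s\n", class(x)[1], x$converged))
  if (length(x$estimates)) {
    est <- format(x$estimates, digits = 4)
    se <- format(x$se, digits = 3)
    for (i in seq_along(est)) {
      cat(sprintf("  %-8s %s +/- %s\n", names(x$estimates)[i], est[i], se[i]))
    }
  }
  cat(sprintf("  rms residual %.4g over %d points\n", x$residual_rms, x$n))
  invisible(x)
}
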