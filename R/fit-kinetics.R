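#' Fit a mono-exponential transition to a kinetic trace
#'
#' Least-squares fit of [exponential_response()] to a time-resolved signal:
#' a decay (chase dissociation experiment, where the observed rate at
#' saturating competitor equals \eqn{k_{off}}) or a rise (pseudo-first-order
#' association, where \eqn{k_{obs} = k_{on}[T] + k_{off}}). Initialisation
#' comes from a log-linearised regression of the baseline-subtracted signal,
#' followed by Levenberg-Marquardt refinement.
#'
#' @param trace Data frame with columns `time` (s, strictly increasing) and
#'   `signal` (a.u.), at least 8 points.
#' @param direction `"auto"` (infer from the trend), `"decay"` or `"rise"`.
#' @param time_col,signal_col Column names.
#' @param bootstrap Also compute residual-resampling bootstrap standard
#'   errors (seeded, `n_boot` refits); stored as `boot_se`.
#' @param n_boot,boot_seed Bootstrap resamples and seed.
#' @return An object of class `monoexp_fit` (also `darpkin_fit`) with
#'   estimates `baseline`, `amplitude`, `k_obs` and their standard errors,
#'   plus `direction`, `halflife_warning` (trace shorter than two half-lives
#'   of the transition) and the usual fit diagnostics. A trace whose fitted
#'   amplitude is indistinguishable from noise (below 3x the residual rms)
#'   raises a "no transition" error.
#' @examples
#' tr <- sim_chase_trace(k_off = 1.49, noise_sd = 0.005, seed = 3)
#' glance(fit_monoexponential(tr))
#' @export
fit_monoexponential <- function(trace, direction = c("auto", "decay", "rise"),
                                time_col = "time", signal_col = "signal",
                                bootstrap = FALSE, n_boot = 500,
                                boot_seed = 1) {
  direction <- match.arg(direction)
  t <- trace[[time_col]]
  y <- trace[[signal_col]]
  if (is.null(t) || is.null(y)) {
    abort(sprintf("`trace` must contain columns `%s` and `%s`",
                  time_col, signal_col))
  }
  if (length(t) < 8) abort("a kinetic trace needs at least 8 points")
  if (is.unsorted(t, strictly = TRUE) || any(t < 0)) {
    abort("`time` must be strictly increasing and non-negative")
  }

  n_edge <- max(3L, ceiling(length(t) / 10))
  head_mean <- mean(head(y, n_edge))
  tail_mean <- mean(tail(y, n_edge))
  if (direction == "auto") {
    direction <- if (head_mean > tail_mean) "decay" else "rise"
  }

  # log-linear initialisation on the baseline-subtracted signal
  resid0 <- if (direction == "decay") y - tail_mean else tail_mean - y
  amp0 <- if (direction == "decay") head_mean - tail_mean
          else tail_mean - head_mean
  scale_y <- max(abs(y - mean(y)), 1e-12)
  if (abs(amp0) < .Machine$double.eps * 100 || sd(y) < 1e-14 * max(1, abs(mean(y)))) {
    abort("no transition: the trace is constant")
  }
  usable <- which(resid0 > 0.02 * abs(amp0))
  k0 <- if (length(usable) >= 3) {
    sl <- unname(coef(lm(log(resid0[usable]) ~ t[usable]))[2])
    if (is.finite(sl) && sl < 0) -sl else 1 / max(t[length(t)], 1e-12)
  } else {
    1 / max(t[length(t)] / 5, 1e-12)
  }

  df <- data.frame(t = t, y = y)
  form <- if (direction == "decay") {
    y ~ baseline + amplitude * exp(-k_obs * t)
  } else {
    y ~ baseline + amplitude * (1 - exp(-k_obs * t))
  }
  start <- if (direction == "decay") {
    list(baseline = tail_mean, amplitude = amp0, k_obs = k0)
  } else {
    list(baseline = head_mean, amplitude = amp0, k_obs = k0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (abs(amp0) < 3 * sd(y)) {
      abort("no transition: the trace shows no resolvable amplitude")
    }
    abort("mono-exponential fit failed to converge")
  }
  est <- coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  if (abs(est[["amplitude"]]) < 3 * rms) {
    abort("no transition: fitted amplitude is indistinguishable from noise")
  }
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  cov_ok <- !is.null(se) && all(is.finite(se))
  if (!cov_ok) se <- setNames(rep(NA_real_, 3), names(est))

  halflife_warning <- max(t) * est[["k_obs"]] < 2 * log(2)
  if (halflife_warning) {
    warn("trace spans less than two half-lives of the fitted transition")
  }
  out <- structure(
    list(estimates = est, se = se, direction = direction,
         residual_rms = rms, n = length(t), dof = length(t) - 3,
         converged = fit$convInfo$isConv %||% TRUE, cov_ok = cov_ok,
         halflife_warning = halflife_warning,
         data = tibble(time = t, signal = y), nls = fit),
    class = c("monoexp_fit", "darpkin_fit"))
  if (bootstrap) {
    pred <- y - stats::residuals(fit)
    res <- stats::residuals(fit)
    boots <- with_stream_seed(boot_seed, "monoexp_boot", {
      vapply(seq_len(n_boot), function(b) {
        yb <- pred + sample(res, replace = TRUE)
        fb <- tryCatch(
          minpack.lm::nlsLM(form, data = data.frame(t = t, y = yb),
                            start = as.list(est),
                            lower = c(-Inf, -Inf, 1e-12),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100)),
          error = function(e) rep(NA_real_, 3))
        if (inherits(fb, "nls")) unname(coef(fb)) else rep(NA_real_, 3)
      }, numeric(3))
    })
    out$boot_se <- setNames(apply(boots, 1, sd, na.rm = TRUE), names(est))
    out$n_boot <- n_boot
  }
  out
}

#' Extract the association rate constant from a k_obs series
#'
#' Under pseudo-first-order conditions the observed association rate is
#' linear in ligand concentration, \eqn{k_{obs} = k_{on} [T] + k_{off}}; the
#' slope of a (weighted) linear regression is \eqn{k_{on}}. The intercept is
#' reported for a consistency check against the chase-derived \eqn{k_{off}}
#' but is not itself used as the dissociation rate (the chase value, measured
#' at saturating competitor, is the primary estimate).
#'
#' @param series Data frame with columns `conc` (mol/L), `k_obs` (1/s) and
#'   optionally `k_obs_se` (used for `1/se^2` weighting when present and all
#'   positive).
#' @return A `kobs_line_fit` with estimates `k_on` (slope, 1/(M s)) and
#'   `intercept` (1/s), standard errors and `r_squared`.
#' @export
fit_kobs_line <- function(series) {
  conc <- series$conc
  k_obs <- series$k_obs
  if (is.null(conc) || is.null(k_obs)) {
    abort("`series` must contain columns `conc` and `k_obs`")
  }
  if (length(unique(conc)) < 3) {
    abort("at least 3 distinct concentrations are needed for the k_obs line")
  }
  w <- series[["k_obs_se"]]
  use_w <- !is.null(w) && all(is.finite(w)) && all(w > 0)
  fit <- if (use_w) lm(k_obs ~ conc, weights = 1 / w^2) else lm(k_obs ~ conc)
  est <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  if (est[["conc"]] <= 0) {
    abort("fitted k_obs slope is non-positive: non-physical association rate")
  }
  structure(list(estimates = c(k_on = unname(est[["conc"]]),
                               intercept = unname(est[["(Intercept)"]])),
                 se = c(k_on = unname(se[["conc"]]),
                        intercept = unname(se[["(Intercept)"]])),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(conc), dof = length(conc) - 2,
                 converged = TRUE, cov_ok = TRUE,
                 weighted = use_w,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 data = tibble(conc = conc, k_obs = k_obs), lm = fit),
            class = c("kobs_line_fit", "darpkin_fit"))
}

#' Kinetic dissociation constant from the rate-constant ratio
#'
#' \eqn{K_D = k_{off}/k_{on}}, with the standard error propagated to first
#' order: \eqn{SE(K_D) = K_D \sqrt{(SE_{k_{off}}/k_{off})^2 +
#' (SE_{k_{on}}/k_{on})^2}}.
#'
#' @param k_off,k_on Rate constants (1/s, 1/(M s)); `k_on` must be > 0.
#' @param k_off_se,k_on_se Standard errors (default 0).
#' @return A one-row tibble: `k_off`, `k_off_se`, `k_on`, `k_on_se`, `kd`
#'   (mol/L), `kd_se`.
#' @examples
#' to_nM(kd_from_rates(1.49, 1.30e7)$kd)   # ~115 nM
#' @export
kd_from_rates <- function(k_off, k_on, k_off_se = 0, k_on_se = 0) {
  check_numeric(k_off, "k_off", non_negative = TRUE, scalar = TRUE)
  if (!is.numeric(k_on) || length(k_on) != 1 || !is.finite(k_on) || k_on <= 0) {
    abort("`k_on` must be a single positive number")
  }
  check_numeric(k_off_se, "k_off_se", non_negative = TRUE, scalar = TRUE)
  check_numeric(k_on_se, "k_on_se", non_negative = TRUE, scalar = TRUE)
  kd <- k_off / k_on
  rel <- sqrt((if (k_off > 0) k_off_se / k_off else 0)^2 + (k_on_se / k_on)^2)
  tibble(k_off = k_off, k_off_se = k_off_se, k_on = k_on, k_on_se = k_on_se,
         kd = kd, kd_se = kd * rel)
}

#' Agreement between two dissociation-constant estimates
#'
#' Compares an equilibrium (titration) and a kinetic (\eqn{k_{off}/k_{on}})
#' estimate of the same \eqn{K_D}: the report gives their max/min ratio and a
#' pass flag at a tolerance factor (default 2, i.e. agreement within
#' two-fold).
#'
#' @param kd_a,kd_b Dissociation constants, mol/L, > 0.
#' @param tolerance_factor Largest acceptable max/min ratio.
#' @return One-row tibble: `kd_a`, `kd_b`, `ratio`, `pass`.
#' @export
kd_consistency <- function(kd_a, kd_b, tolerance_factor = 2) {
  check_numeric(kd_a, "kd_a", positive = TRUE, scalar = TRUE)
  check_numeric(kd_b, "kd_b", positive = TRUE, scalar = TRUE)
  check_numeric(tolerance_factor, "tolerance_factor", positive = TRUE,
                scalar = TRUE)
  ratio <- max(kd_a, kd_b) / min(kd_a, kd_b)
  tibble(kd_a = kd_a, kd_b = kd_b, ratio = ratio,
         pass = ratio <= tolerance_factor)
}

#' Fit an association series end to end
#'
#' Convenience wrapper: fits every trace of a pseudo-first-order association
#' series with [fit_monoexponential()], then regresses the observed rates on
#' concentration with [fit_kobs_line()].
#'
#' @param series Long data frame as produced by [sim_association_series()]
#'   (columns `trace`, `conc`, `time`, `signal`).
#' @return A list with `kobs_table` (tibble of per-trace `conc`, `k_obs`,
#'   `k_obs_se`) and `line` (the `kobs_line_fit`).
#' @export
fit_association_series <- function(series) {
  kobs_table <- series |>
    dplyr::group_by(.data$trace, .data$conc) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_monoexponential(d, direction = "rise")
      tibble(k_obs = f$estimates[["k_obs"]], k_obs_se = f$se[["k_obs"]])
    }) |>
    dplyr::ungroup()
  list(kobs_table = kobs_table, line = fit_kobs_line(kobs_table))
}
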