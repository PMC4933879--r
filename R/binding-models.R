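#' Tight-binding (ligand-depletion) 1:1 equilibrium isotherm
#'
#' Closed-form equilibrium signal for titrating a fixed concentration of a
#' labelled probe (e.g. an acrylodan-labelled DARPin) with its ligand. When
#' the probe concentration is comparable to the dissociation constant, the
#' free ligand concentration differs appreciably from the total, and the
#' bound fraction is the root of a quadratic rather than a hyperbola:
#'
#' \deqn{\Delta F = F_{max} \frac{(K_D + T + D^*) -
#'   \sqrt{(K_D + T + D^*)^2 - 4 T D^*}}{2 D^*}}
#'
#' where \eqn{T} is total ligand, \eqn{D^*} total probe. In the limit
#' \eqn{D^* \ll K_D} this reduces to the familiar hyperbola
#' \eqn{F_{max} T / (K_D + T)}.
#'
#' @param conc Total ligand concentration(s), mol/L, elementwise >= 0.
#' @param kd Equilibrium dissociation constant, mol/L, > 0.
#' @param fmax Signal at saturation, arbitrary units, > 0.
#' @param probe_conc Total labelled-probe concentration, mol/L, > 0.
#' @return Numeric vector of signal changes, in `[0, fmax)`, non-decreasing
#'   in `conc`.
#' @examples
#' isotherm_response(from_nM(c(0, 50, 100, 500)),
#'                   kd = from_nM(127), fmax = 1, probe_conc = from_nM(100))
#' @export
isotherm_response <- function(conc, kd, fmax, probe_conc) {
  check_numeric(conc, "conc", non_negative = TRUE)
  check_numeric(kd, "kd", positive = TRUE, scalar = TRUE)
  check_numeric(fmax, "fmax", positive = TRUE, scalar = TRUE)
  check_numeric(probe_conc, "probe_conc", positive = TRUE, scalar = TRUE)
  s <- kd + conc + probe_conc
  disc <- s^2 - 4 * conc * probe_conc
  # floating-point guard at exact stoichiometric points: the discriminant is
  # mathematically >= kd^2 > 0 but can round below 0 when kd is tiny
  tiny <- disc < 0 & disc > -1e-12 * s^2
  disc[tiny] <- 0
  fmax * (s - sqrt(disc)) / (2 * probe_conc)
}

#' Mono-exponential decay and rise
#'
#' Signal models for dissociation ("chase") and pseudo-first-order
#' association transients. A decay is
#' \eqn{F(t) = F_\infty + \Delta F e^{-k_{obs} t}} (so `baseline` is the
#' signal at infinite time and `amplitude` the total drop); a rise is
#' \eqn{F(t) = F_0 + \Delta F (1 - e^{-k_{obs} t})} (`baseline` is the signal
#' at time zero).
#'
#' @param t Times, s, elementwise >= 0.
#' @param baseline Signal at infinite time (decay) or time zero (rise), a.u.
#' @param amplitude Total signal change, a.u. (finite; may be negative).
#' @param k_obs Observed rate constant, 1/s, > 0.
#' @param direction `"decay"` or `"rise"`.
#' @return Numeric signal vector. At `t = log(2) / k_obs` the transition is
#'   half complete.
#' @export
exponential_response <- function(t, baseline, amplitude, k_obs,
                                 direction = c("decay", "rise")) {
  direction <- match.arg(direction)
  check_numeric(t, "t", non_negative = TRUE)
  check_numeric(baseline, "baseline", scalar = TRUE)
  check_numeric(amplitude, "amplitude", scalar = TRUE)
  check_numeric(k_obs, "k_obs", positive = TRUE, scalar = TRUE)
  if (direction == "decay") {
    baseline + amplitude * exp(-k_obs * t)
  } else {
    baseline + amplitude * (1 - exp(-k_obs * t))
  }
}

#' 1:1 Langmuir sensorgram model
#'
#' Closed-form surface plasmon resonance response for a 1:1 interaction under
#' the standard flow-cell assumption of a constant free analyte concentration.
#' During the injection (association phase)
#' \eqn{R(t) = R_{eq} (1 - e^{-(k_{on} C + k_{off}) t})} with
#' \eqn{R_{eq} = R_{max} C / (C + k_{off}/k_{on})}; after the injection ends
#' at `t_assoc_end` the response decays as
#' \eqn{R(t) = R(t_{end}) e^{-k_{off}(t - t_{end})}}. The curve is continuous
#' at the phase boundary.
#'
#' @param t Times, s, >= 0, measured from the injection start.
#' @param k_on Association rate constant, 1/(M s), > 0.
#' @param k_off Dissociation rate constant, 1/s, > 0.
#' @param r_max Maximal response at surface saturation, response units, > 0.
#' @param conc Analyte concentration C, mol/L, > 0.
#' @param t_assoc_end End of the association phase, s.
#' @param baseline Constant response offset, RU (default 0).
#' @return Response vector, RU.
#' @export
sensorgram_response <- function(t, k_on, k_off, r_max, conc, t_assoc_end,
                                baseline = 0) {
  check_numeric(t, "t", non_negative = TRUE)
  check_numeric(k_on, "k_on", positive = TRUE, scalar = TRUE)
  check_numeric(k_off, "k_off", positive = TRUE, scalar = TRUE)
  check_numeric(r_max, "r_max", positive = TRUE, scalar = TRUE)
  check_numeric(conc, "conc", positive = TRUE, scalar = TRUE)
  check_numeric(t_assoc_end, "t_assoc_end", positive = TRUE, scalar = TRUE)
  k_obs <- k_on * conc + k_off
  r_eq <- r_max * conc / (conc + k_off / k_on)
  r_end <- r_eq * (1 - exp(-k_obs * t_assoc_end))
  out <- ifelse(t <= t_assoc_end,
                r_eq * (1 - exp(-k_obs * t)),
                r_end * exp(-k_off * (t - t_assoc_end)))
  baseline + out
}

#' Equilibrium complex concentration of the 1:1 scheme
#'
#' Root of the equilibrium quadratic for A + B = AB: the complex
#' concentration given total probe, total ligand and \eqn{K_D}.
#'
#' @param probe_total,ligand_total Total concentrations, mol/L.
#' @param kd Dissociation constant, mol/L.
#' @return Complex concentration, mol/L.
#' @export
equilibrium_complex <- function(probe_total, ligand_total, kd) {
  s <- kd + ligand_total + probe_total
  disc <- pmax(s^2 - 4 * ligand_total * probe_total, 0)
  (s - sqrt(disc)) / 2
}
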