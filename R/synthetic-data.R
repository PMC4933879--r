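#' Simulate an equilibrium titration of a labelled probe
#'
#' Generates concentration/response pairs on the tight-binding isotherm
#' ([isotherm_response()]) with i.i.d. Gaussian noise. The default design
#' places 12 log-spaced ligand concentrations from `probe_conc / 10` to
#' `max(20 * kd, 5 * probe_conc)`, covering both the depletion-dominated and
#' the saturation regime.
#'
#' @param kd True dissociation constant, mol/L.
#' @param probe_conc Labelled-probe concentration, mol/L.
#' @param fmax True saturation signal, a.u. (default 1).
#' @param conc Optional explicit ligand concentrations, mol/L.
#' @param n_points Number of design points when `conc` is not given.
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return A tibble with columns `conc` (mol/L) and `dfluo` (a.u.), carrying
#'   the truth, probe concentration and seed as attributes (`"truth"`,
#'   `"probe_conc"`, `"seed"`).
#' @examples
#' sim_titration(kd = from_nM(127), probe_conc = from_nM(100), seed = 1)
#' @export
sim_titration <- function(kd, probe_conc, fmax = 1, conc = NULL,
                          n_points = 12, noise_sd = 0, seed = 1) {
  check_numeric(noise_sd, "noise_sd", non_negative = TRUE, scalar = TRUE)
  if (is.null(conc)) {
    conc <- exp(seq(log(probe_conc / 10),
                    log(max(20 * kd, 5 * probe_conc)),
                    length.out = n_points))
  }
  if (length(conc) < 1) abort("titration design must be non-empty")
  clean <- isotherm_response(conc, kd, fmax, probe_conc)
  noise <- with_stream_seed(seed, "titration",
                            stats::rnorm(length(conc), 0, noise_sd))
  out <- tibble(conc = conc, dfluo = clean + if (noise_sd > 0) noise else 0)
  attr(out, "truth") <- list(kd = kd, fmax = fmax)
  attr(out, "probe_conc") <- probe_conc
  attr(out, "seed") <- seed
  out
}

#' Simulate a chase (dissociation) trace
#'
#' Mono-exponential fluorescence decay observed when pre-formed labelled
#' complex is mixed with a saturating excess of unlabelled competitor, so the
#' observed rate equals the dissociation rate constant.
#'
#' @param k_off True dissociation rate constant, 1/s.
#' @param baseline Signal at infinite time, a.u.
#' @param amplitude Total signal drop, a.u.
#' @param t_max Trace duration, s; defaults to `5 / k_off` (about seven
#'   half-lives).
#' @param n_points Number of samples.
#' @param noise_sd,seed Noise level (a.u.) and RNG seed.
#' @return Tibble with `time` (s) and `signal` (a.u.); truth and seed stored
#'   as attributes.
#' @export
sim_chase_trace <- function(k_off, baseline = 0.2, amplitude = 1,
                            t_max = NULL, n_points = 100, noise_sd = 0,
                            seed = 1) {
  check_numeric(k_off, "k_off", positive = TRUE, scalar = TRUE)
  t_max <- t_max %||% (5 / k_off)
  t <- seq(0, t_max, length.out = n_points)
  clean <- exponential_response(t, baseline, amplitude, k_off, "decay")
  noise <- with_stream_seed(seed, "chase",
                            stats::rnorm(n_points, 0, noise_sd))
  out <- tibble(time = t, signal = clean + if (noise_sd > 0) noise else 0)
  attr(out, "truth") <- list(k_off = k_off, baseline = baseline,
                             amplitude = amplitude)
  attr(out, "seed") <- seed
  out
}

#' Simulate a pseudo-first-order association series
#'
#' One exponential rise per ligand concentration, with observed rate
#' \eqn{k_{obs} = k_{on} [T] + k_{off}}. The pseudo-first-order approximation
#' requires ligand in excess over the probe: concentrations below 5x the
#' probe concentration raise a warning, below 2x an error. In `"ode"` mode
#' the traces are integrated with the full second-order scheme
#' ([ode_binding()]) instead of the closed form, which is how the closed form
#' itself is validated.
#'
#' @param k_on,k_off True rate constants (1/(M s), 1/s).
#' @param probe_conc Labelled-probe concentration, mol/L.
#' @param conc Ligand concentrations, mol/L (one trace each).
#' @param fmax Signal corresponding to fully bound probe, a.u.
#' @param baseline Signal at time zero, a.u.
#' @param t_max Trace duration, s; defaults per trace to `5 / k_obs`.
#' @param n_points Samples per trace.
#' @param noise_sd,seed Noise level and seed.
#' @param method `"closed_form"` (default) or `"ode"`.
#' @return Long tibble with columns `trace`, `conc`, `time`, `signal`;
#'   truth, probe concentration and seed as attributes.
#' @export
sim_association_series <- function(k_on, k_off, probe_conc, conc,
                                   fmax = 1, baseline = 0.1, t_max = NULL,
                                   n_points = 80, noise_sd = 0, seed = 1,
                                   method = c("closed_form", "ode")) {
  method <- match.arg(method)
  check_numeric(k_on, "k_on", positive = TRUE, scalar = TRUE)
  check_numeric(k_off, "k_off", non_negative = TRUE, scalar = TRUE)
  check_numeric(probe_conc, "probe_conc", positive = TRUE, scalar = TRUE)
  check_numeric(conc, "conc", positive = TRUE)
  excess <- conc / probe_conc
  if (any(excess < 2)) {
    abort("ligand concentrations below 2x the probe concentration violate the pseudo-first-order condition")
  }
  if (any(excess < 5)) {
    warn("ligand below 5x the probe concentration: pseudo-first-order approximation is marginal")
  }

  traces <- purrr::imap(conc, function(ci, i) {
    k_obs <- k_on * ci + k_off
    tm <- t_max %||% (5 / k_obs)
    t <- seq(0, tm, length.out = n_points)
    bound_eq <- equilibrium_complex(probe_conc, ci, k_off / max(k_on, 1e-300))
    if (k_off == 0) bound_eq <- probe_conc
    amp <- fmax * bound_eq / probe_conc
    clean <- if (method == "closed_form") {
      exponential_response(t, baseline, amp, k_obs, "rise")
    } else {
      traj <- ode_binding(k_on, max(k_off, 0), probe_conc, ci, t)
      baseline + fmax * traj$complex / probe_conc
    }
    noise <- with_stream_seed(seed, paste0("assoc", i),
                              stats::rnorm(n_points, 0, noise_sd))
    tibble(trace = i, conc = ci, time = t,
           signal = clean + if (noise_sd > 0) noise else 0)
  })
  out <- dplyr::bind_rows(traces)
  attr(out, "truth") <- list(k_on = k_on, k_off = k_off, fmax = fmax,
                             baseline = baseline)
  attr(out, "probe_conc") <- probe_conc
  attr(out, "seed") <- seed
  out
}

#' Simulate a set of 1:1 Langmuir sensorgrams
#'
#' Association/dissociation response curves for a series of analyte
#' concentrations, by default five concentrations spanning geometrically from
#' `kd / 4` to `4 * kd` (centred on the expected dissociation constant, as an
#' SPR kinetic experiment is designed).
#'
#' @param k_on,k_off True rate constants.
#' @param r_max Saturating response, RU.
#' @param conc Optional explicit analyte concentrations, mol/L.
#' @param n_conc Number of concentrations when `conc` is not given.
#' @param t_assoc,t_dissoc Phase durations, s.
#' @param n_per_phase Samples per phase.
#' @param noise_sd,seed Gaussian noise (RU) and seed.
#' @return Long tibble with columns `conc`, `time`, `response`, `phase`;
#'   attributes `"truth"`, `"t_assoc"`, `"t_dissoc"`, `"seed"`.
#' @export
sim_sensorgram_set <- function(k_on, k_off, r_max = 100, conc = NULL,
                               n_conc = 5, t_assoc = 180, t_dissoc = 300,
                               n_per_phase = 120, noise_sd = 0, seed = 1) {
  check_numeric(k_on, "k_on", positive = TRUE, scalar = TRUE)
  check_numeric(k_off, "k_off", positive = TRUE, scalar = TRUE)
  kd <- k_off / k_on
  if (is.null(conc)) {
    conc <- exp(seq(log(kd / 4), log(4 * kd), length.out = n_conc))
  }
  curves <- purrr::imap(conc, function(ci, i) {
    t <- c(seq(0, t_assoc, length.out = n_per_phase),
           seq(t_assoc, t_assoc + t_dissoc, length.out = n_per_phase + 1)[-1])
    clean <- sensorgram_response(t, k_on, k_off, r_max, ci, t_assoc)
    noise <- with_stream_seed(seed, paste0("spr", i),
                              stats::rnorm(length(t), 0, noise_sd))
    tibble(conc = ci, time = t,
           response = clean + if (noise_sd > 0) noise else 0,
           phase = ifelse(t <= t_assoc, "association", "dissociation"))
  })
  out <- dplyr::bind_rows(curves)
  attr(out, "truth") <- list(k_on = k_on, k_off = k_off, r_max = r_max)
  attr(out, "t_assoc") <- t_assoc
  attr(out, "t_dissoc") <- t_dissoc
  attr(out, "seed") <- seed
  out
}

# ratio bands used both by the generator and by the classifier
elisa_bands <- list(
  low = c(0.5, 2), medium = c(3, 6), high = c(8, 16)
)

#' Simulate an ELISA off-rate screening panel
#'
#' Reference (parent) signal plus variant signals whose competitor-condition
#' ratio to the reference is drawn uniformly within the requested affinity
#' band: low in `[0.5, 2)`, medium in `[3, 6]`, high in `[8, 16]`. Buffer
#' condition ratios are drawn compressed towards 1 (square root of the
#' competitor ratio), mimicking the weaker differentiation seen without a
#' rebinding trap.
#'
#' @param categories Named character vector, variant id -> `"low"`,
#'   `"medium"` or `"high"`.
#' @param reference Reference variant id (added automatically, ratio 1).
#' @param reference_signal Reference competitor-condition signal, a.u.
#' @param replicates Replicate count per variant and condition.
#' @param noise_sd Gaussian noise sd, fraction of the reference signal.
#' @param seed Integer seed.
#' @return Tibble with columns `variant`, `condition` (`"buffer"` /
#'   `"competitor"`), `replicate`, `signal`; attributes `"reference"`,
#'   `"true_categories"`, `"seed"`.
#' @export
sim_elisa_panel <- function(categories, reference = "parent",
                            reference_signal = 0.1, replicates = 2,
                            noise_sd = 0, seed = 1) {
  if (is.null(names(categories)) || any(names(categories) == "")) {
    abort("`categories` must be a named vector of variant ids")
  }
  bad <- setdiff(unique(categories), names(elisa_bands))
  if (length(bad)) abort(sprintf("unknown affinity category: %s",
                                 paste(bad, collapse = ", ")))
  with_stream_seed(seed, "elisa", {
    ratios <- purrr::map_dbl(unname(categories), function(cat) {
      b <- elisa_bands[[cat]]
      stats::runif(1, b[1], b[2])
    })
    variants <- c(reference, names(categories))
    comp_ratio <- c(1, ratios)
    buff_ratio <- sqrt(comp_ratio)
    rows <- purrr::pmap(list(variants, comp_ratio, buff_ratio),
      function(v, rc, rb) {
        tidyr::expand_grid(variant = v,
                           condition = c("buffer", "competitor"),
                           replicate = seq_len(replicates)) |>
          dplyr::mutate(signal = ifelse(.data$condition == "competitor",
                                        rc, rb) * reference_signal +
                          stats::rnorm(dplyr::n(), 0,
                                       noise_sd * reference_signal))
      })
    out <- dplyr::bind_rows(rows)
    out$signal <- pmax(out$signal, 0)
    attr(out, "reference") <- reference
    attr(out, "true_categories") <- categories
    attr(out, "seed") <- seed
    out
  })
}
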