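test_that("exact mono-exponential traces are recovered to machine precision", {
  tr <- sim_chase_trace(k_off = 1.49, baseline = 0.2, amplitude = 1)
  f <- fit_monoexponential(tr, "decay")
  expect_equal(f$estimates[["k_obs"]], 1.49, tolerance = 1e-8)
  expect_equal(f$estimates[["baseline"]], 0.2, tolerance = 1e-8)
  expect_equal(f$estimates[["amplitude"]], 1, tolerance = 1e-8)

  # auto direction detection
  f_auto <- fit_monoexponential(tr)
  expect_equal(f_auto$direction, "decay")
  expect_equal(f_auto$estimates[["k_obs"]], 1.49, tolerance = 1e-8)
})

test_that("mirrored rise and decay transitions give the same rate", {
  k <- 0.5
  t <- seq(0, 12, length.out = 120)
  rise <- tibble::tibble(time = t,
                         signal = exponential_response(t, 0.1, 1, k, "rise"))
  f_rise <- fit_monoexponential(rise, "rise")
  # the mirrored transition: same amplitude and rate, falling instead
  decay <- tibble::tibble(time = t,
                          signal = exponential_response(t, 0.1, 1, k,
                                                        "decay"))
  f_dec <- fit_monoexponential(decay, "decay")
  expect_equal(f_rise$estimates[["k_obs"]], k, tolerance = 1e-8)
  expect_equal(f_dec$estimates[["k_obs"]], f_rise$estimates[["k_obs"]],
               tolerance = 1e-8)
  # and their sum reconstructs a constant signal
  expect_equal(rise$signal + decay$signal, rep(1.2, 120), tolerance = 1e-12)
})

test_that("flat traces raise a no-transition error", {
  t <- seq(0, 5, length.out = 60)
  flat <- tibble::tibble(time = t, signal = rep(0.7, 60))
  expect_error(fit_monoexponential(flat, "decay"), "no transition")
  noisy_flat <- tibble::tibble(
    time = t, signal = 0.7 + withr::with_seed(1, rnorm(60, 0, 0.01)))
  expect_error(fit_monoexponential(noisy_flat, "decay"), "no transition")
})

test_that("short traces trigger the half-life warning", {
  t <- seq(0, 0.5, length.out = 40)  # < 2 half-lives of a 1 1/s decay
  tr <- tibble::tibble(time = t,
                       signal = exponential_response(t, 0, 1, 1, "decay"))
  expect_warning(f <- fit_monoexponential(tr, "decay"), "half-lives")
  expect_true(f$halflife_warning)
})

test_that("the k_obs line yields the association rate constant", {
  conc <- from_nM(c(250, 500, 1000, 2000, 4000))
  k_obs <- 1.30e7 * conc + 1.49
  expect_equal(k_obs, c(4.74, 7.99, 14.49, 27.49, 53.49), tolerance = 1e-12)
  f <- fit_kobs_line(tibble::tibble(conc = conc, k_obs = k_obs))
  expect_equal(f$estimates[["k_on"]], 1.30e7, tolerance = 1e-9)
  expect_equal(f$estimates[["intercept"]], 1.49, tolerance = 1e-9)

  expect_error(fit_kobs_line(tibble::tibble(conc = conc[1:2],
                                            k_obs = k_obs[1:2])),
               "3 distinct")
  expect_error(fit_kobs_line(tibble::tibble(conc = conc,
                                            k_obs = rev(k_obs))),
               "non-physical")
})

test_that("standard-error weighting tames an outlying k_obs", {
  conc <- from_nM(c(250, 500, 1000, 2000, 4000))
  k_obs <- 1.30e7 * conc + 1.49
  k_obs[3] <- k_obs[3] * 10
  se <- rep(0.05, 5)
  se[3] <- 50  # the outlier is known to be unreliable
  f <- fit_kobs_line(tibble::tibble(conc = conc, k_obs = k_obs,
                                    k_obs_se = se))
  expect_true(f$weighted)
  expect_equal(f$estimates[["k_on"]], 1.30e7, tolerance = 0.05)
})

test_that("pseudo-first-order fits of the exact ODE recover k_obs", {
  k_on <- 1.3e7; k_off <- 1.49; probe <- from_nM(50)
  for (excess in c(10, 20, 80)) {
    ligand <- probe * excess
    k_obs_true <- k_on * ligand + k_off
    t <- seq(0, 5 / k_obs_true, length.out = 100)
    traj <- ode_binding(k_on, k_off, probe, ligand, t)
    f <- fit_monoexponential(tibble::tibble(time = t,
                                            signal = traj$complex / probe),
                             "rise")
    expect_equal(f$estimates[["k_obs"]], k_obs_true,
                 tolerance = 0.05 * min(1, 10 / excess))
  }
})

test_that("rate-ratio arithmetic is exact and unit-consistent", {
  r <- kd_from_rates(1.49, 1.30e7, 0.07, 0)
  expect_equal(r$kd, 1.49 / 1.30e7)
  expect_equal(r$kd_se, r$kd * (0.07 / 1.49))
  expect_equal(kd_from_rates(1, 1e6, 0, 0)$kd_se, 0)

  # expressing rates in per-minute units and converting back changes nothing
  r_min <- kd_from_rates(1.49 * 60, 1.30e7 * 60, 0.07 * 60, 0)
  expect_equal(r_min$kd, r$kd)
  expect_equal(r_min$kd_se, r$kd_se)

  expect_error(kd_from_rates(1.49, 0), "positive")
  expect_error(kd_from_rates(1.49, -1e6), "positive")
})

test_that("equilibrium and kinetic dissociation constants are compared fairly", {
  expect_true(kd_consistency(from_nM(127), from_nM(127))$pass)
  expect_equal(kd_consistency(from_nM(127), from_nM(127))$ratio, 1)
  d1 <- kd_consistency(from_nM(127), from_nM(115))
  expect_equal(d1$ratio, 127 / 115, tolerance = 1e-12)
  expect_true(d1$pass)
  far <- kd_consistency(from_nM(300), from_nM(3))
  expect_equal(far$ratio, 100)
  expect_false(far$pass)
})

test_that("the association-series wrapper chains trace fits into k_on", {
  s <- sim_association_series(1.3e7, 1.49, from_nM(50),
                              from_nM(c(250, 500, 1000, 2000, 4000)),
                              noise_sd = 0.005, seed = 8)
  fa <- fit_association_series(s)
  expect_equal(nrow(fa$kobs_table), 5)
  expect_equal(fa$line$estimates[["k_on"]], 1.3e7, tolerance = 0.05)
})

test_that("bootstrap standard errors corroborate the asymptotic ones", {
  tr <- sim_chase_trace(k_off = 1.49, noise_sd = 0.01, seed = 6)
  f <- fit_monoexponential(tr, "decay", bootstrap = TRUE, n_boot = 200,
                           boot_seed = 2)
  expect_true(all(is.finite(f$boot_se)))
  ratio <- f$boot_se[["k_obs"]] / f$se[["k_obs"]]
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)

  tit <- sim_titration(from_nM(127), from_nM(100), noise_sd = 0.01,
                       seed = 6)
  ft <- fit_titration(tit, bootstrap = TRUE, n_boot = 200, boot_seed = 2)
  ratio_kd <- ft$boot_se[["kd"]] / ft$se[["kd"]]
  expect_gt(ratio_kd, 0.5); expect_lt(ratio_kd, 2)

  # seeded: identical reruns give identical bootstrap errors
  ft2 <- fit_titration(tit, bootstrap = TRUE, n_boot = 200, boot_seed = 2)
  expect_identical(ft$boot_se, ft2$boot_se)
})
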