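test_that("generators are pure functions of their seed", {
  a <- sim_titration(from_nM(127), from_nM(100), noise_sd = 0.02, seed = 11)
  b <- sim_titration(from_nM(127), from_nM(100), noise_sd = 0.02, seed = 11)
  expect_identical(a, b)
  c <- sim_titration(from_nM(127), from_nM(100), noise_sd = 0.02, seed = 12)
  expect_false(identical(a$dfluo, c$dfluo))

  s1 <- sim_sensorgram_set(1.9e6, 0.0025, noise_sd = 1, seed = 4)
  s2 <- sim_sensorgram_set(1.9e6, 0.0025, noise_sd = 1, seed = 4)
  expect_identical(s1, s2)

  p1 <- sim_elisa_panel(c(x = "high"), seed = 9, noise_sd = 0.02)
  p2 <- sim_elisa_panel(c(x = "high"), seed = 9, noise_sd = 0.02)
  expect_identical(p1, p2)
})

test_that("noise-free outputs lie exactly on the model evaluators", {
  tit <- sim_titration(from_nM(127), from_nM(100), fmax = 2, seed = 1)
  expect_equal(tit$dfluo,
               isotherm_response(tit$conc, from_nM(127), 2, from_nM(100)))

  ch <- sim_chase_trace(k_off = 1.49, baseline = 0.1, amplitude = 0.9)
  expect_equal(ch$signal,
               exponential_response(ch$time, 0.1, 0.9, 1.49, "decay"))

  ss <- sim_sensorgram_set(1.9e6, 0.0025, r_max = 80, seed = 2)
  one <- ss[ss$conc == max(ss$conc), ]
  expect_equal(one$response,
               sensorgram_response(one$time, 1.9e6, 0.0025, 80,
                                   max(ss$conc), attr(ss, "t_assoc")))
})

test_that("titration default design brackets depletion and saturation", {
  tit <- sim_titration(from_nM(127), from_nM(100), seed = 1)
  expect_equal(nrow(tit), 12)
  expect_equal(min(tit$conc), from_nM(100) / 10)
  expect_equal(max(tit$conc), 20 * from_nM(127))
  # probe-dominated case: upper end expands to 5x the probe instead
  tit2 <- sim_titration(from_nM(1), from_nM(100), seed = 1)
  expect_equal(max(tit2$conc), 5 * from_nM(100))
})

test_that("association series enforces the pseudo-first-order excess", {
  expect_error(
    sim_association_series(1e7, 1, from_nM(50), from_nM(80)),
    "pseudo-first-order")
  expect_warning(
    sim_association_series(1e7, 1, from_nM(50), from_nM(150)),
    "5x")
  expect_silent(
    sim_association_series(1e7, 1, from_nM(50), from_nM(250)))
})

test_that("association trace rates follow k_obs = k_on[T] + k_off", {
  # with k_off = 0 the observed rate is purely associative
  s <- sim_association_series(1.3e7, 0, from_nM(50), from_nM(1000))
  f <- fit_monoexponential(s[s$trace == 1, ], "rise")
  expect_equal(f$estimates[["k_obs"]], 1.3e7 * from_nM(1000),
               tolerance = 1e-6)

  # exact ODE mode agrees with the closed form at large excess
  s_ode <- sim_association_series(1.3e7, 1.49, from_nM(10), from_nM(2000),
                                  method = "ode")
  s_cf <- sim_association_series(1.3e7, 1.49, from_nM(10), from_nM(2000))
  expect_equal(s_ode$signal, s_cf$signal, tolerance = 5e-3)
})

test_that("sensorgram sets span the dissociation constant and saturate", {
  ss <- sim_sensorgram_set(1.9e6, 0.0025, r_max = 100, seed = 1)
  kd <- 0.0025 / 1.9e6
  expect_equal(length(unique(ss$conc)), 5)
  expect_equal(range(unique(ss$conc)), c(kd / 4, 4 * kd), tolerance = 1e-9)

  # at strongly saturating analyte the plateau approaches r_max
  sat <- sim_sensorgram_set(1.9e6, 0.0025, r_max = 100,
                            conc = 100 * kd, t_assoc = 3600)
  expect_equal(max(sat$response), 100, tolerance = 2e-2)

  # a short association window leaves the plateau unreached
  short <- extract_plateaus(sim_sensorgram_set(1.2e6, 0.0041, r_max = 100,
                                               t_assoc = 60, seed = 1))
  long <- extract_plateaus(sim_sensorgram_set(1.2e6, 0.0041, r_max = 100,
                                              t_assoc = 3000, seed = 1))
  expect_true(any(short$still_rising))
  expect_false(any(long$still_rising))
})

test_that("ELISA panels draw ratios inside the requested affinity bands", {
  for (seed in 1:20) {
    p <- sim_elisa_panel(c(a = "low", b = "medium", c = "high"), seed = seed)
    comp <- p[p$condition == "competitor", ]
    ref <- mean(comp$signal[comp$variant == "parent"])
    r <- vapply(c("a", "b", "c"),
                function(v) mean(comp$signal[comp$variant == v]) / ref,
                numeric(1))
    expect_true(r[["a"]] >= 0.5 && r[["a"]] < 2)
    expect_true(r[["b"]] >= 3 && r[["b"]] <= 6)
    expect_true(r[["c"]] >= 8)
  }
  expect_error(sim_elisa_panel(c(a = "super")), "unknown affinity category")
})

test_that("generated metadata round-trips through the CSV writers", {
  dir <- withr::local_tempdir()

  tit <- sim_titration(from_nM(127), from_nM(100), noise_sd = 0.01, seed = 3)
  f <- file.path(dir, "tit.csv")
  write_titration_csv(tit, f, label = "parent")
  back <- read_titration_csv(f)
  expect_equal(back$conc, tit$conc)
  expect_equal(back$dfluo, tit$dfluo)
  expect_equal(attr(back, "probe_conc"), from_nM(100))
  expect_equal(attr(back, "truth")$kd, from_nM(127))
  expect_equal(attr(back, "seed"), 3)
  expect_equal(attr(back, "label"), "parent")

  ch <- sim_chase_trace(1.49, noise_sd = 0.01, seed = 4)
  f2 <- file.path(dir, "chase.csv")
  write_trace_csv(ch, f2, ligand_conc = from_nM(500))
  back2 <- read_trace_csv(f2)
  expect_equal(back2$signal, ch$signal)
  expect_equal(attr(back2, "ligand_conc"), from_nM(500))

  ss <- sim_sensorgram_set(1.9e6, 0.0025, noise_sd = 0.5, seed = 5)
  f3 <- file.path(dir, "spr.csv")
  write_sensorgram_csv(ss, f3)
  back3 <- read_sensorgram_csv(f3)
  expect_equal(back3$response, ss$response)
  expect_equal(attr(back3, "t_assoc"), attr(ss, "t_assoc"))
  expect_equal(back3$phase, ss$phase)

  p <- sim_elisa_panel(c(a = "medium"), seed = 6, noise_sd = 0.01)
  f4 <- file.path(dir, "elisa.csv")
  write_elisa_csv(p, f4)
  back4 <- read_elisa_csv(f4)
  expect_equal(back4$signal, p$signal)
  expect_equal(attr(back4, "reference"), "parent")
})

test_that("toy complex realises its designed geometry exactly", {
  tc <- sim_toy_complex(seed = 7, motif_rotation_deg = 25,
                        clash_count_target = 5, interface_pairs = 3,
                        interface_distance = 3.5)
  body_sel <- atom_selection(chain = "D", resno = tc$body_resno)
  motif_sel <- atom_selection(chain = "D", resno = tc$motif_resno)

  # cap rotation recovered to numerical precision
  mr <- motif_rotation(tc$reference, tc$complexed, body_sel, motif_sel)
  expect_equal(mr$angle_deg, 25, tolerance = 1e-6)

  # zero rotation gives zero angle
  tc0 <- sim_toy_complex(seed = 7, motif_rotation_deg = 0)
  mr0 <- motif_rotation(tc0$reference, tc0$complexed, body_sel, motif_sel)
  expect_lt(mr0$angle_deg, 1e-5)

  # the unrotated cap makes exactly the designed number of sub-2 A
  # contacts, all relieved in the rotated (complexed) state
  motif_ref <- structure_model(select_atoms(tc$reference, motif_sel))
  receptor <- structure_model(select_atoms(tc$reference,
                                           atom_selection(chain = "T")))
  clashes <- count_close_contacts(motif_ref, receptor, tc$clash_threshold)
  expect_equal(nrow(clashes), 5)
  binder_rot <- structure_model(select_atoms(tc$complexed,
                                             atom_selection(chain = "D")))
  expect_equal(nrow(count_close_contacts(binder_rot, receptor,
                                         tc$clash_threshold)), 0)

  # the designed interface pairs appear at 3.5 A and vanish at 4.5 A
  ir <- interface_residues(tc$complexed, atom_selection(chain = "T"),
                           atom_selection(chain = "D"), cutoff = 4)
  designed <- tc$body_resno[seq_len(3)]
  expect_true(all(designed %in% ir$residues_b$resno))
  tc_far <- sim_toy_complex(seed = 7, motif_rotation_deg = 25,
                            clash_count_target = 0, interface_pairs = 3,
                            interface_distance = 4.5)
  ir_far <- interface_residues(tc_far$complexed, atom_selection(chain = "T"),
                               atom_selection(chain = "D"), cutoff = 4)
  expect_false(any(designed %in% ir_far$residues_b$resno))

  expect_error(sim_toy_complex(motif_rotation_deg = 190), "180")
})
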