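make_struct <- function(xyz, chain = "A", atom = "CA", element = "C",
                        b = 30, occ = 1) {
  structure_model(data.frame(
    chain = chain, resno = seq_len(nrow(xyz)), resid = "GLY", atom = atom,
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = occ, b = b))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("PDB files round-trip through the writer and reader", {
  tc <- sim_toy_complex(seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tc$complexed, f)
  back <- read_structure(f)
  a0 <- dplyr::arrange(tc$complexed$atoms, chain, resno, atom)
  a1 <- dplyr::arrange(back$atoms, chain, resno, atom)
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1$x, a0$x, tolerance = 1e-3)
  expect_equal(a1$b, a0$b, tolerance = 1e-2)
  expect_equal(a1$chain, a0$chain)
  expect_equal(a1$element, a0$element)
})

test_that("minimal fixed-column records parse exactly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134   2.500  1.00 20.50           N",
    "ATOM      2  CA  ALA A   1      12.560   6.351   2.478  1.00 21.25           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(11.104, 12.560))
  expect_equal(s$atoms$b, c(20.50, 21.25))
  expect_equal(s$atoms$element, c("N", "C"))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AARG A 118      10.000   0.000   0.000  0.60 20.00           C",
    "ATOM      2  CA BARG A 118      12.000   0.000   0.000  0.40 20.00           C",
    "ATOM      3  CB AARG A 118      10.500   1.000   0.000  0.50 20.00           C",
    "ATOM      4  CB BARG A 118      12.500   1.000   0.000  0.50 20.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2)
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_equal(ca$x, 10.0)        # occupancy 0.6 beats 0.4
  cb <- s$atoms[s$atoms$atom == "CB", ]
  expect_equal(cb$altloc, "A")    # occupancy tie broken alphabetically
  expect_equal(attr(s, "altloc_discarded"), 2)
})

test_that("unreadable coordinate files produce a parse error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a coordinate file", f)
  expect_error(read_structure(f), "parse|PDB")
  expect_error(read_structure("/nonexistent/file.pdb"), "no such file")
})

test_that("superposition recovers exact rigid transforms", {
  withr::with_seed(10, {
    xyz <- matrix(rnorm(60, sd = 8), ncol = 3)
    ref <- make_struct(xyz)
    expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
    expect_equal(superpose(ref, ref)$angle_deg, 0, tolerance = 1e-9)

    # constructed 25 degree rotation plus translation
    th <- 25 * pi / 180
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    mob <- make_struct(sweep(xyz %*% t(R), 2, c(5, -3, 11), "+"))
    sp <- superpose(mob, ref)
    expect_equal(sp$angle_deg, 25, tolerance = 1e-9)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-12)

    # applying the returned transform aligns the mobile structure
    aligned <- apply_transform(mob, sp)
    expect_equal(aligned$atoms$x, ref$atoms$x, tolerance = 1e-9)
  })
  expect_error(superpose(make_struct(matrix(rnorm(6), 2, 3)),
                         make_struct(matrix(rnorm(6), 2, 3))),
               "at least 3")
})

test_that("reflection-optimal cases are corrected to a proper rotation", {
  withr::with_seed(11, {
    xyz <- matrix(rnorm(45, sd = 5), ncol = 3)
    mirrored <- xyz
    mirrored[, 1] <- -mirrored[, 1]
    sp <- superpose(make_struct(mirrored), make_struct(xyz))
    expect_equal(det(sp$rotation), 1, tolerance = 1e-12)
    expect_gt(sp$rmsd, 0)  # a true reflection cannot be matched exactly
  })
})

test_that("superposition is invariant under a common rigid transform", {
  withr::with_seed(12, {
    xyz_a <- matrix(rnorm(90, sd = 10), ncol = 3)
    xyz_b <- xyz_a + matrix(rnorm(90, sd = 0.8), ncol = 3)
    base <- superpose(make_struct(xyz_a), make_struct(xyz_b))
    for (i in 1:5) {
      R <- random_rotation()
      t_vec <- rnorm(3, sd = 20)
      move <- function(m) sweep(m %*% t(R), 2, t_vec, "+")
      sp <- superpose(make_struct(move(xyz_a)), make_struct(move(xyz_b)))
      expect_equal(sp$rmsd, base$rmsd, tolerance = 1e-9)
      expect_equal(sp$angle_deg, base$angle_deg, tolerance = 1e-6)
    }
  })
})

test_that("superposition rmsd agrees with the bio3d reference fit", {
  withr::with_seed(13, {
    xyz_a <- matrix(rnorm(75, sd = 10), ncol = 3)
    xyz_b <- xyz_a + matrix(rnorm(75, sd = 1), ncol = 3)
    sp <- superpose(make_struct(xyz_a), make_struct(xyz_b))
    rr <- bio3d::rot.lsq(xx = as.vector(t(xyz_a)), yy = as.vector(t(xyz_b)))
    rmsd_bio3d <- sqrt(mean(rowSums(
      (matrix(rr, ncol = 3, byrow = TRUE) - xyz_b)^2)))
    expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-6)
  })
})

test_that("motif rotation isolates the cap movement from the global fit", {
  tc <- sim_toy_complex(seed = 21, motif_rotation_deg = 73.2)
  mr <- motif_rotation(tc$reference, tc$complexed,
                       atom_selection(chain = "D", resno = tc$body_resno),
                       atom_selection(chain = "D", resno = tc$motif_resno))
  expect_equal(mr$angle_deg, 73.2, tolerance = 1e-6)
  # identical structures give zero rotation
  mr0 <- motif_rotation(tc$reference, tc$reference,
                        atom_selection(chain = "D", resno = tc$body_resno),
                        atom_selection(chain = "D", resno = tc$motif_resno))
  expect_lt(mr0$angle_deg, 1e-9)
})

test_that("cell-list neighbour search equals the all-pairs scan", {
  for (seed in 1:100) {
    cl <- random_cloud_structures(seed, n_a = 35, n_b = 25)
    cutoff <- withr::with_seed(seed * 7, runif(1, 1, 8))
    rep <- interface_residues(structure_model(
      dplyr::bind_rows(cl$a$atoms, cl$b$atoms)),
      atom_selection(chain = "A"), atom_selection(chain = "B"),
      cutoff = cutoff)
    bf <- brute_force_pairs(cbind(cl$a$atoms$x, cl$a$atoms$y, cl$a$atoms$z),
                            cbind(cl$b$atoms$x, cl$b$atoms$y, cl$b$atoms$z),
                            cutoff)
    expect_equal(nrow(rep$pairs), nrow(bf))
    expect_setequal(paste(rep$pairs$resno_a, rep$pairs$resno_b),
                    paste(bf$ia, bf$ib))
    expect_setequal(unique(rep$residues_a$resno), unique(bf$ia))
  }
})

test_that("interface analysis rejects overlapping sides and far chains", {
  tc <- sim_toy_complex(seed = 5)
  expect_error(interface_residues(tc$complexed,
                                  atom_selection(chain = "D"),
                                  atom_selection(chain = "D")),
               "disjoint")
  far_a <- make_struct(matrix(rnorm(30), ncol = 3), chain = "A")
  far_b <- make_struct(matrix(rnorm(30) + 100, ncol = 3), chain = "B")
  both <- structure_model(dplyr::bind_rows(far_a$atoms, far_b$atoms))
  rep <- interface_residues(both, atom_selection(chain = "A"),
                            atom_selection(chain = "B"))
  expect_equal(nrow(rep$pairs), 0)
  expect_equal(nrow(rep$residues_a), 0)
})

test_that("close-contact enumeration is exact and ordered", {
  tc <- sim_toy_complex(seed = 8, clash_count_target = 5)
  motif <- structure_model(select_atoms(
    tc$reference, atom_selection(chain = "D", resno = tc$motif_resno)))
  receptor <- structure_model(select_atoms(tc$reference,
                                           atom_selection(chain = "T")))
  cc <- count_close_contacts(motif, receptor, 2)
  expect_equal(nrow(cc), 5)
  expect_true(all(diff(cc$dist) >= 0))
  expect_true(all(cc$dist <= 2))
  expect_equal(nrow(count_close_contacts(motif, receptor, 0)), 0)
})

test_that("solvent-accessible areas match analytic and grid references", {
  carbon <- make_struct(matrix(0, 1, 3), atom = "C1")
  total <- attr(compute_sasa(carbon), "total")
  expect_equal(total, 4 * pi * 3.1^2, tolerance = 2e-3)
  expect_equal(4 * pi * 3.1^2, 120.76, tolerance = 1e-4)

  # well separated atoms are each fully accessible
  far <- make_struct(rbind(c(0, 0, 0), c(50, 0, 0), c(0, 60, 0)))
  tot_far <- attr(compute_sasa(far), "total")
  expect_equal(tot_far, 3 * 4 * pi * 3.1^2, tolerance = 1e-3)

  # fused carbon-nitrogen pair against the independent quadrature oracle
  d <- 2.0
  pair <- structure_model(data.frame(
    chain = "A", resno = 1:2, resid = "GLY", atom = c("C", "N"),
    element = c("C", "N"), x = c(0, d), y = 0, z = 0, occ = 1, b = 0))
  got <- compute_sasa(pair)
  centres <- rbind(c(0, 0, 0), c(d, 0, 0))
  radii <- c(1.7, 1.55) + 1.4
  expect_equal(got$sasa[got$atom == "C"],
               grid_sasa(centres, radii, 1), tolerance = 0.01)
  expect_equal(got$sasa[got$atom == "N"],
               grid_sasa(centres, radii, 2), tolerance = 0.01)

  # hydrogens are excluded, unknown elements fall back with a warning
  with_h <- structure_model(data.frame(
    chain = "A", resno = 1, resid = "GLY", atom = c("C", "H1"),
    element = c("C", "H"), x = c(0, 1), y = 0, z = 0, occ = 1, b = 0))
  expect_equal(attr(compute_sasa(with_h), "total"), 4 * pi * 3.1^2,
               tolerance = 2e-3)
  odd <- make_struct(matrix(0, 1, 3), element = "X")
  expect_warning(compute_sasa(odd), "van der Waals")
})

test_that("buried surface area is symmetric and shrinks with separation", {
  mk_pair <- function(offset) {
    a <- data.frame(chain = "A", resno = 1:4, resid = "GLY",
                    atom = "C", element = "C",
                    x = c(0, 1.6, 3.2, 4.8), y = 0, z = 0, occ = 1, b = 0)
    b <- a
    b$chain <- "B"
    b$y <- offset
    structure_model(rbind(a, b))
  }
  sel_a <- atom_selection(chain = "A")
  sel_b <- atom_selection(chain = "B")

  far <- buried_surface(mk_pair(100), sel_a, sel_b)
  expect_lt(abs(far), 0.5)

  bsa <- vapply(c(3, 4.5, 6, 8), function(off) {
    buried_surface(mk_pair(off), sel_a, sel_b)
  }, numeric(1))
  expect_true(all(diff(bsa) <= 1e-6))
  expect_gt(bsa[1], 0)

  # symmetry in the two parts
  cx <- mk_pair(3.5)
  expect_equal(buried_surface(cx, sel_a, sel_b),
               buried_surface(cx, sel_b, sel_a), tolerance = 1e-9)

  # two-sphere complex against the quadrature oracle
  pair <- structure_model(data.frame(
    chain = c("A", "B"), resno = 1:2, resid = "GLY", atom = "C",
    element = "C", x = c(0, 2.5), y = 0, z = 0, occ = 1, b = 0))
  got <- buried_surface(pair, sel_a, sel_b)
  centres <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  radii <- c(3.1, 3.1)
  iso <- 4 * pi * 3.1^2
  oracle <- (iso - grid_sasa(centres, radii, 1)) +
            (iso - grid_sasa(centres, radii, 2))
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("region B-factor means are occupancy-weighted", {
  s <- make_struct(matrix(rnorm(30), ncol = 3), b = 50)
  expect_equal(region_mean_bfactor(s), 50)

  two <- structure_model(data.frame(
    chain = "A", resno = 1:2, resid = "GLY", atom = "CA", element = "C",
    x = c(0, 5), y = 0, z = 0, occ = 1, b = c(10, 30)))
  expect_equal(region_mean_bfactor(two), 20)

  part <- structure_model(data.frame(
    chain = "A", resno = 1:2, resid = "GLY", atom = "CA", element = "C",
    x = c(0, 5), y = 0, z = 0, occ = c(1, 0.5), b = c(10, 30)))
  expect_equal(region_mean_bfactor(part), (10 + 15) / 1.5)

  expect_error(region_mean_bfactor(two, atom_selection(chain = "Z")),
               "zero atoms")

  # the toy complex carries its two-level B-factor design
  tc <- sim_toy_complex(seed = 2)
  b_cap <- region_mean_bfactor(tc$complexed,
                               atom_selection(chain = "D",
                                              resno = tc$motif_resno))
  b_body <- region_mean_bfactor(tc$complexed,
                                atom_selection(chain = "D",
                                               resno = tc$body_resno))
  expect_equal(b_cap, 75, tolerance = 0.1)
  expect_equal(b_body, 47, tolerance = 0.1)
})
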