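# Independent oracles used to validate the package's implementations.
# These deliberately use different algorithms from the code under test.

# all-pairs O(n*m) neighbour scan (reference for the cell-list search)
brute_force_pairs <- function(xyzA, xyzB, cutoff) {
  hits <- NULL
  for (i in seq_len(nrow(xyzA))) {
    d <- sqrt(colSums((t(xyzB) - xyzA[i, ])^2))
    j <- which(d <= cutoff)
    if (length(j)) hits <- rbind(hits, cbind(ia = i, ib = j, dist = d[j]))
  }
  if (is.null(hits)) {
    data.frame(ia = integer(), ib = integer(), dist = numeric())
  } else {
    as.data.frame(hits)
  }
}

# latitude-longitude quadrature of the accessible area of sphere `i` in a
# set of extended spheres (centres n x 3, extended radii length n)
grid_sasa <- function(centres, radii_ext, i, n_theta = 400, n_phi = 800) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- expand.grid(th = th, ph = ph)
  R <- radii_ext[i]
  px <- centres[i, 1] + R * sin(grid$th) * cos(grid$ph)
  py <- centres[i, 2] + R * sin(grid$th) * sin(grid$ph)
  pz <- centres[i, 3] + R * cos(grid$th)
  outside <- rep(TRUE, nrow(grid))
  for (j in seq_len(nrow(centres))) {
    if (j == i) next
    d2 <- (px - centres[j, 1])^2 + (py - centres[j, 2])^2 +
          (pz - centres[j, 3])^2
    outside <- outside & d2 >= radii_ext[j]^2
  }
  w <- sin(grid$th) * (pi / n_theta) * (2 * pi / n_phi)
  R^2 * sum(w[outside])
}

# equilibrium bound fraction by root bracketing (independent of the
# closed-form quadratic)
equilibrium_complex_uniroot <- function(probe_total, ligand_total, kd) {
  f <- function(ab) {
    (probe_total - ab) * (ligand_total - ab) - kd * ab
  }
  stats::uniroot(f, c(0, min(probe_total, ligand_total)),
                 tol = 1e-18)$root
}

# random point-cloud structure pair for neighbour-search property tests
random_cloud_structures <- function(seed, n_a = 40, n_b = 30, spread = 20) {
  withr::with_seed(seed, {
    mk <- function(chain, n) {
      structure_model(data.frame(
        chain = chain, resno = seq_len(n), resid = "GLY",
        atom = "CA", element = "C",
        x = runif(n, 0, spread), y = runif(n, 0, spread),
        z = runif(n, 0, spread), occ = 1, b = 30))
    }
    list(a = mk("A", n_a), b = mk("B", n_b))
  })
}

table1_fluorescence <- function() {
  df <- reference_rate_constants()
  df[df$method == "fluorescence", ]
}
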