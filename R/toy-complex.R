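#' Generate a toy receptor-binder complex with known geometry
#'
#' Builds a miniature two-chain system mirroring the geometry problem of a
#' repeat-protein capping motif that must rotate to avoid clashing with its
#' target. The construction is fully specified, so every geometric quantity
#' the package measures has an exact known value:
#'
#' * chain `"T"` (receptor): backbone pseudo-atoms along the x axis, plus
#'   `clash_count_target` probe atoms placed 1.2 Angstrom (along -z) from cap
#'   atoms *in the unrotated state*;
#' * chain `"D"` (binder): a body of residues at 8 Angstrom from the
#'   receptor, `interface_pairs` of which carry an atom exactly
#'   `interface_distance` from a receptor atom, and a contiguous C-terminal
#'   cap motif of alpha carbons on a circle of radius 5 Angstrom about a
#'   recorded axis;
#' * the complexed state has the cap rigidly rotated by exactly
#'   `motif_rotation_deg` about that axis, which carries every probed cap
#'   atom more than 2 Angstrom from its probe (for rotations above about
#'   19 degrees; smaller rotations leave residual clashes and raise a
#'   warning).
#'
#' B-factors are two-level (cap near 75, body near 47, receptor near 30,
#' Angstrom^2) with seed-controlled jitter, for B-factor statistics tests.
#'
#' @param seed Integer seed for the (small, non-critical) coordinate and
#'   B-factor jitter.
#' @param motif_rotation_deg Cap rotation in the complexed state, degrees in
#'   `[0, 180)`.
#' @param clash_count_target Number of receptor-cap atom pairs placed under
#'   2 Angstrom in the unrotated state (at most 6).
#' @param interface_pairs Number of binder body residues touching the
#'   receptor at `interface_distance` (at most 12).
#' @param interface_distance Contact distance for the designed interface
#'   pairs, Angstrom (> 2 to stay clear of the clash threshold).
#' @return A list of class `toy_complex`: `complexed` and `reference`
#'   `structure_model`s (binder cap rotated / unrotated, same receptor),
#'   `motif_resno` (cap residue numbers), `body_resno`, `axis` (unit vector),
#'   `axis_point`, `angle_deg`, `clash_threshold` (2 Angstrom), plus the
#'   generator arguments.
#' @export
sim_toy_complex <- function(seed = 1, motif_rotation_deg = 25,
                            clash_count_target = 5, interface_pairs = 3,
                            interface_distance = 3.5) {
  if (motif_rotation_deg < 0 || motif_rotation_deg >= 180) {
    abort("`motif_rotation_deg` must lie in [0, 180)")
  }
  if (interface_distance <= 2) abort("`interface_distance` must exceed 2 A")
  n_rec <- 24L
  n_body <- 12L
  n_motif <- 6L
  if (clash_count_target > n_motif) {
    abort(sprintf("`clash_count_target` must be at most %d", n_motif))
  }
  if (interface_pairs > n_body) {
    abort(sprintf("`interface_pairs` must be at most %d", n_body))
  }
  body_resno <- 101:(100 + n_body)
  motif_resno <- (100 + n_body + 1):(100 + n_body + n_motif)

  jit <- with_stream_seed(seed, "toy", {
    list(b_body = stats::rnorm(n_body, 0, 2),
         b_motif = stats::rnorm(n_motif, 0, 2),
         b_rec = stats::rnorm(n_rec + clash_count_target, 0, 2),
         ang = stats::runif(n_motif, -4, 4),       # degrees, on the circle
         z = stats::rnorm(n_motif, 0, 0.3))
  })

  # receptor backbone along x at the origin plane
  rec <- tibble(
    chain = "T", resno = seq_len(n_rec), resid = "GLY", atom = "CA",
    element = "C",
    x = seq_len(n_rec) * 3.8, y = 0, z = 0,
    occ = 1, b = pmax(30 + jit$b_rec[seq_len(n_rec)], 1)
  )

  # binder body at y = 8, comfortably outside any contact cutoff
  body <- tibble(
    chain = "D", resno = body_resno, resid = "ALA", atom = "CA",
    element = "C",
    x = seq_len(n_body) * 3.8 + 1.9, y = 8, z = 0,
    occ = 1, b = pmax(47 + jit$b_body, 1)
  )

  # designed interface: selected body residues get a side-chain atom exactly
  # `interface_distance` above a receptor alpha carbon
  if (interface_pairs > 0) {
    iface <- tibble(
      chain = "D", resno = body_resno[seq_len(interface_pairs)],
      resid = "ALA", atom = "CG", element = "C",
      x = seq_len(interface_pairs) * 3.8, y = interface_distance, z = 0,
      occ = 1, b = 47
    )
    body <- dplyr::bind_rows(body, iface)
  }

  # cap motif: alpha carbons on a circle of radius 5 A about the axis
  # (direction z) through `axis_point`, well separated from body and receptor
  axis_point <- c((n_body + 4) * 3.8, 9.5, 0)
  radius <- 5
  ang <- rad(seq(0, 300, length.out = n_motif) + jit$ang)
  motif <- tibble(
    chain = "D", resno = motif_resno, resid = "ALA", atom = "CA",
    element = "C",
    x = axis_point[1] + radius * cos(ang),
    y = axis_point[2] + radius * sin(ang),
    z = axis_point[3] + jit$z,
    occ = 1, b = pmax(75 + jit$b_motif, 1)
  )

  th <- rad(motif_rotation_deg)
  Rz <- matrix(c(cos(th), -sin(th), 0,
                 sin(th),  cos(th), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  rot_xyz <- sweep(as.matrix(motif[, c("x", "y", "z")]), 2, axis_point)
  rot_xyz <- sweep(rot_xyz %*% t(Rz), 2, axis_point, "+")
  motif_rotated <- motif
  motif_rotated$x <- rot_xyz[, 1]
  motif_rotated$y <- rot_xyz[, 2]
  motif_rotated$z <- rot_xyz[, 3]

  # clash probes: receptor atoms 1.2 A below (in z) unrotated cap atoms;
  # the in-plane displacement of a cap atom under the rotation is
  # 2 * radius * sin(theta / 2), so the rotated distance is
  # sqrt(displacement^2 + 1.2^2) and exceeds 2 A once theta > ~19 deg
  clash_threshold <- 2
  if (clash_count_target > 0) {
    disp <- 2 * radius * sin(th / 2)
    if (motif_rotation_deg > 0 &&
        sqrt(disp^2 + 1.2^2) <= clash_threshold) {
      warn("motif rotation too small to fully relieve the constructed clashes")
    }
    targets <- motif[seq_len(clash_count_target), ]
    probes <- tibble(
      chain = "T", resno = n_rec + seq_len(clash_count_target),
      resid = "GLY", atom = "CG", element = "C",
      x = targets$x, y = targets$y, z = targets$z - 1.2,
      occ = 1,
      b = pmax(30 + jit$b_rec[n_rec + seq_len(clash_count_target)], 1)
    )
    rec <- dplyr::bind_rows(rec, probes)
  }

  reference <- structure_model(dplyr::bind_rows(rec, body, motif),
                               title = "toy complex, cap unrotated")
  complexed <- structure_model(dplyr::bind_rows(rec, body, motif_rotated),
                               title = "toy complex, cap rotated")
  structure(list(complexed = complexed, reference = reference,
                 motif_resno = motif_resno, body_resno = body_resno,
                 receptor_chain = "T", binder_chain = "D",
                 axis = c(0, 0, 1), axis_point = axis_point,
                 angle_deg = motif_rotation_deg,
                 clash_threshold = clash_threshold,
                 clash_count_target = clash_count_target,
                 interface_pairs = interface_pairs,
                 interface_distance = interface_distance, seed = seed),
            class = "toy_complex")
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf(
    "<toy_complex> cap rotation %.1f deg, %d designed clashes, %d interface pairs (seed %d)\n",
    x$angle_deg, x$clash_count_target, x$interface_pairs, x$seed))
  invisible(x)
}
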