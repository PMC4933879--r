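#' Least-squares rigid-body superposition (Kabsch)
#'
#' Pairs atoms between two structures by residue number and atom name within
#' the given selections (chains may differ between structures; pairing is by
#' `(resno, atom)` identity, with unmatched atoms dropped and counted), then
#' computes the optimal proper rotation and translation minimising the RMSD,
#' via singular value decomposition with the reflection case corrected.
#'
#' The returned transform maps mobile coordinates into the reference frame:
#' `x' = R x + t`. The total rotation angle is
#' \eqn{\arccos((\mathrm{tr}\,R - 1)/2)} in degrees, the standard measure of
#' a domain motion.
#'
#' @param mobile,reference `structure_model` objects.
#' @param sel_mobile,sel_reference [atom_selection()]s resolving to the atoms
#'   to pair (default: all-chain alpha carbons, the usual choice for
#'   whole-molecule superpositions).
#' @return An object of class `superposition`: a list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_atoms`, `angle_deg`,
#'   `axis` (unit vector), `n_dropped`.
#' @export
superpose <- function(mobile, reference,
                      sel_mobile = atom_selection(atoms = "CA"),
                      sel_reference = sel_mobile) {
  am <- select_atoms(mobile, sel_mobile)
  ar <- select_atoms(reference, sel_reference)
  pm <- pair_atoms(am, ar)
  if (nrow(pm$mobile) < 3) {
    abort(sprintf("superposition needs at least 3 paired atoms, got %d",
                  nrow(pm$mobile)))
  }
  P <- xyz_matrix(pm$mobile)
  Q <- xyz_matrix(pm$reference)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cq - R %*% cp)
  resid <- Qc - Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums(resid^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_atoms = nrow(P), angle_deg = rotation_angle(R),
                 axis = rotation_axis(R), n_dropped = pm$n_dropped),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "<superposition> %d atom pairs, rmsd %.3f A, rotation %.2f deg (%d unmatched dropped)\n",
    x$n_atoms, x$rmsd, x$angle_deg, x$n_dropped))
  invisible(x)
}

# pair two atom tables by (resno, atom); chains are matched positionally by
# sorted chain id when both selections span a single chain each, otherwise by
# identical chain id
pair_atoms <- function(am, ar) {
  key_chain <- length(unique(am$chain)) > 1 || length(unique(ar$chain)) > 1
  keym <- if (key_chain) paste(am$chain, am$resno, am$atom)
          else paste(am$resno, am$atom)
  keyr <- if (key_chain) paste(ar$chain, ar$resno, ar$atom)
          else paste(ar$resno, ar$atom)
  if (anyDuplicated(keym) || anyDuplicated(keyr)) {
    am <- am[!duplicated(keym), , drop = FALSE]
    ar <- ar[!duplicated(keyr), , drop = FALSE]
    keym <- keym[!duplicated(keym)]
    keyr <- keyr[!duplicated(keyr)]
  }
  common <- intersect(keym, keyr)
  list(mobile = am[match(common, keym), , drop = FALSE],
       reference = ar[match(common, keyr), , drop = FALSE],
       n_dropped = (length(keym) - length(common)) +
                   (length(keyr) - length(common)))
}

# total rotation angle of a proper rotation matrix, degrees in [0, 180]
rotation_angle <- function(R) {
  deg(acos(clamp((sum(diag(R)) - 1) / 2, -1, 1)))
}

# unit rotation axis (arbitrary for angle 0; stable sign from skew part)
rotation_axis <- function(R) {
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    # angle near 0 or 180; fall back to dominant eigenvector of (R + I)
    ev <- eigen(R + diag(3), symmetric = FALSE)
    v <- Re(ev$vectors[, which.max(abs(Re(ev$values)))])
    n <- sqrt(sum(v^2))
  }
  v / n
}

#' Apply a superposition transform to a structure
#'
#' @param struct A `structure_model`.
#' @param sp A `superposition` (from [superpose()]).
#' @return The transformed `structure_model`.
#' @export
apply_transform <- function(struct, sp) {
  stopifnot(inherits(struct, "structure_model"),
            inherits(sp, "superposition"))
  xyz <- xyz_matrix(struct$atoms) %*% t(sp$rotation)
  xyz <- sweep(xyz, 2, sp$translation, "+")
  out <- struct
  out$atoms$x <- xyz[, 1]
  out$atoms$y <- xyz[, 2]
  out$atoms$z <- xyz[, 3]
  out
}

#' Rotation of a motif relative to a reference frame
#'
#' Measures how much a sub-motif (e.g. the two-helix C-terminal capping
#' repeat of a DARPin) reorients between two structures, independent of the
#' overall placement: structure A is first superposed onto structure B using
#' `reference_sel` (e.g. the N-cap and internal repeats), the transform is
#' applied, and the motif alone is then superposed. The rotation angle of
#' that second fit is the motif rotation.
#'
#' @param struct_a,struct_b `structure_model` objects.
#' @param reference_sel Selection defining the common reference frame.
#' @param motif_sel Selection defining the motif.
#' @return A list with `angle_deg`, `axis`, and the two `superposition`
#'   objects (`reference_fit`, `motif_fit`).
#' @export
motif_rotation <- function(struct_a, struct_b, reference_sel, motif_sel) {
  fit_ref <- superpose(struct_a, struct_b, reference_sel, reference_sel)
  a_aligned <- apply_transform(struct_a, fit_ref)
  fit_motif <- superpose(a_aligned, struct_b, motif_sel, motif_sel)
  list(angle_deg = fit_motif$angle_deg, axis = fit_motif$axis,
       reference_fit = fit_ref, motif_fit = fit_motif)
}

# all inter-set atom pairs within `cutoff`, via spatial binning (cell lists);
# equals the all-pairs brute force (see tests). Returns a tibble of index
# pairs (ia into A, ib into B) with distances.
neighbor_pairs <- function(xyzA, xyzB, cutoff) {
  stopifnot(cutoff > 0)
  nA <- nrow(xyzA)
  nB <- nrow(xyzB)
  if (nA == 0 || nB == 0) {
    return(tibble(ia = integer(), ib = integer(), dist = numeric()))
  }
  cellA <- floor(xyzA / cutoff)
  cellB <- floor(xyzB / cutoff)
  enc <- function(cell) {
    # collision-free integer-triplet key as a string (ranges are unbounded)
    paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  }
  keyB <- enc(cellB)
  B_by_cell <- split(seq_len(nB), keyB)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  hits <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    keyA_k <- enc(sweep(cellA, 2, offsets[k, ], "+"))
    idx <- B_by_cell[keyA_k]
    lens <- lengths(idx)
    if (!any(lens > 0)) next
    ia <- rep.int(seq_len(nA), lens)
    ib <- unlist(idx, use.names = FALSE)
    hits[[k]] <- cbind(ia, ib)
  }
  pairs <- do.call(rbind, hits)
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble(ia = integer(), ib = integer(), dist = numeric()))
  }
  d2 <- rowSums((xyzA[pairs[, 1], , drop = FALSE] -
                 xyzB[pairs[, 2], , drop = FALSE])^2)
  keep <- d2 <= cutoff^2
  tibble(ia = pairs[keep, 1], ib = pairs[keep, 2], dist = sqrt(d2[keep]))
}

#' Interface residues at a distance cutoff
#'
#' Lists the residues of two disjoint parts of a complex that face each other
#' across the interface: a residue is listed iff any of its heavy atoms lies
#' within `cutoff` of any heavy atom of the other side (the conventional
#' 4 Angstrom contact criterion). The neighbour search uses spatial binning
#' and is exactly equivalent to the all-pairs scan.
#'
#' @param complex A `structure_model` holding both sides.
#' @param side_a,side_b Disjoint [atom_selection()]s.
#' @param cutoff Contact distance, Angstrom (default 4.0).
#' @return A list of class `interface_report`: `residues_a`, `residues_b`
#'   (tibbles of chain/resno/resid with contact counts and minimum
#'   distances), `pairs` (atom pairs with distances), `cutoff`.
#' @export
interface_residues <- function(complex, side_a, side_b, cutoff = 4.0) {
  aa <- select_atoms(complex, side_a)
  ab <- select_atoms(complex, side_b)
  overlap <- intersect(paste(aa$chain, aa$resno, aa$atom),
                       paste(ab$chain, ab$resno, ab$atom))
  if (length(overlap)) {
    abort("interface selections overlap; the two sides must be disjoint")
  }
  np <- neighbor_pairs(xyz_matrix(aa), xyz_matrix(ab), cutoff)
  pairs <- tibble(
    chain_a = aa$chain[np$ia], resno_a = aa$resno[np$ia],
    resid_a = aa$resid[np$ia], atom_a = aa$atom[np$ia],
    chain_b = ab$chain[np$ib], resno_b = ab$resno[np$ib],
    resid_b = ab$resid[np$ib], atom_b = ab$atom[np$ib],
    dist = np$dist
  ) |> dplyr::arrange(.data$dist)
  summarise_side <- function(pairs, side) {
    if (nrow(pairs) == 0) {
      return(tibble(chain = character(), resno = integer(),
                    resid = character(), n_contacts = integer(),
                    min_dist = numeric()))
    }
    pairs |>
      dplyr::group_by(chain = .data[[paste0("chain_", side)]],
                      resno = .data[[paste0("resno_", side)]],
                      resid = .data[[paste0("resid_", side)]]) |>
      dplyr::summarise(n_contacts = dplyr::n(),
                       min_dist = min(.data$dist), .groups = "drop") |>
      dplyr::arrange(.data$chain, .data$resno)
  }
  structure(list(residues_a = summarise_side(pairs, "a"),
                 residues_b = summarise_side(pairs, "b"),
                 pairs = pairs, cutoff = cutoff),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(
    "<interface_report> cutoff %.1f A: %d residues | %d residues, %d atom pairs\n",
    x$cutoff, nrow(x$residues_a), nrow(x$residues_b), nrow(x$pairs)))
  invisible(x)
}

#' Enumerate close inter-model contacts (steric clashes)
#'
#' All heavy-atom pairs between two structures closer than `threshold`,
#' sorted by distance. Used to count the clashes a docked (superposed) motif
#' would make with the partner, e.g. an unrotated capping repeat placed into
#' the complex frame.
#'
#' @param struct_a A `structure_model`, already transformed into the frame of
#'   `struct_b` (see [apply_transform()]).
#' @param struct_b A `structure_model`.
#' @param threshold Distance threshold, Angstrom.
#' @param sel_a,sel_b Optional selections (default: all polymer heavy atoms).
#' @return Tibble of contact pairs with distances, sorted ascending.
#' @export
count_close_contacts <- function(struct_a, struct_b, threshold,
                                 sel_a = NULL, sel_b = NULL) {
  check_numeric(threshold, "threshold", non_negative = TRUE, scalar = TRUE)
  if (threshold == 0) {
    return(tibble(chain_a = character(), resno_a = integer(),
                  atom_a = character(), chain_b = character(),
                  resno_b = integer(), atom_b = character(),
                  dist = numeric()))
  }
  aa <- select_atoms(struct_a, sel_a)
  ab <- select_atoms(struct_b, sel_b)
  np <- neighbor_pairs(xyz_matrix(aa), xyz_matrix(ab), threshold)
  tibble(
    chain_a = aa$chain[np$ia], resno_a = aa$resno[np$ia],
    atom_a = aa$atom[np$ia],
    chain_b = ab$chain[np$ib], resno_b = ab$resno[np$ib],
    atom_b = ab$atom[np$ib],
    dist = np$dist
  ) |> dplyr::arrange(.data$dist)
}

#' Occupancy-weighted mean B-factor over a selection
#'
#' @param struct A `structure_model`.
#' @param sel An [atom_selection()].
#' @return Mean atomic displacement parameter, Angstrom^2.
#' @export
region_mean_bfactor <- function(struct, sel = NULL) {
  a <- select_atoms(struct, sel)
  weighted.mean(a$b, w = a$occ)
}
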