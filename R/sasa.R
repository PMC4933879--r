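# Bondi-style van der Waals radii (Angstrom) used for SASA
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
vdw_default <- 1.70

# deterministic, quasi-uniform unit sphere point set (Fibonacci / golden
# spiral); the same point set is reused for every atom, making the SASA a
# pure function of coordinates, radii and n
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible surface by deterministic sphere sampling: each atom is
#' surrounded by a quasi-uniform point shell at radius `r_vdw + probe`, and
#' the accessible area is the sphere area times the fraction of points not
#' buried inside any neighbour's extended sphere. Waters and hydrogens are
#' excluded. Radii: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Angstrom; other
#' elements fall back to 1.70 with a warning.
#'
#' @param struct A `structure_model`.
#' @param sel Optional [atom_selection()] restricting the atom set (the
#'   selected atoms form the entire occluding environment).
#' @param probe Probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sample points per atom (default 960).
#' @return The selected atom tibble with an additional `sasa` column
#'   (Angstrom^2); total SASA as attribute `"total"`.
#' @examples
#' carbon <- structure_model(data.frame(chain = "A", resno = 1, atom = "C1",
#'                                      element = "C", x = 0, y = 0, z = 0))
#' attr(compute_sasa(carbon), "total")  # 4*pi*(1.7 + 1.4)^2 = 120.76
#' @export
compute_sasa <- function(struct, sel = NULL, probe = 1.4, n_points = 960) {
  check_numeric(probe, "probe", non_negative = TRUE, scalar = TRUE)
  a <- select_atoms(struct, sel)
  a <- a[is.na(a$element) | a$element != "H", , drop = FALSE]
  if (any(is.na(a$element))) {
    abort(sprintf("atoms without an element type: %s",
                  paste(utils::head(a$atom[is.na(a$element)], 5),
                        collapse = ", ")))
  }
  unknown <- setdiff(unique(a$element), names(vdw_radii))
  if (length(unknown)) {
    warn(sprintf("no van der Waals radius for element(s) %s; using %.2f A",
                 paste(unknown, collapse = ", "), vdw_default))
  }
  radii <- unname(vdw_radii[a$element])
  radii[is.na(radii)] <- vdw_default
  ext <- radii + probe

  xyz <- xyz_matrix(a)
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  # neighbour candidates: centre distance below the largest possible sum of
  # extended radii
  nb <- neighbor_pairs(xyz, xyz, cutoff = 2 * max(ext))
  nb <- nb[nb$ia != nb$ib, , drop = FALSE]
  nb_by_atom <- split(nb$ib, factor(nb$ia, levels = seq_len(n)))

  sasa <- numeric(n)
  for (i in seq_len(n)) {
    shell <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    js <- nb_by_atom[[i]]
    acc_frac <- if (length(js) == 0) 1 else {
      buried <- rep(FALSE, n_points)
      for (j in js) {
        if (all(buried)) break
        d2 <- (shell[, 1] - xyz[j, 1])^2 + (shell[, 2] - xyz[j, 2])^2 +
              (shell[, 3] - xyz[j, 3])^2
        buried <- buried | d2 < ext[j]^2
      }
      mean(!buried)
    }
    sasa[i] <- 4 * pi * ext[i]^2 * acc_frac
  }
  a$sasa <- sasa
  attr(a, "total") <- sum(sasa)
  a
}

#' Buried surface area of a binary interface
#'
#' \eqn{BSA = SASA(A) + SASA(B) - SASA(AB)}: the solvent-accessible area
#' hidden when two parts of a complex associate. Symmetric in the two parts
#' and non-negative up to sampling error.
#'
#' @param complex A `structure_model` containing both parts.
#' @param part_a,part_b [atom_selection()]s partitioning the polymer atoms of
#'   interest.
#' @param probe,n_points Passed to [compute_sasa()].
#' @return Buried area, Angstrom^2 (single number).
#' @export
buried_surface <- function(complex, part_a, part_b, probe = 1.4,
                           n_points = 960) {
  sub_a <- structure_model(select_atoms(complex, part_a), title = "part A")
  sub_b <- structure_model(select_atoms(complex, part_b), title = "part B")
  both <- structure_model(dplyr::bind_rows(sub_a$atoms, sub_b$atoms),
                          title = "complex")
  tot <- function(s) attr(compute_sasa(s, probe = probe,
                                       n_points = n_points), "total")
  tot(sub_a) + tot(sub_b) - tot(both)
}
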