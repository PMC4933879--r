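#' Atomic structure container
#'
#' A light S3 wrapper around a per-atom tibble, the common currency of all
#' geometry operations in the package. Columns: `chain`, `resno` (author
#' residue number), `resid` (residue name), `atom` (atom name), `element`,
#' `x`, `y`, `z` (Angstrom), `occ` (occupancy), `b` (B-factor, Angstrom^2),
#' `altloc`, `het` (HETATM flag), `water`.
#'
#' @param atoms Data frame with at least `chain`, `resno`, `atom`, `x`, `y`,
#'   `z`; missing annotation columns are filled with defaults.
#' @param title Optional free-text title.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "") {
  atoms <- as_tibble(atoms)
  required <- c("chain", "resno", "atom", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    abort(sprintf("atoms table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  defaults <- list(resid = "UNK", element = NA_character_, occ = 1,
                   b = 0, altloc = "", het = FALSE, water = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) {
    abort("occupancies must lie in [0, 1]")
  }
  if (all(is.na(atoms$element))) {
    atoms$element <- guess_element(atoms$atom)
  }
  structure(list(atoms = atoms, title = title), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %d atoms, %d chains (%s)%s\n",
              nrow(a), dplyr::n_distinct(a$chain),
              paste(sort(unique(a$chain)), collapse = ","),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

# first alphabetic character of the atom name, PDB convention
guess_element <- function(atom_name) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "",
                            sub("^[0-9]*", "", atom_name)), 1, 1))
  el[el == ""] <- NA_character_
  el
}

#' Read a PDB-format coordinate file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()] and post-processes them
#' into a [structure_model()]: alternate locations are resolved to the
#' highest-occupancy conformer (ties broken alphabetically by altloc id, and
#' the number of discarded conformers is recorded in attribute
#' `"altloc_discarded"`), waters and heteroatoms are flagged and excluded
#' from geometry operations by default.
#'
#' @param path Path to a PDB file.
#' @param title Optional title; defaults to the file name.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, title = basename(path)) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(sprintf("failed to parse PDB file '%s': %s",
                                      path, conditionMessage(e)))
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) {
    abort(sprintf("failed to parse PDB file '%s': no ATOM/HETATM records",
                  path))
  }
  atoms <- tibble(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    resid = as.character(a$resid),
    atom = as.character(a$elety),
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     guess_element(a$elety), toupper(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    het = a$type == "HETATM",
    water = a$resid %in% c("HOH", "WAT", "DOD")
  )
  n_before <- nrow(atoms)
  atoms <- resolve_altloc(atoms)
  out <- structure_model(atoms, title = title)
  attr(out, "altloc_discarded") <- n_before - nrow(atoms)
  out
}

# keep one conformer per (chain, resno, atom): highest occupancy, then
# alphabetical altloc id; file order is preserved
resolve_altloc <- function(atoms) {
  atoms$.row <- seq_len(nrow(atoms))
  out <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)
  out$.row <- NULL
  out
}

#' Write a structure as a minimal PDB-format file
#'
#' Fixed-column ATOM/HETATM records; sufficient for round-tripping the
#' package's own structure models and for viewing in standard tools.
#'
#' @param struct A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "structure_model"))
  a <- struct$atoms
  name4 <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                  paste0(" ", formatC(a$atom, width = -3)))
  lines <- sprintf(
    "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), name4,
    substr(a$resid, 1, 3), substr(a$chain, 1, 1), a$resno,
    a$x, a$y, a$z, a$occ, a$b,
    ifelse(is.na(a$element), "", a$element))
  writeLines(c(sprintf("TITLE     %s", struct$title), lines, "END"), path)
  invisible(path)
}

#' Atom selections
#'
#' A selection names a subset of atoms by chain, author residue number and
#' atom-name class. Selections drive superposition, interface analysis,
#' buried-surface partitioning and B-factor statistics.
#'
#' @param chain Character vector of chain ids, or `NULL` for all.
#' @param resno Integer vector of residue numbers (use ranges like
#'   `1:149`), or `NULL` for all.
#' @param atoms `"heavy"` (all non-hydrogen atoms, the default), `"CA"`
#'   (alpha carbons only), `"all"`, or a character vector of atom names.
#' @return An object of class `atom_selection`.
#' @examples
#' atom_selection(chain = "D", resno = 1:149, atoms = "CA")
#' @export
atom_selection <- function(chain = NULL, resno = NULL, atoms = "heavy") {
  structure(list(chain = chain, resno = resno, atoms = atoms),
            class = "atom_selection")
}

#' Resolve a selection on a structure
#'
#' @param struct A `structure_model`.
#' @param sel An [atom_selection()] (or `NULL` for all polymer heavy atoms).
#' @param include_het,include_water Include heteroatoms / waters (default
#'   `FALSE`: geometry operations work on the polymer).
#' @param allow_empty Return an empty table instead of erroring.
#' @return Tibble of selected atoms.
#' @export
select_atoms <- function(struct, sel = NULL, include_het = FALSE,
                         include_water = FALSE, allow_empty = FALSE) {
  stopifnot(inherits(struct, "structure_model"))
  a <- struct$atoms
  if (!include_het) a <- a[!a$het | a$water, , drop = FALSE]
  if (!include_water) a <- a[!a$water, , drop = FALSE]
  if (!is.null(sel)) {
    stopifnot(inherits(sel, "atom_selection"))
    if (!is.null(sel$chain)) a <- a[a$chain %in% sel$chain, , drop = FALSE]
    if (!is.null(sel$resno)) a <- a[a$resno %in% sel$resno, , drop = FALSE]
    if (length(sel$atoms) == 1 && sel$atoms %in% c("heavy", "all", "CA")) {
      if (sel$atoms == "CA") a <- a[a$atom == "CA", , drop = FALSE]
      if (sel$atoms == "heavy") {
        a <- a[is.na(a$element) | a$element != "H", , drop = FALSE]
      }
    } else {
      a <- a[a$atom %in% sel$atoms, , drop = FALSE]
    }
  } else {
    a <- a[is.na(a$element) | a$element != "H", , drop = FALSE]
  }
  if (!allow_empty && nrow(a) == 0) {
    abort("selection resolves to zero atoms")
  }
  a
}

# coordinates of an atom tibble as an n x 3 matrix
xyz_matrix <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}
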