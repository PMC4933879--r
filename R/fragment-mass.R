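# average residue masses (Da), standard 20-residue table; a protein fragment
# mass is the residue-mass sum plus one water (18.02)
aa_residue_masses <- c(
  G = 57.05, A = 71.08, S = 87.08, P = 97.12, V = 99.13, T = 101.10,
  C = 103.14, L = 113.16, I = 113.16, N = 114.10, D = 115.09, Q = 128.13,
  K = 128.17, E = 129.12, M = 131.19, H = 137.14, F = 147.18, R = 156.19,
  Y = 163.18, W = 186.21
)
water_mass <- 18.02

check_sequence <- function(seq) {
  if (length(seq) == 1 && is.character(seq)) {
    seq <- strsplit(toupper(seq), "")[[1]]
  }
  bad <- setdiff(unique(seq), names(aa_residue_masses))
  if (length(bad)) {
    abort(sprintf("non-canonical residue code(s): %s",
                  paste(bad, collapse = ", ")))
  }
  seq
}

#' Average mass of a contiguous protein fragment
#'
#' Sum of the average residue masses over `start:end` plus one water
#' (18.02 Da), as measured for an intact species by ESI mass spectrometry
#' (average, not monoisotopic, masses are appropriate at the ~16 kDa scale).
#' Terminal modifications (tags, acetylation) are the caller's business via
#' the sequence itself.
#'
#' @param seq Protein sequence: a single string or character vector of
#'   one-letter codes (the 20 canonical residues).
#' @param start,end 1-based inclusive residue indices.
#' @return Fragment average mass, Da.
#' @examples
#' fragment_mass("G", 1, 1)  # 75.07: glycine residue 57.05 + water
#' @export
fragment_mass <- function(seq, start = 1, end = NULL) {
  seq <- check_sequence(seq)
  end <- end %||% length(seq)
  if (start < 1 || end > length(seq) || start > end) {
    abort(sprintf("invalid fragment range %d-%d for a %d-residue sequence",
                  start, end, length(seq)))
  }
  sum(aa_residue_masses[seq[start:end]]) + water_mass
}

#' Fragments consistent with observed masses
#'
#' Exhaustively scans all contiguous `(start, end)` fragments of a sequence
#' and returns, per observed mass, every fragment whose average mass lies
#' within `tolerance`. This reproduces the assignment logic of a limited
#' proteolysis / ESI-MS experiment: an observed intact-fragment mass is
#' explained by the (usually very few) contiguous stretches compatible with
#' it.
#'
#' @param seq Protein sequence (string or character vector).
#' @param observed Numeric vector of observed masses, Da.
#' @param tolerance Match tolerance, Da (default 2, absorbing mass-table
#'   rounding while retaining single-residue discrimination).
#' @return Tibble with columns `observed`, `start`, `end`, `mass`, `delta`
#'   (computed minus observed), sorted by `|delta|` within each observed
#'   mass. Observed masses with no compatible fragment simply contribute no
#'   rows.
#' @export
match_fragments <- function(seq, observed, tolerance = 2) {
  seq <- check_sequence(seq)
  check_numeric(observed, "observed", positive = TRUE)
  check_numeric(tolerance, "tolerance", positive = TRUE, scalar = TRUE)
  n <- length(seq)
  # prefix sums: mass(a, b) = pref[b + 1] - pref[a] + water
  pref <- c(0, cumsum(aa_residue_masses[seq]))
  starts <- rep(seq_len(n), times = n:1)
  ends <- unlist(lapply(seq_len(n), function(a) a:n), use.names = FALSE)
  masses <- pref[ends + 1] - pref[starts] + water_mass
  purrr::map_dfr(observed, function(m) {
    hit <- which(abs(masses - m) <= tolerance)
    tibble(observed = m, start = starts[hit], end = ends[hit],
           mass = masses[hit], delta = masses[hit] - m) |>
      dplyr::arrange(abs(.data$delta))
  })
}

#' Read a protein sequence from a FASTA file
#'
#' @param path FASTA file path (first record is returned).
#' @return Named character scalar: the sequence, named by the record header.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  if (length(recs) == 0) abort("not a FASTA file: no records found")
  setNames(toupper(as.character(recs[[1]])),
           attr(recs[[1]], "Annot") |> sub(pattern = "^>\\s*",
                                           replacement = ""))
}
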