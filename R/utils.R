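# internal helpers shared across modules

#' Convert between molar and nanomolar concentration units
#'
#' All darpkin computations run in SI units (mol/L, s). These helpers are the
#' single place where unit conversion happens, at input and reporting time.
#'
#' @param x Numeric vector.
#' @return Numeric vector in the target unit.
#' @examples
#' to_nM(1.27e-7)
#' from_nM(127)
#' @export
to_nM <- function(x) x * 1e9

#' @rdname to_nM
#' @export
from_nM <- function(x) x * 1e-9

# validate that `x` is numeric, finite, and (optionally) positive / non-negative
check_numeric <- function(x, name, positive = FALSE, non_negative = FALSE,
                          scalar = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", name))
  }
  if (scalar && length(x) != 1) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (positive && any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  if (non_negative && any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

# Derive an independent, reproducible RNG seed for a named generator stream.
# Streams are decoupled so that adding one generator never shifts another.
stream_seed <- function(seed, tag) {
  check_numeric(seed, "seed", scalar = TRUE)
  codes <- utf8ToInt(tag)
  h <- (abs(seed) * 48271 + sum(codes * seq_along(codes)) * 69621) %% 2147483629
  as.integer(h) + 1L
}

# run `expr` under a derived seed without touching the caller's RNG state
with_stream_seed <- function(seed, tag, expr) {
  withr::with_seed(stream_seed(seed, tag), expr)
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
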