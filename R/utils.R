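# Low-level helpers shared across the package. Labeling states are bit strings
# over carbon positions, written C1 (leftmost) to Cn (rightmost); the integer
# value of a pattern reads the string as a binary number (C1 = most significant
# digit), which fixes the canonical per-pool ordering.

#' All labeling patterns of an n-carbon molecule
#'
#' Returns the `2^n` binary labeling patterns of a molecule with `n` mapped
#' carbon positions, ordered by their value as binary integers (the canonical
#' isotopomer order used throughout the package). `"0"` marks a light atom,
#' `"1"` a heavy atom; position 1 is the leftmost character.
#'
#' @param n Number of mapped carbon positions (>= 1).
#' @return Character vector of length `2^n`.
#' @examples
#' iso_patterns(2)
#' @export
iso_patterns <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n <= 30)
  n <- as.integer(n)
  k <- 0:(2^n - 1L)
  vapply(k, function(x) {
    paste(rev(as.integer(intToBits(x))[seq_len(n)]), collapse = "")
  }, character(1))
}

# integer value of a pattern string (C1 = MSB)
pattern_int <- function(p) strtoi(p, base = 2L)

# number of heavy atoms in a pattern string
pattern_weight <- function(p) nchar(p) - nchar(gsub("1", "", p, fixed = TRUE))

# pattern string -> integer bit vector (position 1 first)
pattern_bits <- function(p) as.integer(strsplit(p, "", fixed = TRUE)[[1]])

bits_pattern <- function(bits) paste(bits, collapse = "")

is_pattern <- function(p) grepl("^[01]+$", p)

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Parse one side of an atom-map string, e.g. "DHAP(cba) + GAP(def)".
# Returns list of list(met=, slots=) in written order. An empty side ("") is
# allowed and yields an empty list.
parse_atom_side <- function(side, where = "atom map") {
  side <- trimws(side)
  if (side == "") return(list())
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  lapply(terms, function(term) {
    m <- regmatches(term, regexec("^([A-Za-z0-9_]+)\\(([A-Za-z]*)\\)$", term))[[1]]
    if (length(m) != 3) {
      stop("cannot parse term '", term, "' in ", where,
           "; expected e.g. 'GAP(abc)'", call. = FALSE)
    }
    list(met = m[2], slots = strsplit(m[3], "", fixed = TRUE)[[1]])
  })
}

# Parse a full atom-map string "FBP(abcdef) -> DHAP(cba) + GAP(def)" into
# list(substrates=, products=), each a list of list(met=, slots=).
parse_atom_map <- function(atoms, where = atoms) {
  parts <- strsplit(atoms, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("atom map '", atoms, "' must contain exactly one '->'", call. = FALSE)
  }
  list(substrates = parse_atom_side(parts[1], where),
       products   = parse_atom_side(parts[2], where))
}

deparse_atom_side <- function(side) {
  paste(vapply(side, function(s) {
    paste0(s$met, "(", paste(s$slots, collapse = ""), ")")
  }, character(1)), collapse = " + ")
}

# Full-precision number formatting for text outputs (17 significant digits
# keeps write -> read round trips exact for doubles).
format_full <- function(x) formatC(x, digits = 17, format = "g")
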