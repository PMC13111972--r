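# IUPAC nucleotide ambiguity codes as 4-bit masks over {A, C, G, T}.
# Bit values: A = 1, C = 2, G = 4, T = 8; every mask in 1..15 is a valid code.

.iupac_chars <- c("A", "C", "G", "T", "R", "Y", "S", "W",
                  "K", "M", "B", "D", "H", "V", "N")
.iupac_masks <- c(1L, 2L, 4L, 8L, 5L, 10L, 6L, 9L,
                  12L, 3L, 14L, 13L, 11L, 7L, 15L)

# char indexed by mask value 1..15
.mask_chars <- character(15L)
.mask_chars[.iupac_masks] <- .iupac_chars

# base-wise complement (A<->T, C<->G), indexed by mask value
.mask_comp <- vapply(1:15, function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftR(bitwAnd(m, 8L), 3L)),
         bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L), bitwShiftR(bitwAnd(m, 4L), 1L)))
}, integer(1))

# number of bases in the set, indexed by mask value
.mask_size <- vapply(1:15, function(m) {
  sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

#' The IUPAC nucleotide alphabet
#'
#' Returns the 15 one-letter IUPAC nucleotide codes handled by the package
#' (the four bases plus the 11 ambiguity codes; no gap symbol, no `U`).
#'
#' @return A character vector of length 15.
#' @export
#' @examples
#' iupac_codes()
iupac_codes <- function() .iupac_chars

#' Convert a basecall string to a vector of base-set masks
#'
#' Internal workhorse: each character becomes an integer in 1..15 whose bits
#' encode the subset of \{A, C, G, T\} the code denotes (A = 1, C = 2, G = 4,
#' T = 8). Lowercase input is accepted; case carries no base information.
#'
#' @param x A single string over the IUPAC nucleotide alphabet.
#' @param arg Name used in error messages.
#' @return Integer vector of masks.
#' @keywords internal
#' @noRd
seq_to_mask <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", arg))
  }
  if (!nzchar(x)) return(integer(0))
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, .iupac_chars)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    abort(sprintf(
      "Invalid character '%s' at position %d of %s: expected one of the 15 IUPAC nucleotide codes (%s). Gaps and 'U' are not accepted.",
      chars[p], p, arg, paste(.iupac_chars, collapse = "")))
  }
  .iupac_masks[idx]
}

# inverse of seq_to_mask
mask_to_seq <- function(m) {
  if (length(m) == 0L) return("")
  paste(.mask_chars[m], collapse = "")
}

# accept either a string or an already-converted mask vector
as_mask <- function(x, arg = "sequence") {
  if (is.integer(x)) return(x)
  if (is.numeric(x)) return(as.integer(x))
  seq_to_mask(x, arg = arg)
}

iupac_char1 <- function(x, arg) {
  m <- as_mask(x, arg)
  if (length(m) != 1L) abort(sprintf("`%s` must be a single IUPAC code.", arg))
  m
}

#' Set operations on IUPAC codes
#'
#' An IUPAC code denotes a nonempty subset of \{A, C, G, T\}; these helpers
#' expose the set algebra on single codes. `iupac_compatible()` tests whether
#' two codes share at least one base (the match criterion used throughout the
#' alignment scoring). `iupac_intersect()`, `iupac_union()` and
#' `iupac_subtract()` return the IUPAC character for the resulting set, or
#' `NA` when it is empty (an empty intersection signals a mismatch; an empty
#' difference signals that one code is contained in the other).
#'
#' @param a,b Single IUPAC characters (case-insensitive).
#' @return `iupac_compatible()`: a logical scalar. The set operations: a
#'   single character, or `NA_character_` for the empty set.
#' @export
#' @examples
#' iupac_compatible("W", "R") # share A
#' iupac_compatible("W", "S") # {A,T} vs {C,G}
#' iupac_intersect("Y", "C")
#' iupac_subtract("Y", "C")   # a Y explained by a C leaves a T
#' iupac_union("A", "C")
iupac_compatible <- function(a, b) {
  bitwAnd(iupac_char1(a, "a"), iupac_char1(b, "b")) > 0L
}

#' @rdname iupac_compatible
#' @export
iupac_intersect <- function(a, b) {
  m <- bitwAnd(iupac_char1(a, "a"), iupac_char1(b, "b"))
  if (m == 0L) NA_character_ else .mask_chars[m]
}

#' @rdname iupac_compatible
#' @export
iupac_union <- function(a, b) {
  .mask_chars[bitwOr(iupac_char1(a, "a"), iupac_char1(b, "b"))]
}

#' @rdname iupac_compatible
#' @export
iupac_subtract <- function(a, b) {
  m <- bitwAnd(iupac_char1(a, "a"), bitwNot(iupac_char1(b, "b")))
  m <- bitwAnd(m, 15L)
  if (m == 0L) NA_character_ else .mask_chars[m]
}

#' Reverse-complement an IUPAC basecall string
#'
#' Reverses the string and complements every code base-wise (A with T, C with
#' G), so ambiguity codes map to the code of the complemented set (Y to R, W
#' to W, ...). Applying it twice is the identity.
#'
#' @param x A string over the IUPAC nucleotide alphabet (case-insensitive).
#' @return A string in uppercase.
#' @export
#' @examples
#' reverse_complement("ATGC")
#' reverse_complement("RY")
reverse_complement <- function(x) {
  m <- as_mask(x, "x")
  mask_to_seq(rev(.mask_comp[m]))
}
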