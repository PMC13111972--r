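# Ungapped offset enumeration and the three alignment scoring schemes.
# Offset convention: the offset o is the position of forward[1] in reverse
# coordinates, so forward position i (0-based) pairs with reverse position
# i + o. Offsets may be negative.

.schemes <- c("ambiguity_corrected", "overlap_corrected", "longest_run")

match_scheme <- function(scheme) {
  rlang::arg_match0(scheme, .schemes)
}

#' Enumerate all ungapped alignment offsets
#'
#' Lists every offset at which the forward and reverse strings overlap by at
#' least `min_overlap` positions. The offset is the position of the first
#' forward base in reverse coordinates; forward position `i` (0-based) pairs
#' with reverse position `i + offset`.
#'
#' @param len_fwd,len_rev Sequence lengths (>= 1).
#' @param min_overlap Minimum number of paired positions (default 1, i.e.
#'   every possible alignment).
#' @return Integer vector of offsets in ascending order (possibly empty).
#' @export
#' @examples
#' enumerate_offsets(3, 3, 1)
#' enumerate_offsets(4, 4, 4)
enumerate_offsets <- function(len_fwd, len_rev, min_overlap = 1L) {
  stopifnot(len_fwd >= 1, len_rev >= 1, min_overlap >= 1)
  o <- seq.int(-(len_fwd - 1L), len_rev - 1L)
  ov <- pmin(len_fwd, len_rev - o) - pmax(0L, -o)
  o[ov >= min_overlap]
}

# 0-based forward indices of the overlap at offset o
overlap_fwd_idx <- function(len_fwd, len_rev, o) {
  lo <- max(0L, -o)
  hi <- min(len_fwd, len_rev - o) - 1L
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

# per-position compatibility of the overlap (logical vector)
overlap_compat <- function(fm, rm, o) {
  i <- overlap_fwd_idx(length(fm), length(rm), o)
  bitwAnd(fm[i + 1L], rm[i + o + 1L]) > 0L
}

score_one <- function(fm, rm, o, scheme) {
  i <- overlap_fwd_idx(length(fm), length(rm), o)
  n <- length(i)
  if (n == 0L) abort(sprintf("No alignment at offset %d: the sequences do not overlap.", o))
  f <- fm[i + 1L]
  r <- rm[i + o + 1L]
  compat <- bitwAnd(f, r) > 0L
  n_compatible <- sum(compat)
  score <- switch(scheme,
    overlap_corrected = n_compatible - n / 4,
    ambiguity_corrected = {
      exact <- compat & .mask_size[f] == 1L & .mask_size[r] == 1L
      (sum(exact) + 0.5 * (n_compatible - sum(exact))) - n / 4
    },
    longest_run = {
      if (n_compatible == 0L) 0 else {
        runs <- rle(compat)
        as.numeric(max(runs$lengths[runs$values]))
      }
    })
  list(offset = as.integer(o), score = score, overlap_len = n,
       n_compatible = as.integer(n_compatible),
       n_mismatch = as.integer(n - n_compatible))
}

#' Score a single alignment offset
#'
#' Scores the ungapped alignment of the two basecall strings at one offset
#' under one of three schemes:
#'
#' * `"overlap_corrected"`: number of compatible positions minus one fourth
#'   of the overlap length (two random bases match by chance with
#'   probability 1/4).
#' * `"ambiguity_corrected"` (default): as above, but a compatible pair in
#'   which at least one code is ambiguous contributes 0.5 instead of 1, since
#'   ambiguity codes match many partners by construction.
#' * `"longest_run"`: length of the longest stretch of consecutive
#'   compatible positions.
#'
#' Two codes are compatible when their base sets intersect.
#'
#' @param fwd,rev Basecall strings (IUPAC alphabet); `rev` already in forward
#'   orientation.
#' @param offset Integer offset (see [enumerate_offsets()]).
#' @param scheme Scoring scheme.
#' @return A one-row tibble with columns `offset`, `score`, `overlap_len`,
#'   `n_compatible`, `n_mismatch`, `scheme`.
#' @export
#' @examples
#' score_offset("ACGT", "ACGT", 0, "overlap_corrected")
#' score_offset("AW", "AA", 0, "ambiguity_corrected")
score_offset <- function(fwd, rev, offset, scheme = "ambiguity_corrected") {
  scheme <- match_scheme(scheme)
  fm <- as_mask(fwd, "fwd")
  rm <- as_mask(rev, "rev")
  s <- score_one(fm, rm, offset, scheme)
  tibble(!!!s, scheme = scheme)
}

#' Rank all alignment offsets between two basecall strings
#'
#' Scores every offset with overlap at least `min_overlap` under the chosen
#' scheme and sorts the candidates by descending score, breaking ties by
#' ascending mismatch count, then by smaller absolute offset, then by smaller
#' offset — a total, reproducible order.
#'
#' @inheritParams score_offset
#' @param min_overlap Minimum overlap for an offset to be considered.
#' @return A tibble (subclass `"tp_offsets"`) with one row per offset:
#'   `offset`, `score`, `overlap_len`, `n_compatible`, `n_mismatch`,
#'   `scheme`, `p_value` (`NA` until [classify_outliers()] fills it).
#' @seealso [classify_outliers()], [autoplot.tp_offsets()]
#' @export
#' @examples
#' rank_offsets("ACGTACGT", "CGTACGTA", scheme = "overlap_corrected")
rank_offsets <- function(fwd, rev, scheme = "ambiguity_corrected",
                         min_overlap = 1L) {
  scheme <- match_scheme(scheme)
  fm <- as_mask(fwd, "fwd")
  rm <- as_mask(rev, "rev")
  if (length(fm) == 0L || length(rm) == 0L) {
    abort("Both sequences must be non-empty.")
  }
  offs <- enumerate_offsets(length(fm), length(rm), min_overlap)
  if (length(offs) == 0L) abort("No offset reaches the requested minimum overlap.")
  rows <- lapply(offs, function(o) score_one(fm, rm, o, scheme))
  out <- tibble(
    offset = vapply(rows, `[[`, integer(1), "offset"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    overlap_len = vapply(rows, `[[`, integer(1), "overlap_len"),
    n_compatible = vapply(rows, `[[`, integer(1), "n_compatible"),
    n_mismatch = vapply(rows, `[[`, integer(1), "n_mismatch"),
    scheme = scheme,
    p_value = NA_real_
  )
  out <- out[order(-out$score, out$n_mismatch, abs(out$offset), out$offset), ]
  class(out) <- c("tp_offsets", class(tibble()))
  out
}
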