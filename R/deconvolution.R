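# Steps 2-5: per-offset consensus, ambiguity resolution by mutual
# explanation, remix consistency check, and exploration of alternative
# offset pairs.
#
# Frames: a consensus at offset o lives in reverse coordinates and spans
# columns min(0, o) .. max(len_rev, len_fwd + o) - 1. Column j is covered by
# the reverse string when 0 <= j < len_rev and by the forward string when
# 0 <= j - o < len_fwd.

#' Consensus of the two basecall strings at one offset
#'
#' Combines the forward and reverse strings aligned at a single offset.
#' Columns covered by both strings hold the intersection of the two codes;
#' when the codes are incompatible the column keeps the union of the two
#' (preserving the evidence) and is recorded in `mismatch_columns`. Columns
#' covered by only one string copy that string's code and are rendered in
#' lowercase to mark single-sequence support.
#'
#' @inheritParams rank_offsets
#' @param offset Integer offset with overlap of at least 1.
#' @return An object of class `"consensus"`: list with `offset`, `col_start`
#'   (reverse coordinate of the first column), `code` (internal base-set
#'   masks), `support` (`"both"`, `"forward_only"` or `"reverse_only"` per
#'   column) and `mismatch_columns` (1-based column indices).
#'   `as.character()` renders the case-marked string.
#' @export
#' @examples
#' as.character(build_consensus("ACGT", "ACGTAA", 0))
build_consensus <- function(fwd, rev, offset) {
  fm <- as_mask(fwd, "fwd")
  rm <- as_mask(rev, "rev")
  o <- as.integer(offset)
  if (length(overlap_fwd_idx(length(fm), length(rm), o)) == 0L) {
    abort(sprintf("No alignment at offset %d: the sequences do not overlap.", o))
  }
  lo <- min(0L, o)
  hi <- max(length(rm), length(fm) + o) - 1L
  j <- seq.int(lo, hi)
  covf <- j - o >= 0L & j - o < length(fm)
  covr <- j >= 0L & j < length(rm)
  code <- integer(length(j))
  support <- character(length(j))
  fcode <- integer(length(j)); fcode[covf] <- fm[j[covf] - o + 1L]
  rcode <- integer(length(j)); rcode[covr] <- rm[j[covr] + 1L]
  both <- covf & covr
  inter <- bitwAnd(fcode[both], rcode[both])
  uni <- bitwOr(fcode[both], rcode[both])
  mism <- inter == 0L
  code[both] <- ifelse(mism, uni, inter)
  code[covf & !covr] <- fcode[covf & !covr]
  code[!covf & covr] <- rcode[!covf & covr]
  support[both] <- "both"
  support[covf & !covr] <- "forward_only"
  support[!covf & covr] <- "reverse_only"
  structure(
    list(offset = o, col_start = lo, code = code, support = support,
         mismatch_columns = which(both)[mism]),
    class = "consensus")
}

render_cased <- function(code, support) {
  ch <- .mask_chars[code]
  single <- support != "both"
  ch[single] <- tolower(ch[single])
  paste(ch, collapse = "")
}

#' @export
as.character.consensus <- function(x, ...) render_cased(x$code, x$support)

#' @export
print.consensus <- function(x, ...) {
  cat(sprintf("Consensus at offset %d (%d columns, %d mismatch column(s))\n",
              x$offset, length(x$code), length(x$mismatch_columns)))
  cat(" ", as.character(x), "\n")
  invisible(x)
}

# physical-position table shared by resolution and the remix check:
# one row per observed input character, with its column index in each frame
physical_positions <- function(fm, rm, o1, o2, lo1, lo2) {
  lf <- length(fm); lr <- length(rm)
  tibble(
    strand = c(rep("forward", lf), rep("reverse", lr)),
    position = c(seq_len(lf), seq_len(lr)),              # 1-based, user-facing
    observed = c(fm, rm),
    c1 = c(seq_len(lf) - 1L + o1 - lo1 + 1L, seq_len(lr) - 1L - lo1 + 1L),
    c2 = c(seq_len(lf) - 1L + o2 - lo2 + 1L, seq_len(lr) - 1L - lo2 + 1L))
}

#' Reconstruct the two haplotypes at a pair of offsets
#'
#' Step 2 builds one consensus per offset; each consensus is the starting
#' point for one haplotype. Step 3 then resolves remaining ambiguity codes by
#' mutual explanation: every peak in the input strings must come from one
#' haplotype or the other, so if the code observed at a physical position is
#' `X` and the other haplotype is already resolved to base `b` there, this
#' haplotype is restricted to `X` minus `b` (or to `X` itself when `b`
#' accounts for all of `X`). The rule is swept over all forward then reverse
#' positions until a fixpoint; every effective update strictly shrinks a
#' possibility set, so termination is guaranteed.
#'
#' Two anomalies are recorded in `resolution_warnings` rather than acted on
#' silently: a position where more than one base remains unexplained by the
#' two-haplotype model (e.g. a triple peak), and an update that would empty a
#' column (the original set is kept).
#'
#' @inheritParams rank_offsets
#' @param o1,o2 The two offsets (distinct, each with overlap >= 1);
#'   conventionally `o1` is the higher-ranked one.
#' @param sweep_order Order of the position sweep; the fixpoint should not
#'   depend on it (exposed for verification).
#' @return An object of class `"reconstruction"`: `hap1`/`hap2` (mask
#'   vectors), `support1`/`support2`, `offsets`, `col_start`, per-haplotype
#'   `unresolved` column indices, `resolution_warnings`, and placeholders
#'   `warnings`/`n_check_mismatches` filled by [check_consistency()].
#'   `haplotype_strings()` renders the two case-marked sequences.
#' @export
resolve_haplotypes <- function(fwd, rev, o1, o2,
                               sweep_order = c("forward_first", "reverse_first")) {
  sweep_order <- match.arg(sweep_order)
  o1 <- as.integer(o1); o2 <- as.integer(o2)
  if (o1 == o2) abort("The two offsets must be distinct.")
  fm <- as_mask(fwd, "fwd")
  rm <- as_mask(rev, "rev")
  cons1 <- build_consensus(fm, rm, o1)
  cons2 <- build_consensus(fm, rm, o2)
  h1 <- cons1$code
  h2 <- cons2$code
  pos <- physical_positions(fm, rm, o1, o2, cons1$col_start, cons2$col_start)
  if (sweep_order == "reverse_first") pos <- pos[seq.int(nrow(pos), 1L), ]

  # the explanation candidate a position contributes to one haplotype, given
  # the other haplotype's state at the same physical position
  explain_cand <- function(X, other) {
    if (.mask_size[other] == 1L) {
      cand <- bitwAnd(X, bitwAnd(bitwNot(other), 15L))
      if (cand == 0L) X else cand
    } else X
  }

  # synchronous rounds: all candidates are computed from the previous
  # round's state and combined per column by intersection (commutative), so
  # the fixpoint does not depend on the position order
  empty_warn <- list()
  max_rounds <- 4L * (length(h1) + length(h2)) + 4L
  for (round in seq_len(max_rounds)) {
    acc1 <- rep(15L, length(h1))
    acc2 <- rep(15L, length(h2))
    for (k in seq_len(nrow(pos))) {
      X <- pos$observed[k]; c1 <- pos$c1[k]; c2 <- pos$c2[k]
      acc1[c1] <- bitwAnd(acc1[c1], explain_cand(X, h2[c2]))
      acc2[c2] <- bitwAnd(acc2[c2], explain_cand(X, h1[c1]))
    }
    v1 <- bitwAnd(h1, acc1)
    v2 <- bitwAnd(h2, acc2)
    dead1 <- v1 == 0L
    dead2 <- v2 == 0L
    for (k in seq_len(nrow(pos))) {
      if (dead1[pos$c1[k]] || dead2[pos$c2[k]]) {
        empty_warn[[length(empty_warn) + 1L]] <-
          list(strand = pos$strand[k], position = pos$position[k],
               observed = .mask_chars[pos$observed[k]],
               note = "update would empty a haplotype column; original set kept")
      }
    }
    v1[dead1] <- h1[dead1]
    v2[dead2] <- h2[dead2]
    if (all(v1 == h1) && all(v2 == h2)) break
    stopifnot(all(bitwAnd(v1, h1) == v1), all(bitwAnd(v2, h2) == v2))  # monotone shrink
    h1 <- v1
    h2 <- v2
  }

  # post-convergence anomaly scan: a peak set that minus the other
  # haplotype's resolved base still holds >= 2 bases cannot be explained by
  # a two-haplotype model
  triple_warn <- list()
  for (k in seq_len(nrow(pos))) {
    X <- pos$observed[k]
    for (oth in c(h2[pos$c2[k]], h1[pos$c1[k]])) {
      if (.mask_size[oth] == 1L) {
        left <- bitwAnd(X, bitwAnd(bitwNot(oth), 15L))
        if (left != 0L && .mask_size[left] > 1L) {
          triple_warn[[length(triple_warn) + 1L]] <-
            list(strand = pos$strand[k], position = pos$position[k],
                 observed = .mask_chars[X],
                 note = "more than one base left unexplained by the two-haplotype model")
          break
        }
      }
    }
  }

  res_warn <- dplyr::distinct(dplyr::bind_rows(
    tibble(strand = character(), position = integer(),
           observed = character(), note = character()),
    purrr::map_dfr(c(empty_warn, triple_warn), as_tibble)))

  structure(
    list(hap1 = h1, hap2 = h2,
         support1 = cons1$support, support2 = cons2$support,
         offsets = c(o1, o2),
         col_start = c(cons1$col_start, cons2$col_start),
         mismatch_columns = list(cons1$mismatch_columns, cons2$mismatch_columns),
         unresolved = list(hap1 = which(.mask_size[h1] > 1L),
                           hap2 = which(.mask_size[h2] > 1L)),
         resolution_warnings = res_warn,
         warnings = tibble(strand = character(), position = integer(),
                           observed = character(), predicted = character()),
         n_check_mismatches = NA_integer_),
    class = "reconstruction")
}

#' Render the reconstructed haplotypes as case-marked strings
#'
#' Uppercase marks columns supported by both input strings, lowercase marks
#' single-sequence support; unresolved columns show their IUPAC ambiguity
#' character.
#'
#' @param result A [resolve_haplotypes()] object.
#' @return Named character vector `c(hap1 = ..., hap2 = ...)`.
#' @export
haplotype_strings <- function(result) {
  stopifnot(inherits(result, "reconstruction"))
  c(hap1 = render_cased(result$hap1, result$support1),
    hap2 = render_cased(result$hap2, result$support2))
}

#' Check the reconstruction against the input strings
#'
#' Step 4: simulating the simultaneous sequencing of the two reconstructed
#' haplotypes must reproduce every code observed in the forward and reverse
#' strings. For each physical position the predicted code is the union of
#' the two mapped haplotype possibility sets; any difference from the
#' observed code is appended as a warning (`strand`, 1-based `position`,
#' `observed`, `predicted`), and `n_check_mismatches` counts them.
#'
#' @inheritParams rank_offsets
#' @param result A [resolve_haplotypes()] object for the same inputs.
#' @return The updated `"reconstruction"` object.
#' @export
check_consistency <- function(fwd, rev, result) {
  stopifnot(inherits(result, "reconstruction"))
  fm <- as_mask(fwd, "fwd")
  rm <- as_mask(rev, "rev")
  pos <- physical_positions(fm, rm, result$offsets[1], result$offsets[2],
                            result$col_start[1], result$col_start[2])
  pred <- bitwOr(result$hap1[pos$c1], result$hap2[pos$c2])
  bad <- pred != pos$observed
  result$warnings <- tibble(
    strand = pos$strand[bad], position = pos$position[bad],
    observed = .mask_chars[pos$observed[bad]], predicted = .mask_chars[pred[bad]])
  result$n_check_mismatches <- sum(bad)
  result
}

#' @export
print.reconstruction <- function(x, ...) {
  hs <- haplotype_strings(x)
  cat(sprintf("Haplotype reconstruction at offsets (%d, %d)\n",
              x$offsets[1], x$offsets[2]))
  cat("  hap1:", hs[["hap1"]], "\n")
  cat("  hap2:", hs[["hap2"]], "\n")
  if (!is.na(x$n_check_mismatches)) {
    cat(sprintf("  remix check: %d mismatch(es) with the input strings\n",
                x$n_check_mismatches))
  }
  if (nrow(x$resolution_warnings) > 0) {
    cat(sprintf("  %d resolution warning(s)\n", nrow(x$resolution_warnings)))
  }
  invisible(x)
}

#' @export
tidy.reconstruction <- function(x, ...) {
  dplyr::bind_rows(
    tibble(haplotype = "hap1", column = seq_along(x$hap1),
           code = .mask_chars[x$hap1], support = x$support1,
           n_bases = .mask_size[x$hap1]),
    tibble(haplotype = "hap2", column = seq_along(x$hap2),
           code = .mask_chars[x$hap2], support = x$support2,
           n_bases = .mask_size[x$hap2]))
}

#' @export
glance.reconstruction <- function(x, ...) {
  tibble(offset1 = x$offsets[1], offset2 = x$offsets[2],
         len_hap1 = length(x$hap1), len_hap2 = length(x$hap2),
         n_unresolved = length(x$unresolved$hap1) + length(x$unresolved$hap2),
         n_resolution_warnings = nrow(x$resolution_warnings),
         n_check_mismatches = x$n_check_mismatches)
}

#' Evaluate alternative offset pairs
#'
#' Step 5: runs the full reconstruction and remix check for every unordered
#' pair among the `k` best-ranked offsets, and tabulates the number of check
#' mismatches each pair leaves unexplained. The default pair (the two
#' top-ranked offsets) should also minimise the mismatch count; when it does
#' not, a nearby pair is worth inspecting.
#'
#' @inheritParams rank_offsets
#' @param ranked A [rank_offsets()] tibble for the same inputs.
#' @param k Number of top-ranked offsets to combine (>= 2).
#' @return A tibble with columns `o1`, `o2`, `n_check_mismatches`,
#'   `score_sum`, sorted by ascending mismatches then descending combined
#'   score.
#' @export
explore_offset_pairs <- function(fwd, rev, ranked, k = 5L) {
  stopifnot(k >= 2)
  if (nrow(ranked) < 2L) abort("At least two candidate offsets are required.")
  top <- head(ranked, k)
  prs <- combn(nrow(top), 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    res <- resolve_haplotypes(fwd, rev, top$offset[a], top$offset[b])
    res <- check_consistency(fwd, rev, res)
    tibble(o1 = top$offset[a], o2 = top$offset[b],
           n_check_mismatches = res$n_check_mismatches,
           score_sum = top$score[a] + top$score[b])
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$n_check_mismatches, dplyr::desc(.data$score_sum))
}
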