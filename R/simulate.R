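# Simulation benchmark: length-variant heterozygote pairs, mixed forward and
# reverse basecall strings, a 16-outcome basecalling-error model, 3' padding
# of the reverse read, and offset-recovery rates per scoring scheme.

#' Sample a random template sequence
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`. Uses the session RNG; seed upstream (e.g.
#' [run_trial()] seeds for you).
#'
#' @param length Sequence length.
#' @param gc GC fraction in `[0, 1]`.
#' @return A string over `ACGT`.
#' @export
sample_sequence <- function(length, gc) {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  if (length == 0) return("")
  paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Derive a length-variant haplotype pair from one template
#'
#' The first haplotype deletes the single base at one fourth of the template
#' length; the second deletes the two bases at three fourths (0-based
#' positions `floor(L/4)` and `floor(3L/4)`, `floor(3L/4) + 1`), so the two
#' haplotypes differ by 1 bp in length.
#'
#' @param seq Template string of length at least 8 (so the deletion sites
#'   are distinct).
#' @return List with `hap1` (length `L - 1`) and `hap2` (length `L - 2`).
#' @export
#' @examples
#' make_haplotypes("AACCGGTT")
make_haplotypes <- function(seq) {
  L <- nchar(seq)
  if (L < 8) abort("The template must be at least 8 bp so the deletion positions are distinct.")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  d1 <- floor(L / 4) + 1L
  d2 <- floor(3 * L / 4) + 1L
  list(hap1 = paste(ch[-d1], collapse = ""),
       hap2 = paste(ch[-c(d2, d2 + 1L)], collapse = ""))
}

#' Mix two haplotypes into forward and reverse basecall strings
#'
#' Simulates sequencing the mixture from both ends. The forward trace is the
#' left-anchored position-wise union of the two haplotypes (a position where
#' they differ becomes a double-peak ambiguity code); positions beyond the
#' shorter haplotype's end carry only the longer one. The reverse trace is
#' the right-anchored union, reported as the raw reverse read, i.e.
#' reverse-complemented into the orientation a reverse Sanger read has.
#'
#' @param hap1,hap2 Haplotype strings (plain bases).
#' @return List with `fwd` (forward trace, forward orientation) and
#'   `rev_raw` (reverse trace in its native 5'-to-3' orientation).
#' @export
#' @examples
#' mix_traces("AACGGTT", "AACCGG")
mix_traces <- function(hap1, hap2) {
  m1 <- as_mask(hap1, "hap1")
  m2 <- as_mask(hap2, "hap2")
  if (length(m1) == 0L || length(m2) == 0L) abort("Haplotypes must be non-empty.")
  n <- max(length(m1), length(m2))
  pad_or <- function(a, b, shift_b) {
    out <- integer(n)
    ia <- seq_along(a)
    out[ia] <- a
    ib <- seq_along(b) + shift_b
    out[ib] <- bitwOr(out[ib], b)
    out
  }
  fwd <- pad_or(m1, m2, 0L)
  # right-anchored: column k holds hap1[k] | hap2[k - (len1 - len2)]
  d <- length(m1) - length(m2)
  rev_fwd_orient <- if (d >= 0L) pad_or(m1, m2, d) else pad_or(m2, m1, -d)
  list(fwd = mask_to_seq(fwd),
       rev_raw = reverse_complement(mask_to_seq(rev_fwd_orient)))
}

#' Inject basecalling errors into a trace
#'
#' Each position is hit independently with probability `rate`; a hit replaces
#' the character by one of 16 equally probable outcomes: any of the 15 IUPAC
#' codes, or no change. Uses the session RNG.
#'
#' @param trace Basecall string (IUPAC alphabet).
#' @param rate Per-position error probability in `[0, 1]`.
#' @return The corrupted string.
#' @export
apply_errors <- function(trace, rate) {
  stopifnot(rate >= 0, rate <= 1)
  m <- as_mask(trace, "trace")
  if (length(m) == 0L) return("")
  hit <- runif(length(m)) < rate
  if (any(hit)) {
    draw <- sample.int(16L, sum(hit), replace = TRUE)
    keep <- draw == 16L                  # the "no change" outcome
    repl <- m[hit]
    repl[!keep] <- draw[!keep]           # masks 1..15 enumerate the 15 codes
    m[hit] <- repl
  }
  mask_to_seq(m)
}

check_trial_ranges <- function(length, gc, padding) {
  if (length < 25 || length > 200) {
    warn(sprintf("Template length %d is outside the benchmarked range [25, 200].", length))
  }
  if (gc < 0.30 || gc > 0.50) {
    warn(sprintf("GC fraction %.2f is outside the benchmarked range [0.30, 0.50].", gc))
  }
  if (!padding %in% c(0L, 100L, 200L, 300L)) {
    warn(sprintf("Padding %d is outside the benchmarked set {0, 100, 200, 300}.", padding))
  }
}

#' Run one simulated mixed-sequencing experiment
#'
#' Full pipeline for one trial: sample a template, derive the length-variant
#' haplotype pair, mix the haplotypes into forward and reverse traces, inject
#' basecalling errors into both, append `padding` random bases (same GC bias,
#' error-free) to the 3' end of the raw reverse read to emulate a noisy read
#' end, reverse-complement the reverse read into forward orientation, and
#' rank all offsets under each requested scheme. By construction the true
#' offsets are `padding` (haplotype 1's frame) and `padding + 1` (haplotype
#' 2's); a scheme succeeds when its top-2 offsets equal that set.
#'
#' @param length Template length (benchmarked range 25-200; outside values
#'   warn).
#' @param gc GC fraction (benchmarked range 0.30-0.50).
#' @param error_rate Per-position basecalling-error probability.
#' @param padding Number of random bases appended to the raw reverse read's
#'   3' end (benchmarked values 0, 100, 200, 300).
#' @param schemes Scoring schemes to evaluate.
#' @param seed Integer seed; the trial is a pure function of its arguments.
#' @return An object of class `"tp_trial"`: list with `true_offsets`,
#'   `detected` (per-scheme top-2 offsets), `success` (named logical),
#'   `hap1`, `hap2`, `fwd`, `rev` (the strings actually scored) and the
#'   configuration.
#' @export
#' @examples
#' run_trial(length = 60, gc = 0.4, error_rate = 0, padding = 0, seed = 1)
run_trial <- function(length, gc, error_rate, padding = 0L,
                      schemes = c("overlap_corrected", "ambiguity_corrected",
                                  "longest_run"),
                      seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible trial.")
  schemes <- vapply(schemes, match_scheme, character(1), USE.NAMES = FALSE)
  padding <- as.integer(padding)
  check_trial_ranges(length, gc, padding)
  withr::with_seed(as.integer(seed), {
    tpl <- sample_sequence(length, gc)
    haps <- make_haplotypes(tpl)
    tr <- mix_traces(haps$hap1, haps$hap2)
    fwd <- apply_errors(tr$fwd, error_rate)
    rev_raw <- apply_errors(tr$rev_raw, error_rate)
    if (padding > 0L) rev_raw <- paste0(rev_raw, sample_sequence(padding, gc))
    rev_in <- reverse_complement(rev_raw)
    truth <- c(padding, padding + 1L)
    detected <- lapply(setNames(schemes, schemes), function(sc) {
      rk <- rank_offsets(fwd, rev_in, scheme = sc)
      rk$offset[1:2]
    })
    structure(
      list(true_offsets = truth,
           detected = detected,
           success = vapply(detected, function(d) setequal(d, truth), logical(1)),
           hap1 = haps$hap1, hap2 = haps$hap2,
           fwd = fwd, rev = rev_in,
           config = list(length = length, gc = gc, error_rate = error_rate,
                         padding = padding, schemes = schemes,
                         seed = as.integer(seed))),
      class = "tp_trial")
  })
}

#' @export
print.tp_trial <- function(x, ...) {
  cat(sprintf("Simulated trial (L = %d, GC = %.2f, error = %.2f, padding = %d)\n",
              x$config$length, x$config$gc, x$config$error_rate, x$config$padding))
  cat(sprintf("  true offsets: {%d, %d}\n", x$true_offsets[1], x$true_offsets[2]))
  for (sc in names(x$detected)) {
    cat(sprintf("  %-20s detected {%s} -> %s\n", sc,
                paste(sort(x$detected[[sc]]), collapse = ", "),
                if (x$success[[sc]]) "correct" else "wrong"))
  }
  invisible(x)
}

#' Offset-recovery study over a parameter grid
#'
#' Runs `reps` independent trials for every combination of the supplied
#' template lengths, GC fractions, error rates and paddings, and reports per
#' cell and scheme the proportion of trials whose top-2 offsets were exactly
#' the true pair. Per-trial seeds are derived deterministically from the
#' master seed, so any single trial can be replayed with [run_trial()].
#'
#' @param lengths,gcs,error_rates,paddings Vectors defining the grid.
#' @param reps Trials per grid cell.
#' @param schemes Scoring schemes to evaluate in every trial.
#' @param seed Master seed.
#' @return A tibble (subclass `"tp_study"`) with columns `L`, `gc`,
#'   `error_rate`, `padding`, `scheme`, `prop_correct`, `reps`.
#' @seealso [autoplot.tp_study()]
#' @export
run_study <- function(lengths, gcs, error_rates, paddings = 0L, reps = 100L,
                      schemes = c("overlap_corrected", "ambiguity_corrected",
                                  "longest_run"),
                      seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible study.")
  stopifnot(reps >= 1)
  grid <- tidyr::expand_grid(L = as.integer(lengths), gc = gcs,
                             error_rate = error_rates,
                             padding = as.integer(paddings))
  n_trials <- nrow(grid) * reps
  trial_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max, n_trials))
  rows <- purrr::pmap(
    list(grid$L, grid$gc, grid$error_rate, grid$padding, seq_len(nrow(grid))),
    function(L, gc, er, pad, cell) {
      seeds <- trial_seeds[(cell - 1L) * reps + seq_len(reps)]
      succ <- matrix(FALSE, nrow = reps, ncol = length(schemes),
                     dimnames = list(NULL, schemes))
      for (r in seq_len(reps)) {
        tr <- run_trial(L, gc, er, pad, schemes = schemes, seed = seeds[r])
        succ[r, ] <- tr$success[schemes]
      }
      tibble(L = L, gc = gc, error_rate = er, padding = pad,
             scheme = schemes, prop_correct = colMeans(succ),
             reps = as.integer(reps))
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tp_study", class(tibble()))
  out
}
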