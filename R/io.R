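# Input parsing, the end-to-end deconvolution pipeline, and report
# serialisation (TSV / JSON / FASTA).

#' Read a basecall string from a file, FASTA record or literal
#'
#' Accepts a path to a plain-text or single-record FASTA file, a literal
#' FASTA record (starting with `>`), or a literal sequence string.
#' Whitespace and line breaks are stripped; the alphabet is validated (15
#' IUPAC codes, no gaps, no `U`). Reverse reads entered in their native
#' 5'-to-3' orientation can be flipped with `reverse_complement = TRUE`.
#'
#' @param source File path or literal string.
#' @param reverse_complement Reverse-complement the sequence after reading.
#' @param arg Name used in error messages.
#' @return A single uppercase string.
#' @export
read_basecalls <- function(source, reverse_complement = FALSE, arg = "sequence") {
  stopifnot(is.character(source), length(source) == 1L)
  if (file.exists(source) && !dir.exists(source)) {
    first <- readLines(source, n = 1L, warn = FALSE)
    if (length(first) == 1L && startsWith(trimws(first), ">")) {
      set <- Biostrings::readBStringSet(source)
      if (length(set) != 1L) {
        abort(sprintf("Expected exactly one sequence per input, found %d records in '%s'.",
                      length(set), source))
      }
      txt <- as.character(set[[1]])
    } else {
      txt <- paste(readLines(source, warn = FALSE), collapse = "")
    }
  } else if (startsWith(trimws(source), ">")) {
    lines <- strsplit(source, "\n", fixed = TRUE)[[1]]
    headers <- startsWith(trimws(lines), ">")
    if (sum(headers) != 1L) {
      abort(sprintf("Expected exactly one sequence per input, found %d records.",
                    sum(headers)))
    }
    txt <- paste(lines[!headers], collapse = "")
  } else {
    txt <- source
  }
  txt <- gsub("[[:space:]]", "", txt)
  if (!nzchar(txt)) abort(sprintf("`%s` is empty.", arg))
  m <- seq_to_mask(txt, arg = arg)           # validates the alphabet
  s <- mask_to_seq(m)
  if (reverse_complement) reverse_complement(s) else s
}

#' Deconvolute a mixed Sanger trace pair into two haplotypes
#'
#' The full pipeline. Step 1 ranks every ungapped offset between the forward
#' and reverse basecall strings under the chosen scheme, estimates the
#' shuffle null, fits a Gumbel distribution by moment matching and classifies
#' the significant outliers ([classify_outliers()]). Steps 2-4 reconstruct
#' the two haplotypes at the two best-scoring offsets (or at
#' `manual_offsets`) and remix-check them against the inputs. Step 5
#' (optional) evaluates all pairs among the `top_k` best offsets.
#'
#' @param fwd,rev Basecall strings in forward orientation (use
#'   [read_basecalls()] for files or to reverse-complement a 5'-to-3'
#'   reverse read).
#' @param scheme Scoring scheme; the ambiguity-corrected score is the
#'   recommended default because real mixed traces carry many ambiguity
#'   codes.
#' @param n_shuffles Shuffle iterations for the null (default 2000).
#' @param alpha Familywise significance level (Bonferroni-corrected over the
#'   number of offsets).
#' @param seed Integer seed for the shuffle null (required).
#' @param min_overlap Minimum overlap for an offset to be considered.
#' @param manual_offsets Optional integer pair overriding the automatic
#'   offset choice (scoring and classification still run).
#' @param explore_pairs Also evaluate all offset pairs among the top `top_k`.
#' @param top_k Number of top offsets for the pair exploration.
#' @return An object of class `"trace_report"`: list with `version`,
#'   `config`, `ranked` (annotated offset tibble), `fit`, `outcome`,
#'   `consensus1`, `consensus2`, `reconstruction` and optionally
#'   `pair_table`.
#' @export
#' @examples
#' rep <- deconvolute("ACGTACGTACGTAA", "CGTACGTACGTAAT",
#'                    n_shuffles = 200, seed = 1)
#' glance(rep)
deconvolute <- function(fwd, rev, scheme = "ambiguity_corrected",
                        n_shuffles = 2000L, alpha = 0.05, seed,
                        min_overlap = 1L, manual_offsets = NULL,
                        explore_pairs = FALSE, top_k = 5L) {
  if (missing(seed)) abort("`seed` is required: the shuffle null must be reproducible.")
  scheme <- match_scheme(scheme)
  fwd <- read_basecalls(fwd, arg = "fwd")
  rev <- read_basecalls(rev, arg = "rev")
  ranked <- rank_offsets(fwd, rev, scheme = scheme, min_overlap = min_overlap)
  null <- shuffle_null_scores(fwd, rev, scheme = scheme, n = n_shuffles,
                              seed = seed, min_overlap = min_overlap)
  fit <- fit_gumbel(null)
  outcome <- classify_outliers(ranked, fit, alpha = alpha)
  ranked <- outcome$offsets

  if (!is.null(manual_offsets)) {
    stopifnot(length(manual_offsets) == 2L)
    offs <- as.integer(manual_offsets)
  } else {
    if (nrow(ranked) < 2L) {
      abort("Fewer than two candidate offsets: supply `manual_offsets` to force a pair.")
    }
    offs <- ranked$offset[1:2]
  }
  recon <- resolve_haplotypes(fwd, rev, offs[1], offs[2])
  recon <- check_consistency(fwd, rev, recon)
  pair_table <- if (isTRUE(explore_pairs)) {
    explore_offset_pairs(fwd, rev, ranked, k = min(top_k, nrow(ranked)))
  }
  structure(
    list(version = as.character(packageVersion("tracephase")),
         config = list(scheme = scheme, n_shuffles = as.integer(n_shuffles),
                       alpha = alpha, seed = as.integer(seed),
                       min_overlap = as.integer(min_overlap),
                       manual_offsets = manual_offsets,
                       explore_pairs = isTRUE(explore_pairs),
                       top_k = as.integer(top_k)),
         fwd = fwd, rev = rev,
         ranked = ranked, fit = fit, outcome = outcome,
         consensus1 = build_consensus(fwd, rev, offs[1]),
         consensus2 = build_consensus(fwd, rev, offs[2]),
         reconstruction = recon,
         pair_table = pair_table),
    class = "trace_report")
}

#' @export
print.trace_report <- function(x, ...) {
  cat("Mixed-trace deconvolution report\n")
  cat(sprintf("  scheme: %s | offsets tested: %d | outcome: %s (%d outlier(s))\n",
              x$config$scheme, nrow(x$ranked), x$outcome$category,
              x$outcome$n_outliers))
  cat("  five best alignments:\n")
  print(as_tibble(head(x$ranked, 5)))
  print(x$reconstruction)
  invisible(x)
}

#' @export
tidy.trace_report <- function(x, ...) as_tibble(x$ranked)

#' @export
glance.trace_report <- function(x, ...) {
  tibble(category = x$outcome$category, n_outliers = x$outcome$n_outliers,
         offset1 = x$reconstruction$offsets[1],
         offset2 = x$reconstruction$offsets[2],
         top_score = x$ranked$score[1],
         n_check_mismatches = x$reconstruction$n_check_mismatches,
         n_resolution_warnings = nrow(x$reconstruction$resolution_warnings))
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
}

report_json_list <- function(report) {
  rk <- as_tibble(report$ranked)
  rk$score <- as.numeric(fmt_num(rk$score))
  rk$p_value <- as.numeric(fmt_num(rk$p_value))
  out <- list(
    version = report$version,
    config = report$config[!vapply(report$config, is.null, logical(1))],
    inputs = list(fwd = report$fwd, rev = report$rev),
    offsets = rk,
    gumbel = list(mu = as.numeric(fmt_num(report$fit$mu)),
                  beta = as.numeric(fmt_num(report$fit$beta)),
                  sample_mean = as.numeric(fmt_num(report$fit$sample_mean)),
                  sample_sd = as.numeric(fmt_num(report$fit$sample_sd)),
                  n_samples = report$fit$n_samples),
    outcome = list(category = report$outcome$category,
                   n_outliers = report$outcome$n_outliers,
                   p_threshold = as.numeric(fmt_num(report$outcome$p_threshold))),
    consensus = list(as.character(report$consensus1), as.character(report$consensus2)),
    haplotypes = as.list(haplotype_strings(report$reconstruction)),
    chosen_offsets = report$reconstruction$offsets,
    n_check_mismatches = report$reconstruction$n_check_mismatches,
    check_warnings = as_tibble(report$reconstruction$warnings),
    resolution_warnings = as_tibble(report$reconstruction$resolution_warnings))
  if (!is.null(report$pair_table)) out$pair_table <- as_tibble(report$pair_table)
  out
}

#' Write a deconvolution report to disk
#'
#' Serialises a [deconvolute()] report: `offsets.tsv` (one row per
#' enumerated offset: offset, score, overlap, mismatches, p-value),
#' `null.tsv` (binned null histogram with the fitted curves),
#' `warnings.tsv`, `report.json` (the full report) and `haplotypes.fasta`
#' (two records, `hap1`/`hap2`, offsets in the description, lowercase
#' marking single-sequence support). Floats are written with 6 significant
#' digits; identical runs produce byte-identical files.
#'
#' @param report A [deconvolute()] report.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("tsv", "json", "fasta")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, formats = c("tsv", "json", "fasta")) {
  stopifnot(inherits(report, "trace_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if ("tsv" %in% formats) {
    tab <- as_tibble(report$ranked)[, c("offset", "score", "overlap_len",
                                        "n_compatible", "n_mismatch", "p_value")]
    tab$score <- fmt_num(tab$score)
    tab$p_value <- fmt_num(tab$p_value)
    p <- file.path(dir, "offsets.tsv")
    readr::write_tsv(tab, p)
    paths <- c(paths, p)
    hist_tab <- null_histogram(report$fit)
    hist_tab[] <- lapply(hist_tab, function(col) if (is.double(col)) fmt_num(col) else col)
    p <- file.path(dir, "null.tsv")
    readr::write_tsv(hist_tab, p)
    paths <- c(paths, p)
    p <- file.path(dir, "warnings.tsv")
    readr::write_tsv(as_tibble(report$reconstruction$warnings), p)
    paths <- c(paths, p)
    if (!is.null(report$pair_table)) {
      p <- file.path(dir, "offset_pairs.tsv")
      pt <- as_tibble(report$pair_table)
      pt$score_sum <- fmt_num(pt$score_sum)
      readr::write_tsv(pt, p)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(report_json_list(report), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    paths <- c(paths, p)
  }
  if ("fasta" %in% formats) {
    hs <- haplotype_strings(report$reconstruction)
    set <- Biostrings::BStringSet(unname(hs))
    names(set) <- sprintf("hap%d offset=%d", 1:2, report$reconstruction$offsets)
    p <- file.path(dir, "haplotypes.fasta")
    Biostrings::writeXStringSet(set, p, width = 70L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Re-read a serialised JSON report
#'
#' Parses a `report.json` written by [write_report()] back into a plain
#' list (tibbles for the tabular parts). Content round-trips: the parsed
#' list carries the same offsets, fit, outcome, haplotypes and warnings as
#' the in-memory report it came from.
#'
#' @param path Path to `report.json`.
#' @return A named list.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (nm in intersect(c("offsets", "check_warnings", "resolution_warnings",
                         "pair_table"), names(x))) {
    x[[nm]] <- as_tibble(x[[nm]])
  }
  x
}
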