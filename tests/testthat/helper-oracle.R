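# Naive, character-level reference scorer, written independently of the
# package's bitmask implementation: codes are character vectors of bases,
# the overlap is materialised pair by pair, and compatibility is a plain
# set intersection. Deliberately slow and literal.

oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_offsets <- function(len_fwd, len_rev, min_overlap = 1) {
  out <- integer(0)
  for (o in (-(len_fwd - 1)):(len_rev - 1)) {
    n <- 0
    for (i in 0:(len_fwd - 1)) {
      if (i + o >= 0 && i + o < len_rev) n <- n + 1
    }
    if (n >= min_overlap) out <- c(out, o)
  }
  out
}

# list of (fwd char, rev char) pairs in the overlap at offset o
oracle_pairs <- function(fwd, rev, o) {
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(rev, "")[[1]]
  pairs <- list()
  for (i in seq_along(f)) {
    j <- i + o
    if (j >= 1 && j <= length(r)) pairs[[length(pairs) + 1]] <- c(f[i], r[j])
  }
  pairs
}

oracle_score <- function(fwd, rev, o, scheme) {
  pairs <- oracle_pairs(fwd, rev, o)
  n <- length(pairs)
  compat <- vapply(pairs, function(p) {
    length(intersect(oracle_sets[[p[1]]], oracle_sets[[p[2]]])) > 0
  }, logical(1))
  if (scheme == "overlap_corrected") {
    sum(compat) - n / 4
  } else if (scheme == "ambiguity_corrected") {
    contrib <- 0
    for (k in seq_len(n)) {
      if (!compat[k]) next
      a <- oracle_sets[[pairs[[k]][1]]]
      b <- oracle_sets[[pairs[[k]][2]]]
      contrib <- contrib + if (length(a) == 1 && length(b) == 1) 1 else 0.5
    }
    contrib - n / 4
  } else {
    best <- 0; run <- 0
    for (k in seq_len(n)) {
      run <- if (compat[k]) run + 1 else 0
      best <- max(best, run)
    }
    best
  }
}

random_iupac <- function(n, ambiguous = TRUE) {
  alphabet <- if (ambiguous) names(oracle_sets) else c("A", "C", "G", "T")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

all_schemes <- c("overlap_corrected", "ambiguity_corrected", "longest_run")

# bundled worked example of a length-variant heterozygote mixed trace
example_fwd <- function() {
  read_basecalls(system.file("extdata", "mixed_trace_fwd.fasta",
                             package = "tracephase"))
}
example_rev <- function() {
  read_basecalls(system.file("extdata", "mixed_trace_rev.fasta",
                             package = "tracephase"))
}
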