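---
title: "Phasing length-variant heterozygotes from mixed Sanger traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing length-variant heterozygotes from mixed Sanger traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracephase)
```

## The model

A mixed Sanger chromatogram arises when two DNA templates are sequenced
simultaneously — typically the two alleles of a diploid marker. Wherever the
templates differ at a given electrophoretic position, the trace shows a
double peak, which basecallers encode as an IUPAC ambiguity code. We treat a
basecall string as a sequence of base *sets*: code `X` denotes a nonempty
subset of {A, C, G, T} (internally a 4-bit mask), and two codes are
*compatible* when their sets intersect.

For a length-variant heterozygote (LVH) — alleles of unequal length — the
forward and reverse reads go out of register at different points, so the two
strings align well at exactly two ungapped offsets, one per allele. The
package's working assumptions are therefore:

* the mixture contains at most two templates, read ungapped end to end;
* every observed peak comes from one template or the other;
* basecalling errors exist but are sparse enough that true offsets still
  dominate the score ranking.

The offset `o` places forward position `i` (0-based) against reverse
position `i + o`; `o` is the position of the first forward base in reverse
coordinates and may be negative. Offsets are enumerated exhaustively (every
alignment with at least `min_overlap` paired positions; default 1).

## Scoring schemes

Three per-offset scores are implemented, all on the compatibility relation
above:

* **overlap-corrected** — `#compatible − overlap/4`. The subtraction removes
  the expected chance matches of random bases (probability 1/4), otherwise
  long central overlaps would dominate and the baseline of the score-offset
  plot becomes mountain-shaped.
* **overlap-and-ambiguity-corrected** (default) — a compatible pair scores
  1 only when both codes are unambiguous (and hence equal); if either code
  is ambiguous the pair scores 0.5, because ambiguity codes are compatible
  with many partners and therefore carry less evidence. The `overlap/4`
  correction is retained: this scheme is a modification of the first, not a
  replacement of its chance correction. It is the default because real mixed
  traces are exactly the inputs where ambiguity codes are abundant.
* **longest uninterrupted overlap** — the length of the longest run of
  consecutive compatible positions. Runs are counted on *compatibility*
  (shared base), not strict character equality: a double-peak code that
  genuinely contains the template's base should extend a run, otherwise
  every heterozygous position would break runs and the scheme would be
  useless on precisely the traces it is meant for. This is a deliberate
  design choice where strict equality was also defensible.

Scores are multiples of 0.25 (or integers), exact in double precision, so
ranking uses exact comparisons. The ranking order is total and reproducible:
score descending, then observable mismatches ascending, then smaller
`|offset|`, then smaller offset. The last two keys are our own tie-break —
some tie rule is needed for determinism, and preferring central offsets is
the least surprising choice.

## The null model and outcome classification

The distribution of ungapped alignment scores between random sequences is
extreme-value type I (Gumbel). Rather than deriving its parameters
analytically, the package estimates them empirically: both input strings
are permuted (preserving base composition exactly), one offset is drawn
uniformly, and the score recorded; 2000 iterations by default. Permuting
*both* strings is the stricter reading of "shuffle the inputs" and makes the
null symmetric in the two reads. Moment matching gives scale
`β = s·√6/π` and location `μ = x̄ − γβ` (γ the Euler–Mascheroni constant),
and an offset's p-value is the Gumbel tail `1 − exp(−exp(−(s − μ)/β))`.

An offset is called an outlier when `p < α / n_offsets` with `α = 0.05` by
default. The Bonferroni correction is our choice: several hundred offsets
are tested per run, and an uncorrected 0.05 would flag ~5% of them by
chance; no specific threshold is canonical for this problem, so the
conservative familywise bound is used and `α` is exposed as a parameter.
The outlier count maps to four outcomes: 0 — no signal (probably mismatched
inputs); 1 — one alignment (homozygote, or heterozygote without indel);
2 — the LVH case, reconstruction proceeds; >2 — more than two templates
(CNV, contamination, PCR recombination), where reconstruction at any single
pair is only tentative and the offset-pair exploration table helps.

Reconstruction always uses the two *best-scoring* offsets (or a manual
pair), regardless of the outcome class — the class is a diagnostic, not a
gate.

## Consensus and mutual-explanation resolution

At each chosen offset the consensus holds, per column, the intersection of
the forward and reverse codes where both cover the column, and a lowercase
copy of the single covering code elsewhere. A both-covered column whose
codes are *incompatible* keeps the union of the two codes and is recorded
as a mismatch column: blanking it would discard evidence that the later
resolution and remix steps can still use.

Resolution iterates the explanation rule: for a physical input position
with observed set `X`, if the *other* haplotype's column there is resolved
to the single base `b`, this haplotype's column is intersected with
`X \ {b}` (or with `X` itself when `b` accounts for all of `X`). Updates
are applied in synchronous rounds: all candidates are computed from the
previous round's state and combined per column by intersection. Because
intersection is commutative, the result provably does not depend on the
order positions are visited — sequential in-place sweeping, the more
obvious implementation, turns out to be order-sensitive on noisy inputs,
which is why rounds are used. Every effective round strictly shrinks at
least one possibility set, so the loop terminates; an update that would
empty a column is refused and logged (the column keeps its previous set),
and a position where more than one base remains unexplained by the
two-haplotype model is logged as well — both are signs the input violates
the model's assumptions.

The remix check then unions the two mapped haplotype sets at every physical
position and compares with the observation; each difference becomes a
warning with strand and 1-based position, the user-facing currency for
"recheck your chromatogram here". Warning counts drive the optional
exploration of all pairs among the top-k offsets.

## The simulator

`run_trial()` emulates the bench reality the deconvolution is meant for:

* template length 25–200 bp and GC content 0.30–0.50 (values outside these
  ranges run with a warning — they leave the regime the benchmark was
  designed around);
* haplotype 1 deletes the base at `floor(L/4)` (0-based), haplotype 2 the
  two bases at `floor(3L/4)` and the following position. The fractions are
  the protocol; the flooring and 0-based anchoring are our fixed reading of
  them. The pair always differs by 1 bp in length;
* mixing is the position-wise union of the two haplotypes, left-anchored
  for the forward trace and right-anchored for the reverse trace, which is
  then reverse-complemented into its native orientation;
* basecalling errors hit each position independently with probability
  `error_rate`; a hit redraws the character uniformly from 16 outcomes (the
  15 IUPAC codes or "no change"), so even `rate = 1` leaves ~2/16 of
  unambiguous positions unchanged;
* `padding` random bases are appended to the raw reverse read's 3' end
  *after* error injection ("finally", in protocol order), drawn with the
  same GC bias as the template — the protocol is silent on the padding's
  composition, and composition-matched padding is the conservative choice
  since composition-biased padding would be easier to tell apart. Padding
  shifts the true offsets to `{P, P + 1}`;
* a scheme succeeds when its top-2 offsets equal the true set exactly; a
  tie that pushes a true offset to rank 3 counts as failure.

`run_study()` crosses parameter lists into a grid, derives one
sub-2³¹ seed per trial from the master seed (so any cell's trial can be
replayed in isolation by re-deriving the seed table), and returns a tidy
tibble of recovery proportions; `autoplot()` facets it by GC and error
rate.

What the simulator does *not* emulate: peak-height information, quality
scores, position-dependent error rates (real Sanger ends are noisier),
PCR-mediated recombination chimeras, and more-than-two-template mixtures.
Passing simulation tests therefore demonstrates correctness of the offset
and reconstruction machinery under the stated error model, not performance
on arbitrary real chromatograms.

## Numerical and interface choices

* IUPAC codes are 4-bit masks; set algebra is bitwise; gap characters and
  `U` are rejected rather than coerced, because the model is ungapped DNA
  basecalls and silent coercion would mask upstream problems.
* Scores are compared exactly; p-values use `expm1` for tail accuracy.
* The Gumbel fit refuses degenerate (zero-variance) nulls.
* All user-facing positions are 1-based; internal arithmetic is 0-based.
* Seeds are mandatory wherever randomness enters the library API (no hidden
  global-RNG dependence); the command line defaults the seed to a constant.
* Reports serialise floats at 6 significant digits; two runs with the same
  seed produce byte-identical TSV/JSON/FASTA.
* The test suite and acceptance script keep problem sizes modest by design:
  200 scoring-oracle pairs at lengths 5–30, 50 null-calibration replicates
  at 150 bp, 200 zero-noise trials at `L = 200`, and 300 trials per cell
  for the scheme comparisons — large enough for the stochastic bands
  asserted, small enough to run routinely.

## Known limitations

* Ungapped offsets only: a basecaller that drops or duplicates a peak
  mid-read breaks the single-offset-per-allele premise (the remix warnings
  will point at the region, but the tool cannot repair it).
* Two templates at most; for more, only the pair-exploration table is
  offered.
* The Gumbel null is an approximation for *optimal* scores of random
  sequences applied here to all offsets of shuffled sequences; its
  calibration is verified empirically at the ~5% level in the test suite,
  not proven.
* The longest-run scheme degrades on long, error-rich traces (runs break
  too often), which is why it is not the default despite excelling on
  short, clean inputs.
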