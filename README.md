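# tracephase

Deconvolution of the two haplotypes hidden in a mixed Sanger chromatogram.

## The problem

When a PCR amplicon from a diploid individual contains two templates — the
classic case being a **length-variant heterozygote (LVH)**, whose two alleles
differ by an indel — Sanger sequencing of the mixture produces chromatograms
full of double peaks. Basecallers encode those as IUPAC ambiguity codes
(`Y` = C or T, `W` = A or T, ...). Because the two alleles go out of register
at *different* points in the forward and the reverse read, the two basecall
strings together contain enough information to phase the mixture exactly,
like a system of two equations with two unknowns. `tracephase` reconstructs
both haplotypes from nothing but the forward and reverse basecall strings.

## The method

Write the forward string as `F` and the reverse string (in forward
orientation) as `R`, each a sequence of base *sets* (an IUPAC code `X`
denotes a nonempty subset of {A,C,G,T}). An ungapped **offset** `o` aligns
`F[i]` with `R[i + o]`; two codes are *compatible* when their sets intersect.

1. **Offset scoring.** Every offset is scored under one of three schemes:
   * *overlap-corrected*: `#compatible − overlap/4` (two random bases match
     with probability 1/4);
   * *overlap-and-ambiguity-corrected* (default): compatible pairs involving
     an ambiguity code count 0.5 instead of 1, since ambiguous codes match
     many partners by construction;
   * *longest uninterrupted overlap*: length of the longest run of
     consecutive compatible positions.
2. **Significance.** The null distribution of scores is estimated by
   shuffling both strings 2000 times (one random offset scored per shuffle)
   and fitting a Gumbel distribution by moment matching
   (`β = s·√6/π`, `μ = x̄ − γβ`). Each offset gets the tail p-value
   `P(S > s) = 1 − exp(−exp(−(s − μ)/β))`; outliers are counted at a
   Bonferroni-corrected threshold. Two outliers is the LVH signature; one
   suggests a homozygote or equal-length heterozygote; zero suggests
   mismatched inputs; more than two, more than two templates.
3. **Consensus and resolution.** At each of the two best offsets the
   column-wise intersection of `F` and `R` is one haplotype's starting
   point. Remaining ambiguities are resolved by mutual explanation: every
   observed peak must come from one haplotype or the other, so a `Y` whose
   partner haplotype is already a `C` at that physical position forces a `T`
   here. The rule is iterated to a fixpoint.
4. **Remix check.** Simulated co-sequencing of the two reconstructed
   haplotypes must reproduce every observed code; each discrepancy is
   reported with its strand and position so the user can recheck the
   chromatogram. Optionally all pairs among the top-k offsets are compared
   by this mismatch count.

A simulation benchmark (`run_trial()` / `run_study()`) generates LVH pairs
(one deletion at 1/4 of the template, two at 3/4), mixes them from both
ends, injects basecalling errors (each hit position is redrawn uniformly
from the 15 IUPAC codes plus "no change"), pads the reverse read's 3' end,
and measures how often each scheme recovers the true offset pair.

## Worked example

The package ships a small LVH mixed-trace pair under `inst/extdata/`:

```r
library(tracephase)
fwd <- read_basecalls(system.file("extdata", "mixed_trace_fwd.fasta", package = "tracephase"))
rev <- read_basecalls(system.file("extdata", "mixed_trace_rev.fasta", package = "tracephase"))
report <- deconvolute(fwd, rev, seed = 42)
report
#> Mixed-trace deconvolution report
#>   scheme: ambiguity_corrected | offsets tested: 65 | outcome: two_offsets (2 outlier(s))
#>   five best alignments:
#> # A tibble: 5 × 7
#>   offset score overlap_len n_compatible n_mismatch scheme                p_value
#>    <int> <dbl>       <int>        <int>      <int> <chr>                   <dbl>
#> 1      0 12.8           33           33          0 ambiguity_corrected 0.0000388
#> 2      1 12             32           32          0 ambiguity_corrected 0.0000723
#> 3    -20  2.75          13           10          3 ambiguity_corrected 0.147
#> 4    -18  2.75          15           11          4 ambiguity_corrected 0.147
#> 5     20  2.75          13            7          6 ambiguity_corrected 0.147
#> Haplotype reconstruction at offsets (0, 1)
#>   hap1: CTAAATTCAAATCACACTCGCGAAAATCATGAA
#>   hap2: cCTGAATTCAAATCACACTCGCGAAATCATGAAa
#>   remix check: 0 mismatch(es) with the input strings
```

The two strings align significantly at offsets 0 and 1 (the two Gumbel
outliers): the mixture contained two templates whose lengths differ by 1 bp.
The reconstructed haplotypes remix into exactly the observed double-peak
pattern (0 mismatches); lowercase letters mark positions supported by only
one of the two reads. `tidy(report)` returns the full offset table,
`glance(report)` a one-row summary, `autoplot(report)` the score-vs-offset
scatter, and `write_report(report, "out/")` serialises TSV + JSON + FASTA.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/tracephase.R deconvolute --forward fwd.fasta --reverse rev.fasta --out out/
Rscript inst/cli/tracephase.R simulate --lengths 50,100,200 --error-rates 0,0.05 --reps 200 --out out/
```

(the `deconvolute` exit code encodes the outcome: 0 two offsets, 3 no
signal, 4 single offset, 5 more than two templates).

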