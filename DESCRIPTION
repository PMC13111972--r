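Package: tracephase
Title: Haplotype Deconvolution from Mixed Sanger Chromatogram Basecalls
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the two haplotypes of a length-variant heterozygote
    from the forward and reverse basecall strings of a mixed Sanger
    chromatogram. Enumerates all ungapped offsets between the two strings,
    scores each under three IUPAC-aware schemes (overlap-corrected,
    overlap-and-ambiguity-corrected, longest uninterrupted overlap), calibrates
    offset significance against a shuffle-based Gumbel null distribution,
    builds per-offset consensus sequences, resolves remaining ambiguity codes
    by requiring every observed peak to be explained by one haplotype or the
    other, and checks the reconstruction by remixing the haplotypes. Includes
    a basecall-error simulator for benchmarking the scoring schemes and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
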