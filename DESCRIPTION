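Package: microfold
Title: Scale-Factor Normalization, Trimmed-Mean Summarization and
    Fold-Change Analysis for Replicated-Probe Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for single-channel spotted
    microarrays with within-array probe replication, as used in bacterial
    stress-response transcriptomics. Implements cross-array scale-factor
    normalization (control-mean over treatment-mean), trimmed-mean
    summarization of replicate probe spots (drop one maximum and one
    minimum, average the rest), expression ratios with the signed
    fold-change convention (ratios below one reported as negated
    reciprocals), threshold-based differential-expression calls,
    hypergeometric over-representation testing of annotation terms
    (Fisher and EASE variants) with Benjamini-Hochberg correction,
    comparative-CT (2^-ddCT) qPCR relative quantification with a
    reference-gene stability check, and microarray-versus-qPCR
    concordance. A synthetic-data generator emulating a 5,003-gene,
    five-replicate-probe array design with spiked fold changes, annotated
    term enrichment and matched qPCR plates provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
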