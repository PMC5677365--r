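Package: sistergss
Title: Cooperative, Independent or Redundant Effects of Sister-Histone
    Modifications on Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the joint contribution of a histone modification on
    the two sister histone H3 tails of a nucleosome to transcriptional
    reprogramming, from bulk RNA-seq expression tables of a five-strain
    genotype series (wild type, two single-tail mutants, double-tail mutant,
    and a methyltransferase deletion) sampled before and after glucose
    starvation. Computes reference-gene-normalized log2 fold-changes with
    replicate-consistency and zero-expression filters, screens
    modification-responsive genes by Student t-test, applies the Mid
    betweenness filter and the Gene Skewness Score (GSS), and assigns genes
    to cooperative, independent or redundant regulatory clusters. Includes a
    synthetic-data generator emulating the study design with planted
    regulatory modes, overlap and pathway-membership summaries, and a
    steady-state two-strain quality-control comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
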