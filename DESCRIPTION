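Package: iisnp
Title: Individual-Identification SNP Panels from Paired DNA and RNA Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives minimal individual-identification SNP panels from paired
    DNA- and RNA-based genotype call sets. Reads multi-sample VCFs into a
    genotype matrix, computes per-locus statistics (allele frequencies, call
    rate, observed/expected heterozygosity, fixation index, exact
    Hardy-Weinberg test with Benjamini-Hochberg FDR), prunes linked loci by
    genotype r-squared, and orchestrates the full filtering cascade with a
    per-stage audit trail. Quantifies the discriminative power of a panel via
    the probability of identity for unrelated individuals and for full sibs,
    and detects sample mix-ups between RNA and DNA call sets with an
    allele-concordance matching score. Includes a synthetic-cohort generator
    with planted filter violations, sib pairs and label swaps so the whole
    pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
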