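Package: ssrdem
Title: Microsatellite Diversity, Population Structure, and Demographic
    Inference for Germplasm Collections
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of diploid codominant marker panels (microsatellite /
    SSR genotypes) as used to characterize crop germplasm collections:
    per-locus and per-group diversity statistics with rarefied allelic
    richness and permutation tests, Weir-Cockerham F-statistics, Nei genetic
    distances, two-level AMOVA, neighbor-joining trees with bootstrap and
    principal coordinate analysis, Bayesian admixture clustering with run
    alignment and Evanno's delta-K diagnostic, heterozygosity-excess
    bottleneck tests under IAM/SMM/TPM mutation models, coalescent
    rejection-ABC estimation of present-to-past effective-size ratios and
    admixture proportions, and allele-coverage core-collection selection.
    Includes a forward simulator of admixed genotype panels and text-format
    readers and writers (GenePop, STRUCTURE, CSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
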