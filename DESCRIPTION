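Package: goshawkpop
Title: Population-Genomic Structure, Ancestry-Informative Marker Design and
    Hybrid-Index Estimation for Island/Continental Goshawk Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step population-genomic analysis pipeline for diploid
    biallelic SNP data: genotype-quality and missingness filtering, PCA and
    maximum-likelihood admixture clustering with cross-validation choice of K,
    Weir-Cockerham and Hudson F_ST, f3 admixture tests with block jackknife,
    windowed D_XY / net divergence D_A and divergence-time estimation,
    inbreeding coefficients, selection of ancestry-informative marker (AIM)
    panels from per-site F_ST ranks, and maximum-likelihood joint estimation
    of ancestry index S and interclass heterozygosity H from small marker
    panels. Includes a synthetic-data generator that emulates a strongly
    differentiated island cluster against a weakly structured continental
    cluster, with tiered missingness by tissue source and mtDNA control-region
    haplotypes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
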