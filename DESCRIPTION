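Package: metafoundr
Title: Genotype-Derived Metafounders for Pedigree-Genomic Relationship
    Matrix Compatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives latent population strata (metafounders) directly from
    SNP genotypes and injects them into the pedigree numerator relationship
    matrix to improve its compatibility with the genomic relationship matrix
    built at a base allele frequency of 0.5. Provides an unsupervised
    binomial-likelihood admixture estimator with EM updates and readers for
    ADMIXTURE .Q/.P output, regression-based projection of ancestry
    proportions onto additional animals, generalized least squares estimation
    of strata allele frequencies accounting for pedigree relatedness, the
    metafounder self-relationship matrix Gamma and its base rescalings, the
    stepwise approximation of the metafounder-augmented relationship matrix,
    compatibility diagnostics (element regression, mean differences,
    eigenvalue-scaled principal components), a sweep over the number of
    strata, pedigree utilities (numerator relationship matrix with
    inbreeding, half-sib family thinning), genotype quality control, and a
    gene-dropping simulator of admixed populations with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
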