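Package: geneloss
Title: Detecting Gene Loss from Genomes: Inactivating Mutations, Read
    Validation and Branch-Model dN/dS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for inferring gene loss (pseudogenization) from
    genome assemblies. Candidate loci are located by synteny against
    anchor genes, coding sequences are reconstructed by reference-guided
    alignment and screened for ORF-abolishing mutations (frameshift
    indels, premature stop codons, truncations), calls are validated
    against raw sequencing reads, independent inactivation events are
    counted on a species tree under Dollo parsimony, and relaxation of
    purifying selection is tested with a Goldman-Yang codon substitution
    model allowing per-branch-category dN/dS ratios, fitted by maximum
    likelihood with chi-squared likelihood-ratio tests against
    neutrality. A synthetic-locus simulator generates ground-truth data
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'codon-tables.R'
    'gy94.R'
    'io.R'
    'containers.R'
    'likelihood.R'
    'fit.R'
    'simulate.R'
    'annotate.R'
    'translation-align.R'
    'synteny.R'
    'validate.R'
    'loss.R'
    'fixtures.R'
    'pipeline.R'
    'geneloss-package.R'
    'RcppExports.R'
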