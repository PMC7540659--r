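Package: cagewas
Title: Mixed-Model GWAS for Group-Housed Animals with Cage-Mean Phenotypes
Version: 0.1.0
Authors@R:
    person("Cagewas", "Developers", email = "cagewas@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association tools for livestock raised in collective
    cages, where feed intake is recorded per cage rather than per animal and
    only a fraction of cage members are genotyped.  Implements pedigree-based
    numerator relationship matrices, derivation of growth and feed-efficiency
    traits (average daily gain, cage feed intake, feed conversion ratio,
    residual feed intake) from raw weekly records, genotype quality control
    and linkage-disequilibrium profiling, an EMMAX-style per-SNP mixed-model
    scan for individually recorded traits, a bivariate animal model treating
    SNP allele content as a correlated trait fitted by EM-REML (which maps
    cage-average phenotypes while borrowing information from non-genotyped
    cage mates through the pedigree), Storey positive-FDR q-values at
    genome-wide and chromosome-wide levels, QTL-region merging, and a
    synthetic-data generator reproducing the full experimental design for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
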