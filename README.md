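# cagewas

Mixed-model GWAS for group-housed livestock whose feed efficiency is
recorded **per cage**, not per animal, and where only a minority of cage
members are genotyped.

## The problem and who this is for

Commercial rabbits (and many pigs and poultry) are fattened in collective
cages. Individual body weights are easy to record, so growth (average daily
gain, ADG) is an individual trait; feed intake is measured per cage, so
feed-efficiency traits — average daily feed intake (ADFI), feed conversion
ratio (FCR = ADFI / cage-mean ADG) and residual feed intake (RFI, the
residual of a batch-nested regression of ADFI on cage-mean ADG and metabolic
weight) — exist only as cage means. Genotyping every cage member is rarely
affordable. `cagewas` is aimed at animal-breeding researchers who want to
run a GWAS in exactly this situation.

Two engines are provided:

1. **Per-SNP mixed-model scan** (individually recorded traits): the animal
   model

   *y* = SNP·α + batch + parity + litter-size class + size class +
   cage + litter + *a* + *e*,  *a* ~ N(0, *A*σ²ₐ)

   fitted by ML with a per-SNP likelihood-ratio test on χ²(1)
   (`mode = "exact"`), or the fast EMMAX variant (REML null once, then GLS
   per SNP, `mode = "emmax"`).

2. **Bivariate allele-content model** (cage-mean traits): each SNP's allele
   content (0/1/2, observed only on genotyped animals) is treated as a
   second trait, SNPᵢ = μ + a₂ᵢ + e₂ᵢ, correlated with the performance
   trait through the genetic covariance σ_a1a2 with kernel G₀ ⊗ A. Cage
   means carry 1/N weights on their members' additive and litter effects and
   residual variance σ²ₑ₁/N. Fitted by EM-REML; the association test is the
   LRT of σ_a1a2 = 0, and the SNP effect is

   α̂ₚ = σ̂_a1a2 / (2 fₚ (1 − fₚ)).

   Non-genotyped cage mates contribute through the pedigree — the reason
   this model exists.

Everything upstream and downstream is included: PLINK bed/bim/fam I/O,
pedigree reading and the numerator relationship matrix **A** (tabular method
with inbreeding), trait derivation from raw weekly records (including the
0.75 × 1.1 restricted-feeding ration rule), genotype QC (call rate ≥ 90%,
SNP missingness < 5%, MAF > 5%), LD r² decay profiling with 20 kb distance
pruning, Storey pFDR q-values at genome- or chromosome-wide level, QTL
region merging (significant SNPs < 1 Mb apart) and ±1 Mb annotation
windows, plus a synthetic-data generator reproducing the full experimental
design (batches, litters, size classes, the two feeding regimes, weekly
records, distance-decaying LD).

## Worked example

```r
library(cagewas)

# simulate a 2-batch experiment: cages of 6, half the animals genotyped,
# one causal SNP (effect 4 g/day on growth)
cfg <- sim_config(n_batches = 2, cages_per_batch = 10, animals_per_cage = 6,
                  n_snps = 40, n_chromosomes = 2, frac_genotyped = 0.5,
                  causal = data.frame(snp = 7, trait = "adg", effect = 4),
                  seed = 101)
sim <- simulate_all(cfg)

# derive traits from the raw weekly records
tr <- derive_traits(sim$animals, sim$phen$bw, sim$phen$cage_feed)
round(tapply(tr$individual$adg, tr$individual$regime, mean), 1)
#>    F    R
#> 61.5 46.5          # ad-libitum vs restricted growth, g/day (the causal
#>                    # SNP and sampled batch effects shift both means up)
round(mean(tr$cage$fcr), 2)
#> [1] 2.78           # feed per unit gain, close to the 2.8 target

# relationship matrix and a cage-mean GWAS for FCR
A <- build_A(sim$ped)
litter_of <- setNames(sim$animals$litter, sim$animals$animal)
des <- build_bivar_design(tr$cage, "cage", sim$genotyped_ids, A,
                          trait = "fcr", litter_of = litter_of)
G <- structure(list(geno = sim$geno$content[sim$genotyped_ids, ],
                    map = sim$geno$map), class = "genotypes")
res <- scan_bivariate(des, G)
res <- correct_records(res, level = "chromosome", pfdr = 0.05)
head(res[order(res$p), c("snp_id", "effect", "lrt", "p", "q")], 3)
#>       snp_id     effect      lrt           p          q
#> 17 SNP1_0017 -0.2547142 7.239813 0.007130442 0.05660973
#> 5  SNP1_0005 -0.3887513 6.155841 0.013097882 0.05660973
#> 4  SNP1_0004 -0.5347508 6.059474 0.013831889 0.05660973
```

(At this toy size nothing clears the 0.05 q-value bar -- the causal
effect was planted on growth, and 20 cages of FCR carry little
information; the full-size behaviour is exercised by the test suite.)

The `effect` column is in trait units per allele copy (FCR units here);
`q` is the chromosome-wide Storey q-value. How much phenotypic variance a
top SNP explains:

```r
variance_explained(alpha = 0.52, f = 0.42, sigmaP2 = 0.2)
#> [1] 0.6586944      # i.e. ~66% of FCR phenotypic variance
```

## Command line

A thin CLI wraps the same functions (see `inst/exec/cagewas`):

```sh
Rscript inst/exec/cagewas simulate --out simdir --seed 1
Rscript inst/exec/cagewas qc --bed simdir/geno --out simdir/geno_qc
Rscript inst/exec/cagewas gwas-bivar --dir simdir --trait fcr --out fcr.tsv
Rscript inst/exec/cagewas qvalue --assoc fcr.tsv --level chromosome --out fcr_q.tsv
Rscript inst/exec/cagewas regions --assoc fcr_q.tsv --out fcr_regions.tsv
```

## Documentation

The methods vignette (`vignettes/cagewas-methods.Rmd`) describes the models,
the EM-REML fitter and its monotonicity-safe acceleration, every tunable
constant with its default and rationale, what the simulator does and does
not emulate, and known limitations.
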