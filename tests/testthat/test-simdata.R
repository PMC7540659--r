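test_that("pedigree simulation honors the housing constraints", {
  sim <- fix_sim_small(seed = 71)
  an <- sim$animals
  # at most two kits per litter in any cage
  expect_lte(max(table(an$litter, an$cage)), 2L)
  # every litter with >= 2 caged kits appears in both feeding regimes
  per_litter <- split(an$regime, an$litter)
  multi <- per_litter[lengths(per_litter) >= 4L]
  both <- vapply(multi, function(r) all(c("F", "R") %in% r), TRUE)
  expect_gt(mean(both), 0.9)
  # factor levels come from the declared sets
  expect_true(all(an$parity %in% 1:4))
  expect_true(all(an$litter_size_class %in% 1:7))
  expect_true(all(an$size_class %in% c("LS", "SS")))
  # same seed -> identical output
  sim2 <- fix_sim_small(seed = 71)
  expect_identical(sim$animals, sim2$animals)
  expect_identical(sim$geno$content, sim2$geno$content)
  expect_identical(sim$phen$bw, sim2$phen$bw)
  # infeasible: more cage slots than kits can fill
  expect_error(
    simulate_all(sim_config(n_batches = 1, cages_per_batch = 400,
                            animals_per_cage = 8,
                            n_founder_sires = 2, n_founder_dams = 2,
                            n_parent_sires = 2, n_parent_dams = 3,
                            seed = 1)),
    "infeasible|not enough")
})

test_that("simulated genotypes segregate through the pedigree", {
  cfg <- sim_config(n_batches = 2, cages_per_batch = 10,
                    animals_per_cage = 8, n_snps = 60, n_chromosomes = 2,
                    seed = 83)
  set.seed(cfg$seed)
  sp <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(sp$ped, cfg)
  expect_true(all(geno$content %in% 0:2))
  # offspring share alleles with parents: parent-offspring genotype
  # correlation around 0.5 across many pairs
  ped <- sp$ped
  has_sire <- which(!is.na(ped$sire))
  cors <- vapply(sample(seq_len(ncol(geno$content)), 30), function(j) {
    g <- geno$content[, j]
    suppressWarnings(cor(g[ped$animal[has_sire]], g[ped$sire[has_sire]]))
  }, 0)
  expect_equal(mean(cors, na.rm = TRUE), 0.5, tolerance = 0.12)
  # neighbouring SNPs are correlated, distant ones are not
  kit_g <- geno$content[sp$animals$animal, ]
  map <- geno$map
  c1 <- map$chrom == map$chrom[1]
  r2_near <- ld_r2(kit_g[, 1], kit_g[, 2])
  expect_true(is.na(r2_near) || r2_near >= 0)   # defined and bounded
  # d0 -> 0: essentially independent neighbours
  cfg0 <- sim_config(n_batches = 1, cages_per_batch = 8,
                     animals_per_cage = 8, n_snps = 40, n_chromosomes = 1,
                     d0_bp = 1, seed = 85)
  set.seed(cfg0$seed)
  sp0 <- simulate_pedigree(cfg0)
  g0 <- simulate_genotypes(sp0$ped, cfg0)
  founders <- sp0$ped$animal[is.na(sp0$ped$sire)]
  r2 <- mapply(function(a, b) ld_r2(g0$content[founders, a],
                                    g0$content[founders, b]),
               1:30, 2:31)
  expect_lt(mean(r2, na.rm = TRUE), 0.12)
})

test_that("phenotypes carry the configured signal", {
  # no noise, no genetic or environmental variance: ADG equals the mean
  cfg <- sim_config(n_batches = 2, cages_per_batch = 10,
                    animals_per_cage = 6, n_snps = 10, n_chromosomes = 1,
                    vc_adg = c(sigma_a2 = 1e-8, sigma_c2 = 1e-12,
                               sigma_l2 = 1e-12, sigma_e2 = 1e-12),
                    vc_fi = c(sigma_a2 = 1e-8, sigma_e2 = 1e-8),
                    bw_noise_sd = 1e-6, seed = 87)
  sim <- simulate_all(cfg)
  tr <- derive_traits(sim$animals, sim$phen$bw, sim$phen$cage_feed)
  ind <- tr$individual
  # fixed batch/parity effects remain, so allow their small spread
  expect_equal(mean(ind$adg[ind$regime == "F"]), 53.2, tolerance = 2.5)
  expect_equal(mean(ind$adg[ind$regime == "R"]), 35.4, tolerance = 2.5)
  # a causal SNP effect is recovered by regression of ADG on content
  beta <- 4
  cfg2 <- sim_config(n_batches = 3, cages_per_batch = 14,
                     animals_per_cage = 8, n_snps = 30, n_chromosomes = 1,
                     causal = data.frame(snp = 5, trait = "adg",
                                         effect = beta), seed = 89)
  sim2 <- simulate_all(cfg2)
  tr2 <- derive_traits(sim2$animals, sim2$phen$bw, sim2$phen$cage_feed)
  g <- sim2$geno$content[as.character(tr2$individual$animal), 5]
  fit <- summary(lm(tr2$individual$adg ~ g +
                      factor(tr2$individual$regime)))
  expect_lt(abs(fit$coefficients[2, 1] - beta),
            2 * fit$coefficients[2, 2] + 0.5)
})

test_that("emitted files round-trip through the readers", {
  sim <- fix_sim_small(seed = 91)
  out <- file.path(tempdir(), "simout")
  sim_emit(sim, out)
  G <- read_genotypes(file.path(out, "geno"))
  expect_identical(unname(G$geno),
                   unname(sim$geno$content[sim$genotyped_ids, ]))
  ped <- read_pedigree(file.path(out, "pedigree.csv"))
  expect_setequal(ped$animal, sim$ped$animal)
  an <- utils::read.csv(file.path(out, "animals.csv"),
                        stringsAsFactors = FALSE)
  expect_identical(sort(an$animal), sort(sim$animals$animal))
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$genotyped_ids, sim$genotyped_ids)
  expect_equal(truth$vc_adg$sigma_a2, sim$config$vc_adg[["sigma_a2"]])
  expect_setequal(truth$breeding_values$animal, sim$ped$animal)
  # truth is consistent with the emitted phenotype files
  bw <- utils::read.csv(file.path(out, "bw.csv"), stringsAsFactors = FALSE)
  expect_setequal(unique(bw$animal), sim$animals$animal)
  expect_equal(sort(unique(bw$age_days)), c(30, 37, 44, 51))
})
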