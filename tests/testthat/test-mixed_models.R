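test_that("fit_model1 collapses to OLS when variance ratios vanish", {
  set.seed(41)
  n <- 60
  ped <- data.frame(animal = sprintf("u%02d", 1:n), sire = NA, dam = NA)
  A <- build_A(read_pedigree(ped))
  snp <- setNames(sample(0:2, n, TRUE), ped$animal)
  pheno <- data.frame(animal = ped$animal,
                      batch = rep(c("b1", "b2"), n / 2),
                      cage = rep(sprintf("c%d", 1:6), each = 10),
                      litter = rep(sprintf("l%d", 1:12), each = 5),
                      adg = rnorm(n, 50, 3))
  # iid data on unrelated founders: ML variance ratios go to ~0 and the
  # SNP coefficient approaches plain OLS
  fit <- fit_model1(pheno, A, snp = snp)
  X <- model.matrix(~ factor(pheno$batch) + snp[pheno$animal])
  ols <- lm.fit(X, pheno$adg)$coefficients
  expect_equal(fit$alpha, unname(ols[3]), tolerance = 1e-3)
})

test_that("fit_model1 estimates no effect for an orthogonal SNP", {
  set.seed(43)
  n <- 40
  ped <- data.frame(animal = sprintf("v%02d", 1:n), sire = NA, dam = NA)
  A <- build_A(read_pedigree(ped))
  # noise-free construction: y depends only on batch; snp balanced within
  batch <- rep(c("b1", "b2"), each = n / 2)
  snp <- setNames(rep(c(0, 1, 2, 1), n / 4), ped$animal)
  y <- ifelse(batch == "b1", 50, 60)
  pheno <- data.frame(animal = ped$animal, batch = batch,
                      cage = rep(c("c1", "c2"), n / 2),
                      litter = rep(c("l1", "l2"), n / 2), adg = y)
  fit <- fit_model1(pheno, A, snp = snp)
  expect_lt(abs(fit$alpha), 1e-6)
})

test_that("model-1 ML log-likelihood matches a direct optimizer", {
  set.seed(47)
  sim <- fix_sim_small(seed = 53)
  tr <- derive_traits(sim$animals, sim$phen$bw, sim$phen$cage_feed)
  ind <- tr$individual[tr$individual$regime == "F", ][1:60, ]
  A <- build_A(sim$ped)
  fit <- fit_model1(ind, A, trait = "adg")
  ids <- as.character(ind$animal)
  X <- cagewas:::build_fixed(ind)
  KC <- tcrossprod(cagewas:::incidence(ind$cage))
  KL <- tcrossprod(cagewas:::incidence(ind$litter))
  KA <- subset_relmat(A, ids)$A
  y <- ind$adg; n <- length(y)
  nll <- function(lv) {
    v <- exp(lv)
    V <- v[1] * KC + v[2] * KL + v[3] * KA + v[4] * diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    r <- lm.fit(Xi, yi)$residuals
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  }
  o <- optim(log(c(5, 5, 10, 30)), nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$loglik, -o$value, tolerance = 1e-4)
})

test_that("likelihood-ratio machinery maps to chi-squared(1)", {
  f <- function(ll) structure(list(loglik = ll), class = "cagewas_fit")
  expect_equal(lrt_covariance(f(-10), f(-10))$p, 1)
  t1 <- lrt_covariance(f(-10 + 1.92073), f(-10))
  expect_equal(t1$p, 0.05, tolerance = 1e-4)
  expect_warning(out <- lrt_covariance(f(-10.01), f(-10)), "clamping")
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
})

test_that("variance_explained implements 2f(1-f)a^2/sigmaP2", {
  expect_equal(variance_explained(0, 0.3, 10), 0)
  # worked example with the strongest FCR-region SNP inputs
  expect_equal(variance_explained(0.52, 0.42, 0.2), 0.6587,
               tolerance = 1e-3)
  # growth example lands in the mid single digits
  expect_equal(variance_explained(3.68, 0.39, 77.6), 0.0830,
               tolerance = 1e-3)
  # inverting the formula round-trips an effect/frequency pair
  alpha <- 0.52; f <- 0.42
  sigma_a12 <- alpha * 2 * f * (1 - f)
  expect_equal(sigma_a12, 0.2533, tolerance = 1e-3)
  expect_equal(sigma_a12 / (2 * f * (1 - f)), alpha)
  expect_error(variance_explained(1, 0, 1), "\\(0, 1\\)")
  expect_error(variance_explained(1, 0.5, 0), "positive")
})

test_that("bivariate fit: null constrains the covariance, alpha follows it", {
  sim <- fix_sim_small(seed = 59)
  tr <- derive_traits(sim$animals, sim$phen$bw, sim$phen$cage_feed)
  A <- build_A(sim$ped)
  litter_of <- setNames(sim$animals$litter, sim$animals$animal)
  des <- build_bivar_design(tr$cage, "cage", sim$genotyped_ids, A,
                            trait = "fcr", litter_of = litter_of)
  snp <- sim$geno$content[sim$genotyped_ids, 7]
  f0 <- fit_bivariate(des, snp, null = TRUE)
  expect_equal(f0$vc[["sigma_a12"]], 0)
  expect_equal(f0$alpha, 0)
  f1 <- fit_bivariate(des, snp, null = FALSE)
  expect_equal(f1$alpha,
               f1$vc[["sigma_a12"]] / (2 * f1$freq * (1 - f1$freq)))
  # REML log-likelihood is non-decreasing at every EM iteration
  expect_true(all(diff(f0$loglik_trace) > -1e-6))
  expect_true(all(diff(f1$loglik_trace) > -1e-6))
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  # monomorphic allele content is rejected
  expect_error(fit_bivariate(des, rep(2, length(snp))), "monomorphic")
})

test_that("allele-content heritability is near 1 on error-free genotypes", {
  # per-SNP h2 of allele content is a noisy diagnostic (the genetic vs
  # residual split of content variance rides on the relatedness of the
  # genotyped subset), so the assertion targets its median over SNPs
  sim <- fix_sim_small(seed = 61)
  tr <- derive_traits(sim$animals, sim$phen$bw, sim$phen$cage_feed)
  A <- build_A(sim$ped)
  litter_of <- setNames(sim$animals$litter, sim$animals$animal)
  des <- build_bivar_design(tr$cage, "cage", sim$genotyped_ids, A,
                            trait = "fcr", litter_of = litter_of)
  h2 <- vapply(c(3, 7, 9, 15, 21, 27, 33), function(j) {
    f0 <- fit_bivariate(des, sim$geno$content[sim$genotyped_ids, j],
                        null = TRUE)
    f0$vc[["sigma_a2"]] / (f0$vc[["sigma_a2"]] + f0$vc[["sigma_e2"]])
  }, 0)
  expect_gte(median(h2), 0.9)
})

test_that("cage-mean records carry 1/N weights on effects and residuals", {
  # two-cage toy with member counts 2 and 4: the residual variance of a
  # cage-mean record must scale as sigma_e1^2 / N
  ped <- data.frame(animal = sprintf("t%02d", 1:8), sire = NA, dam = NA)
  A <- build_A(read_pedigree(ped))
  cage_df <- data.frame(cage = c("cgA", "cgB"), batch = "b1",
                        size_class = c("LS", "SS"),
                        n_members = c(2L, 4L),
                        members = I(list(ped$animal[1:2], ped$animal[3:6])),
                        fcr = c(2.5, 2.9))
  litter_of <- setNames(rep(c("l1", "l2"), 4), ped$animal)
  des <- build_bivar_design(cage_df, "cage", ped$animal[7:8], A,
                            trait = "fcr", litter_of = litter_of)
  expect_equal(des$d1, c(1 / 2, 1 / 4))
  # additive and litter incidence rows average the members
  expect_equal(rowSums(des$Z1), c(1, 1))
  expect_equal(max(des$Z1[1, ]), 1 / 2)
  expect_equal(max(des$Z1[2, ]), 1 / 4)
  expect_equal(rowSums(des$ZL1), c(1, 1))
})

test_that("group_genotype_regression matches the normal equations", {
  set.seed(67)
  members <- split(sprintf("g%03d", 1:99), rep(1:33, each = 3))
  snp <- setNames(sample(0:2, 99, TRUE), sprintf("g%03d", 1:99))
  gbar <- vapply(members, function(m) mean(snp[m]), 0)
  y <- 1.5 + 0.4 * gbar + rnorm(33, 0, 0.1)
  res <- group_genotype_regression(y, members, snp)
  X <- cbind(1, gbar)
  bhat <- solve(crossprod(X), crossprod(X, y))
  expect_equal(res$slope, bhat[2], tolerance = 1e-10, ignore_attr = TRUE)
  # exact linear construction recovers the slope exactly (lm warns that
  # the fit is perfect, which is the point)
  y0 <- 2 - 0.7 * gbar
  expect_equal(suppressWarnings(
    group_genotype_regression(y0, members, snp)$slope), -0.7,
    tolerance = 1e-10)
  expect_error(group_genotype_regression(y, members,
                                         setNames(rep(1, 99), names(snp))),
               "constant")
})
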