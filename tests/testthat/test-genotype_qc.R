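make_G <- function(geno, chrom = NULL, pos = NULL) {
  m <- ncol(geno)
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("s%03d", seq_len(m))
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("a%03d", 1:nrow(geno))
  map <- data.frame(snp_id = colnames(geno),
                    chrom = if (is.null(chrom)) "1" else chrom,
                    pos_bp = if (is.null(pos)) seq_len(m) * 1000L else pos,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  structure(list(geno = geno, map = map), class = "genotypes")
}

test_that("qc_filter applies thresholds with the paper's semantics", {
  n <- 10
  geno <- matrix(rep(c(0L, 1L), n * 5), n, 10)  # filler columns: MAF 0.25
  geno[, 1] <- c(rep(0L, 9), 2L)            # MAF 0.10 -> kept at 0.05
  geno[, 2] <- rep(0L, 10)                  # monomorphic -> dropped
  geno[, 3] <- c(rep(0L, 9), 1L)            # MAF 0.05 exactly -> dropped
  geno[, 4] <- rep(c(0L, 2L), 5)            # MAF 0.5 -> kept
  geno[, 10] <- c(NA, NA, rep(1L, 8))       # 20% missing -> dropped at 5%
  G <- make_G(geno)
  out <- qc_filter(G, 0.90, 0.05, 0.05)
  # enumeration by hand: samples all at >= 90% call rate; SNPs 2, 3, 10 go
  expect_setequal(colnames(out$geno),
                  c("s001", "s004", sprintf("s%03d", 5:9)))
  expect_equal(nrow(out$geno), 10L)
  # sample below the 90% call-rate boundary is removed first
  geno2 <- matrix(rep(c(0L, 2L), 50), 10, 10)
  geno2[1, 1:2] <- NA                        # 80% call rate sample
  G2 <- make_G(geno2)
  out2 <- qc_filter(G2, 0.90, 0.5, 0.05)
  expect_false("a001" %in% rownames(out2$geno))
  # idempotence
  again <- qc_filter(out, 0.90, 0.05, 0.05)
  expect_identical(again$geno, out$geno)
  # chromosome restriction and degenerate result
  G3 <- make_G(geno2[-1, ], chrom = rep(c("1", "X"), each = 5))
  out3 <- qc_filter(G3, 0.9, 0.5, 0.05, chromosomes = "1")
  expect_true(all(out3$map$chrom == "1"))
  expect_error(qc_filter(G3, 0.9, 0.5, 0.05, chromosomes = "ZZ"),
               "removed everything")
  expect_error(qc_filter(G, 1.5, 0.05, 0.05), "\\(0, 1\\)")
})

test_that("ld_r2 is squared Pearson correlation over complete pairs", {
  set.seed(21)
  g <- sample(0:2, 50, TRUE)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2L - g), 1)          # sign symmetry
  g2 <- g; g2[1:5] <- NA
  expect_equal(ld_r2(g, g2), 1)              # pairwise-complete
  big1 <- sample(0:2, 1e4, TRUE, prob = c(.25, .5, .25))
  big2 <- sample(0:2, 1e4, TRUE, prob = c(.25, .5, .25))
  expect_lt(ld_r2(big1, big2), 0.01)         # independent SNPs
  expect_error(ld_r2(c(1, NA), c(NA, 1)), "complete pairs")
})

test_that("prune_by_distance keeps the first SNP per window", {
  map <- data.frame(snp_id = c("p0", "p10", "p25", "p50"),
                    chrom = "1", pos_bp = c(1L, 10001L, 25001L, 50001L))
  expect_identical(prune_by_distance(map, 20000), c("p0", "p25", "p50"))
  one <- data.frame(snp_id = "x", chrom = "2", pos_bp = 5L)
  expect_identical(prune_by_distance(one, 20000), "x")
  # dense 1 kb grid over 100 kb: kept at 0, 20k, 40k, 60k, 80k, 100k
  grid <- data.frame(snp_id = sprintf("g%03d", 0:100), chrom = "1",
                     pos_bp = as.integer(0:100 * 1000 + 1))
  expect_length(prune_by_distance(grid, 20000), 6L)
})

test_that("ld_decay recovers a simulated decay profile", {
  set.seed(33)
  # latent AR(1) genotypes with rho = exp(-d/d0), d0 = 2 Mb, 60 SNPs
  n <- 500; m <- 60; d0 <- 2e6
  pos <- sort(sample.int(2e7, m))
  f <- runif(m, 0.3, 0.7)
  hap <- function() {
    z <- numeric(m); z[1] <- rnorm(1)
    rho <- exp(-diff(pos) / d0)
    for (k in seq_len(m - 1)) z[k + 1] <- rho[k] * z[k] +
        sqrt(1 - rho[k]^2) * rnorm(1)
    as.integer(z < qnorm(f))
  }
  geno <- matrix(0L, n, m)
  for (i in seq_len(n)) geno[i, ] <- hap() + hap()
  G <- make_G(geno, chrom = "1", pos = pos)
  dec <- ld_decay(G, max_dist_bp = 8e6, bin_bp = 1e6)
  # bounded in [0,1]; empty bins flagged with zero pairs
  expect_true(all(dec$mean_r2 >= 0 & dec$mean_r2 <= 1, na.rm = TRUE))
  expect_true(all(dec$n_pairs >= 0))
  # monotone decreasing trend over distance
  ok <- dec$n_pairs > 0
  expect_lt(cor(seq_len(nrow(dec))[ok], dec$mean_r2[ok],
                method = "spearman"), 0)
  # decay-scale recovery within a broad factor-of-two band: fit
  # log(mean r2) ~ distance on populated bins
  mid <- (dec$bin_start_bp + dec$bin_end_bp) / 2
  use <- ok & dec$mean_r2 > 0
  slope <- coef(lm(log(dec$mean_r2[use]) ~ mid[use]))[2]
  d0_hat <- -1 / slope
  expect_gt(d0_hat, d0 / 3)
  expect_lt(d0_hat, d0 * 3)
  # two SNPs on one chromosome: a single populated bin with one pair
  G2 <- make_G(geno[, 1:2], chrom = "1", pos = c(1L, 1500000L))
  dec2 <- ld_decay(G2, max_dist_bp = 8e6, bin_bp = 1e6)
  expect_equal(sum(dec2$n_pairs), 1)
})
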