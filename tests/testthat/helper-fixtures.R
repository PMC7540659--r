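# Shared fixture builders.  Everything is generated in code under fixed
# seeds; nothing binary ships with the package.

# small three-generation pedigree with known relationships
fix_pedigree_12 <- function() {
  data.frame(
    animal = c("s1", "s2", "d1", "d2",
               "a", "b",          # full sibs (s1 x d1)
               "c",               # half sib of a/b (s1 x d2)
               "e",               # unrelated-line animal (s2 x d2)
               "x", "y",          # gen 3: a x d2? keep valid: a x e parents
               "z", "w"),
    sire = c(NA, NA, NA, NA, "s1", "s1", "s1", "s2", "a", "a", "b", "c"),
    dam  = c(NA, NA, NA, NA, "d1", "d1", "d2", "d2", "e", "e", "e", "e"),
    stringsAsFactors = FALSE)
}

# a tiny default simulation shared by several tests
fix_sim_small <- function(seed = 101, ...) {
  cfg <- sim_config(n_batches = 2, cages_per_batch = 10,
                    animals_per_cage = 6, n_snps = 40, n_chromosomes = 2,
                    frac_genotyped = 0.5, seed = seed, ...)
  simulate_all(cfg)
}

# Monte-Carlo gene-dropping estimate of 2 x kinship for a pedigree
gene_drop_A <- function(ped, n_drops = 1e5) {
  ids <- ped$animal
  n <- length(ids)
  si <- match(ped$sire, ids); di <- match(ped$dam, ids)
  # drop biallelic founder alleles, labelled uniquely per founder copy
  al1 <- matrix(0L, n_drops, n); al2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      al1[, i] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick, al1[, si[i]], al2[, si[i]])
    }
    if (is.na(di[i])) {
      al2[, i] <- lab + 1L; lab <- lab + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick, al1[, di[i]], al2[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    # kinship: P(random allele from i IBD to random allele from j)
    k <- (al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
      (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])
    A[i, j] <- A[j, i] <- mean(k) / 2
  }
  A
}

# brute-force Storey q-values: double loop, no shortcuts
brute_storey_q <- function(p, pi0) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        best <- min(best, pi0 * m * p[j] / rank_j)
      }
    }
    q[i] <- min(best, 1)
  }
  q
}

# brute-force region clustering: transitive closure of the < gap relation
brute_regions <- function(pos, gap) {
  n <- length(pos)
  pos <- sort(pos)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) < gap && grp[i] != grp[j]) {
        g <- min(grp[i], grp[j])
        grp[grp == grp[i] | grp == grp[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(split(pos, grp), range)
}
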