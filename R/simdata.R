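# Synthetic-data generator emulating the cage-raised feed-efficiency
# experiment: multi-generation pedigree with litters, batches, cages split
# by weaning-size class and feeding regime, weekly body weights, weekly cage
# feed intake under ad-libitum and restricted feeding, and array genotypes
# with distance-decaying LD for a minority of animals per cage.

#' Simulation configuration
#'
#' Defaults state the emulated experiment: 5 batches; cages of 8 animals
#' (6 in the last batch of the real design; configurable); two feeding
#' regimes with the 0.75 x (1 + 0.1) ration rule; two weaning-size classes
#' split at 700 g; litters of 4-10 kits (7 litter-size classes) with at most
#' two kits per litter per cage and every litter represented in both
#' regimes; 4 weekly body weights over days 30-56 (the medicated last week
#' already discarded); 3 weekly cage feed records; ~30% of the members of
#' each cage genotyped.  Growth means and variance components follow the
#' observed scale of the population (ad-libitum ADG 53.2 g/day, restricted
#' 35.4 g/day, phenotypic variance ~78 (g/day)^2, target FCR 2.8, genetic
#' correlation 0.58 between growth and the feed-intake deviation).
#'
#' @param ... overrides of any default entry
#' @return named list of class `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_batches = 5L,
    cages_per_batch = 8L,          # total, split evenly between F and R
    animals_per_cage = 8L,
    frac_genotyped = 0.3,
    n_snps = 500L,
    n_chromosomes = 5L,
    chrom_length_bp = 5e7,
    d0_bp = 2e6,                   # LD decay scale of founder haplotypes
    freq_range = c(0.1, 0.9),
    causal = NULL,                 # data.frame(snp, trait, effect)
    vc_adg = c(sigma_a2 = 20, sigma_c2 = 8, sigma_l2 = 12, sigma_e2 = 38),
    vc_fi = c(sigma_a2 = 80, sigma_e2 = 180),
    gen_corr = 0.58,
    mu_adg = c(F = 53.2, R = 35.4),
    fcr_target = 2.8,
    fi_maintenance = 0,            # g/day intercept of the intake model
    bw_noise_sd = 15,
    wean_mu = 700, wean_sd = 120,
    restriction = 0.75, growth_allowance = 0.10,
    fi_week1_baseline = 110,       # prior-experiment ad-lib g/day per animal
    litter_sizes = 4:10,
    n_founder_sires = 12L, n_founder_dams = 36L,
    n_parent_sires = 20L, n_parent_dams = 80L,
    death_rate = 0,                # per-animal per-fattening probability
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$frac_genotyped > 0, cfg$frac_genotyped <= 1,
            all(unlist(cfg$vc_adg) >= 0), abs(cfg$gen_corr) <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-generation pedigree with litter/cage/batch assignments
#'
#' Three generations: founders, parents, and the phenotyped kits.  Kits are
#' produced in litters (one litter per dam per batch, parity advancing with
#' re-use), split alternately across the two feeding regimes (so every
#' litter with two or more kits appears in both), classed by weaning weight
#' (> 700 g vs <= 700 g), and dealt round-robin into cages so that no cage
#' holds more than two kits of the same litter.  Kits left over after
#' filling whole cages stay in the pedigree but get no cage (and no
#' records).
#'
#' @param config a [sim_config()]
#' @return list: `ped` (topologically ordered pedigree data frame),
#'   `animals` (kit assignment table: `animal, batch, parity,
#'   litter_size_class, size_class, cage, litter, regime, wean_bw`)
#' @export
simulate_pedigree <- function(config = sim_config()) {
  f_sires <- sprintf("FS%02d", seq_len(config$n_founder_sires))
  f_dams <- sprintf("FD%02d", seq_len(config$n_founder_dams))
  p_sires <- sprintf("PS%02d", seq_len(config$n_parent_sires))
  p_dams <- sprintf("PD%02d", seq_len(config$n_parent_dams))
  ped <- data.frame(
    animal = c(f_sires, f_dams, p_sires, p_dams),
    sire = c(rep(NA, length(f_sires) + length(f_dams)),
             sample(f_sires, length(p_sires) + length(p_dams), TRUE)),
    dam = c(rep(NA, length(f_sires) + length(f_dams)),
            sample(f_dams, length(p_sires) + length(p_dams), TRUE)),
    stringsAsFactors = FALSE)
  kits_needed <- config$cages_per_batch * config$animals_per_cage
  animals <- NULL
  kid <- 0L
  dam_use <- stats::setNames(integer(length(p_dams)), p_dams)
  for (b in seq_len(config$n_batches)) {
    kits <- NULL
    dams_avail <- sample(p_dams)
    li <- 0L
    while (is.null(kits) || nrow(kits) < kits_needed * 1.3) {
      li <- li + 1L
      if (li > length(dams_avail))
        stop("infeasible design: not enough dams for the cage count")
      dam <- dams_avail[li]
      dam_use[dam] <- dam_use[dam] + 1L
      sire <- sample(p_sires, 1L)
      sz <- sample(config$litter_sizes, 1L)
      litter_id <- sprintf("L%d_%03d", b, li)
      ids <- sprintf("A%d%04d", b, kid + seq_len(sz))
      kid <- kid + sz
      ped <- rbind(ped, data.frame(animal = ids, sire = sire, dam = dam,
                                   stringsAsFactors = FALSE))
      kits <- rbind(kits, data.frame(
        animal = ids, batch = b, parity = min(dam_use[dam], 4L),
        litter_size_class = match(sz, config$litter_sizes),
        litter = litter_id,
        regime = rep_len(sample(c("F", "R")), sz),  # littermates in both
        wean_bw = stats::rnorm(sz, config$wean_mu, config$wean_sd),
        stringsAsFactors = FALSE))
    }
    kits$size_class <- ifelse(kits$wean_bw > 700, "LS", "SS")
    kits$cage <- NA_character_
    n_cages_batch <- 0L
    for (rg in c("F", "R")) for (scl in c("LS", "SS")) {
      grp <- which(kits$regime == rg & kits$size_class == scl)
      apc <- config$animals_per_cage
      ci <- 0L
      # greedy fill: each cage takes at most 2 kits from any one litter,
      # drawing from the litters with most kits left; leftovers stay uncaged
      repeat {
        remaining <- split(grp[is.na(kits$cage[grp])], kits$litter[grp][is.na(kits$cage[grp])])
        remaining <- remaining[lengths(remaining) > 0L]
        if (sum(lengths(remaining)) < apc) break
        cage_members <- integer(0)
        for (lt in names(remaining)[order(-lengths(remaining))]) {
          if (length(cage_members) >= apc) break
          take <- min(2L, length(remaining[[lt]]),
                      apc - length(cage_members))
          cage_members <- c(cage_members, remaining[[lt]][seq_len(take)])
        }
        if (length(cage_members) < apc) break     # cannot honor <=2/litter
        ci <- ci + 1L
        kits$cage[cage_members] <- sprintf("C%d_%s_%s_%d", b, rg, scl, ci)
      }
      n_cages_batch <- n_cages_batch + ci
    }
    if (n_cages_batch == 0L)
      stop("infeasible design: batch ", b, " produced no full cage; ",
           "increase litters or reduce animals_per_cage")
    animals <- rbind(animals, kits)
  }
  list(ped = read_pedigree(ped), animals = animals)
}

#' Simulate genotypes with distance-decaying LD by gene dropping
#'
#' Founder haplotypes come from a Gaussian-copula Markov chain along each
#' chromosome: the latent correlation between neighbouring SNPs is
#' \eqn{\exp(-\Delta bp / d_0)}, thresholded at the target allele frequency,
#' which yields approximate Hardy-Weinberg genotypes whose r-squared decays
#' with distance.  Haplotypes then drop through the pedigree with crossovers
#' at 1 cM/Mb (Haldane).
#'
#' @param ped topologically ordered pedigree (from [simulate_pedigree()])
#' @param config a [sim_config()]
#' @return list: `content` (allele-content matrix, all pedigree animals x
#'   SNPs), `map` (SNP map), `freq` (founder design frequencies)
#' @export
simulate_genotypes <- function(ped, config = sim_config()) {
  m_per <- ceiling(config$n_snps / config$n_chromosomes)
  map <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(cc) {
    n <- if (cc < config$n_chromosomes) m_per else
      config$n_snps - m_per * (config$n_chromosomes - 1L)
    data.frame(snp_id = sprintf("SNP%d_%04d", cc, seq_len(n)),
               chrom = as.character(cc),
               pos_bp = sort(sample.int(config$chrom_length_bp, n)),
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }))
  m <- nrow(map)
  freq <- stats::runif(m, config$freq_range[1L], config$freq_range[2L])
  thr <- stats::qnorm(freq)
  ids <- ped$animal
  n <- length(ids)
  sidx <- match(ped$sire, ids); didx <- match(ped$dam, ids)
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  chrom_idx <- split(seq_len(m), map$chrom)
  founder_hap <- function(cols) {
    pos <- map$pos_bp[cols]
    rho <- exp(-diff(pos) / config$d0_bp)
    z <- numeric(length(cols))
    z[1L] <- stats::rnorm(1L)
    eps <- stats::rnorm(length(cols) - 1L)
    for (k in seq_along(rho))
      z[k + 1L] <- rho[k] * z[k] + sqrt(1 - rho[k]^2) * eps[k]
    as.integer(z < thr[cols])
  }
  meiosis <- function(h1, h2, pos) {
    r <- 0.5 * (1 - exp(-2 * diff(pos) * 1e-8))    # Haldane, 1 cM/Mb
    cross <- stats::runif(length(r)) < r
    state <- (sample(0:1, 1L) + cumsum(c(0L, cross))) %% 2L
    ifelse(state == 0L, h1, h2)
  }
  for (i in seq_len(n)) {
    for (cols in chrom_idx) {
      pos <- map$pos_bp[cols]
      H1[i, cols] <- if (is.na(sidx[i])) founder_hap(cols) else
        meiosis(H1[sidx[i], cols], H2[sidx[i], cols], pos)
      H2[i, cols] <- if (is.na(didx[i])) founder_hap(cols) else
        meiosis(H1[didx[i], cols], H2[didx[i], cols], pos)
    }
  }
  content <- H1 + H2
  dimnames(content) <- list(ids, map$snp_id)
  list(content = content, map = validate_snp_map(map), freq = freq)
}

#' Simulate phenotypes: weekly body weights and weekly cage feed intake
#'
#' Polygenic breeding values for growth and feed-intake deviation are
#' dropped through the pedigree as a bivariate normal (correlation
#' `gen_corr`); configured causal SNPs add `effect x allele content` to
#' their trait.  Body weights are linear in age around the weaning weight
#' with measurement noise; ad-libitum cage feed follows
#' `FCR_target x ADG + intake deviation` with 10% weekly growth, and
#' restricted cages receive the ration rule allowance computed from the
#' previous week's observed ad-libitum per-animal intake of the same batch
#' and size class.
#'
#' @param sim output of [simulate_pedigree()]
#' @param geno output of [simulate_genotypes()]
#' @param config a [sim_config()]
#' @return list: `bw` (animal, age_days, bw_g), `cage_feed` (cage, week,
#'   feed_g, animal_days), `animals` (assignment table restricted to caged
#'   kits), `truth` (breeding values, true ADG, causal table, variance
#'   components)
#' @export
simulate_phenotypes <- function(sim, geno, config = sim_config()) {
  ped <- sim$ped
  ids <- ped$animal
  n <- length(ids)
  # bivariate polygenic values through the pedigree
  sa1 <- config$vc_adg[["sigma_a2"]]; sa2 <- config$vc_fi[["sigma_a2"]]
  cov12 <- config$gen_corr * sqrt(sa1 * sa2)
  Gp <- matrix(c(sa1, cov12, cov12, sa2), 2)
  Lg <- chol(Gp)
  sidx <- match(ped$sire, ids); didx <- match(ped$dam, ids)
  bv <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    founder <- is.na(sidx[i]) & is.na(didx[i])
    par_mean <- c(0, 0); mend <- 1
    if (!founder) {
      as_ <- if (is.na(sidx[i])) c(0, 0) else bv[sidx[i], ]
      ad_ <- if (is.na(didx[i])) c(0, 0) else bv[didx[i], ]
      par_mean <- (as_ + ad_) / 2
      mend <- sqrt(0.5)
    }
    bv[i, ] <- par_mean + mend * as.numeric(crossprod(Lg, stats::rnorm(2)))
  }
  rownames(bv) <- ids
  animals <- sim$animals[!is.na(sim$animals$cage), , drop = FALSE]
  k <- match(animals$animal, ids)
  # causal SNP contributions
  causal_adg <- numeric(nrow(animals)); causal_fi <- numeric(nrow(animals))
  if (!is.null(config$causal) && nrow(config$causal) > 0L) {
    for (r in seq_len(nrow(config$causal))) {
      snp <- config$causal$snp[r]
      gvec <- geno$content[animals$animal, snp]
      if (config$causal$trait[r] == "adg")
        causal_adg <- causal_adg + config$causal$effect[r] * gvec
      else
        causal_fi <- causal_fi + config$causal$effect[r] * gvec
    }
  }
  # small fixed effects so the factors are estimable but not dominant
  nb <- config$n_batches
  batch_eff <- stats::rnorm(nb, 0, 2)
  parity_eff <- stats::rnorm(4L, 0, 1)
  ls_eff <- stats::rnorm(length(config$litter_sizes), 0, 1)
  cage_ids <- sort(unique(animals$cage))
  cage_eff <- stats::setNames(
    stats::rnorm(length(cage_ids), 0, sqrt(config$vc_adg[["sigma_c2"]])),
    cage_ids)
  litter_ids <- sort(unique(animals$litter))
  litter_eff <- stats::setNames(
    stats::rnorm(length(litter_ids), 0, sqrt(config$vc_adg[["sigma_l2"]])),
    litter_ids)
  adg_true <- config$mu_adg[animals$regime] +
    batch_eff[animals$batch] + parity_eff[animals$parity] +
    ls_eff[animals$litter_size_class] +
    ifelse(animals$size_class == "LS", 1, -1) +
    cage_eff[animals$cage] + litter_eff[animals$litter] +
    bv[k, 1L] + causal_adg +
    stats::rnorm(nrow(animals), 0, sqrt(config$vc_adg[["sigma_e2"]]))
  fi_dev <- bv[k, 2L] + causal_fi +
    stats::rnorm(nrow(animals), 0, sqrt(config$vc_fi[["sigma_e2"]]))
  # weekly body weights, days 30-51 (last medicated week already trimmed)
  ages <- c(30, 37, 44, 51)
  bw <- do.call(rbind, lapply(seq_along(ages), function(wk)
    data.frame(animal = animals$animal, age_days = ages[wk],
               bw_g = animals$wean_bw + adg_true * (ages[wk] - 30) +
                 stats::rnorm(nrow(animals), 0, config$bw_noise_sd),
               stringsAsFactors = FALSE)))
  # cage feed: ad-libitum observed intake, restricted = ration allowance
  week_growth <- (1 + config$growth_allowance)^(0:2)
  week_share <- 3 * week_growth / sum(week_growth)  # mean over weeks = 1
  fi_animal <- config$fi_maintenance + config$fcr_target * adg_true + fi_dev
  cage_rows <- list()
  adlib_week_mean <- list()   # per (batch, size class, week) g/day/animal
  for (cg in cage_ids) {
    memb <- which(animals$cage == cg)
    rg <- animals$regime[memb[1L]]
    b <- animals$batch[memb[1L]]; scl <- animals$size_class[memb[1L]]
    nm <- length(memb)
    if (rg == "F") {
      for (w in 1:3) {
        daily <- sum(fi_animal[memb]) * week_share[w] *
          exp(stats::rnorm(1L, 0, 0.02))
        cage_rows[[length(cage_rows) + 1L]] <- data.frame(
          cage = cg, week = w, feed_g = daily * 7, animal_days = nm * 7,
          stringsAsFactors = FALSE)
        key <- paste(b, scl, w)
        adlib_week_mean[[key]] <- c(adlib_week_mean[[key]], daily / nm)
      }
    }
  }
  for (cg in cage_ids) {
    memb <- which(animals$cage == cg)
    rg <- animals$regime[memb[1L]]
    if (rg != "R") next
    b <- animals$batch[memb[1L]]; scl <- animals$size_class[memb[1L]]
    nm <- length(memb)
    for (w in 1:3) {
      prev <- if (w == 1L) config$fi_week1_baseline else {
        key <- paste(b, scl, w - 1L)
        if (is.null(adlib_week_mean[[key]]))
          config$fi_week1_baseline * (1 + config$growth_allowance)^(w - 1L)
        else mean(adlib_week_mean[[key]])
      }
      allowance <- restricted_ration(prev, nm, config$restriction,
                                     config$growth_allowance)
      cage_rows[[length(cage_rows) + 1L]] <- data.frame(
        cage = cg, week = w, feed_g = allowance * 7, animal_days = nm * 7,
        stringsAsFactors = FALSE)
    }
  }
  cage_feed <- do.call(rbind, cage_rows)
  truth <- list(bv_adg = stats::setNames(bv[, 1L], ids),
                bv_fi = stats::setNames(bv[, 2L], ids),
                adg_true = stats::setNames(adg_true, animals$animal),
                fi_animal = stats::setNames(fi_animal, animals$animal),
                causal = config$causal,
                vc_adg = config$vc_adg, vc_fi = config$vc_fi,
                gen_corr = config$gen_corr)
  list(bw = bw, cage_feed = cage_feed, animals = animals, truth = truth)
}

#' Run the whole simulation under one seed
#'
#' All stochastic draws flow from a single generator seeded once.
#'
#' @param config a [sim_config()]
#' @return list: `ped`, `animals`, `geno` (all-animal content + map),
#'   `genotyped_ids` (the per-cage genotyped minority), `phen`
#'   (see [simulate_phenotypes()]), `config`
#' @export
simulate_all <- function(config = sim_config()) {
  set.seed(config$seed)
  sim <- simulate_pedigree(config)
  geno <- simulate_genotypes(sim$ped, config)
  phen <- simulate_phenotypes(sim, geno, config)
  animals <- phen$animals
  genotyped <- unlist(lapply(split(animals$animal, animals$cage),
                             function(mem) {
    ng <- max(1L, round(config$frac_genotyped * length(mem)))
    sample(mem, ng)
  }), use.names = FALSE)
  list(ped = sim$ped, animals = animals, geno = geno,
       genotyped_ids = sort(genotyped), phen = phen, config = config)
}

#' Write a simulation to disk in the pipeline's input dialects
#'
#' Emits `geno.bed/.bim/.fam` (genotyped animals only), `pedigree.csv`,
#' `animals.csv`, `bw.csv`, `cage_feed.csv` and `truth.json`.
#'
#' @param sim output of [simulate_all()]
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
sim_emit <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- structure(list(
    geno = sim$geno$content[sim$genotyped_ids, , drop = FALSE],
    map = sim$geno$map), class = "genotypes")
  write_genotypes(g, file.path(outdir, "geno"))
  utils::write.csv(as.data.frame(sim$ped), file.path(outdir, "pedigree.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$animals[, c("animal", "batch", "parity",
                                   "litter_size_class", "size_class",
                                   "cage", "litter", "regime")],
                   file.path(outdir, "animals.csv"), row.names = FALSE)
  utils::write.csv(sim$phen$bw, file.path(outdir, "bw.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$phen$cage_feed, file.path(outdir, "cage_feed.csv"),
                   row.names = FALSE)
  tr <- sim$phen$truth
  json <- list(
    breeding_values = data.frame(animal = names(tr$bv_adg),
                                 bv_adg = unname(tr$bv_adg),
                                 bv_fi = unname(tr$bv_fi)),
    animal_truth = data.frame(animal = names(tr$adg_true),
                              adg_true = unname(tr$adg_true),
                              fi_animal = unname(tr$fi_animal)),
    causal = tr$causal,
    vc_adg = as.list(tr$vc_adg),
    vc_fi = as.list(tr$vc_fi),
    gen_corr = tr$gen_corr,
    genotyped_ids = sim$genotyped_ids)
  jsonlite::write_json(json, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
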