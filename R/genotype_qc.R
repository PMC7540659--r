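#' Per-SNP allele frequency
#'
#' Frequency of the counted allele over non-missing calls.
#'
#' @param G a `genotypes` object or a 0/1/2/`NA` matrix (samples x SNPs)
#' @return numeric vector of frequencies in `[0, 1]`
#' @export
snp_freq <- function(G) {
  geno <- if (inherits(G, "genotypes")) G$geno else G
  colMeans(geno, na.rm = TRUE) / 2
}

#' Minor allele frequency
#' @inheritParams snp_freq
#' @return `pmin(f, 1 - f)` per SNP
#' @export
snp_maf <- function(G) {
  f <- snp_freq(G)
  pmin(f, 1 - f)
}

#' Genotype quality control
#'
#' Applies the standard array QC filters in a fixed order: (1) drop samples
#' with call rate below `sample_call_rate`; (2) drop SNPs with missingness at
#' or above `snp_missing_max`; (3) drop SNPs with MAF at or below `maf_min`
#' (threshold semantics: a MAF *higher than* the threshold is kept); (4) keep
#' only the requested chromosomes (e.g. autosomes).
#'
#' @param G a `genotypes` object
#' @param sample_call_rate minimum fraction of non-missing calls per sample
#' @param snp_missing_max maximum tolerated SNP missingness (exclusive)
#' @param maf_min MAF threshold (exclusive: MAF must exceed it)
#' @param chromosomes optional character vector of chromosome labels to keep
#' @param verbose log the per-step counts via `message()`
#' @return the filtered `genotypes` object, with an attribute `qc_log`
#'   (data frame of step, kept samples, kept SNPs)
#' @export
qc_filter <- function(G, sample_call_rate = 0.90, snp_missing_max = 0.05,
                      maf_min = 0.05, chromosomes = NULL, verbose = FALSE) {
  stopifnot(inherits(G, "genotypes"))
  for (thr in c(sample_call_rate, snp_missing_max, maf_min))
    if (thr <= 0 || thr >= 1) stop("QC thresholds must lie in (0, 1)")
  geno <- G$geno; map <- G$map
  log_df <- data.frame(step = "input", samples = nrow(geno),
                       snps = ncol(geno), stringsAsFactors = FALSE)
  note <- function(step) {
    log_df <<- rbind(log_df, data.frame(step = step, samples = nrow(geno),
                                        snps = ncol(geno)))
    if (verbose) message(step, ": ", nrow(geno), " samples x ",
                         ncol(geno), " SNPs")
  }
  cr <- rowMeans(!is.na(geno))
  geno <- geno[cr >= sample_call_rate, , drop = FALSE]
  note("sample_call_rate")
  miss <- colMeans(is.na(geno))
  keep <- miss < snp_missing_max
  geno <- geno[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  note("snp_missingness")
  keep <- snp_maf(geno) > maf_min
  geno <- geno[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  note("maf")
  if (!is.null(chromosomes)) {
    keep <- map$chrom %in% as.character(chromosomes)
    geno <- geno[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
    note("chromosomes")
  }
  if (nrow(geno) == 0L || ncol(geno) == 0L)
    stop("QC removed everything (", nrow(geno), " samples, ",
         ncol(geno), " SNPs left)")
  out <- structure(list(geno = geno, map = map), class = "genotypes")
  attr(out, "qc_log") <- log_df
  out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of allele contents over pairwise-complete
#' samples (missing calls excluded, no imputation).
#'
#' @param g1,g2 allele-content vectors of equal length
#' @return r^2 in `[0, 1]`, or `NA` if either SNP is monomorphic over the
#'   complete pairs
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) stop("need >= 2 complete pairs for r^2")
  v1 <- stats::var(g1[ok]); v2 <- stats::var(g2[ok])
  if (v1 == 0 || v2 == 0) return(NA_real_)
  stats::cor(g1[ok], g2[ok])^2
}

#' Distance-based SNP pruning
#'
#' Greedy scan per chromosome over the position-sorted map: keep the first
#' SNP, then the next SNP at least `window_bp` downstream of the last kept
#' one, and so on ("one SNP every `window_bp`"; first-in-window wins).
#'
#' @param map a SNP map data frame (`snp_id`, `chrom`, `pos_bp`)
#' @param window_bp minimum distance between kept SNPs (default 20 kb)
#' @return character vector of kept `snp_id`s
#' @export
prune_by_distance <- function(map, window_bp = 20000) {
  map <- map[order(map$chrom, map$pos_bp), , drop = FALSE]
  keep <- unlist(lapply(split(map, map$chrom), function(d) {
    last <- -Inf; k <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      if (d$pos_bp[i] - last >= window_bp) {
        k[i] <- TRUE; last <- d$pos_bp[i]
      }
    }
    d$snp_id[k]
  }), use.names = FALSE)
  keep
}

#' Linkage-disequilibrium decay profile
#'
#' Computes r^2 for every intra-chromosome SNP pair closer than
#' `max_dist_bp`, bins the pairs by physical distance, and reports the mean
#' r^2 and pair count per bin.  Feeding a distance-pruned SNP subset keeps
#' the pair count manageable on dense arrays.
#'
#' @param G a `genotypes` object (its `map` supplies coordinates)
#' @param snp_ids optional subset of SNPs to profile (e.g. from
#'   [prune_by_distance()])
#' @param max_dist_bp maximum pair distance considered
#' @param bin_bp bin width
#' @return data frame `bin_start_bp, bin_end_bp, mean_r2, n_pairs`; empty
#'   bins are reported with `n_pairs = 0` and `mean_r2 = NA`
#' @export
ld_decay <- function(G, snp_ids = NULL, max_dist_bp = 8e6, bin_bp = 1e5) {
  stopifnot(inherits(G, "genotypes"))
  map <- G$map
  if (!is.null(snp_ids)) map <- map[map$snp_id %in% snp_ids, , drop = FALSE]
  map <- map[order(map$chrom, map$pos_bp), , drop = FALSE]
  nb <- ceiling(max_dist_bp / bin_bp)
  sum_r2 <- numeric(nb); n_pair <- integer(nb)
  for (chr in unique(map$chrom)) {
    d <- map[map$chrom == chr, , drop = FALSE]
    if (nrow(d) < 2L) next
    g <- G$geno[, d$snp_id, drop = FALSE]
    C2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
    pair <- which(upper.tri(C2), arr.ind = TRUE)
    dist <- d$pos_bp[pair[, 2L]] - d$pos_bp[pair[, 1L]]
    ok <- abs(dist) <= max_dist_bp & abs(dist) > 0 &
      !is.na(C2[pair])
    b <- 1L + (abs(dist[ok]) - 1L) %/% as.integer(bin_bp)
    b <- pmin(b, nb)
    if (any(ok)) {
      sum_r2 <- sum_r2 + as.numeric(tapply(C2[pair][ok], factor(b, levels = seq_len(nb)),
                                           sum, default = 0))
      tab <- table(factor(b, levels = seq_len(nb)))
      n_pair <- n_pair + as.integer(tab)
    }
  }
  data.frame(bin_start_bp = (seq_len(nb) - 1L) * bin_bp,
             bin_end_bp = seq_len(nb) * bin_bp,
             mean_r2 = ifelse(n_pair > 0L, sum_r2 / pmax(n_pair, 1L), NA),
             n_pairs = n_pair)
}
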