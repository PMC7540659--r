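#' Storey q-values with smoother-based pi0 estimate
#'
#' Implements the positive false discovery rate adjustment: \eqn{\hat\pi_0}
#' is estimated by evaluating \eqn{\#\{p > \lambda\}/(m(1-\lambda))} on the
#' grid \eqn{\lambda \in \{0.05, 0.10, ..., 0.95\}}, smoothing with a
#' natural cubic spline (df = 3) and taking the fitted value at the largest
#' \eqn{\lambda}.  Then
#' \eqn{q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}(p_j)},
#' clipped to \eqn{[0, 1]}.  With \eqn{\hat\pi_0 = 1} this reduces exactly to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p vector of p-values in `[0, 1]`
#' @param lambda_grid grid for the pi0 smoother
#' @param pi0 optionally force pi0 (e.g. `pi0 = 1`)
#' @return list with `q` (same order as `p`) and `pi0`
#' @export
storey_q <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                     pi0 = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < 20L) {
      warning("fewer than 20 p-values: pi0 smoother unstable, using pi0 = 1")
      pi0 <- 1
    } else {
      lam <- lambda_grid[lambda_grid < max(pv)]
      if (length(lam) < 4L) {
        pi0 <- 1
      } else {
        pi0_l <- vapply(lam, function(l) mean(pv > l) / (1 - l), 0)
        sp <- stats::smooth.spline(lam, pi0_l, df = 3)
        pi0 <- stats::predict(sp, x = max(lam))$y
        pi0 <- min(max(pi0, 1e-8), 1)
      }
    }
  }
  o <- order(pv, decreasing = TRUE)           # largest p first
  r <- rank(pv, ties.method = "max")
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * pv[o] / r[o])
  q <- pmin(q, 1)
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  list(q = out, pi0 = pi0)
}

#' Multiple-testing correction at genome-wide or chromosome-wide level
#'
#' Adds Storey q-values and significance flags to association records.  At
#' `level = "genome"` a single q-value stratum covers all tests; at
#' `level = "chromosome"` q-values are computed within each chromosome
#' (separately per trait/method stratum when those columns are present), so
#' significance thresholds vary across chromosomes and are much less strict.
#'
#' @param records association data frame with columns `p`, `chrom` (and
#'   optionally `trait`, `method`)
#' @param level `"genome"` or `"chromosome"`
#' @param pfdr target positive FDR (default 0.05)
#' @return `records` with columns `q` and `significant` added
#' @export
correct_records <- function(records, level = c("chromosome", "genome"),
                            pfdr = 0.05) {
  level <- match.arg(level)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    records$q <- numeric(0); records$significant <- logical(0)
    return(records)
  }
  nr <- nrow(records)
  strata <- interaction(
    if ("trait" %in% names(records)) records$trait else rep("t", nr),
    if ("method" %in% names(records)) records$method else rep("m", nr),
    if (level == "chromosome") records$chrom else rep("all", nr),
    drop = TRUE)
  q <- rep(NA_real_, nrow(records))
  for (s in levels(strata)) {
    k <- which(strata == s)
    q[k] <- suppressWarnings(storey_q(records$p[k])$q)
  }
  records$q <- q
  records$significant <- !is.na(q) & q < pfdr
  records
}

#' Merge significant SNPs into QTL regions
#'
#' Single-linkage clustering of significant SNPs along each chromosome:
#' consecutive significant SNPs less than `gap_bp` apart belong to the same
#' QTL region (two SNPs exactly `gap_bp` apart start a new region).  Region
#' bounds are the min/max significant positions; the region's top SNP is the
#' most significant one (minimum q, ties broken by minimum p, then smallest
#' position).
#'
#' @param records association records with `q` (from [correct_records()]);
#'   only rows with `significant == TRUE` seed regions
#' @param gap_bp clustering threshold (default 1 Mb)
#' @param all_records optional full record set used to count how many tested
#'   SNPs fall inside each region span (defaults to `records`)
#' @return data frame, one row per region: `chrom, start_bp, end_bp,
#'   n_significant, n_snps_in_span, top_snp, top_q, top_p, top_effect,
#'   top_maf, snp_ids` (list column), plus `trait`/`method` when present
#' @export
call_regions <- function(records, gap_bp = 1e6, all_records = records) {
  records <- as.data.frame(records)
  sig <- records[which(records$significant), , drop = FALSE]
  if (nrow(sig) == 0L) return(NULL)
  strat_cols <- intersect(c("trait", "method"), names(sig))
  strata <- if (length(strat_cols))
    interaction(sig[strat_cols], drop = TRUE) else factor(rep(1, nrow(sig)))
  out <- list()
  for (s in levels(strata)) {
    d <- sig[strata == s, , drop = FALSE]
    for (chr in unique(d$chrom)) {
      dc <- d[d$chrom == chr, , drop = FALSE]
      dc <- dc[order(dc$pos_bp), , drop = FALSE]
      newreg <- c(TRUE, diff(dc$pos_bp) >= gap_bp)
      grp <- cumsum(newreg)
      for (g in unique(grp)) {
        r <- dc[grp == g, , drop = FALSE]
        ord <- order(r$q, r$p, r$pos_bp)
        top <- r[ord[1L], ]
        span <- all_records$chrom == chr &
          all_records$pos_bp >= min(r$pos_bp) &
          all_records$pos_bp <= max(r$pos_bp)
        if (length(strat_cols))
          for (cl in strat_cols)
            span <- span & all_records[[cl]] == r[[cl]][1L]
        reg <- data.frame(chrom = chr, start_bp = min(r$pos_bp),
                          end_bp = max(r$pos_bp),
                          n_significant = nrow(r),
                          n_snps_in_span = sum(span, na.rm = TRUE),
                          top_snp = top$snp_id, top_q = top$q, top_p = top$p,
                          top_effect = if ("effect" %in% names(top))
                            top$effect else NA_real_,
                          top_maf = if ("maf" %in% names(top))
                            top$maf else NA_real_,
                          stringsAsFactors = FALSE)
        for (cl in strat_cols) reg[[cl]] <- r[[cl]][1L]
        reg$snp_ids <- I(list(r$snp_id))
        out[[length(out) + 1L]] <- reg
      }
    }
  }
  do.call(rbind, out)
}

#' Annotation windows around QTL regions
#'
#' Expands each region by `window_bp` on both sides (clipped at 1 bp) and
#' optionally reports overlapping intervals from a user-supplied gene table.
#'
#' @param regions output of [call_regions()]
#' @param window_bp flank size (default 1 Mb)
#' @param gene_intervals optional data frame `chrom, start_bp, end_bp, id`
#'   (e.g. parsed from BED/GFF3)
#' @return `regions` with `window_start_bp`, `window_end_bp` and, when gene
#'   intervals are given, a `genes` list column of overlapping ids
#' @export
annotation_windows <- function(regions, window_bp = 1e6,
                               gene_intervals = NULL) {
  if (is.null(regions) || nrow(regions) == 0L) return(regions)
  regions$window_start_bp <- pmax(1, regions$start_bp - window_bp)
  regions$window_end_bp <- regions$end_bp + window_bp
  if (!is.null(gene_intervals)) {
    regions$genes <- I(lapply(seq_len(nrow(regions)), function(i) {
      hit <- gene_intervals$chrom == regions$chrom[i] &
        gene_intervals$end_bp >= regions$window_start_bp[i] &
        gene_intervals$start_bp <= regions$window_end_bp[i]
      gene_intervals$id[hit]
    }))
  }
  regions
}
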