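# Univariate animal model with cage + litter + additive random effects,
# fitted by maximum likelihood, and the per-SNP association scan built on it.

# fixed-effect design from whichever of the standard factors are present;
# aliased columns dropped via QR with a warning
build_fixed <- function(df, vars = c("batch", "parity", "litter_size_class",
                                     "size_class")) {
  use <- intersect(vars, names(df))
  use <- use[vapply(use, function(v) length(unique(df[[v]])) >= 2L, TRUE)]
  if (length(use) == 0L) return(matrix(1, nrow(df), 1,
                                       dimnames = list(NULL, "(Intercept)")))
  for (v in use) df[[v]] <- factor(df[[v]])
  f <- stats::as.formula(paste("~", paste(use, collapse = " + ")))
  X <- stats::model.matrix(f, df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    warning("confounded fixed effects; dropping aliased column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  X
}

# incidence matrix records x levels
incidence <- function(fac) {
  fac <- factor(fac)
  Z <- matrix(0, length(fac), nlevels(fac),
              dimnames = list(NULL, levels(fac)))
  Z[cbind(seq_along(fac), as.integer(fac))] <- 1
  Z
}

#' Fit the univariate animal model (with or without a SNP covariate)
#'
#' Maximum-likelihood fit of
#' \deqn{y = X\beta + s\alpha + Z_c c + Z_l l + Z_a a + e}
#' with \eqn{c \sim N(0, I\sigma_c^2)}, \eqn{l \sim N(0, I\sigma_l^2)},
#' \eqn{a \sim N(0, A\sigma_a^2)}, \eqn{e \sim N(0, I\sigma_e^2)}.  Fixed
#' effects are batch, parity, litter-size class and cage-size class (those
#' present in `pheno`); the SNP enters as a regression on allele content.
#' The likelihood is profiled over \eqn{\beta} and the residual scale and
#' maximised over the three variance ratios by Nelder-Mead.
#'
#' @param pheno data frame with `animal`, the factor columns, `cage`,
#'   `litter`, and the trait column
#' @param A a `relmat` covering at least the animals in `pheno`
#' @param trait name of the trait column (default `"adg"`)
#' @param snp optional allele-content vector named by animal id (missing
#'   contents are mean-imputed as \eqn{2f_p})
#' @param start optional starting variance ratios
#'   `c(cage, litter, additive) / residual`
#' @return a `cagewas_fit` list: `loglik`, `vc` (named variance components),
#'   `beta`, `alpha` (SNP effect or `NA`), `se_alpha`, `converged`,
#'   `iterations`, `n`
#' @export
fit_model1 <- function(pheno, A, trait = "adg", snp = NULL, start = NULL,
                       method = c("ML", "REML")) {
  method <- match.arg(method)
  pheno <- as.data.frame(pheno)
  stopifnot(inherits(A, "relmat"), trait %in% names(pheno))
  keep <- !is.na(pheno[[trait]])
  pheno <- pheno[keep, , drop = FALSE]
  ids <- as.character(pheno$animal)
  y <- pheno[[trait]]
  n <- length(y)
  X <- build_fixed(pheno)
  snp_col <- NULL
  if (!is.null(snp)) {
    s <- as.numeric(snp[ids])
    if (anyNA(s)) {                       # mean-impute missing content
      f <- mean(s, na.rm = TRUE) / 2
      s[is.na(s)] <- 2 * f
    }
    if (stats::var(s) == 0) stop("monomorphic SNP")
    snp_col <- s
    X <- cbind(X, snp = s)
  }
  Asub <- subset_relmat(A, ids)$A
  KC <- tcrossprod(incidence(pheno$cage))
  KL <- tcrossprod(incidence(pheno$litter))
  KA <- Asub                               # one record per animal
  p_rank <- qr(X)$rank
  negll <- function(lg) {
    g <- exp(lg)
    Vt <- diag(n) + g[1L] * KC + g[2L] * KL + g[3L] * KA
    ch <- tryCatch(chol(Vt), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    yw <- backsolve(ch, y, transpose = TRUE)
    Xw <- backsolve(ch, X, transpose = TRUE)
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    if (method == "ML")
      0.5 * (n * log(2 * pi) + n + n * log(rss / n) +
               2 * sum(log(diag(ch))))
    else {
      nr <- n - p_rank
      xx <- qr(Xw)
      ldx <- sum(log(abs(diag(qr.R(xx)))))
      0.5 * (nr * log(2 * pi) + nr + nr * log(rss / nr) +
               2 * sum(log(diag(ch))) + 2 * ldx)
    }
  }
  if (is.null(start)) start <- c(0.3, 0.3, 0.5)
  opt <- stats::optim(log(start), negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  g <- exp(opt$par)
  Vt <- diag(n) + g[1L] * KC + g[2L] * KL + g[3L] * KA
  ch <- chol(Vt)
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  s2e <- rss / if (method == "ML") n else n - p_rank
  beta <- stats::setNames(fit$coefficients, colnames(X))
  j_snp <- ncol(X)                         # snp is always the last column
  alpha <- if (!is.null(snp_col)) unname(beta[j_snp]) else NA_real_
  se_alpha <- NA_real_
  if (!is.null(snp_col)) {
    XtX <- crossprod(Xw)
    v <- tryCatch(solve(XtX)[j_snp, j_snp], error = function(e) NA_real_)
    se_alpha <- sqrt(s2e * v)
  }
  structure(list(
    loglik = -opt$value,
    vc = c(sigma_c2 = unname(g[1L] * s2e), sigma_l2 = unname(g[2L] * s2e),
           sigma_a2 = unname(g[3L] * s2e), sigma_e2 = s2e),
    beta = beta, alpha = alpha, se_alpha = se_alpha,
    converged = opt$convergence == 0L, iterations = opt$counts[1L],
    n = n), class = "cagewas_fit")
}

#' Per-SNP mixed-model association scan for individual traits
#'
#' Runs the univariate animal model across a genotype matrix.  Two modes:
#' \describe{
#'   \item{`"exact"`}{variance components are re-estimated by ML for every
#'     SNP's alternative model (the behaviour of classical per-SNP ML
#'     software); the null model is SNP-free and fitted once.}
#'   \item{`"emmax"`}{variance components are estimated once under the
#'     global null; each SNP is then tested by generalised least squares
#'     with the covariance held fixed.  Orders of magnitude faster and
#'     nearly identical test statistics.}
#' }
#' The likelihood-ratio statistic is referred to a chi-squared distribution
#' with one degree of freedom.  Monomorphic SNPs are skipped (recorded with
#' `NA` statistics).
#'
#' @param pheno phenotype data frame (see [fit_model1()]), genotyped animals
#' @param G a `genotypes` object (QC-passed)
#' @param A a `relmat`
#' @param trait trait column name
#' @param mode `"emmax"` (default) or `"exact"`
#' @param verbose message progress every 200 SNPs
#' @return association data frame: `snp_id, chrom, pos_bp, effect, se, lrt,
#'   p, method, trait, maf`
#' @export
scan_model1 <- function(pheno, G, A, trait = "adg",
                        mode = c("emmax", "exact"), verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(G, "genotypes"))
  pheno <- as.data.frame(pheno)
  pheno <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  ids <- as.character(pheno$animal)
  miss_ids <- setdiff(ids, rownames(G$geno))
  if (length(miss_ids))
    stop("animals without genotypes in model-1 scan: ",
         paste(utils::head(miss_ids, 5L), collapse = ", "))
  geno <- G$geno[ids, , drop = FALSE]
  f <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  poly <- !is.na(maf) & maf > 0
  # exact mode reproduces the per-SNP ML refit; emmax follows the usual
  # EMMAX convention of a REML null fit followed by per-SNP GLS
  null_fit <- fit_model1(pheno, A, trait = trait, snp = NULL,
                         method = if (mode == "emmax") "REML" else "ML")
  m <- ncol(geno)
  eff <- se <- lrt <- rep(NA_real_, m)
  if (mode == "emmax") {
    g <- null_fit$vc[c("sigma_c2", "sigma_l2", "sigma_a2")] /
      null_fit$vc["sigma_e2"]
    n <- nrow(pheno)
    Vt <- diag(n) + g[1L] * tcrossprod(incidence(pheno$cage)) +
      g[2L] * tcrossprod(incidence(pheno$litter)) +
      g[3L] * subset_relmat(A, ids)$A
    ch <- chol(Vt)
    y <- pheno[[trait]]
    yw <- backsolve(ch, y, transpose = TRUE)
    Xw <- backsolve(ch, build_fixed(pheno), transpose = TRUE)
    qx <- qr(Xw)
    ry <- qr.resid(qx, yw)
    s2e <- null_fit$vc["sigma_e2"]
    # mean-impute missing content, whiten all SNPs at once
    S <- geno[, poly, drop = FALSE]
    for (j in seq_len(ncol(S))) {
      sj <- S[, j]
      if (anyNA(sj)) sj[is.na(sj)] <- 2 * f[poly][j]
      S[, j] <- sj
    }
    Sw <- backsolve(ch, S, transpose = TRUE)
    RS <- qr.resid(qx, Sw)
    num <- as.numeric(crossprod(RS, ry))
    den <- colSums(RS^2)
    ok <- den > 0
    eff[poly][ok] <- num[ok] / den[ok]
    lrt[poly][ok] <- (num[ok]^2 / den[ok]) / s2e
    se[poly][ok] <- sqrt(s2e / den[ok])
  } else {
    idx <- which(poly)
    for (k in seq_along(idx)) {
      j <- idx[k]
      alt <- fit_model1(pheno, A, trait = trait, snp = geno[, j],
                        start = pmax(null_fit$vc[1:3] / null_fit$vc[4L],
                                     1e-4))
      eff[j] <- alt$alpha
      se[j] <- alt$se_alpha
      lrt[j] <- max(0, 2 * (alt$loglik - null_fit$loglik))
      if (verbose && k %% 200L == 0L)
        message("exact scan: ", k, "/", length(idx))
    }
  }
  if (any(!poly) && verbose)
    message("skipped ", sum(!poly), " monomorphic SNP(s)")
  data.frame(snp_id = G$map$snp_id, chrom = G$map$chrom,
             pos_bp = G$map$pos_bp, effect = eff, se = se, lrt = lrt,
             p = stats::pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE),
             method = "model1", trait = trait, maf = unname(maf),
             stringsAsFactors = FALSE)
}
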