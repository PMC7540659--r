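# Bivariate animal model treating SNP allele content as a second trait,
# fitted by EM-REML.  Trait 1 is a performance trait recorded either on
# individuals (genotyped and non-genotyped) or as cage means; trait 2 is the
# allele content, recorded only on genotyped animals.  The genetic covariance
# between the two traits carries the SNP effect:
#   alpha_p = sigma_a1a2 / (2 f_p (1 - f_p)).
#
# Under the null (sigma_a1a2 = 0) the model separates exactly into a
# trait-1-only REML fit (SNP-independent, cached on the design) and a tiny
# allele-content animal model, so every null fit sits at its true optimum;
# the alternative fit is then warm-started from that optimum and can only
# gain likelihood by freeing the covariance.

#' Precompute the bivariate-model design for one trait
#'
#' Builds every SNP-independent ingredient of the bivariate fit: fixed-effect
#' matrices, record-space covariance kernels \eqn{Z_1 A Z_1'},
#' \eqn{Z_1 A Z_2'}, \eqn{Z_2 A Z_2'}, litter/cage kernels, and the residual
#' weights.  [fit_bivariate()] accepts this object in place of raw data, so a
#' genome scan pays the setup cost (and the trait-1 null fit) once.
#'
#' @param trait_df individual phenotype data frame (`animal`, factor columns,
#'   `cage`, `litter`, trait column) or a cage data frame from
#'   [derive_traits()] (`cage`, `batch`, `size_class`, `members`, trait
#'   column)
#' @param type `"individual"` or `"cage"`
#' @param geno_ids animal ids of the genotyped set (trait-2 record owners)
#' @param A `relmat` covering all animals with records plus the genotyped set
#' @param trait trait column name
#' @param litter_of named vector animal -> litter id, required for
#'   `type = "cage"` (cage rows carry member-weighted litter averages)
#' @return an opaque `bivar_design` list
#' @export
build_bivar_design <- function(trait_df, type = c("individual", "cage"),
                               geno_ids, A, trait, litter_of = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(A, "relmat"))
  trait_df <- as.data.frame(trait_df)
  geno_ids <- as.character(geno_ids)
  y1 <- trait_df[[trait]]
  keep <- !is.na(y1)
  trait_df <- trait_df[keep, , drop = FALSE]
  y1 <- y1[keep]
  n1 <- length(y1)
  if (type == "individual") {
    ids1 <- as.character(trait_df$animal)
    a_ids <- unique(c(ids1, geno_ids))
    Asub <- subset_relmat(A, a_ids)$A
    Z1 <- matrix(0, n1, length(a_ids))
    Z1[cbind(seq_len(n1), match(ids1, a_ids))] <- 1
    X1 <- build_fixed(trait_df)
    ZL1 <- incidence(trait_df$litter)
    ZC1 <- incidence(trait_df$cage)
    d1 <- rep(1, n1)
  } else {
    if (is.null(litter_of)) stop("litter_of required for cage-mean records")
    members <- trait_df$members
    a_ids <- unique(c(unlist(members), geno_ids))
    Asub <- subset_relmat(A, a_ids)$A
    Z1 <- matrix(0, n1, length(a_ids))
    litters <- sort(unique(as.character(litter_of[unlist(members)])))
    ZL1 <- matrix(0, n1, length(litters))
    for (i in seq_len(n1)) {
      mem <- as.character(members[[i]])
      w <- 1 / length(mem)
      Z1[i, match(mem, a_ids)] <- w
      lit <- as.character(litter_of[mem])
      for (lt in lit)                    # duplicate litters accumulate 2/N
        ZL1[i, match(lt, litters)] <- ZL1[i, match(lt, litters)] + w
    }
    d1 <- 1 / vapply(members, length, 1L)   # residual weight of a cage mean
    X1 <- build_fixed(trait_df,
                      vars = c("batch", "size_class", "regime"))
    ZC1 <- NULL                          # no cage effect in the mean model
  }
  n2 <- length(geno_ids)
  Z2 <- matrix(0, n2, length(a_ids))
  Z2[cbind(seq_len(n2), match(geno_ids, a_ids))] <- 1
  AZ1t <- Asub %*% t(Z1)
  K11 <- Z1 %*% AZ1t
  K12 <- t(Z2 %*% AZ1t)                  # n1 x n2
  K22 <- Z2 %*% Asub %*% t(Z2)
  structure(list(
    type = type, trait = trait, y1 = y1, n1 = n1, n2 = n2,
    a_ids = a_ids, geno_ids = geno_ids, A = Asub,
    X1 = X1, Z1 = Z1, Z2 = Z2, ZL1 = ZL1, ZC1 = ZC1, d1 = d1,
    KL = if (!is.null(ZL1)) tcrossprod(ZL1) else NULL,
    KC = if (!is.null(ZC1)) tcrossprod(ZC1) else NULL,
    q_l = if (!is.null(ZL1)) ncol(ZL1) else 0L,
    q_c = if (!is.null(ZC1)) ncol(ZC1) else 0L,
    K11 = K11, K12 = K12, K22 = K22,
    cache = new.env(parent = emptyenv())), class = "bivar_design")
}

# trait-1-only REML fit (the bivariate null's first factor); th = (sa1,
# sc2, sl2, se1).  n_a is the full a-vector dimension so the EM fixed point
# matches the bivariate null exactly.
fit_trait1_reml <- function(d, tol = 1e-8, maxit = 5000L) {
  y <- d$y1; X <- d$X1; n1 <- d$n1
  n_a <- length(d$a_ids)
  p_rank <- qr(X)$rank
  vy <- stats::var(y)
  build_V <- function(th) {
    V <- th[1L] * d$K11
    if (d$q_c) V <- V + th[2L] * d$KC
    if (d$q_l) V <- V + th[3L] * d$KL
    diag(V) <- diag(V) + th[4L] * d$d1
    V
  }
  ll_fn <- function(th) reml_ll(y, X, build_V(th), p_rank)$ll
  step_fn <- function(th) {
    V <- build_V(th)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    chx <- chol(XtVi %*% X)
    B <- backsolve(chx, backsolve(chx, XtVi, transpose = TRUE))
    P <- Vi - t(XtVi) %*% B
    pv <- as.numeric(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * pv) + (n1 - p_rank) * log(2 * pi))
    t1 <- as.numeric(crossprod(d$Z1, pv))
    new <- th
    new[1L] <- (th[1L]^2 * sum(t1 * (d$A %*% t1)) + n_a * th[1L] -
                  th[1L]^2 * sum(P * d$K11)) / n_a
    if (d$q_c) {
      u <- as.numeric(crossprod(d$ZC1, pv))
      new[2L] <- th[2L] + th[2L]^2 / d$q_c * (sum(u^2) - sum(P * d$KC))
    }
    if (d$q_l) {
      u <- as.numeric(crossprod(d$ZL1, pv))
      new[3L] <- th[3L] + th[3L]^2 / d$q_l * (sum(u^2) - sum(P * d$KL))
    }
    new[4L] <- th[4L] + th[4L]^2 / n1 *
      (sum(d$d1 * pv^2) - sum(diag(P) * d$d1))
    new[4L] <- max(new[4L], 1e-8 * vy)
    list(ll = ll, th = new, aux = B)
  }
  floors <- c(1e-10 * vy, 0, 0, 1e-8 * vy)
  sanitize <- function(th) pmax(th, floors)
  th0 <- c(0.3 * vy, if (d$q_c) 0.1 * vy else 0,
           if (d$q_l) 0.1 * vy else 0, 0.5 * vy)
  res <- accel_em(th0, step_fn, ll_fn, sanitize,
                  guard = rep(1e-3 * vy, 4L), floors = floors,
                  scales = rep(vy, 4L), tol = tol, maxit = maxit,
                  snap_ok = c(FALSE, TRUE, TRUE, FALSE))
  res$beta <- as.numeric(res$aux %*% y)
  res
}

# allele-content animal model y2 = mu + a2 + e2; th = (sa2, se2)
fit_content_reml <- function(d, y2, e2_floor, tol = 1e-6, maxit = 500L) {
  n2 <- length(y2)
  n_a <- length(d$a_ids)
  X <- matrix(1, n2, 1L)
  vy <- max(stats::var(y2), 1e-8)
  build_V <- function(th) {
    V <- th[1L] * d$K22
    diag(V) <- diag(V) + th[2L]
    V
  }
  ll_fn <- function(th) reml_ll(y2, X, build_V(th), 1L)$ll
  step_fn <- function(th) {
    V <- build_V(th)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    chx <- chol(XtVi %*% X)
    B <- backsolve(chx, backsolve(chx, XtVi, transpose = TRUE))
    P <- Vi - t(XtVi) %*% B
    pv <- as.numeric(P %*% y2)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y2 * pv) + (n2 - 1L) * log(2 * pi))
    t2 <- as.numeric(crossprod(d$Z2, pv))
    new <- th
    new[1L] <- (th[1L]^2 * sum(t2 * (d$A %*% t2)) + n_a * th[1L] -
                  th[1L]^2 * sum(P * d$K22)) / n_a
    new[2L] <- max(e2_floor, th[2L] + th[2L]^2 / n2 *
                     (sum(pv^2) - sum(diag(P))))
    list(ll = ll, th = new, aux = as.numeric(B %*% y2))
  }
  floors <- c(1e-10 * vy, e2_floor)
  sanitize <- function(th) pmax(th, floors)
  res <- accel_em(c(0.8 * vy, max(0.2 * vy, e2_floor)), step_fn, ll_fn,
                  sanitize, guard = rep(1e-3 * vy, 2L), floors = floors,
                  scales = rep(vy, 2L), tol = tol, maxit = maxit,
                  snap_ok = c(FALSE, TRUE))
  res$mu <- res$aux
  res
}

#' Fit the bivariate allele-content animal model by EM-REML
#'
#' Two correlated traits: the performance trait (individual records or cage
#' means) and the allele content of one SNP, with genetic covariance
#' \eqn{G_0 \otimes A} and independent residuals (the residual covariance
#' between traits is structurally zero; a cage-mean record has residual
#' variance \eqn{\sigma^2_{e1}/N_n}).  Under the null, the genetic
#' covariance \eqn{\sigma_{a1,a2}} is constrained to zero, which makes the
#' model separable: the null is fitted exactly as a trait-1-only REML fit
#' (computed once per design and cached) plus an allele-content animal
#' model.  The likelihood-ratio test of the constraint is the association
#' test.
#'
#' Each EM iteration solves the model at the current variance components and
#' updates every component from its expected complete-data sufficient
#' statistic; the REML log-likelihood is non-decreasing across iterations
#' (asserted by the test suite), with monotonicity-safe Aitken/boundary-snap
#' acceleration collapsing the geometric crawl of components heading to a
#' boundary.  Convergence: maximum relative component change below `tol`,
#' or `maxit` iterations (then the result is flagged, not an error).
#'
#' @param design a `bivar_design` from [build_bivar_design()] (or pass the
#'   raw arguments of that function via `...`)
#' @param snp allele-content vector for the genotyped animals (named or in
#'   `design$geno_ids` order); `NA`s allowed (those records are dropped)
#' @param null constrain the genetic covariance to zero?
#' @param init optional named list of starting components for the
#'   alternative fit (`G0`, `sigma_c2`, `sigma_l2`, `sigma_e1`,
#'   `sigma_e2`); when absent the alternative starts from its own null
#'   solution
#' @param tol relative-change convergence tolerance (default `1e-6`)
#' @param maxit maximum EM iterations (default 500)
#' @param freq_from `"observed"` (frequency of the counted allele among
#'   genotyped animals, the default) or `"mu"` (\eqn{\hat\mu/2})
#' @param ... alternative raw-data interface forwarded to
#'   [build_bivar_design()]
#' @return `cagewas_fit` list: `loglik`, `vc` (named vector incl. `G0`
#'   entries), `G0`, `alpha`, `freq`, `mu`, `beta1`, `converged`,
#'   `iterations`, `loglik_trace`
#' @export
fit_bivariate <- function(design, snp, null = FALSE, init = NULL,
                          tol = 1e-6, maxit = 500L, freq_from = "observed",
                          ...) {
  if (!inherits(design, "bivar_design"))
    design <- build_bivar_design(design, ...)
  d <- design
  y2 <- if (!is.null(names(snp))) as.numeric(snp[d$geno_ids])
        else as.numeric(snp)
  use2 <- !is.na(y2)
  if (!all(use2)) {
    y2 <- y2[use2]
    d$Z2 <- d$Z2[use2, , drop = FALSE]
    d$K12 <- d$K12[, use2, drop = FALSE]
    d$K22 <- d$K22[use2, use2, drop = FALSE]
    d$n2 <- sum(use2)
  }
  f <- mean(y2) / 2
  if (f <= 0 || f >= 1) stop("monomorphic SNP: effect undefined")
  vy1 <- stats::var(d$y1); vy2 <- max(stats::var(y2), 1e-8)
  e2_floor <- 1e-4 * vy2

  # trait-1 null factor: SNP-independent, computed once per design
  t1_fit <- get0("t1_fit", envir = design$cache, inherits = FALSE)
  if (is.null(t1_fit)) {
    t1_fit <- fit_trait1_reml(d, tol = min(tol, 1e-8),
                              maxit = max(maxit, 5000L))
    assign("t1_fit", t1_fit, envir = design$cache)
  }

  if (null) {
    t2_fit <- fit_content_reml(d, y2, e2_floor, tol = tol, maxit = maxit)
    th1 <- t1_fit$th
    mu <- t2_fit$mu
    f_use <- if (freq_from == "mu") mu / 2 else f
    vc <- c(sigma_a1 = th1[1L], sigma_a12 = 0, sigma_a2 = t2_fit$th[1L],
            sigma_c2 = th1[2L], sigma_l2 = th1[3L], sigma_e1 = th1[4L],
            sigma_e2 = t2_fit$th[2L])
    return(structure(list(
      loglik = t1_fit$loglik + t2_fit$loglik,
      vc = vc, G0 = diag(c(vc[["sigma_a1"]], vc[["sigma_a2"]])),
      alpha = 0, freq = f_use, mu = mu, beta1 = t1_fit$beta,
      converged = t1_fit$converged && t2_fit$converged,
      iterations = t2_fit$iterations,
      loglik_trace = t1_fit$loglik + t2_fit$trace,
      n = d$n1 + d$n2), class = "cagewas_fit"))
  }

  # ---- alternative model: joint fit over both traits ---------------------
  n1 <- d$n1; n2 <- d$n2; m <- n1 + n2
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  n_a <- length(d$a_ids)
  X <- rbind(cbind(d$X1, 0), cbind(matrix(0, n2, ncol(d$X1)), 1))
  p_rank <- qr(X)$rank
  y <- c(d$y1, y2)
  # flat parameter order: (sa1, sa12, sa2, sc2, sl2, se1, se2)
  unflatten <- function(th) list(
    G0 = matrix(c(th[1L], th[2L], th[2L], th[3L]), 2),
    sigma_c2 = th[4L], sigma_l2 = th[5L], sigma_e1 = th[6L],
    sigma_e2 = th[7L])
  build_V <- function(th) {
    vc <- unflatten(th)
    V <- matrix(0, m, m)
    V[i1, i1] <- vc$G0[1, 1] * d$K11 +
      (if (d$q_l) vc$sigma_l2 * d$KL else 0) +
      (if (d$q_c) vc$sigma_c2 * d$KC else 0)
    V[i1, i2] <- vc$G0[1, 2] * d$K12
    V[i2, i1] <- t(V[i1, i2])
    V[i2, i2] <- vc$G0[2, 2] * d$K22
    diag(V)[i1] <- diag(V)[i1] + vc$sigma_e1 * d$d1
    diag(V)[i2] <- diag(V)[i2] + vc$sigma_e2
    V
  }
  ll_fn <- function(th) reml_ll(y, X, build_V(th), p_rank)$ll
  step_fn <- function(th) {
    G0 <- matrix(c(th[1L], th[2L], th[2L], th[3L]), 2)
    ch <- chol(build_V(th))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    chx <- chol(XtVi %*% X)
    B <- backsolve(chx, backsolve(chx, XtVi, transpose = TRUE))
    P <- Vi - t(XtVi) %*% B
    pv <- as.numeric(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * pv) + (m - p_rank) * log(2 * pi))
    p1 <- pv[i1]; p2 <- pv[i2]
    t1 <- as.numeric(crossprod(d$Z1, p1))
    t2 <- as.numeric(crossprod(d$Z2, p2))
    s1 <- G0[1, 1] * t1 + G0[1, 2] * t2
    s2 <- G0[1, 2] * t1 + G0[2, 2] * t2
    Smat <- cbind(s1, s2)
    M1 <- crossprod(Smat, d$A %*% Smat)
    Tm <- matrix(0, 2, 2)
    Tm[1, 1] <- sum(P[i1, i1] * d$K11)
    Tm[1, 2] <- Tm[2, 1] <- sum(P[i1, i2] * d$K12)
    Tm[2, 2] <- sum(P[i2, i2] * d$K22)
    E <- M1 + n_a * G0 - G0 %*% Tm %*% G0
    G0_new <- (E + t(E)) / (2 * n_a)
    new <- th
    new[1L] <- G0_new[1, 1]; new[2L] <- G0_new[1, 2]
    new[3L] <- G0_new[2, 2]
    if (d$q_l) {
      u <- as.numeric(crossprod(d$ZL1, p1))
      new[5L] <- th[5L] + th[5L]^2 / d$q_l *
        (sum(u^2) - sum(P[i1, i1] * d$KL))
    }
    if (d$q_c) {
      u <- as.numeric(crossprod(d$ZC1, p1))
      new[4L] <- th[4L] + th[4L]^2 / d$q_c *
        (sum(u^2) - sum(P[i1, i1] * d$KC))
    }
    new[6L] <- max(th[6L] + th[6L]^2 / n1 *
                     (sum(d$d1 * p1^2) - sum(diag(P)[i1] * d$d1)),
                   1e-8 * vy1)
    new[7L] <- max(e2_floor,
                   th[7L] + th[7L]^2 / n2 *
                     (sum(p2^2) - sum(diag(P)[i2])))
    list(ll = ll, th = new, aux = B)
  }
  floors <- c(1e-10 * vy1, NA, 1e-10 * vy2, 0, 0, 1e-8 * vy1, e2_floor)
  scales <- c(vy1, sqrt(vy1 * vy2), vy2, vy1, vy1, vy1, vy2)
  sanitize <- function(th) {
    th[1L] <- max(th[1L], floors[1L])
    th[3L] <- max(th[3L], floors[3L])
    bound <- 0.999 * sqrt(th[1L] * th[3L])
    th[2L] <- min(max(th[2L], -bound), bound)
    th[4L] <- max(th[4L], 0); th[5L] <- max(th[5L], 0)
    th[6L] <- max(th[6L], floors[6L]); th[7L] <- max(th[7L], floors[7L])
    th
  }
  # boundary snap must not target the covariance: use 0 as its "floor"
  floors[2L] <- 0
  th0 <- if (!is.null(init)) {
    G0i <- init$G0
    c(G0i[1, 1], G0i[1, 2], G0i[2, 2],
      if (is.null(init$sigma_c2)) (if (d$q_c) 0.1 * vy1 else 0)
        else init$sigma_c2,
      if (is.null(init$sigma_l2)) (if (d$q_l) 0.1 * vy1 else 0)
        else init$sigma_l2,
      if (is.null(init$sigma_e1)) 0.5 * vy1 else init$sigma_e1,
      if (is.null(init$sigma_e2)) max(0.2 * vy2, e2_floor)
        else init$sigma_e2)
  } else {
    # start from this SNP's exact null solution; additive variances at a
    # zero boundary are lifted, because sigma_a1 = 0 makes sigma_a12 = 0 an
    # EM fixed point and the alternative could never express a covariance
    t2_fit <- fit_content_reml(d, y2, e2_floor, tol = tol, maxit = maxit)
    sa1_0 <- max(t1_fit$th[1L], 0.05 * vy1)
    sa2_0 <- max(t2_fit$th[1L], 0.05 * vy2)
    # seed the covariance from the sign of the raw cross-moment between
    # trait records and the (cage-averaged) content of their animals
    gbar <- as.numeric(d$Z1 %*% (t(d$Z2) %*% (y2 - mean(y2))))
    cm <- suppressWarnings(stats::cov(d$y1, gbar))
    sgn <- if (is.na(cm) || cm == 0) 1 else sign(cm)
    c(sa1_0, sgn * 0.05 * sqrt(sa1_0 * sa2_0), sa2_0,
      t1_fit$th[2L], t1_fit$th[3L], t1_fit$th[4L], t2_fit$th[2L])
  }
  res <- accel_em(sanitize(th0), step_fn, ll_fn, sanitize,
                  guard = 1e-3 * scales, floors = floors, scales = scales,
                  tol = tol, maxit = maxit,
                  snap_ok = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  th <- res$th
  beta <- as.numeric(res$aux %*% y)
  mu <- beta[length(beta)]
  f_use <- if (freq_from == "mu") mu / 2 else f
  alpha <- th[2L] / (2 * f_use * (1 - f_use))
  structure(list(
    loglik = res$loglik,
    vc = c(sigma_a1 = th[1L], sigma_a12 = th[2L], sigma_a2 = th[3L],
           sigma_c2 = th[4L], sigma_l2 = th[5L], sigma_e1 = th[6L],
           sigma_e2 = th[7L]),
    G0 = matrix(c(th[1L], th[2L], th[2L], th[3L]), 2),
    alpha = alpha, freq = f_use, mu = mu,
    beta1 = beta[-length(beta)], converged = res$converged,
    iterations = res$iterations,
    loglik_trace = res$trace, n = m), class = "cagewas_fit")
}

#' Likelihood-ratio test for the genetic covariance
#'
#' \eqn{\mathrm{LRT} = \max(0, 2(\ell_{alt} - \ell_{null}))} referred to a
#' chi-squared distribution with one degree of freedom (the covariance is an
#' interior parameter).  A negative difference, possible numerically, is
#' clamped to zero with a warning.
#'
#' @param fit_alt,fit_null `cagewas_fit` objects for the same data
#' @return list `statistic`, `p`
#' @export
lrt_covariance <- function(fit_alt, fit_null) {
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -0.01)
    warning("alternative log-likelihood below null (", format(stat),
            "); clamping LRT to 0")
  stat <- max(0, stat)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bivariate genome scan
#'
#' Fits the null and alternative bivariate model for every SNP.  The
#' trait-1 side of the null is fitted once and cached on the design; each
#' SNP then costs one small allele-content fit plus one warm-started
#' alternative fit.
#'
#' @param design a `bivar_design`
#' @param G a `genotypes` object; its rows must cover `design$geno_ids`
#' @param tol,maxit EM controls (see [fit_bivariate()])
#' @param verbose message progress every 100 SNPs
#' @return association data frame (`snp_id, chrom, pos_bp, effect, se, lrt,
#'   p, method, trait, maf, converged`)
#' @export
scan_bivariate <- function(design, G, tol = 1e-6, maxit = 500L,
                           verbose = FALSE) {
  stopifnot(inherits(design, "bivar_design"), inherits(G, "genotypes"))
  geno <- G$geno[design$geno_ids, , drop = FALSE]
  mS <- ncol(geno)
  eff <- lrt <- maf <- rep(NA_real_, mS)
  conv <- rep(NA, mS)
  for (j in seq_len(mS)) {
    s <- geno[, j]
    fj <- mean(s, na.rm = TRUE) / 2
    if (is.na(fj) || fj <= 0 || fj >= 1) next   # monomorphic: skip
    maf[j] <- min(fj, 1 - fj)
    fit0 <- fit_bivariate(design, s, null = TRUE, tol = tol, maxit = maxit)
    fit1 <- fit_bivariate(design, s, null = FALSE, tol = tol,
                          maxit = maxit)
    test <- lrt_covariance(fit1, fit0)
    eff[j] <- fit1$alpha
    lrt[j] <- test$statistic
    conv[j] <- fit0$converged && fit1$converged
    if (verbose && j %% 100L == 0L) message("bivariate scan: ", j, "/", mS)
  }
  data.frame(snp_id = G$map$snp_id, chrom = G$map$chrom,
             pos_bp = G$map$pos_bp, effect = eff, se = NA_real_, lrt = lrt,
             p = stats::pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE),
             method = "bivar", trait = design$trait, maf = maf,
             converged = conv, stringsAsFactors = FALSE)
}

#' Fraction of phenotypic variance explained by a SNP
#'
#' \eqn{2 f (1-f) \alpha^2 / \sigma_P^2}: the additive variance contributed
#' by a biallelic locus with allele frequency \eqn{f} and substitution
#' effect \eqn{\alpha}, relative to the phenotypic variance.
#'
#' @param alpha allele substitution effect (trait units)
#' @param f allele frequency, in (0, 1)
#' @param sigmaP2 phenotypic variance (trait units squared)
#' @return fraction (not percent)
#' @export
variance_explained <- function(alpha, f, sigmaP2) {
  if (any(f <= 0 | f >= 1)) stop("frequency must lie in (0, 1)")
  if (any(sigmaP2 <= 0)) stop("phenotypic variance must be positive")
  2 * f * (1 - f) * alpha^2 / sigmaP2
}

#' Regression of a cage trait on the cage-average genotype
#'
#' Model-free check of a cage-trait association: ordinary least squares of
#' the cage phenotype on the mean allele content of the cage's genotyped
#' members, with intercept.
#'
#' @param cage_trait numeric vector of cage phenotypes
#' @param members list of member id vectors, one per cage
#' @param snp named allele-content vector for genotyped animals
#' @return list `slope`, `se`, `p`, `n` (cages with at least one genotyped
#'   member)
#' @export
group_genotype_regression <- function(cage_trait, members, snp) {
  gbar <- vapply(members, function(mem) {
    g <- snp[as.character(mem)]
    if (all(is.na(g))) NA_real_ else mean(g, na.rm = TRUE)
  }, 0)
  ok <- !is.na(gbar) & !is.na(cage_trait)
  if (sum(ok) < 3L) stop("need >= 3 cages with genotyped members")
  if (stats::var(gbar[ok]) == 0)
    stop("constant cage-average genotype: slope undefined")
  fit <- summary(stats::lm(cage_trait[ok] ~ gbar[ok]))
  co <- fit$coefficients
  list(slope = co[2L, 1L], se = co[2L, 2L], p = co[2L, 4L], n = sum(ok))
}
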