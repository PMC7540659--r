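# Accelerated EM driver shared by every REML fitter in the package.
#
# EM guarantees a non-decreasing (restricted) log-likelihood but crawls
# geometrically when a variance component heads for a boundary.  Every five
# iterations the driver proposes candidate jumps -- Aitken extrapolation
# along the EM path at two aggressiveness levels plus snapping monotonically
# decaying near-zero components to their floors -- and accepts the best
# candidate only if the log-likelihood does not decrease (a generalized-EM
# step, so the monotone trace is preserved).
#
# step_fn(th)  -> list(ll = loglik at th, th = EM-updated parameters,
#                      aux = anything the caller wants back)
# ll_fn(th)    -> loglik only (cheap, no inverse)
# sanitize(th) -> projected-to-valid parameter vector
# guard        -> denominators guarding the relative-change criterion
# floors/scales -> per-component boundary values and magnitudes
accel_em <- function(th0, step_fn, ll_fn, sanitize, guard, floors, scales,
                     tol = 1e-6, maxit = 500L,
                     snap_ok = rep(TRUE, length(th0))) {
  th <- th0
  trace <- numeric(0)
  hist <- list()
  converged <- FALSE
  iter <- 0L
  aux <- NULL
  repeat {
    iter <- iter + 1L
    step <- step_fn(th)
    aux <- step$aux
    trace <- c(trace, step$ll)
    rel <- max(abs(step$th - th) / pmax(abs(th), guard))
    th <- step$th
    hist <- c(hist, list(th))
    if (length(hist) > 3L) hist <- hist[-1L]
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
    if (iter %% 5L == 0L && length(hist) == 3L) {
      d1v <- hist[[2L]] - hist[[1L]]; d2v <- hist[[3L]] - hist[[2L]]
      r <- ifelse(abs(d1v) > 0, d2v / d1v, 0)
      th_cur <- hist[[3L]]
      decaying <- snap_ok & d1v < 0 & d2v < 0 & th_cur < 0.05 * scales
      th_snap <- th_cur
      th_snap[decaying] <- floors[decaying]
      cand <- list(
        sanitize(th_cur + pmin(pmax(r, 0), 0.995) /
                   (1 - pmin(pmax(r, 0), 0.995)) * d2v),
        sanitize(th_cur + pmin(pmax(r, 0), 0.9999) /
                   (1 - pmin(pmax(r, 0), 0.9999)) * d2v),
        sanitize(th_snap))
      best_ll <- step$ll; best <- NULL
      for (th_acc in cand) {
        llc <- ll_fn(th_acc)
        if (llc >= best_ll) { best_ll <- llc; best <- th_acc }
      }
      if (!is.null(best)) {
        th <- best
        hist <- list()
      }
    }
  }
  list(th = th, loglik = trace[length(trace)], trace = trace,
       converged = converged, iterations = iter, aux = aux)
}

# generic REML pieces for a univariate system y = Xb + sum_j u_j + e with
# V = sum_j th_j K_j + th_e D; "A-type" components use E[u'A^-1 u] with
# denominator n_a, iid components use E[u'u] with their level count.
reml_ll <- function(y, X, V, n_rank) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  yv <- backsolve(ch, y, transpose = TRUE)
  Xv <- backsolve(ch, X, transpose = TRUE)
  XVX <- crossprod(Xv)
  chx <- tryCatch(chol(XVX), error = function(e) NULL)
  if (is.null(chx)) return(list(ll = -Inf))
  bw <- backsolve(chx, crossprod(Xv, yv), transpose = TRUE)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                sum(yv^2) - sum(bw^2) +
                (length(y) - n_rank) * log(2 * pi))
  list(ll = ll, ch = ch, chx = chx)
}
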