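## Kernel-based REML engine for variance-component models of the form
##
##   y = X b + sum_k u_k + e,   u_k ~ N(0, s2_k K_k),   e ~ N(0, s2_e I)
##
## with arbitrary symmetric PSD n x n kernels K_k. Average-information (AI)
## updates with a monotone fixed-point fallback and step halving, so the REML
## log-likelihood is non-decreasing across iterations. Dense algebra; meant
## for the record counts of two-stage analyses (hundreds to a few thousand).

## Restricted log-likelihood and the quantities reused by the updates.
## Returns NULL when V is numerically non-PD.
reml_eval <- function(theta, y, X, kernels) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(kernels))
    V <- V + theta[k] * kernels[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  XtViX_inv <- chol2inv(chx)
  P <- Vi - t(XtVi) %*% XtViX_inv %*% XtVi
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = Py,
       beta = as.numeric(XtViX_inv %*% (XtVi %*% y)),
       beta_vcov = XtViX_inv)
}

## theta layout: c(s2_1, ..., s2_m, s2_e)
reml_fit <- function(y, X, kernels, init = NULL, tol = 1e-6, max_iter = 200,
                     verbose = FALSE) {
  n <- length(y)
  m <- length(kernels)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0)
    stopf("reml_fit: response is constant; nothing to estimate")
  lb <- 1e-10 * vy
  theta <- if (!is.null(init)) pmax(init, lb) else rep(vy / (m + 1), m + 1)

  ev <- reml_eval(theta, y, X, kernels)
  if (is.null(ev)) stopf("reml_fit: initial covariance not positive definite")
  ll_trace <- ev$ll
  converged <- FALSE
  it <- 0L

  for (it in seq_len(max_iter)) {
    P <- ev$P; Py <- ev$Py
    ## scores and AI matrix over all m + 1 components (residual kernel = I)
    KPy <- vector("list", m + 1L)
    trPK <- numeric(m + 1L)
    yPKPy <- numeric(m + 1L)
    for (k in seq_len(m)) {
      KPy[[k]] <- kernels[[k]] %*% Py
      trPK[k] <- sum(P * kernels[[k]])
      yPKPy[k] <- sum(Py * KPy[[k]])
    }
    KPy[[m + 1L]] <- Py
    trPK[m + 1L] <- sum(diag(P))
    yPKPy[m + 1L] <- sum(Py * Py)

    score <- -0.5 * (trPK - yPKPy)
    AI <- matrix(0, m + 1L, m + 1L)
    PKPy <- lapply(KPy, function(v) P %*% v)
    for (a in seq_len(m + 1L)) for (b in a:(m + 1L)) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(KPy[[a]] * PKPy[[b]])
    }

    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    proposals <- list()
    if (!is.null(step)) proposals$ai <- pmax(theta + step, lb)
    ## monotone fixed point: s2 <- s2 * (y'P K P y) / tr(P K)
    fp <- theta * yPKPy / pmax(trPK, 1e-12)
    ## components decaying towards zero are offered the bound directly,
    ## avoiding a long geometric crawl; accepted only if the likelihood
    ## does not drop
    tiny <- theta < 1e-5 * vy & fp < theta
    if (any(tiny)) {
      pin <- pmax(fp, lb)
      pin[tiny] <- lb
      proposals$pin <- pin
    }
    proposals$em <- pmax(fp, lb)

    accepted <- FALSE
    theta_old <- theta
    for (prop in proposals) {
      cand <- prop
      for (h in 0:4) {               # step halving toward current theta
        th_try <- theta + (cand - theta) / 2^h
        ev_try <- reml_eval(th_try, y, X, kernels)
        if (!is.null(ev_try) && is.finite(ev_try$ll) &&
            ev_try$ll >= utils::tail(ll_trace, 1) - 1e-10) {
          theta <- th_try; ev <- ev_try; accepted <- TRUE
          break
        }
      }
      if (accepted) break
    }
    if (!accepted) { converged <- TRUE; break }  # no uphill move left
    ll_trace <- c(ll_trace, ev$ll)
    ## stationary in the parameters (components pinned near a boundary)
    if (max(abs(theta - theta_old) / pmax(theta_old, lb)) < 1e-8) {
      converged <- TRUE
      break
    }
    dll <- abs(ll_trace[length(ll_trace)] - ll_trace[length(ll_trace) - 1L])
    rel <- dll / max(1, abs(ev$ll))
    if (verbose)
      gs_log("DEBUG", sprintf("REML iter %d logLik %.6f", it, ev$ll))
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("reml_fit: not converged after %d iterations (last rel. change above %g)",
                    max_iter, tol), call. = FALSE)
  list(theta = theta, logLik = utils::tail(ll_trace, 1), ll_trace = ll_trace,
       iterations = it, converged = converged,
       beta = ev$beta, beta_vcov = ev$beta_vcov, Py = as.numeric(ev$Py))
}
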