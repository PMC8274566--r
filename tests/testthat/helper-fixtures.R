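# Shared fixtures and independent dense-matrix oracles. Oracles are written
# from the model definitions directly (solve(), determinant(), enumeration)
# and never call the package's iterative fitters.

# plain numeric matrix from a grm (drops the bookkeeping attributes)
gmat <- function(G) {
  matrix(as.numeric(G), nrow(G), ncol(G), dimnames = dimnames(G))
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_populations = 4L, lines_per_population = 30L,
                   n_founders = 8L, n_markers = 400L,
                   trials_per_year_ww = 1L, trials_per_year_ws = 1L,
                   n_qtl = 60L, n_checks = 3L,
                   year_weights = c(1, 1, 1), seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

## simulate line x environment means directly on the BLUE scale from a given
## G, with known variance parts (bypasses the trial layer on purpose)
make_blue_fixture <- function(G, n_env = 2, s2_E = 1, s2_g = 1, s2_gE = 0.5,
                              s2_e = 1, mu = 10, seed = 1) {
  set.seed(seed)
  n_l <- nrow(G)
  d <- expand.grid(line_id = rownames(G), env = paste0("E", seq_len(n_env)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(d$line_id, rownames(G))
  n <- nrow(d)
  Kg <- unclass(G)[idx, idx]
  Ke <- if (n_env > 1)
    tcrossprod(stats::model.matrix(~ 0 + factor(d$env)))
  else matrix(1, n, n)
  draw <- function(K, s2) {
    if (s2 == 0) return(numeric(n))
    ch <- chol(K + diag(1e-8, n))
    sqrt(s2) * as.numeric(t(ch) %*% stats::rnorm(n))
  }
  d$blue <- mu + draw(Ke, s2_E) + draw(Kg, s2_g) + draw(Kg * Ke, s2_gE) +
    stats::rnorm(n, 0, sqrt(s2_e))
  d
}

## closed-form GBLUP at fixed variances: GLS intercept, then
## g_hat = s2_g * G * Vinv * (y - mu_hat), for single-environment data
blup_oracle <- function(y, G, s2_g, s2_e) {
  n <- length(y)
  V <- s2_g * unclass(G) + diag(s2_e, n)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- sum(Vi %*% y) / sum(Vi)
  as.numeric(s2_g * unclass(G) %*% Vi %*% (y - mu))
}

## REML log-likelihood from its definition, via solve()/determinant() only
reml_ll_oracle <- function(theta, y, X, kernels) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(kernels)) V <- V + theta[k] * kernels[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  B <- solve(XtViX, t(X) %*% Vi)
  P <- Vi - Vi %*% X %*% B
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}

## brute-force REML maximization on the log-variance scale
reml_brute_force <- function(y, X, kernels, start) {
  obj <- function(lt) -reml_ll_oracle(exp(lt), y, X, kernels)
  o <- stats::optim(log(start), obj, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  exp(o$par)
}

## marker-effect ridge regression with lambda = m * s2_e / s2_g, the
## equivalent of GBLUP when G = W W' / m
ridge_oracle <- function(y, W, s2_g, s2_e) {
  m <- ncol(W)
  lambda <- m * s2_e / s2_g
  n <- nrow(W)
  one <- rep(1, n)
  ## joint GLS/ridge: solve for intercept and marker effects together
  V <- (s2_g / m) * tcrossprod(W) + diag(s2_e, n)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  beta <- solve(crossprod(W) + diag(lambda, m), crossprod(W, y - mu))
  as.numeric(W %*% beta)
}

## small multi-trial plot fixture with known effects, for stage-1 oracles
make_plot_fixture <- function(n_lines = 6, n_reps = 2, block_size = 3,
                              s2_block = 0.25, s2_e = 0.5, seed = 7) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  gv <- stats::rnorm(n_lines, sd = 1)
  recs <- list()
  for (r in seq_len(n_reps)) {
    ord <- sample(lines)
    blk <- ceiling(seq_along(ord) / block_size)
    beff <- stats::rnorm(max(blk), sd = sqrt(s2_block))
    recs[[r]] <- data.frame(
      year = "2017", management = "WW", trial = "T1", rep = r, block = blk,
      line_id = ord,
      GY = 5 + 0.2 * r + gv[match(ord, lines)] + beff[blk] +
        stats::rnorm(n_lines, sd = sqrt(s2_e)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}
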