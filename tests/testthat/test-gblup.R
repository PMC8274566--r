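make_small_G <- function(n = 30, m = 120, seed = 1) {
  set.seed(seed)
  mk <- matrix(rbinom(n * m, 1, 0.5), n, m,
               dimnames = list(sprintf("L%02d", seq_len(n)), NULL))
  build_grm(filter_markers(mk, 0.05, quiet = TRUE))
}

test_that("single-environment GEBVs equal the closed-form BLUP oracle", {
  G <- make_small_G(40, 200, seed = 2)
  d <- make_blue_fixture(G, n_env = 1, s2_E = 0, s2_gE = 0, s2_g = 1,
                         s2_e = 0.5, seed = 3)
  fit <- gblup(d, G, env = NULL)
  oracle <- blup_oracle(d$blue, G + diag(1e-6, nrow(G)),
                        fit$vc["sigma2_g"], fit$vc["sigma2_e"])
  expect_lt(max(abs(fit$gebv[d$line_id] - oracle)), 1e-6)
})

test_that("GBLUP equals marker-effect ridge regression on its own G", {
  set.seed(5)
  n <- 35; m <- 150
  mk <- matrix(rbinom(n * m, 1, 0.5), n, m,
               dimnames = list(sprintf("L%02d", 1:n), NULL))
  G <- build_grm(filter_markers(mk, 0.05, quiet = TRUE))
  W <- scale(mk[, apply(mk, 2, sd) > 0]) *
    sqrt(n / (n - 1))                         # population-sd standardization
  d <- make_blue_fixture(G, n_env = 1, s2_E = 0, s2_gE = 0, s2_g = 1.2,
                         s2_e = 0.8, seed = 6)
  fit <- gblup(d, G, env = NULL)
  ## ridge with lambda = m * s2_e / s2_g on the standardized markers
  ridge <- ridge_oracle(d$blue, W[d$line_id, ], fit$vc["sigma2_g"],
                        fit$vc["sigma2_e"])
  expect_lt(max(abs(fit$gebv[d$line_id] - ridge)), 1e-4)
})

test_that("REML matches brute-force likelihood maximization on a small fixture", {
  G <- make_small_G(25, 100, seed = 7)
  d <- make_blue_fixture(G, n_env = 2, s2_E = 0.5, s2_g = 1, s2_gE = 0.4,
                         s2_e = 0.7, seed = 8)
  fit <- gblup(d, G, env = "env", tol = 1e-10)
  Gs <- unclass(G) + diag(1e-6, nrow(G))
  idx <- match(d$line_id, rownames(G))
  Ke <- tcrossprod(stats::model.matrix(~ 0 + factor(d$env)))
  Kg <- Gs[idx, idx]
  kernels <- list(Ke, Kg, Kg * Ke)
  X <- matrix(1, nrow(d), 1)
  bf <- reml_brute_force(d$blue, X, kernels, start = unname(fit$vc))
  ll_fit <- reml_ll_oracle(unname(fit$vc), d$blue, X, kernels)
  ll_bf <- reml_ll_oracle(bf, d$blue, X, kernels)
  ## same optimum: likelihoods agree closely and components to ~3 decimals
  expect_lt(abs(ll_fit - ll_bf), 1e-3)
  expect_equal(unname(fit$vc), bf, tolerance = 5e-3)
})

test_that("the REML criterion never decreases across iterations", {
  G <- make_small_G(30, 150, seed = 9)
  for (s in 1:3) {
    d <- make_blue_fixture(G, n_env = 3, s2_E = 1, s2_g = 0.8, s2_gE = 0.5,
                           s2_e = 1.2, seed = 20 + s)
    fit <- gblup(d, G, env = "env")
    expect_true(all(diff(fit$ll_trace) >= -1e-10))
  }
})

test_that("no-signal data give zero GEBVs", {
  G <- make_small_G(20, 80, seed = 10)
  d <- data.frame(line_id = rownames(G), blue = 7.7)
  fit <- gblup(d, G, env = NULL)
  expect_true(all(fit$gebv == 0))
  ## near-pure-noise: GEBVs shrink towards zero relative to the response
  d2 <- data.frame(line_id = rownames(G), blue = rnorm(20, sd = 3))
  fit2 <- gblup(d2, G, env = NULL)
  expect_lt(stats::var(fit2$gebv[d2$line_id]), stats::var(d2$blue))
})

test_that("GEBV extraction honours duplicates, orthogonality and errors", {
  set.seed(11)
  mk <- matrix(rbinom(20 * 150, 1, 0.5), 20, 150,
               dimnames = list(sprintf("L%02d", 1:20), NULL))
  mk <- rbind(mk, dup = mk[1, ])      # genomic duplicate of L01
  G <- build_grm(filter_markers(mk, 0.05, quiet = TRUE))
  obs <- sprintf("L%02d", 1:20)       # dup has no phenotype
  d <- make_blue_fixture(G, n_env = 1, s2_E = 0, s2_gE = 0, seed = 12)
  d <- d[d$line_id %in% obs, ]
  fit <- gblup(d, G, env = NULL)
  ## equal up to the documented 1e-6 ridge stabilization of G
  expect_equal(unname(fit$gebv["dup"]), unname(fit$gebv["L01"]),
               tolerance = 1e-5)
  expect_error(predict(fit, "NOPE"), "unknown line")
  ## an unphenotyped line genomically orthogonal to all others predicts ~0
  G0 <- unclass(G)
  G0 <- cbind(rbind(G0, 0), 0)
  G0[nrow(G0), ncol(G0)] <- 1
  dimnames(G0) <- list(c(rownames(G), "ORTH"), c(rownames(G), "ORTH"))
  fit0 <- gblup(d, structure(G0, class = c("grm", "matrix", "array")),
                env = NULL)
  expect_lt(abs(fit0$gebv["ORTH"]), 1e-8)
})

test_that("reduced-form G-propagation equals the full solve for held-out lines", {
  G <- make_small_G(30, 200, seed = 13)
  d <- make_blue_fixture(G, n_env = 1, s2_E = 0, s2_gE = 0, seed = 14)
  trn <- rownames(G)[1:22]; tst <- rownames(G)[23:30]
  fit <- gblup(d[d$line_id %in% trn, ], G, env = NULL)
  Gm <- unclass(G) + diag(1e-6, nrow(G))
  prop <- Gm[tst, trn] %*% solve(Gm[trn, trn], fit$gebv[trn])
  expect_lt(max(abs(fit$gebv[tst] - prop[, 1])), 1e-6)
})

test_that("permuting line order permutes the GEBVs identically", {
  G <- make_small_G(24, 120, seed = 15)
  d <- make_blue_fixture(G, n_env = 2, seed = 16)
  fit <- gblup(d, G, env = "env")
  set.seed(17)
  perm <- sample(nrow(d))
  fit2 <- gblup(d[perm, ], G, env = "env")
  expect_equal(fit2$gebv[names(fit$gebv)], fit$gebv, tolerance = 1e-6)
})

test_that("REML recovers the generating reaction-norm variance components", {
  ## 400 lines x 4 environments, s2_g = 1, s2_gE = 0.5, s2_e = 1
  cfg <- tiny_config(n_populations = 8, lines_per_population = 50,
                     n_founders = 10, n_markers = 800, seed = 30)
  G <- build_grm(filter_markers(
    derive_dh_lines(simulate_founders(cfg), cfg)$markers, 0.05, quiet = TRUE))
  est <- sapply(1:10, function(s) {
    d <- make_blue_fixture(G, n_env = 4, s2_E = 1, s2_g = 1, s2_gE = 0.5,
                           s2_e = 1, seed = 40 + s)
    gblup(d, G, env = "env")$vc[c("sigma2_g", "sigma2_gE", "sigma2_e")]
  })
  means <- rowMeans(est)
  expect_lt(abs(means["sigma2_g"] - 1), 0.25)
  expect_lt(abs(means["sigma2_gE"] - 0.5), 0.25 * 0.5)
  expect_lt(abs(means["sigma2_e"] - 1), 0.25)
})

test_that("Gibbs posterior means agree with REML GEBVs", {
  G <- make_small_G(40, 200, seed = 18)
  d <- make_blue_fixture(G, n_env = 2, s2_E = 0.5, s2_g = 1, s2_gE = 0.3,
                         s2_e = 0.8, seed = 19)
  reml <- gblup(d, G, env = "env")
  gibbs <- gblup(d, G, env = "env", method = "gibbs",
                 n_iter = 6000, burnin = 1000, thin = 5, seed = 77)
  expect_gt(stats::cor(reml$gebv, gibbs$gebv), 0.98)
  ## sampler is seeded and reproducible
  gibbs2 <- gblup(d, G, env = "env", method = "gibbs",
                  n_iter = 2000, burnin = 500, seed = 99)
  gibbs3 <- gblup(d, G, env = "env", method = "gibbs",
                  n_iter = 2000, burnin = 500, seed = 99)
  expect_identical(gibbs2$gebv, gibbs3$gebv)
})

test_that("single-environment input drops the E and interaction terms", {
  G <- make_small_G(20, 100, seed = 20)
  d <- make_blue_fixture(G, n_env = 1, s2_E = 0, s2_gE = 0, seed = 21)
  d$env <- "only_one"
  expect_message(fit <- gblup(d, G, env = "env", verbose = TRUE),
                 "single environment")
  expect_named(fit$vc, c("sigma2_g", "sigma2_e"))
})
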