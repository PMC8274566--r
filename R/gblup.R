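#' Reaction-norm GBLUP for line x environment adjusted means
#'
#' Fits the genomic best linear unbiased prediction model on stage-1 BLUEs:
#' an intercept, a random environment main effect, a random genomic line
#' effect with covariance `sigma2_g * G`, a genotype-by-environment
#' interaction whose covariance is the Hadamard product of the genomic and
#' environment-incidence kernels (`sigma2_gE * (Zg G Zg') # (Ze Ze')`), and an
#' independent residual. With a single environment (or `env = NULL`) the
#' environment and interaction terms are dropped automatically and the model
#' reduces to plain GBLUP. Variance components are estimated by REML
#' (average-information updates with a monotone fallback) or by a Gibbs
#' sampler with scaled-inverse-chi-squared priors; genomic estimated breeding
#' values (GEBVs) are returned for every line in `G`, including lines without
#' phenotypes, via the genomic covariance.
#'
#' @param data data.frame with one row per line x environment mean.
#' @param G genomic relationship matrix from [build_grm()] covering all lines
#'   that need predictions (phenotyped or not).
#' @param response,line,env names of the response, line-id and environment
#'   columns. `env = NULL` fits plain GBLUP.
#' @param method `"reml"` (default, deterministic) or `"gibbs"`.
#' @param include_interaction drop the Hadamard interaction term when `FALSE`.
#' @param init optional initial variance components (REML), in the order
#'   environment, genomic, interaction, residual (present terms only).
#' @param tol,max_iter REML convergence tolerance (relative log-likelihood
#'   change) and iteration cap.
#' @param n_iter,burnin,thin,df_prior Gibbs sampler settings.
#' @param seed seed for the Gibbs sampler.
#' @param verbose print iteration progress.
#' @return object of class `gblup`: variance components `vc`, intercept
#'   `beta`, `gebv` (named, all lines of `G`), record-level `fitted` and
#'   `residuals`, the REML log-likelihood trace or posterior summaries, and
#'   bookkeeping (`n`, `lines`, `envs`, `converged`, `iterations`).
#' @seealso [predict.gblup()], [run_scenario()]
#' @export
gblup <- function(data, G, response = "blue", line = "line_id", env = "env",
                  method = c("reml", "gibbs"), include_interaction = TRUE,
                  init = NULL, tol = 1e-6, max_iter = 200,
                  n_iter = 12000, burnin = 2000, thin = 5, df_prior = 5,
                  seed = 1L, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), inherits(G, "grm") || is.matrix(G))
  y <- data[[response]]
  if (is.null(y)) stopf("gblup: no column '%s' in data", response)
  keep <- is.finite(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 3L) stopf("gblup: need >= 3 records")
  if (stats::var(y) == 0) {
    ## no-signal degenerate case: all effects zero, variances at the floor
    gebv <- stats::setNames(rep(0, nrow(G)), rownames(G))
    return(structure(list(method = method, vc = c(sigma2_g = 0, sigma2_e = 0),
                          beta = y[1], gebv = gebv, fitted = rep(y[1], n),
                          residuals = rep(0, n), logLik = NA_real_,
                          ll_trace = NA_real_, iterations = 0L,
                          converged = TRUE, n = n, lines = rownames(G),
                          envs = NULL, degenerate = TRUE),
                     class = "gblup"))
  }

  line_ids <- as.character(data[[line]])
  miss <- setdiff(unique(line_ids), rownames(G))
  if (length(miss))
    stopf("gblup: %d lines absent from G (first: %s)", length(miss), miss[1])
  Gs <- stabilize_grm(G)
  idx <- match(line_ids, rownames(Gs))

  envf <- NULL
  if (!is.null(env) && env %in% names(data)) {
    envf <- droplevels(factor(data[[env]]))
    if (nlevels(envf) < 2L) {
      if (verbose)
        gs_log("INFO", "gblup: single environment; dropping E and gxE terms (plain GBLUP)")
      envf <- NULL
    }
  }

  K_g <- Gs[idx, idx]
  kernels <- list(); kn <- character(0)
  if (!is.null(envf)) {
    Ze <- stats::model.matrix(~ 0 + envf)
    K_E <- tcrossprod(Ze)
    kernels <- c(kernels, list(K_E)); kn <- c(kn, "sigma2_E")
  }
  kernels <- c(kernels, list(K_g)); kn <- c(kn, "sigma2_g")
  if (!is.null(envf) && include_interaction) {
    kernels <- c(kernels, list(K_g * K_E)); kn <- c(kn, "sigma2_gE")
  }
  X <- matrix(1, n, 1)

  if (method == "reml") {
    fit <- reml_fit(y, X, kernels, init = init, tol = tol,
                    max_iter = max_iter, verbose = verbose)
    theta <- stats::setNames(fit$theta, c(kn, "sigma2_e"))
    Py <- fit$Py
    zpy <- rowsum_by_line(Py, line_ids, rownames(Gs))
    gebv <- as.numeric(theta["sigma2_g"] * (Gs %*% zpy))
    names(gebv) <- rownames(Gs)
    blups <- lapply(seq_along(kernels), function(k)
      as.numeric(fit$theta[k] * (kernels[[k]] %*% Py)))
    names(blups) <- kn
    fitted <- fit$beta[1] + Reduce(`+`, blups, accumulate = FALSE)
    out <- list(method = method, vc = theta, beta = fit$beta[1], gebv = gebv,
                blups = blups, fitted = as.numeric(fitted),
                residuals = as.numeric(y - fitted), logLik = fit$logLik,
                ll_trace = fit$ll_trace, iterations = fit$iterations,
                converged = fit$converged, n = n, lines = rownames(Gs),
                envs = if (is.null(envf)) NULL else levels(envf),
                line_ids = line_ids, y = y)
  } else {
    out <- gibbs_gblup(y, kernels, kn, line_ids, Gs, n_iter = n_iter,
                       burnin = burnin, thin = thin, df_prior = df_prior,
                       seed = seed, verbose = verbose)
    out$n <- n
    out$envs <- if (is.null(envf)) NULL else levels(envf)
    out$line_ids <- line_ids
    out$y <- y
  }
  structure(out, class = "gblup")
}

## sum a record-level vector into a vector over all G lines (zeros elsewhere)
rowsum_by_line <- function(v, line_ids, all_lines) {
  s <- rowsum(v, group = line_ids)
  out <- stats::setNames(numeric(length(all_lines)), all_lines)
  out[rownames(s)] <- s[, 1]
  out
}

## Gibbs sampler over the kernel representation. Each random term is
## reparameterized through the eigendecomposition of its kernel,
## u_k = Q_k a_k with a_k ~ N(0, s2_k Lambda_k); because Q_k is orthonormal
## the full conditional of a_k is diagonal. Scaled-inverse-chi-squared priors
## with df_prior and scale set from the phenotypic variance.
gibbs_gblup <- function(y, kernels, kn, line_ids, Gs, n_iter, burnin, thin,
                        df_prior, seed, verbose = FALSE) {
  with_seed(seed, {
    n <- length(y)
    m <- length(kernels)
    eigs <- lapply(kernels, function(K) {
      e <- eigen(K, symmetric = TRUE)
      keep <- e$values > 1e-8 * max(e$values)
      list(Q = e$vectors[, keep, drop = FALSE], lam = e$values[keep])
    })
    vy <- stats::var(y)
    S0 <- vy / (m + 1)
    mu <- mean(y)
    alpha <- lapply(eigs, function(e) numeric(length(e$lam)))
    u <- lapply(eigs, function(e) numeric(n))
    s2 <- rep(vy / (m + 1), m)
    s2e <- vy / (m + 1)
    resid <- y - mu

    g_row <- match(unique(line_ids), line_ids)       # one record per obs line
    obs_lines <- line_ids[g_row]
    kg <- match("sigma2_g", kn)
    sum_s2 <- numeric(m); sum_s2e <- 0; sum_mu <- 0
    sum_gobs <- numeric(length(obs_lines))
    sum_fit <- numeric(n)
    kept <- 0L

    for (it in seq_len(n_iter)) {
      for (k in seq_len(m)) {
        rk <- resid + u[[k]]
        rhs <- crossprod(eigs[[k]]$Q, rk)[, 1] / s2e
        prec <- 1 / s2e + 1 / (s2[k] * eigs[[k]]$lam)
        a <- rhs / prec + stats::rnorm(length(prec)) / sqrt(prec)
        alpha[[k]] <- a
        u[[k]] <- as.numeric(eigs[[k]]$Q %*% a)
        resid <- rk - u[[k]]
        ss <- sum(a^2 / eigs[[k]]$lam)
        s2[k] <- (ss + df_prior * S0) /
          stats::rchisq(1, df_prior + length(a))
        if (!is.finite(s2[k]) || s2[k] <= 0)
          stopf("gblup: Gibbs sampler diverged (non-finite variance)")
      }
      rmu <- resid + mu
      mu <- stats::rnorm(1, mean(rmu), sqrt(s2e / n))
      resid <- rmu - mu
      s2e <- (sum(resid^2) + df_prior * S0) /
        stats::rchisq(1, df_prior + n)
      if (it > burnin && ((it - burnin - 1L) %% thin == 0L)) {
        kept <- kept + 1L
        sum_s2 <- sum_s2 + s2; sum_s2e <- sum_s2e + s2e; sum_mu <- sum_mu + mu
        sum_gobs <- sum_gobs + u[[kg]][g_row]
        sum_fit <- sum_fit + mu + Reduce(`+`, u)
      }
    }
    vc <- stats::setNames(c(sum_s2 / kept, sum_s2e / kept),
                          c(kn, "sigma2_e"))
    g_obs <- stats::setNames(sum_gobs / kept, obs_lines)
    ## propagate posterior-mean line effects to unphenotyped lines through G
    gebv <- stats::setNames(numeric(nrow(Gs)), rownames(Gs))
    gebv[obs_lines] <- g_obs
    un <- setdiff(rownames(Gs), obs_lines)
    if (length(un))
      gebv[un] <- as.numeric(Gs[un, obs_lines, drop = FALSE] %*%
                               solve(Gs[obs_lines, obs_lines], g_obs))
    fitted <- sum_fit / kept      # posterior-mean fitted values
    list(method = "gibbs", vc = vc, beta = sum_mu / kept, gebv = gebv,
         fitted = as.numeric(fitted), residuals = as.numeric(y - fitted),
         logLik = NA_real_, ll_trace = NULL,
         iterations = n_iter, converged = TRUE, n_kept = kept,
         lines = rownames(Gs))
  })
}

#' Extract GEBVs for requested lines
#'
#' @param object a fitted [gblup()] model.
#' @param line_ids character vector of line ids (default: all lines in `G`).
#' @param ... unused.
#' @return named numeric vector of GEBVs.
#' @export
predict.gblup <- function(object, line_ids = NULL, ...) {
  if (is.null(line_ids)) return(object$gebv)
  miss <- setdiff(line_ids, names(object$gebv))
  if (length(miss))
    stopf("predict.gblup: unknown line id(s): %s",
          paste(utils::head(miss, 3), collapse = ", "))
  object$gebv[line_ids]
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("Reaction-norm GBLUP (%s): %d records, %d lines%s\n",
              toupper(x$method), x$n, length(x$gebv),
              if (is.null(x$envs)) ", single environment"
              else sprintf(", %d environments", length(x$envs))))
  cat("  variance components:\n")
  print(round(x$vc, 5))
  if (x$method == "reml")
    cat(sprintf("  logLik %.4f after %d iterations (%s)\n", x$logLik,
                x$iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  vc <- object$vc
  out <- list(vc = vc, prop = vc / sum(vc), beta = object$beta,
              n = object$n, method = object$method,
              gebv_summary = summary(object$gebv),
              converged = object$converged)
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("Variance components and shares of the phenotypic variance:\n")
  print(round(rbind(estimate = x$vc, share = x$prop), 4))
  cat(sprintf("Intercept %.4f; GEBV range [%.3f, %.3f]\n", x$beta,
              min(x$gebv_summary), max(x$gebv_summary)))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) c(intercept = unname(object$beta))

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$logLik, df = length(object$vc) + 1, class = "logLik")
}

#' @export
plot.gblup <- function(x, ...) {
  graphics::plot(x$fitted, x$y %||% (x$fitted + x$residuals),
                 xlab = "fitted", ylab = "observed adjusted mean",
                 main = "Reaction-norm GBLUP fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
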