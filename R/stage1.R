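#' Stage-1 phenotypic analysis of one trial-network slice
#'
#' Fits the per-slice linear mixed model for one trait on the plot records of
#' a single year x management slice (or a pooled multi-year slice): genotype,
#' trial and replicate-within-trial as fixed effects, incomplete block within
#' replicate as random, giving best linear unbiased estimates (BLUEs) of the
#' genotype means by generalized least squares at the REML variance
#' estimates. A companion fit with genotype (and genotype x trial) random
#' supplies the variance components used for heritability reporting, the
#' convention of standard multi-environment-trial software. Both fits use
#' REML via \pkg{lme4}; sum-to-zero contrasts on the design factors make each
#' genotype coefficient its mean at the average trial and replicate.
#'
#' @param data plot-level data.frame with columns `year`, `management`,
#'   `trial`, `rep`, `block`, `line_id` and the trait columns.
#' @param trait name of the trait column to analyse.
#' @param year year label(s) selecting the slice; `NULL` keeps all years
#'   (pooled analysis).
#' @param management `"WW"` or `"WS"`; `NULL` keeps both.
#' @return object of class `stage1_fit` with components `blues` (data.frame
#'   `line_id`, `blue`, `se`), `varcomp` (class `varcomp`: sigma2_g,
#'   sigma2_trial, sigma2_gxt, sigma2_block, sigma2_e, n_trials, n_reps),
#'   `trait`, `scope`, `mean`, `n_obs`.
#' @seealso [heritability()], [summarize_slice()]
#' @export
fit_stage1 <- function(data, trait = "GY", year = NULL, management = NULL) {
  stopifnot(is.data.frame(data), trait %in% names(data))
  d <- data
  if (!is.null(year)) d <- d[d$year %in% year, , drop = FALSE]
  if (!is.null(management)) d <- d[d$management %in% management, , drop = FALSE]
  d <- d[is.finite(d[[trait]]), , drop = FALSE]
  if (nrow(d) < 2L || length(unique(d$line_id)) < 2L)
    stopf("fit_stage1: need >= 2 lines with non-missing '%s' in the slice", trait)

  d$y <- d[[trait]]
  d$line <- factor(d$line_id)
  d$trialf <- factor(d$trial)
  d$trf <- factor(paste(d$trial, d$rep, sep = ":"))     # replicate within trial
  d$blockf <- factor(paste(d$trial, d$rep, d$block, sep = ":"))
  n_trials <- nlevels(d$trialf)
  n_reps <- max(tapply(d$rep, d$trialf, function(x) length(unique(x))))

  use_trf <- nlevels(d$trf) > 1L
  use_block <- nlevels(d$blockf) > nlevels(d$trf)   # blocks finer than reps
  ctr <- if (use_trf) list(trf = "contr.sum") else NULL

  ## ---- fit A: genotype fixed -> BLUEs --------------------------------
  fx <- paste(c("0 + line", if (use_trf) "trf"), collapse = " + ")
  blues_fit <- if (use_block) {
    lme4::lmer(stats::as.formula(paste("y ~", fx, "+ (1 | blockf)")),
               data = d, contrasts = ctr,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  } else {
    stats::lm(stats::as.formula(paste("y ~", fx)), data = d, contrasts = ctr)
  }
  cf <- if (inherits(blues_fit, "merMod")) lme4::fixef(blues_fit)
        else stats::coef(blues_fit)
  ## REML variances of the BLUE model (block + residual), kept so the GLS
  ## solution is reproducible from the returned object alone
  blues_vc <- if (inherits(blues_fit, "merMod")) {
    vv <- as.data.frame(lme4::VarCorr(blues_fit))
    i <- match("blockf", vv$grp)
    c(sigma2_block = if (is.na(i)) 0 else vv$vcov[i],
      sigma2_e = vv$vcov[vv$grp == "Residual"])
  } else c(sigma2_block = 0, sigma2_e = summary(blues_fit)$sigma^2)
  vc_mat <- as.matrix(stats::vcov(blues_fit))
  is_line <- grepl("^line", names(cf))
  ids <- sub("^line", "", names(cf)[is_line])
  blues <- data.frame(line_id = ids,
                      blue = unname(cf[is_line]),
                      se = sqrt(diag(vc_mat)[which(is_line)]),
                      stringsAsFactors = FALSE)
  dropped <- setdiff(levels(d$line), c(ids, NA))
  if (length(dropped) || anyNA(blues$blue)) {
    gs_log("WARN", sprintf("fit_stage1: %d aliased genotype levels dropped",
                           length(dropped) + sum(is.na(blues$blue))))
    blues <- blues[is.finite(blues$blue), , drop = FALSE]
  }

  ## ---- fit B: genotype (and genotype x trial) random -> components ----
  rterms <- c("(1 | line)",
              if (n_trials > 1L) c("(1 | trialf)", "(1 | line:trialf)"),
              if (use_trf) "(1 | trf)",
              if (use_block) "(1 | blockf)")
  vfit <- lme4::lmer(stats::as.formula(paste("y ~ 1 +",
                                             paste(rterms, collapse = " + "))),
                     data = d,
                     control = lme4::lmerControl(check.conv.singular = "ignore",
                                                 calc.derivs = FALSE))
  vcs <- as.data.frame(lme4::VarCorr(vfit))
  getv <- function(g) {
    i <- match(g, vcs$grp)
    if (is.na(i)) 0 else vcs$vcov[i]
  }
  varcomp <- structure(list(
    sigma2_g = getv("line"),
    sigma2_trial = getv("trialf"),
    sigma2_gxt = getv("line:trialf"),
    sigma2_block = getv("blockf"),
    sigma2_e = vcs$vcov[vcs$grp == "Residual"],
    n_trials = n_trials, n_reps = n_reps,
    trait = trait,
    scope = list(year = year, management = management)),
    class = "varcomp")

  structure(list(blues = blues, varcomp = varcomp, blues_vc = blues_vc,
                 trait = trait,
                 scope = list(year = year, management = management),
                 mean = mean(d$y), n_obs = nrow(d),
                 n_lines = length(unique(d$line_id))),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  sc <- x$scope
  cat(sprintf("Stage-1 analysis: %s | year %s | management %s\n", x$trait,
              if (is.null(sc$year)) "all" else paste(sc$year, collapse = "+"),
              sc$management %||% "all"))
  cat(sprintf("  %d plots, %d lines, %d trial(s), %d rep(s); grand mean %.3f\n",
              x$n_obs, x$n_lines, x$varcomp$n_trials, x$varcomp$n_reps, x$mean))
  print(x$varcomp)
  invisible(x)
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "  sigma2_g %.4g | sigma2_trial %.4g | sigma2_gxt %.4g | sigma2_block %.4g | sigma2_e %.4g\n",
    x$sigma2_g, x$sigma2_trial, x$sigma2_gxt, x$sigma2_block, x$sigma2_e))
  cat(sprintf("  entry-mean H2 = %.3f  (l = %d, r = %d)\n",
              heritability(x), x$n_trials, x$n_reps))
  invisible(x)
}

#' @export
coef.stage1_fit <- function(object, ...) {
  stats::setNames(object$blues$blue, object$blues$line_id)
}

#' Entry-mean broad-sense heritability
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_gxt / l + sigma2_e / (l * r))`, the
#' proportion of variance among genotype means attributable to genotypes when
#' each genotype is evaluated in `l` trials with `r` replicates each.
#'
#' @param x either a `varcomp` object from [fit_stage1()] or the genotypic
#'   variance `sigma2_g`.
#' @param sigma2_e residual (plot error) variance.
#' @param sigma2_gxt genotype x trial interaction variance (default 0).
#' @param n_trials number of trials/locations `l` (>= 1).
#' @param n_reps number of replicates `r` (>= 1).
#' @param ... unused.
#' @return heritability in \[0, 1\].
#' @export
#' @examples
#' heritability(0.36, sigma2_e = 1.91, sigma2_gxt = 0.21,
#'              n_trials = 34, n_reps = 2)   # 0.91
#' heritability(0.25, sigma2_e = 0.50, n_trials = 1, n_reps = 2)  # 0.50
heritability <- function(x, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.varcomp <- function(x, ...) {
  heritability(x$sigma2_g, sigma2_e = x$sigma2_e, sigma2_gxt = x$sigma2_gxt,
               n_trials = x$n_trials, n_reps = x$n_reps)
}

#' @rdname heritability
#' @export
heritability.default <- function(x, sigma2_e, sigma2_gxt = 0, n_trials = 1,
                                 n_reps = 1, ...) {
  sigma2_g <- x
  if (any(c(sigma2_g, sigma2_e, sigma2_gxt) < 0))
    stopf("heritability: variance components must be >= 0")
  if (n_trials < 1 || n_reps < 1)
    stopf("heritability: n_trials and n_reps must be >= 1")
  denom <- sigma2_g + sigma2_gxt / n_trials + sigma2_e / (n_trials * n_reps)
  if (denom <= 0)
    stopf("heritability: all variance components are zero (undefined)")
  sigma2_g / denom
}

#' Percent reduction of a trait mean under drought stress
#'
#' `100 * (mean_ww - mean_ws) / mean_ww`, reported to one decimal place, the
#' conventional summary of managed-stress severity relative to the
#' well-watered check.
#'
#' @param mean_ww trait mean under well-watered management (> 0).
#' @param mean_ws trait mean under water stress.
#' @return percent reduction, rounded to 1 decimal.
#' @export
#' @examples
#' stress_reduction(6.05, 3.28)   # 45.8
stress_reduction <- function(mean_ww, mean_ws) {
  if (any(mean_ww <= 0))
    stopf("stress_reduction: mean_ww must be positive")
  round(100 * (mean_ww - mean_ws) / mean_ww, 1)
}

#' One-row trial-network summary of a fitted slice
#'
#' Mean, coefficient of variation, least significant difference and
#' entry-mean heritability for one trait x management x slice, in the layout
#' of a classical multi-environment-trial report. CV is computed as
#' `100 * sqrt(sigma2_e) / mean` and LSD as the two-sided 5% t-quantile times
#' the standard error of a difference between entry means,
#' `sqrt(2 * sigma2_e / (l * r))`; both are reporting conventions.
#'
#' @param fit a `stage1_fit`.
#' @param alpha significance level for the LSD (default 0.05).
#' @return one-row data.frame: trait, year, management, n_lines, mean,
#'   cv_pct, lsd, h2 and the variance components.
#' @export
summarize_slice <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "stage1_fit"))
  vc <- fit$varcomp
  df_res <- max(fit$n_obs - fit$n_lines - vc$n_trials * vc$n_reps, 1)
  sed <- sqrt(2 * vc$sigma2_e / (vc$n_trials * vc$n_reps))
  data.frame(
    trait = fit$trait,
    year = if (is.null(fit$scope$year)) "all"
           else paste(fit$scope$year, collapse = "+"),
    management = fit$scope$management %||% "all",
    n_lines = fit$n_lines,
    mean = fit$mean,
    cv_pct = 100 * sqrt(vc$sigma2_e) / fit$mean,
    lsd = stats::qt(1 - alpha / 2, df_res) * sed,
    h2 = heritability(vc),
    sigma2_g = vc$sigma2_g, sigma2_trial = vc$sigma2_trial,
    sigma2_gxt = vc$sigma2_gxt, sigma2_e = vc$sigma2_e,
    stringsAsFactors = FALSE)
}

#' BLUE table for all year x management slices
#'
#' Runs [fit_stage1()] on every combination of year, management and trait
#' present in the data and stacks the adjusted means into the long-format
#' table consumed by [gblup()] and the cross-validation engine.
#'
#' @param data plot-level phenotype data.frame.
#' @param traits trait columns to analyse (default GY, AD, PH intersected
#'   with the data).
#' @param quiet suppress per-slice progress messages.
#' @return list with `blues` (data.frame: line_id, year, management, trait,
#'   blue, se) and `varcomps` (list of `varcomp` objects keyed by
#'   `year.management.trait`).
#' @export
stage1_blues <- function(data, traits = intersect(c("GY", "AD", "PH"),
                                                  names(data)),
                         quiet = TRUE) {
  out <- list(); vcs <- list()
  for (yr in unique(data$year)) for (mg in unique(data$management)) {
    sl <- data[data$year == yr & data$management == mg, , drop = FALSE]
    if (!nrow(sl)) next
    for (tr in traits) {
      if (!quiet)
        gs_log("INFO", sprintf("stage 1: %s %s %s", yr, mg, tr))
      f <- fit_stage1(sl, trait = tr)
      b <- f$blues
      b$year <- yr; b$management <- mg; b$trait <- tr
      out[[length(out) + 1L]] <- b[, c("line_id", "year", "management",
                                       "trait", "blue", "se")]
      vcs[[paste(yr, mg, tr, sep = ".")]] <- f$varcomp
    }
  }
  list(blues = do.call(rbind, out), varcomps = vcs)
}
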