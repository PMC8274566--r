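#' Simulate multi-environment testcross phenotypes with known ground truth
#'
#' Generates plot-level trial records for grain yield (GY, t/ha), anthesis
#' date (AD, days) and plant height (PH, cm) over the configured years and the
#' two managements (WW = well-watered, WS = managed water stress). The
#' generative model is additive: each trait has `n_qtl` causal markers whose
#' effects are correlated across environments (compound-symmetric correlation
#' `gxe_corr`), giving each line an environment-specific testcross genetic
#' value; year, trial, incomplete-block and residual effects are layered on
#' top. Within a year each line is evaluated in one trial (checks in all
#' trials), with `replicates` complete replicates randomized anew into
#' incomplete blocks. Residual variance per management is back-solved so that
#' the entry-mean heritability of a single-trial slice hits the configured
#' target. Under WS the GY and PH means are reduced by the configured
#' fractions and AD shifted by `drought_ad_shift` days.
#'
#' @param lines lines x markers 0/1 matrix (rownames = line ids).
#' @param cfg a [sim_config()].
#' @param pedigree optional pedigree data.frame (used to stratify the
#'   year allocation by population); when `NULL` all lines form one stratum.
#' @param seed integer seed for this step (default derived from `cfg$seed`).
#' @return list with `phenotypes` (plot-level data.frame: year, management,
#'   trial, rep, block, line_id, GY, AD, PH), `evaluations` (line x year
#'   assignment), and `truth` (QTL indices and effects per trait, true
#'   genetic values per line x environment x trait, the generating variance
#'   parts and the realized entry-mean heritability per slice).
#' @export
simulate_phenotypes <- function(lines, cfg, pedigree = NULL,
                                seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "sim_config"), is.matrix(lines))
  if (nrow(lines) < 1L) stopf("simulate_phenotypes: no lines")
  traits <- c("GY", "AD", "PH")
  line_ids <- rownames(lines)
  if (is.null(line_ids)) line_ids <- sprintf("L%05d", seq_len(nrow(lines)))
  n <- nrow(lines)
  years <- cfg$years
  mgmts <- c("WW", "WS")
  pops <- if (!is.null(pedigree)) {
    pedigree$population[match(line_ids, pedigree$line_id)]
  } else rep("P01", n)

  with_seed(seed, {
    ## --- causal architecture -------------------------------------------
    qtl <- list()
    qtl$GY <- sort(sample.int(ncol(lines), min(cfg$n_qtl, ncol(lines))))
    pick_overlapping <- function(base) {
      k <- length(base)
      n_sh <- round(cfg$qtl_overlap * k)
      shared <- sample(base, n_sh)
      pool <- setdiff(seq_len(ncol(lines)), base)
      sort(c(shared, sample(pool, min(k - n_sh, length(pool)))))
    }
    qtl$AD <- pick_overlapping(qtl$GY)
    qtl$PH <- pick_overlapping(qtl$GY)

    envs <- expand.grid(year = years, management = mgmts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rho <- cfg$gxe_corr
    gval <- list()     # [[trait]] n x n_env matrix of true genetic values
    effects <- list()  # per-trait per-env QTL effect vectors
    for (tr in traits) {
      W <- lines[, qtl[[tr]], drop = FALSE]
      k <- ncol(W)
      b0 <- stats::rnorm(k)
      gm <- matrix(0, n, nrow(envs))
      eff <- matrix(0, k, nrow(envs))
      for (e in seq_len(nrow(envs))) {
        be <- sqrt(rho) * b0 + sqrt(1 - rho) * stats::rnorm(k)
        g <- as.numeric(W %*% be)
        s <- stats::sd(g)
        tgt <- if (envs$management[e] == "WW") cfg$genetic_var_ww[tr]
               else cfg$genetic_var_ws[tr]
        sc <- if (s > 0) sqrt(tgt) / s else 0
        gm[, e] <- (g - mean(g)) * sc
        eff[, e] <- be * sc
      }
      rownames(gm) <- line_ids
      gval[[tr]] <- gm
      effects[[tr]] <- eff
    }

    ## --- management means and residual scales --------------------------
    mu <- rbind(
      WW = cfg$ww_trait_means,
      WS = c(GY = unname(cfg$ww_trait_means["GY"]) * (1 - cfg$drought_gy_reduction),
             AD = unname(cfg$ww_trait_means["AD"]) + cfg$drought_ad_shift,
             PH = unname(cfg$ww_trait_means["PH"]) * (1 - cfg$drought_ph_reduction)))
    r <- cfg$replicates
    res_var <- rbind(
      WW = r * cfg$genetic_var_ww * (1 - cfg$target_h2_ww) /
        pmax(cfg$target_h2_ww, 1e-12),
      WS = r * cfg$genetic_var_ws * (1 - cfg$target_h2_ws) /
        pmax(cfg$target_h2_ws, 1e-12))

    ## --- cohort allocation ---------------------------------------------
    n_checks <- min(cfg$n_checks, n)
    check_ids <- if (n_checks > 0) sample(line_ids, n_checks) else character(0)
    test_ids <- setdiff(line_ids, check_ids)
    wts <- cfg$year_weights / sum(cfg$year_weights)
    first_year <- stats::setNames(rep(years[1L], length(test_ids)), test_ids)
    for (p in unique(pops)) {
      ids <- intersect(test_ids, line_ids[pops == p])
      if (length(ids))
        first_year[ids] <- sample(years, length(ids), replace = TRUE, prob = wts)
    }
    eval_list <- data.frame(line_id = names(first_year),
                            year = unname(first_year),
                            stringsAsFactors = FALSE)
    if (cfg$overlap_fraction > 0 && length(years) > 1L) {
      idx <- match(eval_list$year, years)
      carry <- idx < length(years) &
        stats::runif(nrow(eval_list)) < cfg$overlap_fraction
      if (any(carry))
        eval_list <- rbind(eval_list,
                           data.frame(line_id = eval_list$line_id[carry],
                                      year = years[idx[carry] + 1L]))
    }

    year_eff <- matrix(stats::rnorm(length(years) * 3,
                                    sd = rep(cfg$year_effect_sd, each = length(years))),
                       nrow = length(years),
                       dimnames = list(as.character(years), traits))

    ## --- plot records ----------------------------------------------------
    recs <- list()
    for (yi in seq_along(years)) {
      yr <- years[yi]
      yr_lines <- eval_list$line_id[eval_list$year == yr]
      for (mg in mgmts) {
        n_tr <- if (mg == "WW") cfg$trials_per_year_ww[yi]
                else cfg$trials_per_year_ws[yi]
        n_tr <- max(1L, min(n_tr, max(1L, length(yr_lines))))
        alloc <- if (length(yr_lines))
          split(sample(yr_lines), rep_len(seq_len(n_tr),
                                          length(yr_lines)))
        else rep(list(character(0)), n_tr)
        env_row <- which(envs$year == yr & envs$management == mg)
        trial_eff <- matrix(stats::rnorm(n_tr * 3,
                                         sd = rep(cfg$trial_effect_sd, each = n_tr)),
                            nrow = n_tr, dimnames = list(NULL, traits))
        for (t in seq_len(n_tr)) {
          entries <- c(alloc[[t]], check_ids)
          if (!length(entries)) next
          trial_id <- sprintf("%s_%s_T%02d", yr, mg, t)
          for (rep_i in seq_len(r)) {
            ord <- sample(entries)
            blk <- ceiling(seq_along(ord) / cfg$block_size)
            n_blk <- max(blk)
            blk_eff <- matrix(stats::rnorm(n_blk * 3,
                                           sd = rep(cfg$block_effect_sd, each = n_blk)),
                              nrow = n_blk, dimnames = list(NULL, traits))
            vals <- sapply(traits, function(tr) {
              g <- gval[[tr]][ord, env_row]
              mu[mg, tr] + year_eff[as.character(yr), tr] +
                trial_eff[t, tr] + blk_eff[blk, tr] + g +
                stats::rnorm(length(ord), sd = sqrt(res_var[mg, tr]))
            })
            if (!is.matrix(vals))
              vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, traits))
            recs[[length(recs) + 1L]] <- data.frame(
              year = yr, management = mg, trial = trial_id, rep = rep_i,
              block = blk, line_id = ord,
              GY = vals[, "GY"], AD = vals[, "AD"], PH = vals[, "PH"],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    pheno <- do.call(rbind, recs)
    rownames(pheno) <- NULL

    ## --- realized heritability per slice --------------------------------
    h2 <- list()
    for (e in seq_len(nrow(envs))) {
      yr <- envs$year[e]; mg <- envs$management[e]
      ids <- unique(pheno$line_id[pheno$year == yr & pheno$management == mg])
      for (tr in traits) {
        vg <- if (length(ids) > 1) stats::var(gval[[tr]][ids, e]) else 0
        denom <- vg + res_var[mg, tr] / r
        h2[[length(h2) + 1L]] <- data.frame(
          year = yr, management = mg, trait = tr,
          var_g = vg, var_e = unname(res_var[mg, tr]),
          realized_h2 = if (denom > 0) vg / denom else 1)
      }
    }

    truth <- list(
      qtl_indices = qtl,
      qtl_effects = effects,
      genetic_values = gval,
      environments = envs,
      management_means = mu,
      residual_var = res_var,
      realized_h2 = do.call(rbind, h2),
      check_ids = check_ids)
    list(phenotypes = pheno, evaluations = eval_list, truth = truth)
  })
}

#' Simulate a complete early-stage breeding program
#'
#' Convenience wrapper running [simulate_founders()], [derive_dh_lines()] and
#' [simulate_phenotypes()] under seeds derived from `cfg$seed`, so the whole
#' program is reproducible bit for bit from the configuration alone.
#'
#' @param cfg a [sim_config()].
#' @return object of class `gs_sim`: list with `config`, `founders`,
#'   `markers`, `pedigree` (with an `is_check` flag), `phenotypes`,
#'   `evaluations` and `truth`.
#' @export
#' @examples
#' sim <- simulate_breeding_program(sim_config(
#'   n_populations = 3, lines_per_population = 20, n_founders = 6,
#'   n_markers = 200, trials_per_year_ww = 1, seed = 42))
#' sim
simulate_breeding_program <- function(cfg = sim_config()) {
  founders <- simulate_founders(cfg)
  dh <- derive_dh_lines(founders, cfg)
  ph <- simulate_phenotypes(dh$markers, cfg, pedigree = dh$pedigree)
  ped <- dh$pedigree
  ped$is_check <- ped$line_id %in% ph$truth$check_ids
  structure(list(config = cfg, founders = founders, markers = dh$markers,
                 pedigree = ped, phenotypes = ph$phenotypes,
                 evaluations = ph$evaluations, truth = ph$truth),
            class = "gs_sim")
}

#' @export
print.gs_sim <- function(x, ...) {
  cat("Synthetic early-stage breeding program\n")
  cat(sprintf("  %d DH lines (%d populations), %d markers\n",
              nrow(x$markers), length(unique(x$pedigree$population)),
              ncol(x$markers)))
  cat(sprintf("  %d plot records over years %s (WW/WS), %d checks\n",
              nrow(x$phenotypes),
              paste(unique(x$phenotypes$year), collapse = ", "),
              sum(x$pedigree$is_check)))
  invisible(x)
}
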