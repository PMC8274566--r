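#' Describe a forward-prediction scenario
#'
#' A scenario names the training years, the testing year, the conversion
#' fraction `f` (the share of testing-year lines whose phenotypes are moved
#' into the training set before predicting the rest), the trait and
#' management analysed, and the replication count of the random partitioning.
#'
#' @param trn_years year labels used as training data.
#' @param tst_year the year being predicted (must not be a training year).
#' @param f conversion fraction in \[0, 1).
#' @param n_replications number of random partitions (default 20).
#' @param management `"WW"` or `"WS"`.
#' @param trait trait name.
#' @param seed scenario seed.
#' @return object of class `cv_scenario`.
#' @export
cv_scenario <- function(trn_years, tst_year, f = 0, n_replications = 20,
                        management = "WW", trait = "GY", seed = 1L) {
  if (tst_year %in% trn_years)
    stopf("cv_scenario: tst_year must not be among trn_years")
  if (!is.finite(f) || f < 0 || f >= 1)
    stopf("cv_scenario: f must lie in [0, 1)")
  if (n_replications < 1) stopf("cv_scenario: n_replications >= 1 required")
  structure(list(trn_years = trn_years, tst_year = tst_year, f = f,
                 n_replications = as.integer(n_replications),
                 management = management, trait = trait,
                 seed = as.integer(seed)),
            class = "cv_scenario")
}

#' @export
print.cv_scenario <- function(x, ...) {
  cat(sprintf("CV scenario: TRN {%s} -> TST %s | f = %.2f | %s %s | %d reps\n",
              paste(x$trn_years, collapse = ","), x$tst_year, x$f,
              x$trait, x$management, x$n_replications))
  invisible(x)
}

scenario_descriptor <- function(s) {
  sprintf("trn=%s|tst=%s|f=%g|%s|%s",
          paste(sort(as.character(s$trn_years)), collapse = ","),
          s$tst_year, s$f, s$management, s$trait)
}

#' Randomly partition the testing set for fractional conversion
#'
#' Splits the testing-year lines into a converted subset (moved into the
#' training set, `round(f * n)` lines, ties rounding to even) and the
#' predicted remainder. Seeded and reproducible; the two subsets are disjoint
#' and exhaustive.
#'
#' @param tst_lines character vector of testing-set line ids.
#' @param f conversion fraction in \[0, 1).
#' @param seed integer seed for this partition.
#' @return list with `converted` and `predicted` character vectors.
#' @export
make_partition <- function(tst_lines, f, seed) {
  n <- length(tst_lines)
  if (n < 1L) stopf("make_partition: empty testing set")
  if (!is.finite(f) || f < 0 || f >= 1) stopf("make_partition: f must lie in [0, 1)")
  k <- round(f * n)
  if (k >= n)
    stopf("make_partition: f = %g converts the whole testing set; nothing left to predict", f)
  conv <- if (k > 0) with_seed(seed, sample(tst_lines, k)) else character(0)
  list(converted = conv, predicted = setdiff(tst_lines, conv))
}

#' Run one forward-prediction scenario
#'
#' For each replication: the testing-year lines are partitioned with
#' [make_partition()]; the training data are the training-year BLUEs plus the
#' BLUEs of the converted testing-year lines (environment = year); a
#' reaction-norm GBLUP is fitted on the training records only; GEBVs are
#' predicted for the remaining testing-year lines through the genomic
#' relationship matrix; and accuracy is the Pearson correlation between those
#' GEBVs and the held-out testing-year BLUEs. Lines appearing in both a
#' training year and the testing year are assigned to the testing year and
#' removed from the training records, so no testing-year phenotype outside
#' the converted subset ever enters the fit.
#'
#' @param scenario a [cv_scenario()].
#' @param blues long-format BLUE table (`line_id`, `year`, `management`,
#'   `trait`, `blue`) from [stage1_blues()].
#' @param G genomic relationship matrix covering all lines involved.
#' @param method,... passed to [gblup()] (REML by default).
#' @param keep_predictions also return the per-replication GEBV/observed
#'   pairs (used by diagnostics and leakage checks).
#' @return object of class `cv_result`: per-replication accuracies, their
#'   mean and sd, `n_predicted`, and the scenario.
#' @export
run_scenario <- function(scenario, blues, G, method = "reml",
                         keep_predictions = FALSE, ...) {
  stopifnot(inherits(scenario, "cv_scenario"))
  b <- blues[blues$trait == scenario$trait &
               blues$management == scenario$management, , drop = FALSE]
  tst <- b[b$year == scenario$tst_year, , drop = FALSE]
  trn <- b[b$year %in% scenario$trn_years &
             !(b$line_id %in% tst$line_id), , drop = FALSE]
  if (!nrow(tst)) stopf("run_scenario: no testing-year BLUEs")
  if (!nrow(trn)) stopf("run_scenario: no training-year BLUEs")
  tst_lines <- unique(tst$line_id)

  desc <- scenario_descriptor(scenario)
  acc <- numeric(scenario$n_replications)
  npred <- integer(scenario$n_replications)
  preds <- if (keep_predictions) vector("list", scenario$n_replications)
  init <- NULL
  n_capped <- 0L
  for (i in seq_len(scenario$n_replications)) {
    part <- make_partition(tst_lines, scenario$f,
                           seed = hash_seed(desc, scenario$seed, i))
    if (length(part$predicted) < 3L)
      stopf("run_scenario: fewer than 3 predicted lines; accuracy undefined")
    trn_data <- rbind(trn, tst[tst$line_id %in% part$converted, , drop = FALSE])
    trn_data$env <- as.character(trn_data$year)
    ## iteration-cap warnings are tallied across replications instead of
    ## surfacing one warning per fit
    fit <- withCallingHandlers(
      gblup(trn_data, G, response = "blue", line = "line_id",
            env = "env", method = method, init = init, ...),
      warning = function(w) {
        if (grepl("not converged", conditionMessage(w))) {
          n_capped <<- n_capped + 1L
          invokeRestart("muffleWarning")
        }
      })
    if (method == "reml" && fit$converged && is.null(fit$degenerate))
      init <- unname(fit$vc)     # warm start the next replication
    obs <- tst$blue[match(part$predicted, tst$line_id)]
    ghat <- predict(fit, part$predicted)
    ok <- is.finite(obs)
    acc[i] <- stats::cor(ghat[ok], obs[ok])
    npred[i] <- sum(ok)
    if (keep_predictions)
      preds[[i]] <- data.frame(replication = i, line_id = part$predicted[ok],
                               gebv = unname(ghat[ok]), observed = obs[ok])
  }
  if (n_capped > 0)
    gs_log("INFO", sprintf(
      "run_scenario: %d of %d fits stopped at the iteration cap (flat likelihood ridge)",
      n_capped, scenario$n_replications))
  structure(list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 n_predicted = npred, scenario = scenario,
                 n_not_converged = n_capped,
                 predictions = if (keep_predictions) do.call(rbind, preds)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  accuracy: mean %.3f (sd %.3f) over %d replications; %d lines predicted\n",
              x$mean, x$sd, length(x$accuracy), x$n_predicted[1]))
  invisible(x)
}

#' Run a grid of forward-prediction scenarios
#'
#' Runs [run_scenario()] for every scenario in the list and returns a tidy
#' per-replication results table plus a per-scenario summary. Per-scenario
#' seeds are derived by stable hashing of the scenario descriptor and the
#' master seed, so adding a scenario to the grid never changes the random
#' streams of the others. Duplicate descriptors are an error.
#'
#' @param scenarios list of [cv_scenario()] objects.
#' @param blues,G,method,... as in [run_scenario()].
#' @param master_seed integer master seed combined with each descriptor.
#' @return object of class `cv_grid`: `results` (one row per scenario x
#'   replication) and `summary` (one row per scenario).
#' @export
run_experiment_grid <- function(scenarios, blues, G, method = "reml",
                                master_seed = 1L, ...) {
  descs <- vapply(scenarios, scenario_descriptor, character(1))
  if (anyDuplicated(descs))
    stopf("run_experiment_grid: duplicate scenario descriptors")
  rows <- list(); summ <- list()
  for (j in seq_along(scenarios)) {
    s <- scenarios[[j]]
    s$seed <- hash_seed(descs[j], master_seed)
    r <- run_scenario(s, blues, G, method = method, ...)
    rows[[j]] <- data.frame(
      scenario = descs[j],
      trn_years = paste(s$trn_years, collapse = "+"),
      tst_year = s$tst_year, management = s$management, trait = s$trait,
      f = s$f, replication = seq_along(r$accuracy),
      n_predicted = r$n_predicted, accuracy = r$accuracy,
      stringsAsFactors = FALSE)
    summ[[j]] <- data.frame(
      scenario = descs[j],
      trn_years = paste(s$trn_years, collapse = "+"),
      tst_year = s$tst_year, management = s$management, trait = s$trait,
      f = s$f, n_replications = s$n_replications,
      mean_accuracy = r$mean, sd_accuracy = r$sd,
      stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, rows),
                 summary = do.call(rbind, summ)),
            class = "cv_grid")
}

#' @export
print.cv_grid <- function(x, ...) {
  cat("Forward-prediction experiment grid\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Accuracy against conversion fraction, one line per scenario family
#'
#' @param x a `cv_grid`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cv_grid <- function(x, ...) {
  s <- x$summary
  s$family <- sprintf("%s->%s %s %s", s$trn_years, s$tst_year, s$trait,
                      s$management)
  fams <- unique(s$family)
  fs <- sort(unique(s$f))
  m <- sapply(fams, function(fa)
    s$mean_accuracy[s$family == fa][match(fs, s$f[s$family == fa])])
  graphics::matplot(fs, m, type = "b", pch = 19, lty = 1,
                    xlab = "conversion fraction f",
                    ylab = "mean prediction accuracy",
                    main = "Forward prediction accuracy vs f", ...)
  graphics::legend("bottomright", legend = fams, col = seq_along(fams),
                   lty = 1, pch = 19, cex = 0.7, bty = "n")
  invisible(x)
}

#' Within-year k-fold cross-validation (auxiliary scheme)
#'
#' Classic k-fold partition of a single year's lines: each fold is predicted
#' from the remaining folds. Provided as a companion to the forward schemes.
#'
#' @param blues long BLUE table restricted by `year`, `management`, `trait`.
#' @param G genomic relationship matrix.
#' @param year,management,trait slice selectors.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param ... passed to [gblup()].
#' @return data.frame with one row per fold: fold, n_predicted, accuracy.
#' @export
kfold_within_year <- function(blues, G, year, management = "WW", trait = "GY",
                              k = 5, seed = 1L, ...) {
  b <- blues[blues$year == year & blues$management == management &
               blues$trait == trait, , drop = FALSE]
  ids <- unique(b$line_id)
  if (length(ids) < k) stopf("kfold_within_year: fewer lines than folds")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), length(ids))))
  out <- lapply(seq_len(k), function(fi) {
    trn <- b[b$line_id %in% ids[fold != fi], , drop = FALSE]
    fit <- gblup(trn, G, env = NULL, ...)
    pred_ids <- ids[fold == fi]
    obs <- b$blue[match(pred_ids, b$line_id)]
    data.frame(fold = fi, n_predicted = length(pred_ids),
               accuracy = stats::cor(predict(fit, pred_ids), obs))
  })
  do.call(rbind, out)
}
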