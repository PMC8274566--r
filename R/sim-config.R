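#' Configuration for the breeding-program simulator
#'
#' Builds and validates the parameter set that drives
#' [simulate_breeding_program()]. Defaults emulate a large early-stage
#' tropical-maize testcross program: 54 biparental doubled-haploid (DH)
#' populations (about 3,078 lines), 9,155 dominant presence/absence markers,
#' three years of trials under well-watered (WW) and managed water-stress (WS)
#' regimes with two replicates in incomplete blocks, drought cutting grain
#' yield by roughly half, and per-year entry-mean heritabilities in the ranges
#' typical of such trials. Any subset of parameters can be overridden, which
#' is how the test suite runs scaled-down programs.
#'
#' @param n_populations number of biparental DH populations.
#' @param lines_per_population DH lines derived per population.
#' @param n_founders size of the elite founder pool the population parents are
#'   drawn from (>= 2).
#' @param n_markers number of dominant 0/1 markers.
#' @param founder_presence_freq_range length-2 numeric in \[0,1\]; each
#'   marker's founder presence frequency is drawn uniformly from this range.
#' @param recomb_fraction recombination fraction between adjacent markers on
#'   the single synthetic linkage map.
#' @param maf_threshold minor-allele-frequency threshold carried in the config
#'   for downstream marker filtering (default 0.05).
#' @param years vector of year labels.
#' @param year_weights relative share of lines first evaluated in each year.
#' @param trials_per_year_ww,trials_per_year_ws trials per year under each
#'   management (scalar or one per year). Lines are nested in trials and
#'   connected by shared checks, as in an early-stage program.
#' @param n_checks number of check entries planted in every trial.
#' @param replicates replicates per trial (default 2).
#' @param block_size target incomplete-block size (>= 2); trailing blocks may
#'   be smaller.
#' @param n_qtl number of causal loci per trait.
#' @param qtl_overlap fraction of the AD/PH QTL sets shared with the GY set.
#' @param target_h2_ww,target_h2_ws per-trait entry-mean heritability targets
#'   for a single-trial slice (l = 1, r = `replicates`); residual variance is
#'   back-solved from these.
#' @param genetic_var_ww,genetic_var_ws per-trait genetic variances among line
#'   testcross values within one management.
#' @param ww_trait_means per-trait grand means under WW (GY t/ha, AD days,
#'   PH cm).
#' @param drought_gy_reduction,drought_ph_reduction fractional reduction of
#'   the GY and PH means under WS relative to WW.
#' @param drought_ad_shift additive shift (days) of anthesis date under WS.
#' @param year_effect_sd,trial_effect_sd,block_effect_sd per-trait standard
#'   deviations of year, trial and incomplete-block effects.
#' @param gxe_corr genetic correlation of a line's value between any two
#'   environments (compound symmetric), in (0, 1].
#' @param overlap_fraction fraction of lines re-evaluated in the following
#'   year (default 0: each cohort is tested once, as in forward prediction).
#' @param seed integer seed; the same seed reproduces the program bit for bit.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_breeding_program()]
#' @export
#' @examples
#' cfg <- sim_config(n_populations = 4, lines_per_population = 25,
#'                   n_markers = 300, seed = 1)
#' cfg
sim_config <- function(n_populations = 54,
                       lines_per_population = 57,
                       n_founders = 36,
                       n_markers = 9155,
                       founder_presence_freq_range = c(0.1, 0.9),
                       recomb_fraction = 0.05,
                       maf_threshold = 0.05,
                       years = c(2017, 2018, 2019),
                       year_weights = c(923, 1423, 722),
                       trials_per_year_ww = c(14, 34, 17),
                       trials_per_year_ws = 1,
                       n_checks = 5,
                       replicates = 2,
                       block_size = 10,
                       n_qtl = 200,
                       qtl_overlap = 0.5,
                       target_h2_ww = c(GY = 0.75, AD = 0.90, PH = 0.81),
                       target_h2_ws = c(GY = 0.30, AD = 0.62, PH = 0.36),
                       genetic_var_ww = c(GY = 0.19, AD = 0.80, PH = 35.26),
                       genetic_var_ws = c(GY = 0.12, AD = 0.94, PH = 40.82),
                       ww_trait_means = c(GY = 6.69, AD = 65.55, PH = 243.96),
                       drought_gy_reduction = 0.57,
                       drought_ph_reduction = 0.135,
                       drought_ad_shift = 2,
                       year_effect_sd = c(GY = 0.5, AD = 2, PH = 8),
                       trial_effect_sd = c(GY = 0.7, AD = 11, PH = 23),
                       block_effect_sd = c(GY = 0.3, AD = 0.8, PH = 5),
                       gxe_corr = 0.7,
                       overlap_fraction = 0,
                       seed = 1L) {
  cfg <- list(
    n_populations = as.integer(n_populations),
    lines_per_population = as.integer(lines_per_population),
    n_founders = as.integer(n_founders),
    n_markers = as.integer(n_markers),
    founder_presence_freq_range = as.numeric(founder_presence_freq_range),
    recomb_fraction = as.numeric(recomb_fraction),
    maf_threshold = as.numeric(maf_threshold),
    years = years,
    year_weights = as.numeric(rep_len(year_weights, length(years))),
    trials_per_year_ww = as.integer(rep_len(trials_per_year_ww, length(years))),
    trials_per_year_ws = as.integer(rep_len(trials_per_year_ws, length(years))),
    n_checks = as.integer(n_checks),
    replicates = as.integer(replicates),
    block_size = as.integer(block_size),
    n_qtl = as.integer(n_qtl),
    qtl_overlap = as.numeric(qtl_overlap),
    target_h2_ww = trait_vec(target_h2_ww),
    target_h2_ws = trait_vec(target_h2_ws),
    genetic_var_ww = trait_vec(genetic_var_ww),
    genetic_var_ws = trait_vec(genetic_var_ws),
    ww_trait_means = trait_vec(ww_trait_means),
    drought_gy_reduction = as.numeric(drought_gy_reduction),
    drought_ph_reduction = as.numeric(drought_ph_reduction),
    drought_ad_shift = as.numeric(drought_ad_shift),
    year_effect_sd = trait_vec(year_effect_sd),
    trial_effect_sd = trait_vec(trial_effect_sd),
    block_effect_sd = trait_vec(block_effect_sd),
    gxe_corr = as.numeric(gxe_corr),
    overlap_fraction = as.numeric(overlap_fraction),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_populations", "lines_per_population", "n_markers",
              "n_qtl", "replicates")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stopf("sim_config: '%s' must be a count >= 1", f)
  if (cfg$n_founders < 2L)
    stopf("sim_config: 'n_founders' must be >= 2 (biparental crosses)")
  fr <- cfg$founder_presence_freq_range
  if (length(fr) != 2L || any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) ||
      fr[1] > fr[2])
    stopf("sim_config: 'founder_presence_freq_range' must be an increasing pair in [0,1]")
  if (cfg$block_size < 2L)
    stopf("sim_config: 'block_size' must be >= 2")
  probs <- c(recomb_fraction = cfg$recomb_fraction,
             maf_threshold = cfg$maf_threshold,
             qtl_overlap = cfg$qtl_overlap,
             drought_gy_reduction = cfg$drought_gy_reduction,
             drought_ph_reduction = cfg$drought_ph_reduction,
             overlap_fraction = cfg$overlap_fraction,
             cfg$target_h2_ww, cfg$target_h2_ws)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stopf("sim_config: fractions/probabilities must lie in [0,1]")
  if (!is.finite(cfg$gxe_corr) || cfg$gxe_corr <= 0 || cfg$gxe_corr > 1)
    stopf("sim_config: 'gxe_corr' must lie in (0,1]")
  if (any(cfg$trials_per_year_ww < 1L) || any(cfg$trials_per_year_ws < 1L))
    stopf("sim_config: trial counts must be >= 1")
  if (any(c(cfg$genetic_var_ww, cfg$genetic_var_ws) <= 0))
    stopf("sim_config: genetic variances must be positive")
  if (cfg$n_checks < 0L)
    stopf("sim_config: 'n_checks' must be >= 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  n_lines <- x$n_populations * x$lines_per_population
  cat("Breeding-program simulation configuration\n")
  cat(sprintf("  populations: %d x %d DH lines  (%d lines, %d founders)\n",
              x$n_populations, x$lines_per_population, n_lines, x$n_founders))
  cat(sprintf("  markers: %d dominant 0/1, adjacent recombination %.3f\n",
              x$n_markers, x$recomb_fraction))
  cat(sprintf("  years: %s; trials WW %s / WS %s; %d reps, blocks of %d\n",
              paste(x$years, collapse = ", "),
              paste(x$trials_per_year_ww, collapse = "/"),
              paste(x$trials_per_year_ws, collapse = "/"),
              x$replicates, x$block_size))
  cat(sprintf("  drought: GY -%d%%, PH -%.1f%%, AD %+.1f d; GxE corr %.2f\n",
              round(100 * x$drought_gy_reduction),
              100 * x$drought_ph_reduction, x$drought_ad_shift, x$gxe_corr))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
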