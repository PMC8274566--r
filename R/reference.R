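#' Published variance components of the motivating trial network
#'
#' Per-year and pooled variance components, heritabilities and trait means of
#' a three-year tropical-maize testcross network evaluated under well-watered
#' and managed water-stress regimes, as printed in the originating trial
#' report. Shipped as a plain-text table; used as the worked-example input
#' for [heritability()] and [stress_reduction()] and by the acceptance
#' script. `n_trials` is the number of trials contributing to each slice
#' (water-stress slices were single trials).
#'
#' @return data.frame with columns year, management, trait, sigma2_g,
#'   sigma2_trial, sigma2_gxt, sigma2_e, h2_printed, mean, n_trials, n_reps.
#' @export
#' @examples
#' tab <- reference_varcomp()
#' gy18 <- subset(tab, year == "2018" & management == "WW" & trait == "GY")
#' heritability(gy18$sigma2_g, sigma2_e = gy18$sigma2_e,
#'              sigma2_gxt = gy18$sigma2_gxt,
#'              n_trials = gy18$n_trials, n_reps = gy18$n_reps)
reference_varcomp <- function() {
  path <- system.file("extdata", "table1_variance_components.tsv",
                      package = "earlygs")
  utils::read.delim(path, colClasses = c(year = "character"))
}
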