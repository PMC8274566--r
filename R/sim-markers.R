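#' Simulate founder genomes as dominant presence/absence markers
#'
#' Draws a pool of elite founder lines. Each marker is assigned a presence
#' frequency uniformly from `founder_presence_freq_range`; founder alleles at
#' that marker are then independent Bernoulli draws. Markers are dominant
#' 0 (absence) / 1 (presence) scores, emulating repetitive-amplicon
#' (rAmpSeq-style) genotyping of fully homozygous material.
#'
#' @param cfg a [sim_config()].
#' @return integer matrix (`n_founders` x `n_markers`) with entries in
#'   \{0, 1\}; rownames are founder ids, colnames marker ids.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    fr <- cfg$founder_presence_freq_range
    p <- stats::runif(cfg$n_markers, fr[1], fr[2])
    m <- matrix(stats::rbinom(cfg$n_founders * cfg$n_markers, 1L,
                              rep(p, each = cfg$n_founders)),
                nrow = cfg$n_founders, ncol = cfg$n_markers)
    dimnames(m) <- list(sprintf("F%03d", seq_len(cfg$n_founders)),
                        sprintf("M%05d", seq_len(cfg$n_markers)))
    m
  })
}

#' Derive doubled-haploid lines from biparental crosses
#'
#' For each population two distinct founders are crossed; each DH line is one
#' recombinant gamete of that F1, chromosome-doubled. Markers sit on a single
#' synthetic linkage map with a constant recombination fraction between
#' adjacent markers, so each gamete is a mosaic of parental blocks. Because a
#' DH line is fully homozygous, its dominant 0/1 score at a marker equals the
#' sampled gamete allele, which in turn equals one of the two parents' scores.
#'
#' @param founders founder marker matrix from [simulate_founders()].
#' @param cfg a [sim_config()].
#' @param seed optional integer overriding `cfg$seed` for this step.
#' @return list with `markers` (lines x markers 0/1 integer matrix, rownames
#'   line ids) and `pedigree` (data.frame: line_id, population, parent1,
#'   parent2).
#' @export
derive_dh_lines <- function(founders, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"), is.matrix(founders))
  if (nrow(founders) < 2L)
    stopf("derive_dh_lines: need at least 2 founders for biparental crosses")
  n_pop <- cfg$n_populations
  n_per <- cfg$lines_per_population
  m <- ncol(founders)
  r <- cfg$recomb_fraction
  with_seed(seed, {
    ped <- vector("list", n_pop)
    geno <- matrix(0L, nrow = n_pop * n_per, ncol = m)
    row <- 0L
    for (p in seq_len(n_pop)) {
      par <- sample(nrow(founders), 2L)
      a <- founders[par[1L], ]
      b <- founders[par[2L], ]
      for (i in seq_len(n_per)) {
        row <- row + 1L
        ## parental origin along the map: start at random, switch between
        ## adjacent markers with probability r
        switches <- stats::runif(m - 1L) < r
        origin <- (sample(0:1, 1L) + c(0L, cumsum(switches))) %% 2L
        geno[row, ] <- ifelse(origin == 0L, a, b)
      }
      ped[[p]] <- data.frame(
        line_id = sprintf("P%02d_L%03d", p, seq_len(n_per)),
        population = sprintf("P%02d", p),
        parent1 = rownames(founders)[par[1L]],
        parent2 = rownames(founders)[par[2L]],
        stringsAsFactors = FALSE)
    }
    pedigree <- do.call(rbind, ped)
    dimnames(geno) <- list(pedigree$line_id, colnames(founders))
    list(markers = geno, pedigree = pedigree)
  })
}
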