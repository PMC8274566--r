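test_that("founder matrices are binary, frequency-faithful and deterministic", {
  cfg <- tiny_config(seed = 5)
  f1 <- simulate_founders(cfg)
  f2 <- simulate_founders(cfg)
  expect_identical(f1, f2)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_equal(dim(f1), c(cfg$n_founders, cfg$n_markers))

  all1 <- simulate_founders(tiny_config(founder_presence_freq_range = c(1, 1)))
  expect_true(all(all1 == 1L))
  expect_error(sim_config(founder_presence_freq_range = c(0.9, 0.1)),
               "freq")
})

test_that("DH lines obey Mendelian inheritance from their two parents", {
  cfg <- tiny_config(n_populations = 3, lines_per_population = 15,
                     n_markers = 120, seed = 2)
  f <- simulate_founders(cfg)
  dh <- derive_dh_lines(f, cfg)
  expect_equal(nrow(dh$markers), 45)
  expect_true(all(dh$markers %in% c(0L, 1L)))
  ## every DH value equals one of its parents' values at that marker
  for (i in seq_len(nrow(dh$markers))) {
    p <- dh$pedigree[i, ]
    a <- f[p$parent1, ]; b <- f[p$parent2, ]
    expect_true(all(dh$markers[i, ] == a | dh$markers[i, ] == b))
  }
  ## pedigree is a function: one population per line
  expect_false(anyDuplicated(dh$pedigree$line_id) > 0)
  ## markers where both parents carry 1 are 1 in all offspring
  p1 <- dh$pedigree[1, ]
  both1 <- f[p1$parent1, ] == 1 & f[p1$parent2, ] == 1
  pop1 <- dh$markers[dh$pedigree$population == p1$population, , drop = FALSE]
  expect_true(all(pop1[, both1] == 1L))
})

test_that("zero recombination makes each gamete a single parental block", {
  cfg <- tiny_config(n_populations = 2, lines_per_population = 10,
                     n_markers = 80, recomb_fraction = 0, seed = 3)
  f <- simulate_founders(cfg)
  dh <- derive_dh_lines(f, cfg)
  for (i in seq_len(nrow(dh$markers))) {
    p <- dh$pedigree[i, ]
    whole_a <- all(dh$markers[i, ] == f[p$parent1, ])
    whole_b <- all(dh$markers[i, ] == f[p$parent2, ])
    expect_true(whole_a || whole_b)
  }
  expect_error(derive_dh_lines(f[1, , drop = FALSE], cfg), "2 founders")
})

test_that("full sibs share more of the genome than cross-population pairs", {
  cfg <- tiny_config(n_populations = 6, lines_per_population = 20,
                     n_markers = 500, seed = 4)
  dh <- derive_dh_lines(simulate_founders(cfg), cfg)
  m <- dh$markers
  pop <- dh$pedigree$population
  sharing <- tcrossprod(m) + tcrossprod(1L - m)  # identical marker count
  same <- outer(pop, pop, "==")
  diag(same) <- NA
  within <- mean(sharing[same & upper.tri(sharing)], na.rm = TRUE)
  between <- mean(sharing[!same & upper.tri(sharing)], na.rm = TRUE)
  expect_gt(within, between)
})

test_that("phenotype records carry the configured structure and stress signal", {
  cfg <- tiny_config(seed = 11)
  sim <- simulate_breeding_program(cfg)
  ph <- sim$phenotypes
  expect_true(all(c("year", "management", "trial", "rep", "block", "line_id",
                    "GY", "AD", "PH") %in% names(ph)))
  ## keys unique at plot level
  key <- with(ph, paste(year, management, trial, rep, block, line_id))
  expect_false(anyDuplicated(key) > 0)
  ## WS grain yield reduced roughly by the configured fraction
  red <- 1 - mean(ph$GY[ph$management == "WS"]) /
    mean(ph$GY[ph$management == "WW"])
  expect_lt(abs(red - cfg$drought_gy_reduction), 0.12)
  ## bit-identical regeneration under the same config
  sim2 <- simulate_breeding_program(cfg)
  expect_identical(sim$phenotypes, sim2$phenotypes)
  expect_identical(sim$markers, sim2$markers)
})

test_that("drought reduction of 0.46 from a 6.05 WW mean lands near 3.27 t/ha", {
  ## year/trial/block effects silenced so only sampling noise remains around
  ## the constructed WS mean
  cfg <- tiny_config(n_populations = 6, lines_per_population = 40,
                     ww_trait_means = c(GY = 6.05, AD = 65, PH = 240),
                     drought_gy_reduction = 0.46,
                     year_effect_sd = 0, trial_effect_sd = 0,
                     block_effect_sd = 0, seed = 21)
  sim <- simulate_breeding_program(cfg)
  ws <- sim$phenotypes$GY[sim$phenotypes$management == "WS"]
  expect_lt(abs(mean(ws) - 6.05 * (1 - 0.46)),
            3 * stats::sd(ws) / sqrt(length(ws)))
})

test_that("perfect GxE correlation gives identical genetic values across years", {
  cfg <- tiny_config(gxe_corr = 1, seed = 6)
  sim <- simulate_breeding_program(cfg)
  g <- sim$truth$genetic_values$GY
  envs <- sim$truth$environments
  ww <- which(envs$management == "WW")
  for (j in ww[-1]) expect_equal(g[, ww[1]], g[, j], tolerance = 1e-10)
})

test_that("noise-free limit puts every plot at mean + genetic value with H2 = 1", {
  cfg <- tiny_config(n_populations = 2, lines_per_population = 15,
                     target_h2_ww = 1, target_h2_ws = 1,
                     year_effect_sd = 0, trial_effect_sd = 0,
                     block_effect_sd = 0, n_checks = 0, seed = 8)
  sim <- simulate_breeding_program(cfg)
  ph <- sim$phenotypes
  envs <- sim$truth$environments
  e <- which(envs$year == ph$year[1] & envs$management == ph$management[1])
  g <- unname(sim$truth$genetic_values$GY[ph$line_id[1], e])
  expect_equal(ph$GY[1],
               unname(sim$truth$management_means[ph$management[1], "GY"]) + g,
               tolerance = 1e-8)
  expect_true(all(sim$truth$realized_h2$realized_h2 == 1))
})

test_that("higher residual noise lowers the realized heritability", {
  h2s <- c(0.9, 0.6, 0.3, 0.1)
  realized <- sapply(h2s, function(h) {
    cfg <- tiny_config(n_populations = 3, lines_per_population = 25,
                       target_h2_ww = c(GY = h, AD = h, PH = h), seed = 13)
    sim <- simulate_breeding_program(cfg)
    r <- sim$truth$realized_h2
    mean(r$realized_h2[r$management == "WW" & r$trait == "GY"])
  })
  expect_true(all(diff(realized) < 0))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(block_size = 1), "block_size")
  expect_error(sim_config(gxe_corr = 0), "gxe_corr")
  expect_error(sim_config(n_founders = 1), "n_founders")
  expect_error(sim_config(drought_gy_reduction = 1.2), "\\[0,1\\]")
})
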