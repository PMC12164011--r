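test_that("plate densities and viability follow the counting arithmetic", {
  expect_equal(density_from_plate(100, 100, 1e5), 1e5)
  expect_equal(density_from_plate(0, 100, 10), 0)
  expect_error(density_from_plate(10, 0, 1), "plated_volume")
  # Poisson plating at a known density is recovered without bias
  set.seed(91)
  dens <- 40  # cells/uL
  counts <- stats::rpois(1000, dens * 100 / 10)  # 100 uL at 10x dilution
  est <- density_from_plate(counts, 100, 10)
  expect_lt(abs(mean(est) - dens), 3 * stats::sd(est) / sqrt(1000))

  expect_equal(viability(5e4, 1e5), 0.5)
  expect_equal(viability(2e4, 2e4), 1)
  expect_warning(viability(3, 2), "above 1")
  expect_error(viability(1, 0), "total_density")
})

test_that("mutation frequencies normalize as ratios and percentages", {
  expect_equal(canr_frequency(10, 1e6), 1e-5)
  expect_equal(canr_frequency(0, 5), 0)
  expect_error(canr_frequency(1, 0), "viable_density")
  expect_equal(normalize_mutation_frequency(1e-5, 0.5), 2e-5)
  expect_equal(normalize_mutation_frequency(3e-4, 1), 3e-4)
  expect_error(normalize_mutation_frequency(1e-5, 0), "f must be > 0")
  expect_equal(relative_normalized_frequency(0.7, 0.7), 100)
  expect_equal(relative_normalized_frequency(0.33 * 5, 5), 33)
  expect_error(relative_normalized_frequency(1, 0), "reference_norm")
})

test_that("red-colony fractions flag deletion-driven resistance", {
  expect_equal(red_fraction(2, 100), 0.02)
  expect_equal(red_fraction(0, 50), 0)
  expect_equal(red_fraction(0, 0), 0)
  expect_error(red_fraction(5, 3), "exceed")
})

test_that("per-position relative frequency excludes zero-reference sites
           and ignores depth", {
  treated <- make_pileup(0:2, c("G", "C", "A"),
                         A = c(20, 0, 980), C = c(0, 999, 0),
                         G = c(980, 0, 10), T = c(0, 1, 10))
  untreated <- make_pileup(0:2, c("G", "C", "A"),
                           A = c(1, 0, 1000), C = c(0, 1000, 0),
                           G = c(999, 0, 10), T = c(0, 0, 10))
  out <- per_position_relative_frequency(treated, untreated)
  # pos 0: treated 0.02 vs untreated 0.001 -> 20
  expect_equal(out$table$relative_frequency[out$table$pos == 0], 20)
  # pos 1 has zero untreated mutation frequency -> excluded
  expect_true(1 %in% out$excluded_positions)
  expect_false(1 %in% out$table$pos)
  # doubling all counts changes nothing
  doubled <- per_position_relative_frequency(
    transform(treated, A = 2 * A, C = 2 * C, G = 2 * G, T = 2 * T),
    transform(untreated, A = 2 * A, C = 2 * C, G = 2 * G, T = 2 * T))
  expect_equal(doubled$table, out$table)
  bad <- untreated; bad$pos <- bad$pos + 1
  expect_error(per_position_relative_frequency(treated, bad),
               "share positions")
})

test_that("spectrum classification reads the deaminated strand", {
  # deamination of the non-sense strand shows up as sense-strand G>A
  ga <- make_pileup(0:3, c("G", "G", "C", "A"),
                    A = c(50, 40, 0, 990), C = c(0, 0, 995, 0),
                    G = c(950, 960, 0, 5), T = c(0, 0, 5, 5))
  sp <- classify_spectrum(ga)
  expect_equal(sp$dominant, "G>A")
  expect_gt(sp$ga_ct_ratio, 1)
  # the symmetric construction: sense-strand deamination gives C>T
  ct <- make_pileup(0:3, c("C", "C", "G", "A"),
                    A = c(0, 0, 3, 990), C = c(940, 955, 0, 0),
                    G = c(0, 0, 995, 5), T = c(60, 45, 2, 5))
  expect_equal(classify_spectrum(ct)$dominant, "C>T")
  # no mutations at all
  clean <- make_pileup(0:1, c("A", "T"), A = c(100, 0), T = c(0, 100))
  expect_true(is.na(classify_spectrum(clean)$dominant))
  bad <- make_pileup(0, "N", A = 10)
  expect_error(classify_spectrum(bad), "unannotated")
})

test_that("correlation handles the degenerate inputs", {
  x <- c(0.1, 0.4, 0.7, 0.9)
  expect_equal(correlate(x, 2 - 3 * x), -1)
  expect_error(correlate(x, rep(1, 4)), "zero-variance")
  expect_error(correlate(x[1:2], x[1:2]), "3 paired points")
})

test_that("simulated bisulfite mutagenesis carries the resection signature", {
  lay <- default_layout()
  cfg <- sim_config(n_cells = 4000, seed = 92L)
  pop <- simulate_population(cfg, lay)
  treated <- simulate_mutagenesis(pop, cfg, lay, treated = TRUE)
  untreated <- simulate_mutagenesis(pop, cfg, lay, treated = FALSE)
  # resection exposes the non-sense strand: sense G>A dominates
  expect_equal(classify_spectrum(treated$pileup)$dominant, "G>A")
  # and the symmetric transcription-exposure model gives C>T
  sense <- simulate_mutagenesis(pop, cfg, lay, treated = TRUE,
                                exposed_strand = "sense")
  expect_equal(classify_spectrum(sense$pileup)$dominant, "C>T")
  # mutations require exposure: untreated cells score none
  expect_equal(sum(untreated$truth$n_mutations), 0)
  # no deletions, no red colonies
  cfg0 <- cfg; cfg0$deletion_prob <- 0
  pop0 <- simulate_population(cfg0, lay)
  mut0 <- simulate_mutagenesis(pop0, cfg0, lay, treated = TRUE)
  expect_equal(mut0$plates$red_colonies[2], 0L)
  # deamination confined to resection-exposed region of the pileup
  reach_max <- lay$dsb_site + max(pop$tel_extent)
  beyond <- treated$pileup$pos > reach_max & treated$pileup$ref == "G"
  if (any(beyond)) {
    freq_beyond <- treated$pileup$A[beyond] /
      (treated$pileup$A[beyond] + treated$pileup$G[beyond])
    expect_lt(mean(freq_beyond), 5 * cfg$seq_error_rate)
  }
})

test_that("an absolute roadblock before CAN1 removes DSB-coupled mutants", {
  lay <- default_layout()
  cfg <- sim_config(n_cells = 4000, seed = 93L,
                    block_probs = c(sg1 = 1), residence_minutes = 1e9,
                    deletion_prob = 0)
  pop <- simulate_population(cfg, lay)
  mut <- simulate_mutagenesis(pop, cfg, lay, treated = TRUE)
  expect_equal(mut$canr_cells, 0)
})

test_that("blocking reduces measured mutation frequency and the readouts
           anticorrelate with blocking", {
  lay <- default_layout()
  conditions <- list(none = numeric(0), sg3 = c(sg3 = 0.30),
                     sg2 = c(sg2 = 0.47),
                     dual = c(sg1 = 0.53, sg2 = 0.47))
  config_block <- vapply(conditions, function(b) {
    1 - prod(1 - b)
  }, numeric(1))
  n_seeds <- 12
  signs <- vapply(seq_len(n_seeds), function(s) {
    set.seed(1000 + s)
    cfg <- sim_config(n_cells = 3000, residence_minutes = 1e9)
    relint <- numeric(length(conditions))
    mutfreq <- numeric(length(conditions))
    cfg_nc <- cfg; cfg_nc$f_true <- 0
    nc <- simulate_population(cfg_nc, lay)
    ref <- simulate_population(cfg, lay)
    for (i in seq_along(conditions)) {
      cfg_i <- cfg; cfg_i$block_probs <- conditions[[i]]
      pop <- simulate_population(cfg_i, lay)
      relint[i] <- relative_intensity(mean(pop$fluorescence),
                                      mean(nc$fluorescence),
                                      mean(ref$fluorescence))
      mut <- simulate_mutagenesis(pop, cfg_i, lay, treated = TRUE)
      freq <- canr_frequency(
        density_from_plate(mut$plates$colonies[2], 250),
        density_from_plate(mut$plates$colonies[1], 100))
      mutfreq[i] <- normalize_mutation_frequency(freq, mean(pop$dsb))
    }
    c(correlate(config_block, relint) < 0,
      correlate(config_block, mutfreq) < 0,
      which.min(mutfreq) == which.max(config_block))
  }, logical(3))
  expect_gte(mean(signs[1, ]), 0.95)
  expect_gte(mean(signs[2, ]), 0.95)
  # the double-targeting condition shows the lowest mutation frequency in
  # most runs
  expect_gte(mean(signs[3, ]), 0.75)
})
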