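test_that("seeded simulations are bit-reproducible", {
  cfg <- sim_config(n_cells = 1000, block_probs = c(sg2 = 0.5), seed = 99L)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
})

test_that("unblocked tract coverage matches the closed-form Gamma law", {
  lay <- default_layout()
  cfg <- sim_config(n_cells = 40000, f_true = 0.5, seed = 7L)
  pop <- simulate_population(cfg, lay)
  # extent = speed * hours * m with m ~ Gamma(shape, shape), so the tract
  # covers distance d iff m >= d / (speed * hours)
  reach <- cfg$resection_speed * cfg$induction_hours
  for (site in names(lay$sphi_sites)) {
    d <- lay$sphi_sites[[site]] - lay$dsb_site
    want <- cfg$f_true *
      stats::pgamma(d / reach, shape = cfg$tract_shape,
                    rate = cfg$tract_shape, lower.tail = FALSE)
    got <- ssdna_fraction_at(pop, lay$sphi_sites[[site]])
    se <- sqrt(want * (1 - want) / cfg$n_cells)
    expect_lt(abs(got - want), 4 * se + 1e-6)
  }
})

test_that("an always-on roadblock with long dwell is absolute", {
  lay <- default_layout()
  cfg <- sim_config(n_cells = 5000, block_probs = c(sg1 = 1),
                    residence_minutes = 1e9, seed = 11L)
  pop <- simulate_population(cfg, lay)
  # nothing passes sg1, so SphI-2 (beyond it) is never single-stranded
  expect_equal(ssdna_fraction_at(pop, lay$sphi_sites[["SphI-2"]]), 0)
  # SphI-1 (before it) is untouched
  expect_gt(ssdna_fraction_at(pop, lay$sphi_sites[["SphI-1"]]), 0.4)
  blocked <- !is.na(pop$stalled_at)
  expect_true(all(pop$stalled_at[blocked] == "sg1"))
  expect_equal(sort(unique(pop$tel_extent[blocked])),
               lay$dcas9_sites[["sg1"]] - lay$dsb_site)
})

test_that("two roadblocks act independently", {
  lay <- default_layout()
  pass_at_sphi2 <- function(blocks, seed) {
    cfg <- sim_config(n_cells = 10000, f_true = 1,
                      block_probs = blocks, residence_minutes = 1e9,
                      seed = seed)
    pop <- simulate_population(cfg, lay)
    ssdna_fraction_at(pop, lay$sphi_sites[["SphI-2"]])
  }
  p1 <- pass_at_sphi2(c(sg1 = 0.53), 21L)
  p2 <- pass_at_sphi2(c(sg2 = 0.47), 22L)
  p12 <- pass_at_sphi2(c(sg1 = 0.53, sg2 = 0.47), 23L)
  se <- sqrt(0.25 / 10000) * sqrt(3)  # generous SE for the product
  expect_lt(abs(p12 - p1 * p2), 3 * se + 0.01)
})

test_that("tract bookkeeping conserves geometry", {
  lay <- default_layout()
  cfg <- sim_config(n_cells = 3000, block_probs = c(sg2 = 0.6), seed = 31L)
  pop <- simulate_population(cfg, lay)
  expect_true(all(pop$tel_extent >= 0 & pop$cen_extent >= 0))
  expect_true(all(pop$cen_extent <= cfg$centromeric_cap_bp))
  expect_true(all(pop$tel_extent[!pop$dsb] == 0))
  expect_true(all(pop$cen_extent[!pop$dsb] == 0))
  # positions beyond the centromeric cap are never single-stranded
  far <- lay$dsb_site - cfg$centromeric_cap_bp
  if (far >= 0) expect_equal(ssdna_fraction_at(pop, far), 0)
  # just telomeric of the break every cut cell is single-stranded
  expect_equal(ssdna_fraction_at(pop, lay$dsb_site + 1), mean(pop$dsb))
  expect_error(ssdna_fraction_at(pop, lay$length + 5), "outside")
})

test_that("different seeds give statistically indistinguishable tracts", {
  cfg_a <- sim_config(n_cells = 4000, seed = 41L)
  cfg_b <- sim_config(n_cells = 4000, seed = 42L)
  a <- simulate_population(cfg_a)
  b <- simulate_population(cfg_b)
  ks <- suppressWarnings(
    stats::ks.test(a$tel_extent[a$dsb], b$tel_extent[b$dsb]))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated plates have the expected tidy structure", {
  lay <- default_layout()
  set.seed(51)
  built <- panel_populations(numeric(0), n_cells = 500)
  pq <- simulate_ct_plate(built$pops, built$config, lay)
  expect_setequal(names(pq$plate),
                  c("sample_id", "amplicon_id", "condition", "replicate",
                    "ct"))
  counts <- table(pq$plate$sample_id, pq$plate$amplicon_id,
                  pq$plate$condition)
  # duplicates everywhere a measurement exists
  expect_true(all(counts %in% c(0L, 2L)))
  expect_true(all(c("SphI-1", "SphI-2", "SphI-3", "ACT1", "DSB") %in%
                  pq$plate$amplicon_id))
  expect_gte(min(table(pq$standards$amplicon_id)), 3)
})

test_that("an uninduced population yields no measured DSBs", {
  lay <- default_layout()
  set.seed(61)
  built <- panel_populations(numeric(0), n_cells = 2000, ct_noise_sd = 0)
  pq <- simulate_ct_plate(built$pops, built$config, lay)
  res <- analyze_experiment(pq$plate, pq$standards, lay,
                            "reference", "glucose")
  # no-DSB control is excluded from the test table by construction
  expect_false("glucose" %in% res$table$sample_id)
  # the DSB amplicon of a glucose-grown duplicate strain reads f ~ 0
  cfg0 <- built$config; cfg0$f_true <- 0
  pops <- built$pops
  pops$uninduced <- simulate_population(cfg0, lay)
  pq0 <- simulate_ct_plate(pops, built$config, lay)
  res0 <- analyze_experiment(pq0$plate, pq0$standards, lay,
                             "reference", "glucose")
  expect_equal(unname(res0$f[["uninduced"]]), 0, tolerance = 1e-6)
})

test_that("packaged scenarios assemble analyzable bundles", {
  cfg <- sim_config(n_cells = 3000, seed = 71L)
  expect_error(run_scenario("mystery", cfg), "unknown scenario")
  lay <- default_layout()
  blocking_of <- function(scenario) {
    bn <- run_scenario(scenario, cfg, lay)
    res <- analyze_experiment(bn$qpcr$plate, bn$qpcr$standards, lay,
                              reference_sample = "reference",
                              no_dsb_sample = "no_dsb")
    res$table$blocking_efficiency[res$table$sample_id == "test" &
                                  res$table$site == "SphI-3"]
  }
  b_single <- blocking_of("single-sg")
  b_double <- blocking_of("double-sg")
  expect_gt(b_double, b_single)
  nod <- run_scenario("no-dsb", cfg, lay)
  expect_lt(mean(nod$populations$test$dsb), 1e-9)
  # mutagenesis arms are included for induced scenarios
  bn <- run_scenario("double-sg", cfg, lay)
  expect_true(all(c("treated", "untreated") %in% names(bn$mutagenesis)))
  expect_s3_class(bn$mutagenesis$treated$pileup, "data.frame")
})
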