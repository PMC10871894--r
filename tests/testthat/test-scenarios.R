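test_that("presets encode the six optimum-shift scenarios exactly", {
  expect_equal(schedule_for(preset("fig2A"), "P1", 0), c(1, 0, 0, 0, 0))
  expect_equal(schedule_for(preset("fig2A"), "P1", 1500), c(2, 0, 0, 0, 0))
  expect_equal(schedule_for(preset("fig2B"), "P2", 0), c(3, 0, 0, 0, 0))
  expect_equal(schedule_for(preset("fig2B"), "H", 1600), c(2, 0, 0, 0, 0))
  expect_equal(schedule_for(preset("fig2C"), "H", 1500),
               c(2.5, 0, 0, 0, 0))
  expect_equal(schedule_for(preset("fig3A"), "P1", 2000), c(0, 2, 0, 0, 0))
  fig3B <- preset("fig3B")
  expect_equal(schedule_for(fig3B, "P1", 10), c(2, 0, 0, 0, 0))
  expect_equal(schedule_for(fig3B, "P2", 10), c(0, 2, 0, 0, 0))
  expect_equal(schedule_for(fig3B, "P2", 1500), c(2, 2, 0, 0, 0))
  fig3C <- preset("fig3C")
  expect_false(isTRUE(all.equal(schedule_for(fig3C, "P1", 0),
                                schedule_for(fig3C, "P2", 0))))
  expect_equal(schedule_for(fig3C, "H", 1500), c(0, 0, 2, 0, 0))
  expect_error(preset("fig9Z"), "fig2A.*fig3C|valid presets")
})

test_that("preset defaults follow the standard parameterization", {
  dip <- preset("fig2A", system = "diploid")
  expect_identical(dip$N_pop, 1500L)
  expect_equal(dip$r_bp, 2 / 3 * 1e-6)
  hap <- preset("fig2A", system = "haplodiploid")
  expect_identical(hap$N_pop, 2000L)
  expect_equal(hap$r_bp, 1e-6)
  for (cfg in list(dip, hap)) {
    expect_equal(cfg$mu, 1e-8)
    expect_equal(cfg$L, 1e6)
    expect_identical(cfg$n, 5L)
    expect_equal(cfg$lambda_mean, 0.2)
    expect_equal(cfg$h, 0.5)
    expect_equal(cfg$shape, 1)
    expect_identical(cfg$T_parental, 1500L)
    expect_identical(cfg$replicates, 100L)
  }
})

test_that("schedules validate change points and require a start optimum", {
  expect_error(optimum_schedule(P1 = list(
    list(generation = 10, optimum = c(0, 0)),
    list(generation = 10, optimum = c(1, 0)))), "strictly increasing")
  sched <- optimum_schedule(P1 = list(list(generation = 5,
                                           optimum = c(1, 0))))
  expect_error(
    run_parental_phase(scenario_config("diploid", schedule = sched,
                                       N_pop = 8, n = 2, T_parental = 3,
                                       T_novel = 1, replicates = 1)),
    "generation-0")
})

test_that("with no mutation and a resident optimum nothing changes", {
  sched <- optimum_schedule(P1 = list(list(generation = 0,
                                           optimum = c(0, 0, 0, 0, 0))))
  cfg <- scenario_config("diploid", schedule = sched, N_pop = 12, mu = 0,
                         T_parental = 10, T_novel = 5, replicates = 1)
  set.seed(1)
  par <- run_parental_phase(cfg)
  expect_equal(population_phenotypes(par$P1), matrix(0, 12, 5))
  recs <- records_to_df(par$records)
  expect_true(all(recs$mean_fitness_all == 1))
  expect_true(all(recs$pi == 0))
})

test_that("replicates are byte-identical under the same seed", {
  cfg <- preset("fig2A", system = "haplodiploid", N_pop = 40,
                T_parental = 30, T_novel = 20, replicates = 2, mu = 1e-6,
                seed = 99)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$seeds, b$seeds)
})

test_that("hybrid founders are an exact 50:50 split of sexes and ancestries", {
  cfg <- preset("fig2A", system = "haplodiploid", N_pop = 40,
                T_parental = 20, T_novel = 5, replicates = 1, mu = 1e-6)
  set.seed(3)
  par <- run_parental_phase(cfg)
  H <- create_hybrid_population(par$P1, par$P2)
  anc <- attr(H, "ancestry")
  expect_identical(pop_size(H), 40L)
  expect_identical(sum(anc == "P1"), 20L)
  expect_identical(sum(anc == "P2"), 20L)
  expect_identical(sum(H$sex == "female" & anc == "P1"), 10L)
  expect_identical(sum(H$sex == "male" & anc == "P2"), 10L)
  # copied, not shared: mutating H leaves parents untouched
  old <- par$P1$genomes[[1L]]
  H$genomes[[1L]] <- c(H$genomes[[1L]], -99L)
  expect_identical(par$P1$genomes[[1L]], old)
})

test_that("mismatched parents cannot hybridize", {
  reg <- new_registry(2)
  P1 <- new_population("P1", "diploid", 8, list(), registry = reg)
  P2 <- new_population("P2", "haplodiploid", 8, list(), registry = reg)
  expect_error(create_hybrid_population(P1, P2), "system")
  P3 <- new_population("P2", "diploid", 12, list(), registry = reg)
  expect_error(create_hybrid_population(P1, P3), "size")
})

test_that("a full two-phase run produces a complete record stream", {
  cfg <- preset("fig2A", system = "diploid", N_pop = 24, T_parental = 15,
                T_novel = 10, replicates = 1, mu = 1e-6, seed = 5)
  rep1 <- run_replicate(cfg, 1, seed = 11)
  recs <- rep1$records
  # parents: generations 0..25; hybrid: 15..25
  expect_identical(sum(recs$population == "P1"), 26L)
  expect_identical(sum(recs$population == "H"), 11L)
  expect_true(all(recs$N == 24L))
  # the adaptation rate is defined except in each population's last row
  last <- tapply(recs$generation, recs$population, max)
  for (p in names(last)) {
    sub <- recs[recs$population == p, ]
    expect_true(all(is.na(sub$adaptation_rate[sub$generation == last[[p]]])))
  }
})
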