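test_that("BDMI multipliers need both derived alleles to cost anything", {
  reg <- new_registry(2)
  P1 <- new_population("P1", "diploid", 8, list(), registry = reg)
  P2 <- new_population("P2", "diploid", 8, list(), registry = reg)
  seeded <- seed_bdmi_markers(P1, P2, bdmi_config(2, cost = 0.3))
  pairs <- seeded$pairs
  # pure parental individuals carry one side only: multiplier 1
  expect_equal(bdmi_multipliers(seeded$P1, pairs), rep(1, 8))
  expect_equal(bdmi_multipliers(seeded$P2, pairs), rep(1, 8))
  expect_equal(bdmi_fitness_multiplier(get_individual(seeded$P1, 1), pairs),
               1)
  # a double heterozygote with m(het, het) = 1 pays 1 - c per pair
  H <- create_hybrid_population(seeded$P1, seeded$P2)
  kid <- list(sex = "female", ploidy = 2L,
              genomes = list(sort(pairs$a_ids), sort(pairs$b_ids)),
              registry = reg)
  expect_equal(bdmi_fitness_multiplier(kid, pairs), (1 - 0.3)^2)
  # order of pairs is exchangeable
  rev_pairs <- pairs
  rev_pairs$a_ids <- rev(pairs$a_ids)
  rev_pairs$b_ids <- rev(pairs$b_ids)
  expect_equal(bdmi_fitness_multiplier(kid, rev_pairs),
               bdmi_fitness_multiplier(kid, pairs))
  # recessive scheme: heterozygous carriers pay nothing
  rec <- pairs
  rec$dominance <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_equal(bdmi_fitness_multiplier(kid, rec), 1)
  hom_kid <- list(sex = "male", ploidy = 1L,
                  genomes = list(sort(c(pairs$a_ids, pairs$b_ids))),
                  registry = reg)
  # haploid carrier expresses fully (counts as homozygous)
  expect_equal(bdmi_fitness_multiplier(hom_kid, rec), (1 - 0.3)^2)
})

test_that("cost-0 BDMIs reproduce the base model bit-for-bit", {
  base_cfg <- preset("fig3B", system = "haplodiploid", N_pop = 40,
                     T_parental = 25, T_novel = 15, replicates = 2,
                     mu = 1e-6, seed = 17)
  bdmi_cfg <- preset("fig3B", system = "haplodiploid", N_pop = 40,
                     T_parental = 25, T_novel = 15, replicates = 2,
                     mu = 1e-6, seed = 17,
                     bdmi = bdmi_config(3, cost = 0))
  base <- run_scenario(base_cfg)
  with_bdmi <- run_scenario(bdmi_cfg)
  expect_identical(base$records, with_bdmi$records)
})

test_that("nonzero BDMI cost lowers early hybrid fitness", {
  base_cfg <- preset("fig3B", system = "diploid", N_pop = 40,
                     T_parental = 20, T_novel = 10, replicates = 3,
                     mu = 1e-6, seed = 18)
  costly <- preset("fig3B", system = "diploid", N_pop = 40,
                   T_parental = 20, T_novel = 10, replicates = 3,
                   mu = 1e-6, seed = 18,
                   bdmi = bdmi_config(4, cost = 0.4))
  base <- run_scenario(base_cfg)$records
  hit <- run_scenario(costly)$records
  early <- function(r) mean(r$mean_fitness_all[r$population == "H" &
                                                 r$generation %in% 21:25])
  expect_lt(early(hit), early(base))
})

test_that("demographic updates cap growth and declare extinction", {
  set.seed(21)
  s <- demography_settings(K = 100, growth_factor = 50,
                           extinction_threshold = 3)
  up <- demographic_update(100, s, Wbar = 1)
  expect_identical(up$N, 100L)  # capped at K
  expect_false(up$extinct)
  expect_true(demographic_update(100, s, Wbar = 0)$extinct)
  # isolated substream: the global RNG is untouched
  state <- fgmhybrid:::rng_substream(1, "demo")
  before <- .Random.seed
  upd <- demographic_update(50, s, Wbar = 0.5, state = state)
  expect_identical(.Random.seed, before)
  expect_false(identical(upd$state, state))
})

test_that("capped demography reproduces constant-size runs bit-for-bit", {
  base_cfg <- preset("fig2A", system = "diploid", N_pop = 40,
                     T_parental = 25, T_novel = 15, replicates = 2,
                     mu = 1e-6, seed = 23)
  demog_cfg <- preset("fig2A", system = "diploid", N_pop = 40,
                      T_parental = 25, T_novel = 15, replicates = 2,
                      mu = 1e-6, seed = 23,
                      demography = demography_settings(K = 40,
                                                      growth_factor = 500))
  base <- run_scenario(base_cfg)
  demog <- run_scenario(demog_cfg)
  expect_identical(base$records, demog$records)
  expect_true(all(lengths(demog$extinct) == 0))
})

test_that("severe shifts can drive populations extinct under demography", {
  cfg <- preset("fig3A", system = "diploid", N_pop = 40, T_parental = 15,
                T_novel = 30, replicates = 3, mu = 1e-6, seed = 29,
                demography = demography_settings(K = 40,
                                                 growth_factor = 1.05,
                                                 extinction_threshold = 5))
  run <- run_scenario(cfg)
  expect_gt(length(unlist(run$extinct)), 0)
  # extinct populations emit no further records
  for (r in seq_along(run$extinct)) {
    for (lab in run$extinct[[r]]) {
      sub <- run$records[run$records$replicate == r &
                           run$records$population == lab, ]
      expect_lt(max(sub$generation), 45)
    }
  }
})

test_that("parameter sweeps run every valid point and report failures", {
  grid <- data.frame(h = c(0.2, 0.8, 2))
  res <- sweep_scenarios("fig2A", grid, system = "diploid", N_pop = 16,
                         T_parental = 5, T_novel = 5, replicates = 1,
                         mu = 1e-7, seed = 31)
  expect_identical(nrow(res$errors), 1L)
  expect_match(res$errors$message, "dominance h")
  expect_setequal(unique(res$records$h), c(0.2, 0.8))
  expect_true(all(c("h", "replicate", "generation", "population",
                    "mean_fitness_all", "pi") %in% names(res$records)))
})
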