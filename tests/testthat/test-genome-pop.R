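test_that("gametes without recombination are verbatim parental copies", {
  reg <- new_registry(2)
  ids <- reg_add(reg, position = c(1e5, 5e5, 9e5),
                 effect = matrix(rnorm(6), 2), h = 0.5)
  parent <- list(sex = "female", ploidy = 2L,
                 genomes = list(ids[c(1, 3)], ids[2]), registry = reg)
  set.seed(1)
  for (i in 1:20) {
    g <- draw_gamete(parent, r_bp = 0, L = 1e6)
    expect_true(identical(g, ids[c(1, 3)]) || identical(g, ids[2]))
  }
})

test_that("crossover counts are Poisson with mean r_bp * L", {
  reg <- new_registry(2)
  # dense marker map so every crossover is observable
  pos <- seq(0, 1e6 - 1, length.out = 201)
  ids_a <- reg_add(reg, pos, matrix(0, 2, 201), h = 0.5)
  ids_b <- reg_add(reg, pos, matrix(0, 2, 201), h = 0.5)
  parent <- list(sex = "female", ploidy = 2L,
                 genomes = list(ids_a, ids_b), registry = reg)
  set.seed(402)
  n_gam <- 1e4
  switches <- vapply(seq_len(n_gam), function(i) {
    g <- draw_gamete(parent, r_bp = 1e-6, L = 1e6)
    sum(diff(g <= 201) != 0)  # source switches along the genome
  }, numeric(1))
  # observed switches undercount crossovers that fall between the same
  # marker pair an even number of times; with 200 intervals and mean 1
  # crossover the loss is below ~0.3%
  expect_lt(abs(mean(switches) - 1), 3 * sd(switches) / sqrt(n_gam) + 0.01)
})

test_that("a heterozygous site is transmitted to half the gametes", {
  lp <- single_locus_pop("diploid", 10, delta = c(0.1, 0), carriers = 1L)
  parent <- get_individual(lp$pop, 1L)
  set.seed(403)
  n_gam <- 1e4
  hits <- vapply(seq_len(n_gam), function(i) {
    lp$id %in% draw_gamete(parent, r_bp = 1e-6, L = 1e6)
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 3 * 0.5 / sqrt(n_gam))
})

test_that("new mutations arrive at rate mu * L and keep genomes sorted", {
  reg <- new_registry(3)
  set.seed(404)
  expect_identical(apply_new_mutations(integer(0), reg, mu = 0, L = 1e6),
                   integer(0))
  n_gam <- 2e4
  counts <- vapply(seq_len(n_gam), function(i) {
    length(apply_new_mutations(integer(0), reg, mu = 1e-8, L = 1e6))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 0.01), 3 * sqrt(0.01 / n_gam))
  pos <- reg_positions(reg)
  expect_true(all(pos[seq_len(reg$count)] >= 0 &
                    pos[seq_len(reg$count)] < 1e6))
  # insertion preserves position order
  g <- sort(reg_add(reg, c(2e5, 8e5), matrix(0, 3, 2), 0.5))
  set.seed(1)
  repeat {
    g2 <- apply_new_mutations(g, reg, mu = 5e-7, L = 1e6)
    if (length(g2) > length(g)) break
  }
  expect_true(!is.unsorted(reg_positions(reg)[g2]))
})

test_that("mutation application is deterministic under a fixed seed", {
  reg1 <- new_registry(2)
  set.seed(99)
  g1 <- apply_new_mutations(integer(0), reg1, mu = 5e-6, L = 1e6)
  reg2 <- new_registry(2)
  set.seed(99)
  g2 <- apply_new_mutations(integer(0), reg2, mu = 5e-6, L = 1e6)
  expect_identical(g1, g2)
  expect_identical(reg_positions(reg1)[g1], reg_positions(reg2)[g2])
})

test_that("one generation preserves size, sex ratio, and copy rules", {
  s <- fitness_surface(c(0.5, 0))
  for (system in c("diploid", "haplodiploid", "tetraploid")) {
    set.seed(405)
    pop <- new_population("P1", system, 31, list(mu = 1e-6), n_traits = 2)
    for (i in 1:5) pop <- next_generation(pop, s)
    expect_identical(length(pop$sex), 31L)
    expect_identical(sum(pop$sex == "female"), 16L)
    expect_identical(sum(pop$sex == "male"), 15L)
    expected_copies <- switch(system,
                              diploid = rep(2L, 31),
                              haplodiploid = ifelse(pop$sex == "female",
                                                    2L, 1L),
                              tetraploid = rep(4L, 31))
    expect_identical(pop$copies, as.integer(expected_copies))
    expect_identical(length(pop$genomes), sum(pop$copies))
    pos <- reg_positions(pop$registry)
    expect_true(all(vapply(pop$genomes,
                           function(g) !is.unsorted(pos[g]), logical(1))))
  }
})

test_that("reproduction is deterministic under a fixed seed", {
  s <- fitness_surface(c(1, 0))
  mk <- function() {
    set.seed(406)
    pop <- new_population("P1", "haplodiploid", 20, list(mu = 1e-6),
                          n_traits = 2)
    for (i in 1:10) pop <- next_generation(pop, s)
    pop
  }
  a <- mk()
  b <- mk()
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$sex, b$sex)
})

test_that("selection collapse raises an informative error", {
  pop <- new_population("P1", "diploid", 10, list(mu = 0), n_traits = 2)
  far <- fitness_surface(c(40, 0))  # exp(-1600) underflows to 0
  expect_error(next_generation(pop, far), "selection collapse")
})

test_that("allele frequencies count gene copies, not individuals", {
  # haplodiploid: 2 females (2 copies) + 2 males (1 copy) = 6 copies
  lp <- single_locus_pop("haplodiploid", 4, delta = c(0.1, 0),
                         carriers = 1L)
  expect_equal(freq_of(lp$pop, lp$id), 1 / 6)
  expect_equal(unname(allele_frequencies(lp$pop)[as.character(lp$id)]),
               1 / 6)
  # absent mutation: empty map
  empty <- new_population("P1", "diploid", 4, list(), n_traits = 2)
  expect_identical(length(allele_frequencies(empty)), 0L)
  # fixed in all copies
  lp2 <- single_locus_pop("diploid", 4, delta = c(0.1, 0), carriers = 8L)
  expect_equal(freq_of(lp2$pop, lp2$id), 1)
})

test_that("pruning folds jointly fixed mutations without moving phenotypes", {
  reg <- new_registry(2)
  P1 <- new_population("P1", "diploid", 6, list(), registry = reg)
  P2 <- new_population("P2", "diploid", 6, list(), registry = reg)
  shared <- reg_add(reg, 1e5, c(0.3, -0.1), h = 0.5)
  p1_only <- reg_add(reg, 2e5, c(0.2, 0.4), h = 0.5)
  P1$genomes <- rep(list(sort(c(shared, p1_only))), 12)
  P2$genomes <- rep(list(shared), 12)
  ph_before <- list(population_phenotypes(P1), population_phenotypes(P2))
  s <- fitness_surface(c(0.5, 0))
  w_before <- list(population_fitness(P1, s), population_fitness(P2, s))
  pruned <- fix_and_prune(list(P1 = P1, P2 = P2), mode = "joint")
  # fixed in P1 but absent in P2: must stay segregating in P1
  expect_true(p1_only %in% unlist(pruned$P1$genomes))
  # fixed in both: pruned everywhere, ledger updated, nothing moves
  expect_false(shared %in% unlist(pruned$P1$genomes))
  expect_true(shared %in% pruned$P1$substitutions)
  expect_equal(population_phenotypes(pruned$P1), ph_before[[1]])
  expect_equal(population_phenotypes(pruned$P2), ph_before[[2]])
  expect_equal(population_fitness(pruned$P1, s), w_before[[1]])
  expect_equal(population_fitness(pruned$P2, s), w_before[[2]])
  # per-population mode now prunes the P1-private fixation too
  solo <- fix_and_prune(list(pruned$P1), mode = "per_population")[[1]]
  expect_false(p1_only %in% unlist(solo$genomes))
  expect_equal(population_phenotypes(solo), ph_before[[1]])
  # substitutions never overlap segregating ids
  expect_length(intersect(solo$substitutions, unlist(solo$genomes)), 0)
})
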