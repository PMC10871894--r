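#' @useDynLib fgmhybrid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SYSTEMS <- c("diploid", "haplodiploid", "tetraploid")

system_code <- function(system) {
  code <- match(system, SYSTEMS)
  if (is.na(code)) stop("unknown genetic system '", system, "'")
  code - 1L
}

# Copies carried by an individual of a given sex under a genetic system.
copies_for <- function(system, sex) {
  switch(system,
         diploid = rep(2L, length(sex)),
         haplodiploid = ifelse(sex == "female", 2L, 1L),
         tetraploid = rep(4L, length(sex)))
}

#' Create a monomorphic population
#'
#' All individuals start with empty genomes and a phenotype equal to
#' `fixed_background` (the origin by default): no genetic variation.  The sex
#' ratio is 50:50 (`ceiling(N/2)` females).  Haplodiploid males carry one
#' genome copy, females two; diploids carry two; tetraploids four.
#'
#' @param label Population label (e.g. "P1", "P2", "H").
#' @param system One of `"diploid"`, `"haplodiploid"`, `"tetraploid"`.
#' @param N_pop Population size.
#' @param params List of rates: `L` (sites), `mu` (per-site mutation rate),
#'   `r_bp` (per-bp recombination rate), `lambda_mean`, `h`.
#' @param registry Shared [new_registry()]; created if missing.
#' @param n_traits Trait dimensionality (used if `registry` is missing).
#' @return An object of class `fgm_population`.
#' @export
new_population <- function(label, system, N_pop, params, registry = NULL,
                           n_traits = 5L) {
  system <- match.arg(system, SYSTEMS)
  N_pop <- as.integer(N_pop)
  stopifnot(N_pop >= 2L)
  if (is.null(registry)) registry <- new_registry(n_traits)
  sex <- rep(c("female", "male"), c(ceiling(N_pop / 2), floor(N_pop / 2)))
  copies <- copies_for(system, sex)
  genomes <- rep(list(integer(0)), sum(copies))
  defaults <- list(L = 1e6, mu = 1e-8, r_bp = 1e-6, lambda_mean = 0.2,
                   h = 0.5)
  params <- utils::modifyList(defaults, params[!vapply(params, is.null,
                                                       logical(1))])
  params$N_pop <- N_pop
  structure(list(label = label, system = system, sex = sex, copies = copies,
                 genomes = genomes,
                 fixed_background = numeric(registry$n_traits),
                 substitutions = integer(0), params = params,
                 registry = registry, generation = 0L),
            class = "fgm_population")
}

#' @export
print.fgm_population <- function(x, ...) {
  cat("<fgm_population>", x$label, x$system, "N =", length(x$sex),
      "generation", x$generation, "\n")
  cat("  segregating ids:", length(unique(unlist(x$genomes))),
      " substitutions:", length(x$substitutions), "\n")
  invisible(x)
}

pop_size <- function(pop) length(pop$sex)

# index of the first genome of individual i
genome_offsets <- function(pop) cumsum(c(0L, pop$copies))[seq_along(pop$copies)]

#' Extract one individual from a population
#'
#' @param pop An `fgm_population`.
#' @param i Individual index.
#' @return List with `sex`, `ploidy`, `genomes` (list of id vectors), and a
#'   reference to the shared registry.
#' @export
get_individual <- function(pop, i) {
  off <- genome_offsets(pop)[i]
  list(sex = pop$sex[i], ploidy = pop$copies[i],
       genomes = pop$genomes[off + seq_len(pop$copies[i])],
       registry = pop$registry)
}

#' Phenotypes of every individual
#'
#' @param pop An `fgm_population`.
#' @return Matrix (N x n_traits) of phenotypes.
#' @export
population_phenotypes <- function(pop) {
  cpp_phenotypes(pop$genomes, pop$copies, reg_effects(pop$registry),
                 reg_h(pop$registry), pop$fixed_background)
}

#' Fitness of every individual
#'
#' @param pop An `fgm_population`.
#' @param surface A [fitness_surface()], or `NULL` for a neutral (flat)
#'   surface where every individual has fitness 1.
#' @param bdmi Optional [bdmi_pairs()] whose incompatibility multiplier is
#'   applied on top of the environmental fitness.
#' @return Numeric vector of fitnesses.
#' @export
population_fitness <- function(pop, surface, bdmi = NULL) {
  w <- if (is.null(surface)) rep(1, pop_size(pop))
  else fgm_fitness(population_phenotypes(pop), surface)
  if (!is.null(bdmi)) w <- w * bdmi_multipliers(pop, bdmi)
  w
}

#' Draw one gamete from a parent
#'
#' Diploid parents recombine their two copies with a Poisson(`r_bp * L`)
#' number of crossovers at uniform positions, starting from a random copy.
#' Haploid parents transmit their single copy unchanged.  Tetraploid parents
#' pair their four copies into two random bivalents and return one
#' recombinant product from each, so the gamete is diploid (a list of two).
#'
#' @param parent An individual from [get_individual()].
#' @param r_bp Per-bp recombination rate.
#' @param L Genome length in sites.
#' @return For 1- and 2-copy parents an integer vector of mutation ids; for
#'   tetraploid parents a list of two such vectors.
#' @export
draw_gamete <- function(parent, r_bp, L) {
  pos <- reg_positions(parent$registry)
  if (parent$ploidy == 1L) {
    parent$genomes[[1L]]
  } else if (parent$ploidy == 2L) {
    cpp_meiosis_one(parent$genomes[[1L]], parent$genomes[[2L]], pos, r_bp, L)
  } else {
    ord <- sample.int(4L)
    list(cpp_meiosis_one(parent$genomes[[ord[1L]]], parent$genomes[[ord[2L]]],
                         pos, r_bp, L),
         cpp_meiosis_one(parent$genomes[[ord[3L]]], parent$genomes[[ord[4L]]],
                         pos, r_bp, L))
  }
}

#' Add new mutations to a gamete
#'
#' Poisson(`mu * L`) new mutations at uniform integer positions, each with an
#' effect from [draw_mutation_effect()].  A position already occupied simply
#' receives an additional, independent mutation record (stacking).
#'
#' @param gamete Integer vector of mutation ids (one haploid genome).
#' @param registry The run's [new_registry()].
#' @param mu Per-site mutation rate.
#' @param L Genome length.
#' @param lambda_mean,h Effect-law parameters.
#' @param generation,pop_label Origin metadata recorded in the registry.
#' @return The gamete with any new mutation ids inserted in position order.
#' @export
apply_new_mutations <- function(gamete, registry, mu, L, lambda_mean = 0.2,
                                h = 0.5, generation = 0L, pop_label = "") {
  k <- stats::rpois(1L, mu * L)
  if (k == 0L) return(gamete)
  newpos <- floor(stats::runif(k, 0, L))
  eff <- vapply(seq_len(k),
                function(i) draw_mutation_effect(registry$n_traits,
                                                 lambda_mean, h)$delta,
                numeric(registry$n_traits))
  ids <- reg_add(registry, newpos, eff, h = h,
                 origin_generation = generation, origin_population = pop_label)
  allpos <- reg_positions(registry)
  combined <- c(gamete, ids)
  combined[order(allpos[combined], combined)]
}

#' Advance a population by one Wright-Fisher generation
#'
#' Produces exactly `ceiling(N/2)` daughters and `floor(N/2)` sons (or the
#' counts implied by `n_offspring`).  Each offspring's mother is sampled with
#' probability proportional to female fitness and its father proportional to
#' male fitness, independently and with replacement.  Diploid and tetraploid
#' offspring unite one gamete from each parent; haplodiploid daughters unite
#' a maternal and a paternal gamete while sons develop from a single maternal
#' gamete (arrhenotoky).  Gametes recombine and mutate as described in
#' [draw_gamete()] and [apply_new_mutations()].
#'
#' @param pop An `fgm_population`.
#' @param surface A [fitness_surface()] or `NULL` for neutrality.
#' @param bdmi Optional [bdmi_pairs()] applied to fitness.
#' @param n_offspring Offspring count (defaults to the parent population
#'   size, i.e. constant-size reproduction).
#' @param fitness Optional precomputed fitness vector (skips the surface
#'   evaluation; used by the scenario runner to avoid recomputing
#'   phenotypes).
#' @return The next-generation `fgm_population`.
#' @export
next_generation <- function(pop, surface, bdmi = NULL, n_offspring = NULL,
                            fitness = NULL) {
  fit <- if (is.null(fitness)) population_fitness(pop, surface, bdmi)
  else fitness
  if (all(fit <= 0 | !is.finite(fit)))
    stop("selection collapse: all fitnesses are numerically zero in ",
         pop$label)
  N <- if (is.null(n_offspring)) pop$params$N_pop else as.integer(n_offspring)
  n_f <- as.integer(ceiling(N / 2))
  n_m <- as.integer(floor(N / 2))
  reg <- pop$registry
  out <- cpp_wf_generation(pop$genomes, pop$copies, pop$sex == "female", fit,
                           system_code(pop$system), n_f, n_m,
                           reg_positions(reg), reg$count, pop$params$r_bp,
                           pop$params$L, pop$params$mu,
                           pop$params$lambda_mean, reg$n_traits)
  if (length(out$new_positions) > 0L) {
    ids <- reg_add(reg, out$new_positions, out$new_effects,
                   h = pop$params$h,
                   origin_generation = pop$generation + 1L,
                   origin_population = pop$label)
    if (ids[length(ids)] != reg$count)
      stop("registry id mismatch after mutation append")
  }
  pop$sex <- c("male", "female")[out$female + 1L]
  pop$copies <- out$copies
  pop$genomes <- out$genomes
  pop$generation <- pop$generation + 1L
  pop
}

#' Allele frequencies of segregating mutations
#'
#' Frequency = carrying gene copies / total gene copies.  Haplodiploid totals
#' count two copies per female and one per male automatically, because each
#' carried genome is one gene copy.
#'
#' @param pop An `fgm_population`.
#' @param ids Optional ids to report (default: all present in the
#'   population).
#' @return Named numeric vector of frequencies (names = mutation ids).
#' @export
allele_frequencies <- function(pop, ids = NULL) {
  total <- sum(pop$copies)
  counts <- tabulate(unlist(pop$genomes, use.names = FALSE),
                     nbins = pop$registry$count)
  if (is.null(ids)) {
    present <- which(counts > 0L)
    stats::setNames(counts[present] / total, present)
  } else {
    stats::setNames(counts[ids] / total, ids)
  }
}

allele_counts <- function(pop) {
  tabulate(unlist(pop$genomes, use.names = FALSE), nbins = pop$registry$count)
}

#' Fold fixed mutations into the background
#'
#' A mutation fixed in a population contributes its full effect to every
#' individual; pruning removes it from the segregating genomes, adds it to
#' the substitution ledger, and folds its effect into `fixed_background`, so
#' no phenotype changes.  Before hybridization (`mode = "joint"`) a mutation
#' is pruned only if fixed in every population passed in, which keeps
#' lineage-specific fixed differences segregating so the hybrid can be
#' polymorphic for them.  After hybridization (`mode = "per_population"`)
#' pruning is independent per population.
#'
#' @param pops List of `fgm_population` objects sharing one registry.
#' @param mode `"joint"` or `"per_population"`.
#' @return The list of populations, pruned.
#' @export
fix_and_prune <- function(pops, mode = c("joint", "per_population")) {
  mode <- match.arg(mode)
  single <- inherits(pops, "fgm_population")
  if (single) pops <- list(pops)
  counts <- lapply(pops, allele_counts)
  totals <- vapply(pops, function(p) sum(p$copies), numeric(1))
  if (mode == "joint") {
    fixed_all <- Reduce(`&`, Map(function(cn, tot) cn == tot, counts, totals))
    fixed_ids <- list(which(fixed_all))
    fixed_ids <- rep(fixed_ids, length(pops))
  } else {
    fixed_ids <- Map(function(cn, tot) which(cn == tot), counts, totals)
  }
  pops <- Map(function(pop, ids) {
    if (length(ids) == 0L) return(pop)
    eff <- reg_effects(pop$registry)
    pop$fixed_background <- pop$fixed_background +
      rowSums(eff[, ids, drop = FALSE])
    drop <- logical(pop$registry$count)
    drop[ids] <- TRUE
    pop$genomes <- lapply(pop$genomes, function(g) g[!drop[g]])
    pop$substitutions <- sort(c(pop$substitutions, as.integer(ids)))
    pop
  }, pops, fixed_ids)
  if (single) pops[[1L]] else pops
}
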