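#' Configure intrinsic genetic incompatibilities
#'
#' Bateson-Dobzhansky-Muller incompatibilities (BDMIs) are pairwise,
#' environment-independent incompatibilities between a derived allele that
#' arose in P1 (locus a) and one that arose in P2 (locus b).  An individual
#' carrying both sides of a pair suffers a multiplicative fitness cost
#' `1 - cost * m(genotype)` per pair, where `m` is a cost multiplier per
#' joint genotype class; individuals carrying only one side pay nothing.
#'
#' @param n_pairs Number of incompatible locus pairs.
#' @param cost Per-pair fitness cost in `[0, 1]`.
#' @param dominance Either a 2x2 numeric matrix of multipliers indexed by
#'   carrier status (rows: locus a het/hom, columns: locus b het/hom; a
#'   haploid carrier counts as hom), or one of `"dominant"` (any
#'   co-occurrence pays the full cost), `"recessive"` (only the double
#'   homozygote pays), `"partial"` (cost scales with the product of allele
#'   dosages).
#' @return An object of class `bdmi_config`.
#' @export
bdmi_config <- function(n_pairs = 1L, cost = 0.1, dominance = "dominant") {
  stopifnot(n_pairs >= 1, cost >= 0, cost <= 1)
  if (is.character(dominance)) {
    dominance <- switch(match.arg(dominance,
                                  c("dominant", "recessive", "partial")),
                        dominant = matrix(1, 2, 2),
                        recessive = matrix(c(0, 0, 0, 1), 2, 2),
                        partial = matrix(c(0.25, 0.5, 0.5, 1), 2, 2))
  }
  dominance <- matrix(as.numeric(dominance), 2, 2)
  dimnames(dominance) <- list(a = c("het", "hom"), b = c("het", "hom"))
  structure(list(n_pairs = as.integer(n_pairs), cost = cost,
                 dominance = dominance, a_ids = NULL, b_ids = NULL),
            class = "bdmi_config")
}

#' Seed BDMI marker loci as fixed differences between the parents
#'
#' Injects, for each pair, a phenotypically neutral marker mutation fixed in
#' every genome of P1 (locus a) and another fixed in every genome of P2
#' (locus b), at deterministic evenly spaced genomic positions.  In either
#' pure parent only one side of each pair is present, so parental fitness is
#' unaffected: the incompatibilities are intrinsic and only expressed when
#' hybridization combines the two sides.
#'
#' @param P1,P2 Parental populations sharing a registry.
#' @param pairs A [bdmi_config()].
#' @return List with the modified `P1`, `P2`, and the seeded `pairs`
#'   (carrying `a_ids` / `b_ids`).
#' @export
seed_bdmi_markers <- function(P1, P2, pairs) {
  reg <- P1$registry
  k <- pairs$n_pairs
  L <- P1$params$L
  positions <- floor(L * (seq_len(2L * k) - 0.5) / (2L * k))
  eff <- matrix(0, reg$n_traits, 2L * k)
  ids <- reg_add(reg, positions, eff, h = 0.5,
                 origin_generation = P1$generation,
                 origin_population = "bdmi")
  pairs$a_ids <- ids[seq_len(k) * 2L - 1L]
  pairs$b_ids <- ids[seq_len(k) * 2L]
  insert_ids <- function(genomes, add) {
    pos <- reg_positions(reg)
    lapply(genomes, function(g) {
      combined <- c(g, add)
      combined[order(pos[combined], combined)]
    })
  }
  P1$genomes <- insert_ids(P1$genomes, pairs$a_ids)
  P2$genomes <- insert_ids(P2$genomes, pairs$b_ids)
  list(P1 = P1, P2 = P2, pairs = pairs)
}

bdmi_marker_ids <- function(pairs) {
  if (is.null(pairs)) NULL else c(pairs$a_ids, pairs$b_ids)
}

# Carrier status per pair side: 0 absent, 1 het (partial dosage), 2 hom
# (all carried copies, incl. the haploid single copy).
bdmi_status <- function(count, ploidy) {
  ifelse(count == 0L, 0L, ifelse(count == ploidy, 2L, 1L))
}

# Vectorized incompatibility multipliers for a whole population.
bdmi_multipliers <- function(pop, pairs) {
  N <- pop_size(pop)
  if (is.null(pairs) || is.null(pairs$a_ids)) return(rep(1, N))
  ids <- c(pairs$a_ids, pairs$b_ids)
  memb <- vapply(pop$genomes, function(g) ids %in% g, logical(length(ids)))
  memb <- matrix(memb, nrow = length(ids))
  gi <- rep(seq_len(N), pop$copies)
  cnt <- rowsum(t(memb) * 1, gi)  # N x ids
  k <- pairs$n_pairs
  mult <- rep(1, N)
  for (p in seq_len(k)) {
    sa <- bdmi_status(cnt[, p], pop$copies)
    sb <- bdmi_status(cnt[, k + p], pop$copies)
    both <- sa > 0L & sb > 0L
    if (any(both)) {
      m <- pairs$dominance[cbind(sa[both], sb[both])]
      mult[both] <- mult[both] * (1 - pairs$cost * m)
    }
  }
  mult
}

#' Incompatibility fitness multiplier for one individual
#'
#' Multiplicative across pairs: `prod(1 - cost * m(genotype))`, with `m`
#' from the dominance matrix.  Haploid males express carried alleles fully
#' (single copy counts as homozygous); an individual carrying only one side
#' of a pair suffers no cost.
#'
#' @param ind An individual from [get_individual()].
#' @param pairs A seeded [bdmi_config()].
#' @return Multiplier in `[0, 1]`.
#' @export
bdmi_fitness_multiplier <- function(ind, pairs) {
  if (is.null(pairs) || is.null(pairs$a_ids)) return(1)
  counts <- function(id) sum(vapply(ind$genomes, function(g) id %in% g,
                                    logical(1)))
  mult <- 1
  for (p in seq_len(pairs$n_pairs)) {
    sa <- bdmi_status(counts(pairs$a_ids[p]), ind$ploidy)
    sb <- bdmi_status(counts(pairs$b_ids[p]), ind$ploidy)
    if (sa > 0L && sb > 0L)
      mult <- mult * (1 - pairs$cost * pairs$dominance[sa, sb])
  }
  mult
}

#' Demography settings
#'
#' Optional demographic mode: each generation the next population size is
#' drawn as `Poisson(N * Wbar * growth_factor)` truncated at the carrying
#' capacity `K`; the population is declared extinct when the size falls to
#' `extinction_threshold` or below.
#'
#' @param K Carrying capacity.
#' @param growth_factor Per-capita fecundity scale (> 0).
#' @param extinction_threshold Size at or below which the population is
#'   extinct (default 3: below the minimum for two-sex reproduction).
#' @return An object of class `demography_settings`.
#' @export
demography_settings <- function(K, growth_factor = 2,
                                extinction_threshold = 3L) {
  stopifnot(growth_factor > 0, extinction_threshold >= 0,
            K >= extinction_threshold)
  structure(list(K = as.integer(K), growth_factor = growth_factor,
                 extinction_threshold = as.integer(extinction_threshold)),
            class = "demography_settings")
}

#' One demographic update
#'
#' @param N Current population size.
#' @param settings A [demography_settings()].
#' @param Wbar Current mean fitness in `[0, 1]`.
#' @param state Optional isolated RNG substream state (see the scenario
#'   runner); when `NULL` the global RNG is used.
#' @return List with the next size `N`, an `extinct` flag, and the advanced
#'   substream `state`.
#' @export
demographic_update <- function(N, settings, Wbar, state = NULL) {
  stopifnot(Wbar >= 0, Wbar <= 1)
  lambda <- N * Wbar * settings$growth_factor
  if (is.null(state)) {
    X <- stats::rpois(1L, lambda)
    new_state <- NULL
  } else {
    out <- with_rng_state(state, stats::rpois(1L, lambda))
    X <- out$value
    new_state <- out$state
  }
  size <- min(settings$K, X)
  list(N = as.integer(size), extinct = size <= settings$extinction_threshold,
       state = new_state)
}

#' Run a parameter sweep
#'
#' Runs a scenario at every row of a parameter grid (columns among
#' `h`, `lambda_mean`, `n`, `shape`, `system`, `N_pop`, `r_bp`,
#' `T_parental`, `T_novel`, `replicates`), each with an independent derived
#' seed, and returns one tidy record table keyed by the grid parameters.
#' Invalid grid points produce a per-point error entry; the sweep continues.
#'
#' @param preset_name Preset passed to [preset()] for every grid point.
#' @param grid Data frame of parameter combinations.
#' @param ... Common overrides applied to every point.
#' @return List with `records` (all points, grid columns prepended) and
#'   `errors` (data frame of failed points and messages).
#' @export
sweep_scenarios <- function(preset_name, grid, ...) {
  common <- list(...)
  seeds <- derive_seeds(if (!is.null(common$seed)) common$seed else 1L,
                        nrow(grid))
  all_records <- list()
  errors <- list()
  for (i in seq_len(nrow(grid))) {
    point <- as.list(grid[i, , drop = FALSE])
    args <- utils::modifyList(common, point)
    args$seed <- seeds[i]
    res <- tryCatch({
      cfg <- do.call(preset, c(list(name = preset_name), args))
      run <- run_scenario(cfg)
      rec <- run$records
      for (nm in rev(names(point))) rec[[nm]] <- point[[nm]]
      rec[, c(names(point), setdiff(names(rec), names(point)))]
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(point = i, message = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      all_records[[length(all_records) + 1L]] <- res
    }
  }
  list(records = if (length(all_records)) do.call(rbind, all_records)
       else NULL,
       errors = if (length(errors)) do.call(rbind, errors)
       else data.frame(point = integer(0), message = character(0)))
}
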