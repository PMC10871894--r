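#' Optimum schedule
#'
#' Per-population list of change points `(generation, optimum)`.  The
#' optimum in force at generation g is the one from the latest change point
#' with `generation <= g`.  A population missing from the schedule falls
#' back to P1's entries.
#'
#' @param ... Named per-population lists, each a list of
#'   `list(generation =, optimum =)` entries with strictly increasing
#'   generations.
#' @return An object of class `optimum_schedule`.
#' @export
optimum_schedule <- function(...) {
  sched <- list(...)
  if (length(sched) == 1L && is.null(names(sched)) && is.list(sched[[1L]]) &&
      !is.null(names(sched[[1L]])))
    sched <- sched[[1L]]
  for (label in names(sched)) {
    gens <- vapply(sched[[label]], function(e) as.numeric(e$generation),
                   numeric(1))
    if (any(diff(gens) <= 0))
      stop("schedule for ", label,
           " must have strictly increasing generations")
  }
  structure(sched, class = "optimum_schedule")
}

schedule_optimum <- function(schedule, label, generation) {
  entries <- schedule[[label]]
  if (is.null(entries)) entries <- schedule[["P1"]]
  if (is.null(entries)) stop("schedule has no entries for ", label)
  gens <- vapply(entries, function(e) as.numeric(e$generation), numeric(1))
  ok <- which(gens <= generation)
  if (length(ok) == 0L)
    stop("schedule for ", label, " defines no optimum at generation ",
         generation, " (a generation-0 optimum is required)")
  entries[[max(ok)]]$optimum
}

surface_for <- function(config, label, generation) {
  fitness_surface(schedule_optimum(config$schedule, label, generation),
                  shape = config$shape)
}

#' Scenario configuration
#'
#' Bundles every parameter of a two-phase adaptation scenario.  Defaults per
#' genetic system: diploid `N_pop = 1500`, `r_bp = 2/3e-6`; haplodiploid
#' `N_pop = 2000`, `r_bp = 1e-6` (scaled for comparable effective sizes and
#' recombination rates); tetraploid `N_pop = 750`, `r_bp = 1e-6` (matching
#' gene-copy number).  Shared defaults: `L = 1e6` sites, `mu = 1e-8` per
#' site, `n = 5` trait dimensions, `lambda_mean = 0.2`, `h = 0.5`,
#' `shape = 1`, `T_parental = 1500`, `T_novel = 1000`, `replicates = 100`.
#'
#' @param system Genetic system.
#' @param schedule An [optimum_schedule()].
#' @param N_pop,L,mu,r_bp,n,lambda_mean,h,shape Model parameters (see
#'   above).
#' @param T_parental,T_novel Generations of the two phases.
#' @param replicates Number of replicate simulations.
#' @param bdmi Optional [bdmi_config()].
#' @param demography Optional [demography_settings()] (applied during the
#'   novel phase).
#' @param seed Root seed; per-replicate seeds are derived from it.
#' @param prune_every Generations between substitution-pruning sweeps.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(system = c("diploid", "haplodiploid",
                                       "tetraploid"),
                            schedule, N_pop = NULL, L = 1e6, mu = 1e-8,
                            r_bp = NULL, n = 5L, lambda_mean = 0.2, h = 0.5,
                            shape = 1, T_parental = 1500L, T_novel = 1000L,
                            replicates = 100L, bdmi = NULL,
                            demography = NULL, seed = 1L,
                            prune_every = 20L) {
  system <- match.arg(system)
  if (is.null(N_pop))
    N_pop <- switch(system, diploid = 1500L, haplodiploid = 2000L,
                    tetraploid = 750L)
  if (is.null(r_bp))
    r_bp <- switch(system, diploid = 2 / 3 * 1e-6, haplodiploid = 1e-6,
                   tetraploid = 1e-6)
  if (!inherits(schedule, "optimum_schedule"))
    schedule <- optimum_schedule(schedule)
  cfg <- list(system = system, N_pop = as.integer(N_pop), L = L, mu = mu,
              r_bp = r_bp, n = as.integer(n), lambda_mean = lambda_mean,
              h = h, shape = shape, schedule = schedule,
              T_parental = as.integer(T_parental),
              T_novel = as.integer(T_novel),
              replicates = as.integer(replicates), bdmi = bdmi,
              demography = demography, seed = as.integer(seed),
              prune_every = as.integer(prune_every))
  validate_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_config <- function(cfg) {
  if (cfg$mu < 0) stop("mutation rate mu must be nonnegative")
  if (cfg$r_bp < 0) stop("recombination rate r_bp must be nonnegative")
  if (cfg$lambda_mean <= 0) stop("lambda_mean must be positive")
  if (cfg$h < 0 || cfg$h > 1) stop("dominance h must be in [0, 1]")
  if (cfg$shape <= 0) stop("shape q must be positive")
  if (cfg$n < 1) stop("trait dimensionality n must be >= 1")
  if (cfg$N_pop < 4) stop("N_pop must be at least 4")
  if (cfg$T_parental < 1 || cfg$T_novel < 1)
    stop("T_parental and T_novel must be >= 1")
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  for (lab in names(cfg$schedule))
    for (e in cfg$schedule[[lab]])
      if (length(e$optimum) != cfg$n)
        stop("schedule optimum for ", lab, " has length ",
             length(e$optimum), ", expected n = ", cfg$n)
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$system, "N_pop =", x$N_pop,
      "T =", x$T_parental, "+", x$T_novel, "gens,",
      x$replicates, "replicates\n")
  invisible(x)
}

PRESET_OPTIMA <- list(
  fig2A = list(P1 = c(1, 0, 0, 0, 0), P2 = c(1, 0, 0, 0, 0),
               novel = c(2, 0, 0, 0, 0)),
  fig2B = list(P1 = c(3, 0, 0, 0, 0), P2 = c(3, 0, 0, 0, 0),
               novel = c(2, 0, 0, 0, 0)),
  fig2C = list(P1 = c(3, 0, 0, 0, 0), P2 = c(3, 0, 0, 0, 0),
               novel = c(2.5, 0, 0, 0, 0)),
  fig3A = list(P1 = c(3, 0, 0, 0, 0), P2 = c(3, 0, 0, 0, 0),
               novel = c(0, 2, 0, 0, 0)),
  fig3B = list(P1 = c(2, 0, 0, 0, 0), P2 = c(0, 2, 0, 0, 0),
               novel = c(2, 2, 0, 0, 0)),
  fig3C = list(P1 = c(2, 0, 0, 0, 0), P2 = c(0, 2, 0, 0, 0),
               novel = c(0, 0, 2, 0, 0)))

#' Preset scenarios
#'
#' The six optimum-shift scenarios: parents adapt for `T_parental`
#' generations to their initial optima, after which a single novel optimum
#' applies to parents and hybrid alike.
#'
#' * `fig2A`: both parents at `{1,0,0,0,0}`, novel `{2,0,0,0,0}`
#' * `fig2B`: both parents at `{3,0,0,0,0}`, novel `{2,0,0,0,0}`
#' * `fig2C`: both parents at `{3,0,0,0,0}`, novel `{2.5,0,0,0,0}`
#' * `fig3A`: both parents at `{3,0,0,0,0}`, novel `{0,2,0,0,0}`
#' * `fig3B`: P1 `{2,0,0,0,0}`, P2 `{0,2,0,0,0}`, novel `{2,2,0,0,0}`
#' * `fig3C`: P1 `{2,0,0,0,0}`, P2 `{0,2,0,0,0}`, novel `{0,0,2,0,0}`
#'
#' @param name Preset name.
#' @param system Genetic system (sets `N_pop` and `r_bp` defaults).
#' @param ... Overrides passed to [scenario_config()] (e.g. scaled-down
#'   `N_pop`, `T_parental`, `replicates`).
#' @return A [scenario_config()].
#' @export
preset <- function(name, system = "diploid", ...) {
  if (length(name) != 1L || !name %in% names(PRESET_OPTIMA))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(PRESET_OPTIMA), collapse = ", "))
  opt <- PRESET_OPTIMA[[name]]
  dots <- list(...)
  T_parental <- if (!is.null(dots$T_parental)) as.integer(dots$T_parental)
  else 1500L
  schedule <- optimum_schedule(
    P1 = list(list(generation = 0L, optimum = opt$P1),
              list(generation = T_parental, optimum = opt$novel)),
    P2 = list(list(generation = 0L, optimum = opt$P2),
              list(generation = T_parental, optimum = opt$novel)),
    H = list(list(generation = T_parental, optimum = opt$novel)))
  do.call(scenario_config,
          c(list(system = system, schedule = schedule), dots))
}

#' List the preset scenarios
#'
#' @return Data frame with one row per preset and its optimum schedule.
#' @export
list_presets <- function() {
  fmt <- function(v) paste0("{", paste(v, collapse = ","), "}")
  data.frame(preset = names(PRESET_OPTIMA),
             P1_optimum = vapply(PRESET_OPTIMA, function(o) fmt(o$P1), ""),
             P2_optimum = vapply(PRESET_OPTIMA, function(o) fmt(o$P2), ""),
             novel_optimum = vapply(PRESET_OPTIMA, function(o) fmt(o$novel),
                                    ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

pop_params <- function(config) {
  list(L = config$L, mu = config$mu, r_bp = config$r_bp,
       lambda_mean = config$lambda_mean, h = config$h)
}

# Advance `pop` from its current generation to `to_gen`, recording every
# generation.  Selection producing generation g uses the optimum in force at
# generation g - 1 (the environment the parents experienced); the record at
# generation g uses the optimum at g.
advance_and_record <- function(pop, config, to_gen, replicate, records,
                               bdmi = NULL) {
  ph <- population_phenotypes(pop)
  while (pop$generation < to_gen) {
    s_sel <- surface_for(config, pop$label, pop$generation)
    w <- phenotype_fitness(ph, s_sel, pop, bdmi)
    pop <- next_generation(pop, s_sel, bdmi = bdmi, fitness = w)
    ph <- population_phenotypes(pop)
    s_now <- surface_for(config, pop$label, pop$generation)
    records[[length(records) + 1L]] <-
      record_row(pop, s_now, replicate, bdmi = bdmi,
                 fitness = phenotype_fitness(ph, s_now, pop, bdmi))
  }
  list(pop = pop, records = records)
}

phenotype_fitness <- function(ph, surface, pop, bdmi = NULL) {
  w <- if (is.null(surface)) rep(1, nrow(ph)) else fgm_fitness(ph, surface)
  if (!is.null(bdmi)) w <- w * bdmi_multipliers(pop, bdmi)
  w
}

#' Run the parental phase of a scenario
#'
#' Two allopatric parental populations start genetically identical
#' (monomorphic, every phenotype at the origin) and evolve independently for
#' `T_parental` generations toward the optima of their schedules.  Records
#' are emitted every generation; jointly fixed mutations are pruned
#' periodically.
#'
#' @param config A [scenario_config()].
#' @param replicate Replicate index recorded in the output.
#' @return List with populations `P1`, `P2`, the shared `registry`, and the
#'   accumulated `records` (list of one-row data frames).
#' @export
run_parental_phase <- function(config, replicate = 1L) {
  registry <- new_registry(config$n)
  pops <- lapply(c("P1", "P2"), function(lab) {
    new_population(lab, config$system, config$N_pop, pop_params(config),
                   registry = registry)
  })
  names(pops) <- c("P1", "P2")
  records <- list()
  for (lab in names(pops))
    records[[length(records) + 1L]] <-
      record_row(pops[[lab]], surface_for(config, lab, 0L), replicate)
  g <- 0L
  while (g < config$T_parental) {
    step_to <- min(g + config$prune_every, config$T_parental)
    for (lab in names(pops)) {
      out <- advance_and_record(pops[[lab]], config, step_to, replicate,
                                records)
      pops[[lab]] <- out$pop
      records <- out$records
    }
    pops <- fix_and_prune(pops, mode = "joint")
    g <- step_to
  }
  list(P1 = pops$P1, P2 = pops$P2, registry = registry, records = records)
}

#' Create the hybrid population
#'
#' The hybrid H is founded by `N_pop / 4` females and `N_pop / 4` males
#' sampled uniformly without replacement from each parent (so exactly
#' `N_pop / 2` descendants of each parent, 50:50 sexes and ancestries).
#' Founders are copies: no mutable state is shared, and no further gene flow
#' occurs afterwards -- subsequent generations mate at random within H.
#'
#' @param P1,P2 Parental `fgm_population` objects with identical system and
#'   parameters.
#' @return An `fgm_population` labelled `"H"` with an `ancestry` attribute
#'   giving each founder's source population.
#' @export
create_hybrid_population <- function(P1, P2) {
  if (!identical(P1$system, P2$system))
    stop("parent populations have different genetic systems")
  if (pop_size(P1) != pop_size(P2))
    stop("parent populations have different sizes")
  if (!identical(P1$registry, P2$registry))
    stop("parent populations do not share a mutation registry")
  if (!isTRUE(all.equal(P1$fixed_background, P2$fixed_background)))
    stop("parental fixed backgrounds differ; prune jointly before ",
         "hybridization")
  N <- pop_size(P1)
  if (N %% 4L != 0L)
    stop("N_pop must be divisible by 4 to found a 50:50 hybrid population")
  q <- N %/% 4L
  take <- function(pop, sex) sort(sample(which(pop$sex == sex), q))
  founders <- list(list(pop = P1, idx = take(P1, "female")),
                   list(pop = P2, idx = take(P2, "female")),
                   list(pop = P1, idx = take(P1, "male")),
                   list(pop = P2, idx = take(P2, "male")))
  sex <- character(0); copies <- integer(0); genomes <- list()
  ancestry <- character(0)
  for (f in founders) {
    off <- genome_offsets(f$pop)
    for (i in f$idx) {
      sex <- c(sex, f$pop$sex[i])
      copies <- c(copies, f$pop$copies[i])
      genomes <- c(genomes, f$pop$genomes[off[i] + seq_len(f$pop$copies[i])])
      ancestry <- c(ancestry, f$pop$label)
    }
  }
  H <- P1
  H$label <- "H"
  H$sex <- sex
  H$copies <- copies
  H$genomes <- genomes
  H$substitutions <- P1$substitutions
  attr(H, "ancestry") <- ancestry
  H
}

#' Run the novel-environment phase
#'
#' All three populations face the same novel optimum from generation
#' `T_parental` on and evolve independently for `T_novel` generations.
#' Pruning is per-population.  With [demography_settings()], each
#' population's next size is drawn from its current mean fitness (on an
#' isolated RNG substream, so constant-size reproduction is untouched) and
#' extinct populations stop emitting records.
#'
#' @param P1,P2,H Populations at generation `T_parental`.
#' @param config The [scenario_config()].
#' @param replicate Replicate index.
#' @param records Record list to append to.
#' @param bdmi Optional seeded [bdmi_pairs] (see [seed_bdmi_markers()]).
#' @return List with the final populations, `records`, and an `extinct`
#'   character vector of extinct population labels.
#' @export
run_novel_phase <- function(P1, P2, H, config, replicate = 1L,
                            records = list(), bdmi = NULL) {
  pops <- list(P1 = P1, P2 = P2, H = H)
  extinct <- character(0)
  demog <- config$demography
  demog_state <- if (!is.null(demog))
    lapply(pops, function(p) rng_substream(config$seed + 7919L * replicate,
                                           p$label))
  T_end <- config$T_parental + config$T_novel
  g <- config$T_parental
  while (g < T_end) {
    step_to <- min(g + config$prune_every, T_end)
    for (lab in names(pops)) {
      if (lab %in% extinct) next
      pop <- pops[[lab]]
      ph <- population_phenotypes(pop)
      while (pop$generation < step_to) {
        s_sel <- surface_for(config, lab, pop$generation)
        w_sel <- phenotype_fitness(ph, s_sel, pop, bdmi)
        n_off <- NULL
        if (!is.null(demog)) {
          upd <- demographic_update(pop_size(pop), demog, mean(w_sel),
                                    demog_state[[lab]])
          demog_state[[lab]] <- upd$state
          if (upd$extinct) {
            extinct <- c(extinct, lab)
            break
          }
          n_off <- upd$N
          pop$params$N_pop <- n_off
        }
        pop <- next_generation(pop, s_sel, bdmi = bdmi,
                               n_offspring = n_off, fitness = w_sel)
        ph <- population_phenotypes(pop)
        s_now <- surface_for(config, lab, pop$generation)
        records[[length(records) + 1L]] <-
          record_row(pop, s_now, replicate, bdmi = bdmi,
                     fitness = phenotype_fitness(ph, s_now, pop, bdmi))
      }
      pops[[lab]] <- pop
    }
    alive <- setdiff(names(pops), extinct)
    pops[alive] <- fix_and_prune(pops[alive], mode = "per_population")
    g <- step_to
  }
  list(P1 = pops$P1, P2 = pops$P2, H = pops$H, records = records,
       extinct = extinct)
}

#' Run one replicate of a scenario
#'
#' Executes the full two-phase design: parental adaptation, hybrid creation
#' at generation `T_parental` (with records for all three populations at the
#' creation generation under the novel optimum), and the novel phase.
#'
#' @param config A [scenario_config()].
#' @param replicate Replicate index.
#' @param seed Seed for this replicate (defaults to a value derived from
#'   `config$seed`).
#' @param keep_populations Return the final population objects too.
#' @return List with `records` (data frame, rates filled in) and optionally
#'   `populations`, `extinct`.
#' @export
run_replicate <- function(config, replicate = 1L, seed = NULL,
                          keep_populations = FALSE) {
  if (is.null(seed)) seed <- derive_seeds(config$seed,
                                          config$replicates)[replicate]
  set.seed(seed)
  par <- run_parental_phase(config, replicate)
  pops <- fix_and_prune(list(P1 = par$P1, P2 = par$P2), mode = "joint")
  bdmi <- NULL
  if (!is.null(config$bdmi)) {
    seeded <- seed_bdmi_markers(pops$P1, pops$P2, config$bdmi)
    pops$P1 <- seeded$P1
    pops$P2 <- seeded$P2
    bdmi <- seeded$pairs
  }
  H <- create_hybrid_population(pops$P1, pops$P2)
  records <- par$records
  records[[length(records) + 1L]] <-
    record_row(H, surface_for(config, "H", H$generation), replicate,
               bdmi = bdmi)
  nov <- run_novel_phase(pops$P1, pops$P2, H, config, replicate, records,
                         bdmi = bdmi)
  records <- finalize_records(records_to_df(nov$records))
  out <- list(records = records, extinct = nov$extinct, seed = seed)
  if (keep_populations)
    out$populations <- list(P1 = nov$P1, P2 = nov$P2, H = nov$H)
  out
}

#' Derive per-replicate seeds from a root seed
#'
#' @param root_seed Root seed.
#' @param n Number of replicates.
#' @return Integer vector of derived seeds (all below 2^31).
#' @export
derive_seeds <- function(root_seed, n) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(root_seed)
  sample.int(.Machine$integer.max, n)
}

#' Run a full scenario over replicates
#'
#' @param config A [scenario_config()].
#' @param replicates Override of `config$replicates`.
#' @return List of class `fgm_run` with `records` (all replicates, rates
#'   filled), `config`, `seeds`, and `extinct` (per-replicate list).
#' @export
run_scenario <- function(config, replicates = config$replicates) {
  seeds <- derive_seeds(config$seed, replicates)
  reps <- lapply(seq_len(replicates), function(r) {
    run_replicate(config, replicate = r, seed = seeds[r])
  })
  records <- do.call(rbind, lapply(reps, `[[`, "records"))
  rownames(records) <- NULL
  structure(list(records = records, config = config, seeds = seeds,
                 extinct = lapply(reps, `[[`, "extinct")),
            class = "fgm_run")
}

#' @export
print.fgm_run <- function(x, ...) {
  cat("<fgm_run>", length(x$seeds), "replicates,", nrow(x$records),
      "records\n")
  invisible(x)
}
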