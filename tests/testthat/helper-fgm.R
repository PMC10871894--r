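# Shared builders for the test suite.  Everything is generated in code; no
# stored fixtures.

# A population with a single segregating mutation inserted into `carriers`
# of its gene copies (chosen from the first genomes).  delta is the
# full-expression effect vector; the registry is fresh.
single_locus_pop <- function(system, N, delta, h = 0.5, carriers = 1L,
                             params = list(mu = 0, r_bp = 0)) {
  reg <- new_registry(length(delta))
  pop <- new_population("P1", system, N, params, registry = reg)
  id <- reg_add(reg, position = 5e5, effect = delta, h = h)
  for (g in seq_len(carriers)) pop$genomes[[g]] <- id
  list(pop = pop, id = id, registry = reg)
}

# Frequency of one mutation id.
freq_of <- function(pop, id) {
  unname(allele_frequencies(pop, ids = id))
}

# Independent single-locus Wright-Fisher fixation oracles: the same
# two-sex, fitness-proportional breeding structure as the simulator, but
# implemented directly on genotype counts (no genomes, no recombination
# machinery), vectorized across trials.  Multinomial offspring classes are
# drawn as sequential binomials.
oracle_fixation_diploid <- function(n_trials, N, s_hom, s_het) {
  nf <- N %/% 2L
  nm <- N - nf
  w_hom <- 1 + s_hom
  w_het <- 1 + s_het
  # one mutant copy in a uniformly chosen gene copy
  in_female <- stats::runif(n_trials) < 0.5
  hetf <- as.integer(in_female); homf <- integer(n_trials)
  hetm <- as.integer(!in_female); homm <- integer(n_trials)
  fixed <- rep(NA_integer_, n_trials)
  active <- seq_len(n_trials)
  while (length(active)) {
    hf <- homf[active]; ef <- hetf[active]
    hm <- homm[active]; em <- hetm[active]
    pm <- (hf * w_hom + 0.5 * ef * w_het) /
      (hf * w_hom + ef * w_het + (nf - hf - ef))
    pp <- (hm * w_hom + 0.5 * em * w_het) /
      (hm * w_hom + em * w_het + (nm - hm - em))
    p_hom <- pm * pp
    p_het <- pm + pp - 2 * pm * pp
    clamp <- function(p) pmin(pmax(p, 0), 1)
    draw <- function(n_off) {
      hom <- stats::rbinom(length(active), n_off, clamp(p_hom))
      het <- stats::rbinom(length(active), n_off - hom,
                           clamp(ifelse(p_hom < 1,
                                        p_het / (1 - p_hom), 0)))
      list(hom = hom, het = het)
    }
    dg <- draw(nf); sn <- draw(nm)
    homf[active] <- dg$hom; hetf[active] <- dg$het
    homm[active] <- sn$hom; hetm[active] <- sn$het
    copies <- 2 * dg$hom + dg$het + 2 * sn$hom + sn$het
    lost <- copies == 0L
    fix <- copies == 2L * N
    fixed[active[lost]] <- 0L
    fixed[active[fix]] <- 1L
    active <- active[!(lost | fix)]
  }
  fixed
}

oracle_fixation_haplodiploid <- function(n_trials, N, s_hom, s_het) {
  nf <- N %/% 2L
  nm <- N - nf
  w_hom <- 1 + s_hom
  w_het <- 1 + s_het
  w_m <- 1 + s_hom  # haploid males express fully
  in_female <- stats::runif(n_trials) < 2 / 3  # 2 of 3 copies are female
  hetf <- as.integer(in_female); homf <- integer(n_trials)
  carm <- as.integer(!in_female)
  fixed <- rep(NA_integer_, n_trials)
  active <- seq_len(n_trials)
  while (length(active)) {
    hf <- homf[active]; ef <- hetf[active]; m <- carm[active]
    pm <- (hf * w_hom + 0.5 * ef * w_het) /
      (hf * w_hom + ef * w_het + (nf - hf - ef))
    pp <- m * w_m / (m * w_m + (nm - m))  # fathers transmit verbatim
    p_hom <- pm * pp
    p_het <- pm + pp - 2 * pm * pp
    clamp <- function(p) pmin(pmax(p, 0), 1)
    hom <- stats::rbinom(length(active), nf, clamp(p_hom))
    het <- stats::rbinom(length(active), nf - hom,
                         clamp(ifelse(p_hom < 1,
                                      p_het / (1 - p_hom), 0)))
    sons <- stats::rbinom(length(active), nm, clamp(pm)) # maternal only
    homf[active] <- hom; hetf[active] <- het; carm[active] <- sons
    copies <- 2 * hom + het + sons
    lost <- copies == 0L
    fix <- copies == 2L * nf + nm
    fixed[active[lost]] <- 0L
    fixed[active[fix]] <- 1L
    active <- active[!(lost | fix)]
  }
  fixed
}

# Optimum in force for a population at a generation, from a config.
schedule_for <- function(cfg, label, generation) {
  fgmhybrid:::schedule_optimum(cfg$schedule, label, generation)
}

# Longest run of TRUE values.
longest_true_run <- function(x) {
  r <- rle(x)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

# Mean trajectory of one statistic for one population from aggregated
# records, over a generation window.
traj <- function(agg, population, stat, generations) {
  sub <- agg[agg$population == population &
               agg$generation %in% generations, ]
  sub <- sub[order(sub$generation), ]
  sub[[paste0(stat, "_mean")]]
}

# Scaled two-phase runs reused across acceptance checks (cached so several
# test blocks can interrogate one simulated data set).
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# The standard scaled-down figure reproduction: parental phase 500
# generations, novel phase 300, mutation rate scaled up fivefold, ten
# replicates.
scaled_preset <- function(name, system, N_pop, seed, T_parental = 500L,
                          T_novel = 300L, replicates = 10L, mu = 5e-8,
                          ...) {
  preset(name, system = system, N_pop = N_pop, T_parental = T_parental,
         T_novel = T_novel, replicates = replicates, mu = mu, seed = seed,
         ...)
}
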