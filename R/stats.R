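#' Mean fitness by sex
#'
#' Arithmetic mean of individual fitnesses within each sex and overall.  An
#' empty sex class yields `NA` for that sex, never an error.  In
#' haplodiploids the overall mean weights every individual equally
#' regardless of sex.
#'
#' @inheritParams population_fitness
#' @return Named numeric vector `c(female =, male =, all =)`.
#' @export
mean_fitness_by_sex <- function(pop, surface, bdmi = NULL) {
  w <- population_fitness(pop, surface, bdmi)
  f <- pop$sex == "female"
  c(female = if (any(f)) mean(w[f]) else NA_real_,
    male = if (any(!f)) mean(w[!f]) else NA_real_,
    all = mean(w))
}

#' Per-generation rate of adaptation
#'
#' The change in mean fitness from one generation to the next relative to
#' how far mean fitness currently is from its maximum:
#' `(W_next - W_t) / (1 - W_t)`.  Undefined (`NA`) when `W_t = 1`, i.e. when
#' the population is already fully adapted.  Vectorized.
#'
#' @param W_t,W_next Mean fitnesses at consecutive generations, in `[0, 1]`.
#' @return The normalized rate; at most 1 (full adaptation in one step).
#' @export
adaptation_rate <- function(W_t, W_next) {
  stopifnot(all(W_t >= 0 & W_t <= 1, na.rm = TRUE),
            all(W_next >= 0 & W_next <= 1, na.rm = TRUE))
  out <- (W_next - W_t) / (1 - W_t)
  out[W_t == 1] <- NA_real_
  out
}

#' Expected heterozygosity per site
#'
#' The probability that two randomly chosen gene copies differ at a site,
#' averaged over all `L` sites: `pi = (1/L) * sum over segregating sites of
#' 2 p (1 - p)`, with p the population frequency over gene copies
#' (haplodiploids: two per female, one per male).  Fixed substitutions
#' contribute zero.  In the rare case of independent mutations stacked at
#' one position, the site's heterozygosity is `1 - sum(p_i^2)` over its
#' allele classes (ancestral class included), which reduces to `2p(1-p)`
#' for biallelic sites.
#'
#' @param pop An `fgm_population`.
#' @param L Number of sites (defaults to the population's genome length).
#' @param exclude Optional mutation ids to leave out (e.g. artificial marker
#'   loci).
#' @return Per-site expected heterozygosity (>= 0).
#' @export
expected_heterozygosity <- function(pop, L = pop$params$L, exclude = NULL) {
  counts <- allele_counts(pop)
  if (!is.null(exclude)) counts[exclude] <- 0L
  total <- sum(pop$copies)
  seg <- which(counts > 0L & counts < total)
  if (length(seg) == 0L) return(0)
  p <- counts[seg] / total
  pos <- reg_positions(pop$registry)[seg]
  if (anyDuplicated(pos) == 0L) {
    sum(2 * p * (1 - p)) / L
  } else {
    het_site <- vapply(split(p, pos), function(ps) {
      p0 <- max(0, 1 - sum(ps))
      1 - p0^2 - sum(ps^2)
    }, numeric(1))
    sum(het_site) / L
  }
}

#' One generation record for a population
#'
#' @param pop An `fgm_population`.
#' @param surface Current [fitness_surface()] (or `NULL`).
#' @param replicate Replicate index.
#' @param bdmi Optional [bdmi_config()].
#' @param fitness Optional precomputed per-individual fitness vector.
#' @return One-row data frame with the per-generation summary statistics.
#'   `adaptation_rate` is filled in afterwards by [finalize_records()].
#' @export
generation_record <- function(pop, surface, replicate = 1L, bdmi = NULL,
                              fitness = NULL) {
  records_to_df(list(record_row(pop, surface, replicate, bdmi, fitness)))
}

# Internal fast path: one record as a plain list (data.frame construction
# per generation is a measurable cost at scale).
record_row <- function(pop, surface, replicate = 1L, bdmi = NULL,
                       fitness = NULL) {
  if (is.null(fitness)) fitness <- population_fitness(pop, surface, bdmi)
  f <- pop$sex == "female"
  list(replicate = as.integer(replicate),
       generation = pop$generation,
       population = pop$label,
       N = pop_size(pop),
       mean_fitness_female = if (any(f)) mean(fitness[f]) else NA_real_,
       mean_fitness_male = if (any(!f)) mean(fitness[!f]) else NA_real_,
       mean_fitness_all = mean(fitness),
       adaptation_rate = NA_real_,
       pi = expected_heterozygosity(pop,
                                    exclude = bdmi_marker_ids(bdmi)))
}

records_to_df <- function(rows) {
  grab_d <- function(field) vapply(rows, function(r) as.numeric(r[[field]]),
                                   numeric(1))
  data.frame(replicate = vapply(rows, `[[`, integer(1), "replicate"),
             generation = vapply(rows, function(r)
               as.integer(r$generation), integer(1)),
             population = vapply(rows, `[[`, character(1), "population"),
             N = vapply(rows, function(r) as.integer(r$N), integer(1)),
             mean_fitness_female = grab_d("mean_fitness_female"),
             mean_fitness_male = grab_d("mean_fitness_male"),
             mean_fitness_all = grab_d("mean_fitness_all"),
             adaptation_rate = grab_d("adaptation_rate"),
             pi = grab_d("pi"),
             stringsAsFactors = FALSE)
}

#' Fill in the forward adaptation rate of a record stream
#'
#' Within each (replicate, population), ordered by generation:
#' `rate[t] = (W[t+1] - W[t]) / (1 - W[t])`, `NA` in the last generation and
#' wherever `W[t] = 1`.
#'
#' @param records Data frame of [generation_record()] rows.
#' @return The records with the `adaptation_rate` column computed.
#' @export
finalize_records <- function(records) {
  key <- interaction(records$replicate, records$population, drop = TRUE)
  idx <- order(key, records$generation)
  records <- records[idx, , drop = FALSE]
  for (grp in split(seq_len(nrow(records)), key[idx])) {
    W <- records$mean_fitness_all[grp]
    m <- length(W)
    if (m > 1L)
      records$adaptation_rate[grp] <-
        c(adaptation_rate(W[-m], W[-1L]), NA_real_)
  }
  rownames(records) <- NULL
  records
}

#' Aggregate replicate record streams
#'
#' Replicate-wise arithmetic mean and standard error of every statistic at
#' every generation, per population.  Undefined (`NA`) values are excluded
#' and the number of replicates actually used is reported per statistic.
#' Rates are averaged across per-replicate rates, never recomputed from mean
#' trajectories.
#'
#' @param records Data frame of [generation_record()] rows (with the rate
#'   column filled by [finalize_records()]).
#' @return Data frame keyed by (population, generation) with `<stat>_mean`,
#'   `<stat>_se`, and `<stat>_n` columns.
#' @export
aggregate_replicates <- function(records) {
  stats_cols <- c("mean_fitness_female", "mean_fitness_male",
                  "mean_fitness_all", "adaptation_rate", "pi")
  key <- interaction(records$population, records$generation, drop = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    out <- data.frame(population = g$population[1L],
                      generation = g$generation[1L],
                      n_replicates = length(unique(g$replicate)),
                      stringsAsFactors = FALSE)
    for (col in stats_cols) {
      x <- g[[col]][!is.na(g[[col]])]
      out[[paste0(col, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      out[[paste0(col, "_se")]] <-
        if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
      out[[paste0(col, "_n")]] <- length(x)
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$population, out$generation), , drop = FALSE]
  rownames(out) <- NULL
  out
}
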