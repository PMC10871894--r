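#' Single-mutant fixation trials
#'
#' Wright-Fisher trials of one new mutant copy in an otherwise monomorphic
#' population, run until fixation or loss.  The selective benefit is
#' engineered geometrically: the wild type sits at the origin and the
#' optimum at distance d along the mutation's axis, with d chosen so a
#' homozygote (full expression, magnitude `delta_mag`) has relative fitness
#' exactly `1 + s`; for small `delta_mag` a heterozygote then has relative
#' fitness close to `1 + h s`.  Classic predictions: fixation probability
#' about `2hs` in diploids and `(1/3) 2s + (2/3) 2hs` in haplodiploids
#' (haploid males express the full effect), and the initial copy frequency
#' under neutrality.
#'
#' @param system `"diploid"` or `"haplodiploid"`.
#' @param N Population size.
#' @param n_trials Number of independent trials.
#' @param s Homozygous selection coefficient (ignored when
#'   `neutral = TRUE`).
#' @param h Dominance coefficient of the mutant.
#' @param delta_mag Phenotypic effect magnitude of the mutant (small values
#'   keep heterozygote selection close to `h s`).
#' @param neutral If `TRUE` the mutant has a zero effect vector, so all
#'   fitnesses are equal and fixation is by drift alone.
#' @param max_gen Per-trial generation cap (trials hitting it count as
#'   `NA`).
#' @return List with `outcomes` (1 fixed / 0 lost / `NA`), the fixation
#'   probability estimate `p_hat`, its binomial `se`, the realized
#'   heterozygous selection coefficient `s_het`, and the initial copy
#'   frequency `p0`.
#' @export
run_fixation_trials <- function(system = c("diploid", "haplodiploid"), N,
                                n_trials, s = 0.05, h = 0.5,
                                delta_mag = 0.02, neutral = FALSE,
                                max_gen = 100L * N) {
  system <- match.arg(system)
  n_traits <- 2L
  m <- delta_mag
  d <- if (neutral) 1 else (log(1 + s) + m^2) / (2 * m)
  reg <- new_registry(n_traits)
  target <- reg_add(reg, position = 5e5,
                    effect = c(if (neutral) 0 else m, 0), h = h)
  optimum <- c(d, 0)
  background <- numeric(n_traits)
  sex <- rep(c("female", "male"), c(ceiling(N / 2), floor(N / 2)))
  copies <- copies_for(system, sex)
  total <- sum(copies)
  n_f <- as.integer(ceiling(N / 2))
  n_m <- as.integer(floor(N / 2))
  w_wt <- exp(-d^2)
  w_het <- exp(-(d - h * m)^2)
  outcomes <- vapply(seq_len(n_trials), function(i) {
    genomes <- rep(list(integer(0)), total)
    genomes[[sample.int(total, 1L)]] <- target
    res <- cpp_fixation_trial(genomes, copies, sex == "female",
                              system_code(system), reg_positions(reg),
                              reg_effects(reg), reg_h(reg), background,
                              optimum, 1, 0, 1e6, n_f, n_m, target,
                              as.integer(max_gen))
    as.integer(res$outcome)
  }, integer(1))
  ok <- !is.na(outcomes)
  p_hat <- mean(outcomes[ok])
  list(outcomes = outcomes, p_hat = p_hat,
       se = sqrt(p_hat * (1 - p_hat) / sum(ok)),
       s_het = w_het / w_wt - 1, p0 = 1 / total)
}
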