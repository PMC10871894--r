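---
title: "Hybrid and parental adaptation under Fisher's geometric model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid and parental adaptation under Fisher's geometric model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmhybrid)
```

## The model

`fgmhybrid` simulates adaptation of hybrid and parental populations with
individual-based, forward-in-time Wright–Fisher reproduction under Fisher's
geometric model (FGM).  Each individual's phenotype is a point in an
n-dimensional trait space (default n = 5).  Fitness declines with the
Euclidean distance x from a single optimum as

  w(x) = exp(−(x²)^q),

so fitness is exactly 1 at the optimum and Gaussian in shape at the default
shape exponent q = 1.  Environmental change is a displacement of the
optimum; nothing else about the organism changes.

Mutations are the only source of phenotypic novelty.  A new mutation
displaces the phenotype in a uniformly random direction (isotropic: a
normalized vector of independent standard Gaussians) with a magnitude drawn
from an exponential distribution with mean λ (default 0.2).  The stored
effect is the *full-expression* displacement: what a haploid carrier or a
homozygous diploid expresses.  A diploid heterozygote expresses a fraction
h of it (default h = 0.5, codominant on the phenotypic scale), and an
autotetraploid expresses copies/4 (a single copy has a quarter effect).
Dominance and epistasis *in fitness* are emergent: a mutation's fitness
effect depends on where the genome already sits relative to the optimum,
which is why, for example, a mutation whose homozygous effect straddles the
optimum makes the heterozygote fitter than both homozygotes.

Genomes are a single chromosome of L = 10⁶ sites with per-site mutation
rate μ = 10⁻⁸ and Poisson crossovers at a per-bp rate r.  Reproduction is
Wright–Fisher with fitness-proportional parentage: every generation exactly
⌈N/2⌉ daughters and ⌊N/2⌋ sons are produced; each offspring samples its
mother in proportion to female fitness and its father in proportion to male
fitness, independently and with replacement.  Fitness acts on the
probability of parentage, not on survival.

Three genetic systems are supported:

* **diploid** — both sexes carry two genome copies (default N = 1500,
  r = ⅔·10⁻⁶);
* **haplodiploid** — females are diploid, males develop from unfertilized
  eggs and are haploid (arrhenotoky): sons receive a single recombinant
  maternal gamete, daughters additionally receive their father's genome
  without recombination (default N = 2000, r = 10⁻⁶; these values keep
  effective size and effective recombination comparable to the diploid
  setting);
* **tetraploid** — four copies, meiosis pairs the copies into two random
  bivalents without double reduction and transmits one recombinant product
  from each, so gametes are diploid.  Defaults N = 750 and r = 10⁻⁶ are a
  package choice: the paper-style diploid and haplodiploid settings hold
  3000 gene copies, and N = 750 tetraploids match that copy number.

## The two-phase scenario design

A scenario (`scenario_config()`, or one of the six `preset()`s) runs in two
phases.  Two parental populations P1 and P2 start genetically identical —
monomorphic, with every phenotype at the origin — and adapt in allopatry
for `T_parental` generations (default 1500) to the optima of their
schedules, which may be identical or divergent.  At generation
`T_parental` a hybrid population H is founded from N/4 females and N/4
males drawn uniformly without replacement from each parent — exactly N/2
descendants of each parent with 50:50 sexes and ancestries — and the
optimum moves to its novel position for all three populations.  There is no
further gene flow; H mates panmictically from its first generation, so the
first hybrid-bred generation already contains F1 crosses and later
generations contain recombinant F2-type genotypes.  All three populations
then evolve independently for `T_novel` generations (default 1000; the
paper's figures span several hundred post-shift generations and the value
is configurable).

Per generation and population the simulator records mean fitness (overall
and by sex), the adaptation rate, and the expected heterozygosity π.  The
adaptation rate is the forward-looking normalized gain
ΔW(t)/(1−W(t)) = (W(t+1) − W(t))/(1 − W(t)): the share of the remaining
fitness gap closed in one generation.  We take ΔW forward because the
denominator is "how far mean fitness currently is from the optimum"; the
statistic is undefined (NA) at W = 1 and is capped at 1 by construction.
π is the probability that two randomly drawn gene copies differ at a site,
averaged over all L sites: Σ 2p(1−p)/L over segregating sites, with p the
copy frequency (two copies per haplodiploid female, one per male).  We use
population frequencies without a sample-size correction factor; the choice
is constant across populations, so every comparison in the package is
unaffected.  In the rare case of independently arisen mutations stacked at
one position, the site contributes 1 − Σpᵢ² over its allele classes.

A note on "hybrid fitness at creation": at the creation generation the
hybrid pool is literally a 50:50 sample of parental individuals, so its
mean fitness equals the parental mixture in expectation.  Reduced initial
hybrid fitness — the incompatibility cost visible when the novel optimum is
close to the parental one — appears in the first hybrid-*bred* generations,
when crossing and recombination combine divergent parental backgrounds.
Accordingly the package's checks compare hybrids with parents over the
first post-creation generations rather than at the founder snapshot.

## Bookkeeping that must not move anything

Mutation bookkeeping lives in a shared append-only registry; genomes are
sorted integer id vectors.  A mutation fixed in a population is
periodically moved to a substitution ledger and its effect folded into a
constant `fixed_background` (`fix_and_prune()`), which changes no
phenotype, fitness, or π value — only the representation.  Before
hybridization, pruning requires fixation in *every* population: a mutation
fixed in P1 but absent from P2 must stay segregating so that the hybrid can
be polymorphic for it.  (Because the parents start without shared
variation, jointly fixed mutations essentially never occur pre-contact; the
joint rule is a correctness guard, not an optimization.)  After
hybridization, pruning is per-population.

All randomness flows through R's global RNG: one root seed, per-replicate
seeds derived from it, and every C++ kernel draws from the same stream, so
a configuration plus seed reproduces a run bit for bit.  Two deliberate
exceptions keep optional machinery from perturbing the reproduction
stream: BDMI marker loci are placed at deterministic, evenly spaced
positions, and demographic size draws use an isolated RNG substream.  As a
result, cost-free incompatibilities and never-binding demography reproduce
the base model exactly, which the test suite asserts byte for byte.

## Extensions

**Intrinsic incompatibilities (BDMIs).**  Pairwise incompatibilities are
seeded at hybridization as phenotypically neutral marker mutations fixed
alternately in P1 (locus a) and P2 (locus b).  An individual carrying both
sides of a pair multiplies its fitness by 1 − cost·m, where m comes from a
2×2 dominance matrix over carrier classes (heterozygous/homozygous; a
haploid carrier counts as homozygous).  The named schemes "dominant",
"recessive", and "partial" cover the common constructions; the matrix is
fully configurable because the exact supplementary construction is not
specified in the source text.  Individuals carrying only one side pay
nothing, so the incompatibilities are intrinsic (environment-independent)
and invisible within either pure parental population.  Marker loci are
excluded from π: they are bookkeeping for the incompatibility overlay, not
part of the mutational process, and their heterozygosity is an artifact of
the seeding procedure.

**Demography.**  In demographic mode the next population size is
Poisson(N·W̄·g) truncated at a carrying capacity K, with extinction
declared at or below a threshold (default 3, below the minimum for
two-sex reproduction).  The functional form is a package choice (the
source defers its demographic model to supplementary material); it
reproduces the qualitative behavior of interest — populations whose mean
fitness stays low after a shift decline and can go extinct, and faster
adaptation rescues.  Demography applies during the novel phase, where the
environmental shift creates the extinction risk.

**Sweeps.**  `sweep_scenarios()` runs a preset over a parameter grid
(h, λ, n, shape, system, sizes), each point with an independent derived
seed, and returns one tidy record table keyed by the grid columns; invalid
points are reported per-point without aborting the sweep.

## Scaled test conditions, and what they do and do not show

The full parameterization (N = 1500–2000, 1500 + 1000 generations, 100
replicates) is impractical inside a test suite, so the checks run
scaled-down versions chosen once: N = 300 (diploid) / 400 (haplodiploid) /
150 (tetraploid, matching 600 gene copies), 400–500 parental and 60–300
novel generations, μ raised fivefold to 5·10⁻⁸ so the population mutation
supply stays comparable, and 8–10 replicates.  Fixation-probability oracles
use N = 500, s = 0.05, h = 0.5, and 2·10⁴ trials; neutral-diversity checks
scale μ so 4Nμ = 10⁻³ and average π over the second half of a 1000-
generation run.

Two scaling lessons are built into the choices and worth knowing when
interpreting results:

* The tetraploid-vs-diploid speed comparison is made in the
  mutation-limited regime (μ = 5·10⁻⁸).  When the mutation supply is made
  very large, the masking disadvantage of quarter-effect copies is offset
  by tetraploids' smaller phenotypic variance around the mean (four-copy
  averaging produces fewer overshooting individuals), and the speed
  ordering can reverse.
* The "larger λ shrinks the hybrid edge" comparison uses a large optimum
  shift (the fig3A geometry, shift distance ≈ 3.6).  For a small shift
  (distance 1), λ = 0.4 mutations mostly overshoot, parents adapt more
  slowly, and the hybrid edge grows instead.  The hybrid edge is measured
  as the replicate-mean fitness advantage over the first 50 post-shift
  generations, which is far more stable across seeds than the
  per-generation rate gap.

The simulator emulates the statistical structure of the study design:
isotropic exponential-magnitude mutation effects, Gaussian fitness,
Poisson mutation and recombination, fitness-proportional two-sex
Wright–Fisher reproduction, and the two-phase hybridization scenario.  It
does not model spatial structure, assortative mating, ongoing gene flow,
multiple optima, or interactions with other species — conclusions about
such settings cannot be drawn from these simulations.  Passing tests at
reduced scale establish the qualitative patterns (hybrid advantage and its
modifiers), not the quantitative trajectories of the full-scale runs.

## Numerical choices

* Coordinates are 0-based, half-open [0, L); mutation positions are
  integers, crossover breakpoints continuous points, so a breakpoint never
  splits co-located mutations.
* Multiple mutations may stack at one position (expected ~10⁻⁴ of
  mutations at μL = 0.01); they remain distinct alleles.
* Offspring sex counts are exact (⌈N/2⌉/⌊N/2⌋), not binomial, so both
  sexes always exist at the small N used in tests.
* Selfing is not excluded: mother and father draws are independent, which
  at N in the hundreds is a negligible-probability event, and nothing in
  the design depends on it.
* The shape exponent enters as exp(−(x²)^q); q and the alternative
  "surface shape" parameterization are treated as the same single knob,
  and it is configurable precisely because the two readings
  (exp(−(x²)^q) vs exp(−x^k)) coincide up to reparameterization of the
  sweep values.
* Dominance h is a global simulation parameter applied to all mutations of
  a run (the registry stores it per mutation, so per-mutation dominance is
  representable, but no interface sets it heterogeneously).
* `fix_and_prune()` equality checks are exact in floating point except for
  the background fold, which is order-stable and tested to 10⁻¹².
* All-zero fitness (possible only if every phenotype underflows
  exp(−(x²)^q) at x ≳ 27) aborts with a "selection collapse" error rather
  than sampling from a zero measure.

## A worked miniature

```{r example, eval = FALSE}
cfg <- preset("fig2A", system = "haplodiploid", N_pop = 100,
              T_parental = 150, T_novel = 80, replicates = 3,
              mu = 5e-8, seed = 1)
run <- run_scenario(cfg)
agg <- aggregate_replicates(run$records)
subset(agg, generation %in% c(150, 160, 200) ,
       select = c(population, generation, mean_fitness_all_mean, pi_mean))
```

The same run is available from the shell:

```sh
Rscript inst/scripts/fgmhybrid run --preset fig2A --system haplodiploid \
  --n-pop 100 --t-parental 150 --t-novel 80 --replicates 3 --seed 1 \
  --out out/
```

which writes `records.tsv`, a `config.yaml` echo, and a `manifest.json`
with per-replicate seeds and file checksums; the manifest plus config
reproduce the run exactly.
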