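#' Gaussian fitness surface of Fisher's geometric model
#'
#' Fitness declines with the Euclidean distance x of a phenotype from a
#' single optimum, as `exp(-(x^2)^q)`.  At the default shape `q = 1` this is
#' the classical Gaussian surface dropping from a height of one at the
#' optimum to `exp(-x^2)` at distance x.  Larger `q` flattens the peak and
#' steepens the flanks; smaller `q` does the opposite.
#'
#' @param optimum Numeric vector: the optimal phenotype (length = number of
#'   trait dimensions).
#' @param shape Positive shape exponent q (default 1).
#' @return An object of class `fitness_surface`.
#' @examples
#' s <- fitness_surface(c(2, 0, 0, 0, 0))
#' fgm_fitness(c(1, 0, 0, 0, 0), s)  # exp(-1)
#' @export
fitness_surface <- function(optimum, shape = 1) {
  optimum <- as.numeric(optimum)
  if (length(optimum) < 1L || !all(is.finite(optimum)))
    stop("optimum must be a finite numeric vector")
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape <= 0)
    stop("shape exponent q must be a positive number")
  structure(list(optimum = optimum, shape = as.numeric(shape)),
            class = "fitness_surface")
}

#' @export
print.fitness_surface <- function(x, ...) {
  cat("<fitness_surface> optimum {", paste(x$optimum, collapse = ","),
      "}, shape q =", x$shape, "\n")
  invisible(x)
}

as_phenotype_matrix <- function(z, n_traits) {
  if (is.null(dim(z))) z <- matrix(as.numeric(z), nrow = 1L)
  if (ncol(z) != n_traits)
    stop("phenotype has ", ncol(z), " dimensions but the surface has ",
         n_traits)
  if (!all(is.finite(z))) stop("phenotype contains non-finite values")
  z
}

#' Euclidean distance of a phenotype from the optimum
#'
#' @param z Phenotype vector, or a matrix with one phenotype per row.
#' @param surface A [fitness_surface()].
#' @return Non-negative distance(s).
#' @export
distance_to_optimum <- function(z, surface) {
  z <- as_phenotype_matrix(z, length(surface$optimum))
  sqrt(rowSums(sweep(z, 2L, surface$optimum)^2))
}

#' Fitness of a phenotype
#'
#' `exp(-(x^2)^q)` with x the Euclidean distance from the optimum; exactly 1
#' at the optimum and strictly decreasing in x for any shape q > 0.
#'
#' @inheritParams distance_to_optimum
#' @return Fitness value(s) in (0, 1].
#' @export
fgm_fitness <- function(z, surface) {
  x <- distance_to_optimum(z, surface)
  exp(-(x^2)^surface$shape)
}

#' Draw a random mutation effect
#'
#' A new mutation displaces the phenotype in a uniformly random direction of
#' the n-dimensional trait space (an isotropic direction generated by
#' normalizing independent standard Gaussians) with a magnitude drawn from an
#' exponential distribution with mean `lambda_mean`.  The returned `delta` is
#' the full-expression displacement (haploid carriers or homozygous
#' diploids); partial expression is governed by the dominance coefficient.
#'
#' @param n Number of trait dimensions (>= 1).
#' @param lambda_mean Mean effect magnitude (default 0.2).
#' @param h Dominance coefficient in `[0, 1]` for single-copy expression in
#'   diploids (default 0.5, codominant).
#' @return A list of class `mutation_effect` with fields `delta` and
#'   `dominance_h`.
#' @export
draw_mutation_effect <- function(n, lambda_mean = 0.2, h = 0.5) {
  stopifnot(n >= 1, lambda_mean > 0, h >= 0, h <= 1)
  repeat {
    d <- stats::rnorm(n)
    nrm <- sqrt(sum(d^2))
    if (nrm > 0) break
  }
  mag <- stats::rexp(1L, rate = 1 / lambda_mean)
  structure(list(delta = d / nrm * mag, dominance_h = h),
            class = "mutation_effect")
}

#' Map a genotype to its phenotype
#'
#' Mutations act additively on the phenotype: the phenotype is the fixed
#' background plus, for every carried mutation, a dosage-weighted multiple of
#' its full-expression effect `delta`.  The weight is 1 when all carried
#' copies bear the mutation (haploids, homozygotes), the dominance
#' coefficient h for diploid heterozygotes, and `copies / 4` for tetraploids
#' (pure additive dosage: a single copy has 1/4 effect).
#'
#' @param fixed_background Numeric phenotype vector of the fixed (substituted)
#'   background.
#' @param dosage_list List of entries `list(effect = <mutation_effect>,
#'   copies = <int>, ploidy = <1, 2, or 4>)`.
#' @return Phenotype vector.
#' @export
genotype_to_phenotype <- function(fixed_background, dosage_list = list()) {
  z <- as.numeric(fixed_background)
  for (entry in dosage_list) {
    eff <- entry$effect
    copies <- entry$copies
    ploidy <- entry$ploidy
    if (!ploidy %in% c(1L, 2L, 4L)) stop("ploidy must be 1, 2, or 4")
    if (copies < 1L || copies > ploidy)
      stop("copies (", copies, ") must be between 1 and ploidy (", ploidy, ")")
    w <- if (copies == ploidy) 1
    else if (ploidy == 2L) eff$dominance_h
    else copies / 4
    z <- z + w * eff$delta
  }
  z
}
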