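#' Create a mutation registry
#'
#' The registry is the shared, append-only ledger of every mutation that has
#' ever arisen in a simulation run.  Populations store genomes as integer
#' vectors of registry ids; the registry holds each mutation's genomic
#' position, full-expression phenotypic effect vector, dominance coefficient,
#' and origin metadata.  It is an environment so that all populations of a
#' run (parents and hybrid) share one id space.  Columns are preallocated
#' and grown by doubling; appends write in place through a small C++ helper
#' and only ever touch slots beyond the current count, so earlier snapshots
#' of the meaningful prefix stay valid.
#'
#' @param n_traits Number of phenotypic dimensions.
#' @return An object of class `mutation_registry`.
#' @export
new_registry <- function(n_traits) {
  stopifnot(is.numeric(n_traits), length(n_traits) == 1L, n_traits >= 1)
  n_traits <- as.integer(n_traits)
  reg <- new.env(parent = emptyenv())
  reg$n_traits <- n_traits
  reg$count <- 0L
  cap <- 1024L
  reg$position <- numeric(cap)
  reg$effect <- matrix(0, nrow = n_traits, ncol = cap)
  reg$h <- numeric(cap)
  reg$origin_generation <- integer(cap)
  reg$origin_code <- integer(cap)
  reg$pop_levels <- character(0)
  class(reg) <- "mutation_registry"
  reg
}

reg_grow <- function(reg, need) {
  cap <- length(reg$position)
  if (reg$count + need <= cap) return(invisible(reg))
  newcap <- cap
  while (reg$count + need > newcap) newcap <- newcap * 2L
  reg$position <- c(reg$position, numeric(newcap - cap))
  reg$effect <- cbind(reg$effect, matrix(0, reg$n_traits, newcap - cap))
  reg$h <- c(reg$h, numeric(newcap - cap))
  reg$origin_generation <- c(reg$origin_generation, integer(newcap - cap))
  reg$origin_code <- c(reg$origin_code, integer(newcap - cap))
  invisible(reg)
}

#' Register new mutations
#'
#' @param reg A [new_registry()] object.
#' @param position Integer-valued base-pair positions in `[0, L)`.
#' @param effect Matrix (`n_traits` x k) of full-expression effect vectors.
#' @param h Dominance coefficient(s), recycled to k.
#' @param origin_generation,origin_population Origin metadata, recycled.
#' @return Integer vector of assigned ids (contiguous, increasing).
#' @export
reg_add <- function(reg, position, effect, h = 0.5,
                    origin_generation = 0L, origin_population = "") {
  k <- length(position)
  if (k == 0L) return(integer(0))
  effect <- matrix(effect, nrow = reg$n_traits)
  if (ncol(effect) != k) stop("effect matrix does not match positions")
  reg_grow(reg, k)
  ids <- reg$count + seq_len(k)
  code <- match(origin_population, reg$pop_levels)
  if (anyNA(code)) {
    reg$pop_levels <- c(reg$pop_levels,
                        unique(origin_population[is.na(code)]))
    code <- match(origin_population, reg$pop_levels)
  }
  cpp_reg_write(reg$position, reg$effect, reg$h, reg$origin_generation,
                reg$origin_code, as.integer(ids), as.numeric(position),
                effect, rep_len(as.numeric(h), k),
                rep_len(as.integer(origin_generation), k),
                rep_len(as.integer(code), k))
  reg$count <- reg$count + k
  as.integer(ids)
}

#' @export
print.mutation_registry <- function(x, ...) {
  cat("<mutation_registry>", x$count, "mutations,", x$n_traits, "traits\n")
  invisible(x)
}

# Views used at the R/C++ boundary.  Entries beyond `count` are
# uninitialized padding; the kernels only read ids <= count.
reg_positions <- function(reg) reg$position
reg_effects <- function(reg) reg$effect
reg_h <- function(reg) reg$h
reg_origin_pop <- function(reg, ids) reg$pop_levels[reg$origin_code[ids]]
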