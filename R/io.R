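CONFIG_KEYS <- c("preset", "system", "schedule", "N_pop", "L", "mu", "r_bp",
                 "n", "lambda_mean", "h", "shape", "T_parental", "T_novel",
                 "replicates", "bdmi", "demography", "seed", "prune_every")

# atomic write: write to a sibling temp file, then rename into place
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot write to ", path)
  ok <- TRUE
  invisible(path)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$schedule <- lapply(unclass(out$schedule), function(entries) {
    lapply(entries, function(e) list(generation = e$generation,
                                     optimum = e$optimum))
  })
  if (!is.null(out$bdmi))
    out$bdmi <- list(n_pairs = out$bdmi$n_pairs, cost = out$bdmi$cost,
                     dominance = as.vector(out$bdmi$dominance))
  if (!is.null(out$demography))
    out$demography <- unclass(out$demography)
  out
}

list_to_config <- function(lst, source = "config") {
  unknown <- setdiff(names(lst), CONFIG_KEYS)
  if (length(unknown) > 0L)
    stop("unknown ", source, " key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(lst$bdmi)) lst$bdmi <- do.call(bdmi_config, lst$bdmi)
  if (!is.null(lst$demography))
    lst$demography <- do.call(demography_settings, lst$demography)
  if (!is.null(lst$schedule)) {
    lst$schedule <- optimum_schedule(lapply(lst$schedule, function(entries) {
      lapply(entries, function(e) list(generation = as.integer(e$generation),
                                       optimum = as.numeric(e$optimum)))
    }))
  }
  if (!is.null(lst$preset)) {
    name <- lst$preset
    lst$preset <- NULL
    lst$schedule <- NULL
    do.call(preset, c(list(name = name), lst))
  } else {
    if (is.null(lst$schedule))
      stop("config requires either a 'preset' or a 'schedule'")
    do.call(scenario_config, lst)
  }
}

#' Load a scenario configuration from YAML or JSON
#'
#' Missing keys are filled with the standard defaults (see
#' [scenario_config()]); unknown keys are rejected with an error naming
#' them.  A `preset` key builds on the named [preset()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE,
                                           simplifyDataFrame = FALSE,
                                           simplifyMatrix = FALSE),
                stop("unsupported config format '.", ext,
                     "' (use .yaml/.yml/.json)"))
  if (is.null(lst)) lst <- list()
  list_to_config(lst, source = "config")
}

#' Save a scenario configuration
#'
#' @param config A [scenario_config()].
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  lst <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  write_atomic(path, function(tmp) {
    switch(ext,
           yaml = , yml = yaml::write_yaml(lst, tmp),
           json = jsonlite::write_json(lst, tmp, auto_unbox = TRUE,
                                       digits = NA, null = "null"),
           stop("unsupported config format '.", ext, "'"))
  })
}

#' Write a generation-record table
#'
#' One row per (replicate, generation, population); tab-separated with a
#' header row, undefined values as `NA`, deterministic row order, and an
#' atomic write-then-rename.
#'
#' @param records Data frame of records.
#' @param path Destination path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("replicate", "generation", "population", "N",
            "mean_fitness_female", "mean_fitness_male", "mean_fitness_all",
            "adaptation_rate", "pi")
  extra <- setdiff(names(records), cols)
  records <- records[order(records$replicate, records$generation,
                           records$population), c(cols, extra),
                     drop = FALSE]
  for (col in names(records))
    if (is.double(records[[col]]))
      records[[col]] <- signif(records[[col]], 12)
  write_atomic(path, function(tmp) {
    utils::write.table(records, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  })
}

#' Read a generation-record table
#'
#' @param path Path written by [write_records()].
#' @return Data frame of records.
#' @export
read_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export the mutation table of a population
#'
#' Tab-separated table of all segregating mutations and fixed substitutions:
#' id, position, status, frequency, origin metadata, the effect vector, and
#' the dominance coefficient.
#'
#' @param pop An `fgm_population`.
#' @param path Destination path.
#' @return The exported data frame, invisibly.
#' @export
export_mutations <- function(pop, path) {
  reg <- pop$registry
  counts <- allele_counts(pop)
  total <- sum(pop$copies)
  seg <- which(counts > 0L & counts < total)
  fixed_unpruned <- which(counts == total)
  subs <- sort(unique(c(pop$substitutions, fixed_unpruned)))
  ids <- c(seg, setdiff(subs, seg))
  status <- c(rep("segregating", length(seg)),
              rep("substitution", length(setdiff(subs, seg))))
  freq <- c(counts[seg] / total, rep(1, length(setdiff(subs, seg))))
  eff <- t(reg_effects(reg)[, ids, drop = FALSE])
  colnames(eff) <- paste0("effect_", seq_len(reg$n_traits))
  tab <- data.frame(id = ids, position = reg_positions(reg)[ids],
                    status = status, frequency = freq,
                    origin_generation = reg$origin_generation[ids],
                    origin_population = reg_origin_pop(reg, ids),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, eff, dominance_h = reg_h(reg)[ids])
  tab <- tab[order(tab$position, tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  write_atomic(path, function(tmp) {
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  })
  invisible(tab)
}

#' Write a reproducibility manifest
#'
#' JSON manifest with the configuration echo, root and per-replicate seeds,
#' package version, generation span, and an inventory of output files with
#' MD5 checksums.  Manifest plus config suffice to reproduce a run exactly.
#'
#' @param run An `fgm_run` from [run_scenario()].
#' @param dir Output directory.
#' @param files Character vector of file paths to inventory.
#' @param path Manifest destination (default `manifest.json` in `dir`).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(run, dir, files,
                           path = file.path(dir, "manifest.json")) {
  manifest <- list(
    package = "fgmhybrid",
    version = as.character(utils::packageVersion("fgmhybrid")),
    root_seed = run$config$seed,
    replicate_seeds = run$seeds,
    config = config_to_list(run$config),
    generation_span = c(min(run$records$generation),
                        max(run$records$generation)),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  write_atomic(path, function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(manifest)
}
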