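#' Run configuration for grammatical-evolution decision tree analysis
#'
#' Bundles every tunable parameter of the search. Defaults reproduce the
#' published analysis settings: 1000 generations, population of 500 split
#' across 4 islands, migration every 25 generations, crossover rate 0.9,
#' per-bit mutation rate 0.01, chromosome size between 50 and 1000 codons,
#' tournament selection, and 10-fold cross-validation.
#'
#' @param generations maximum number of generations.
#' @param population_size total population size (split across islands).
#' @param crossover_rate fraction of each new generation produced by
#'   one-point codon-boundary crossover of tournament-selected parents.
#' @param mutation_rate per-bit probability of flipping a genome bit in
#'   non-elite offspring.
#' @param duplication_rate fraction of each island copied unchanged (elitist
#'   reproduction) into the next generation.
#' @param tournament_size individuals drawn (with replacement) per tournament.
#' @param n_islands number of island subpopulations.
#' @param migration_interval generations between best-individual broadcasts;
#'   0 disables migration.
#' @param min_chromosome,max_chromosome genome size limits, in bits (a
#'   genome holds between `min_chromosome / codon_size_bits` and
#'   `max_chromosome / codon_size_bits` whole codons). The 1000-bit upper
#'   limit caps mapped trees at about 60 nodes, which keeps evolved models
#'   interpretable and overfitting bounded.
#' @param max_wraps times the codon sequence may be reused (wrapped) during
#'   mapping before the genome is declared invalid.
#' @param sensible_init_max_depth maximum tree depth used by sensible
#'   initialization. The default, 3, is the deepest full ternary tree whose
#'   codon encoding fits inside `max_chromosome`.
#' @param codon_size_bits bits per codon.
#' @param cv_folds number of cross-validation folds.
#' @return An object of class `gedt_config` (a named list).
#' @seealso [read_gedt_config()], [evolve()], [run_cv()]
#' @export
gedt_config <- function(generations = 1000L, population_size = 500L,
                        crossover_rate = 0.9, mutation_rate = 0.01,
                        duplication_rate = 0.05, tournament_size = 2L,
                        n_islands = 4L, migration_interval = 25L,
                        min_chromosome = 50L, max_chromosome = 1000L,
                        max_wraps = 2L, sensible_init_max_depth = 3L,
                        codon_size_bits = 8L, cv_folds = 10L) {
  cfg <- list(generations = as.integer(generations),
              population_size = as.integer(population_size),
              crossover_rate = as.numeric(crossover_rate),
              mutation_rate = as.numeric(mutation_rate),
              duplication_rate = as.numeric(duplication_rate),
              tournament_size = as.integer(tournament_size),
              n_islands = as.integer(n_islands),
              migration_interval = as.integer(migration_interval),
              min_chromosome = as.integer(min_chromosome),
              max_chromosome = as.integer(max_chromosome),
              max_wraps = as.integer(max_wraps),
              sensible_init_max_depth = as.integer(sensible_init_max_depth),
              codon_size_bits = as.integer(codon_size_bits),
              cv_folds = as.integer(cv_folds))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("generations", "population_size", "tournament_size", "n_islands",
           "min_chromosome", "max_chromosome", "sensible_init_max_depth",
           "codon_size_bits", "cv_folds")
  for (k in pos)
    if (is.na(cfg[[k]]) || cfg[[k]] < 1L)
      stop("config field '", k, "' must be a positive integer")
  for (k in c("crossover_rate", "mutation_rate", "duplication_rate"))
    if (is.na(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1)
      stop("config field '", k, "' must lie in [0, 1]")
  if (cfg$max_wraps < 0L) stop("max_wraps must be non-negative")
  if (cfg$migration_interval < 0L) stop("migration_interval must be >= 0")
  if (cfg$min_chromosome > cfg$max_chromosome)
    stop("min_chromosome (", cfg$min_chromosome,
         ") exceeds max_chromosome (", cfg$max_chromosome, ")")
  if (cfg$codon_size_bits > 24L)
    stop("codon_size_bits above 24 is not supported")
  lim <- codon_limits(cfg)
  if (lim[["max"]] < 1L)
    stop("max_chromosome must hold at least one whole codon")
  # a full ternary tree of depth d encodes to 3^(d+1) - 1 codons (2 per
  # node); sensible initialization must be able to fit its deepest tree
  d <- cfg$sensible_init_max_depth
  full_codons <- 3^(d + 1) - 1
  if (full_codons > lim[["max"]])
    stop("sensible_init_max_depth = ", d, " encodes full trees of ",
         full_codons, " codons, above the max_chromosome limit of ",
         lim[["max"]], " codons")
  structure(cfg, class = "gedt_config")
}

# chromosome size limits converted from bits to whole-codon counts
codon_limits <- function(cfg) {
  c(min = max(1L, as.integer(ceiling(cfg$min_chromosome / cfg$codon_size_bits))),
    max = as.integer(floor(cfg$max_chromosome / cfg$codon_size_bits)))
}

#' @export
print.gedt_config <- function(x, ...) {
  cat("GEDT run configuration:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a run configuration file
#'
#' Parses a flat `key = value` (or `key value`) text file whose keys mirror
#' the arguments of [gedt_config()]. Missing keys take the published default
#' values; blank lines and `#` comments are ignored; unknown keys raise a
#' warning. The resulting configuration is validated.
#'
#' @param path path to the configuration file.
#' @return A validated `gedt_config` object.
#' @export
read_gedt_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- gedt_config()
  vals <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[=[:space:]]+")[[1L]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L) stop("cannot parse config line: '", ln, "'")
    key <- parts[1L]
    if (!key %in% names(defaults)) {
      warning("unknown config key '", key, "' ignored")
      next
    }
    vals[[key]] <- as.numeric(parts[2L])
  }
  cfg <- unclass(defaults)
  for (k in names(vals))
    cfg[[k]] <- if (is.integer(defaults[[k]])) as.integer(vals[[k]]) else vals[[k]]
  validate_config(cfg)
}
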