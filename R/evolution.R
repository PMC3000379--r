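#' Genetic operators
#'
#' `tournament_select()` draws `k` individuals uniformly with replacement and
#' returns the index of the fittest (ties broken uniformly at random).
#' `mutate_genome()` flips each bit of the genome independently with
#' probability `rate`. `crossover_genomes()` performs one-point crossover at
#' codon boundaries, drawing a cut point independently in each parent and
#' swapping tails; cut points are resampled (up to `retries` times) until
#' both offspring respect the chromosome-size limits, after which the parents
#' are returned unchanged. Total codon count is always conserved.
#'
#' @param fitnesses numeric vector of population fitnesses.
#' @param k tournament size (>= 1).
#' @param genome,a,b [gedt_genome] objects.
#' @param rate per-bit mutation probability in `[0, 1]`.
#' @param config a [gedt_config] (chromosome-size limits).
#' @param retries cut-point resampling attempts.
#' @return `tournament_select()`: the selected index; `mutate_genome()`: a
#'   mutated genome; `crossover_genomes()`: list of two offspring genomes.
#' @export
tournament_select <- function(fitnesses, k = 2L) {
  n <- length(fitnesses)
  stopifnot(n >= 1L, k >= 1L)
  cand <- sample.int(n, k, replace = TRUE)
  best <- cand[fitnesses[cand] == max(fitnesses[cand])]
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' @rdname tournament_select
#' @export
mutate_genome <- function(genome, rate) {
  stopifnot(inherits(genome, "gedt_genome"), rate >= 0, rate <= 1)
  gedt_genome(cpp_mutate(genome$codons, rate, genome$codon_size),
              genome$codon_size)
}

#' @rdname tournament_select
#' @export
crossover_genomes <- function(a, b, config = gedt_config(), retries = 10L) {
  stopifnot(inherits(a, "gedt_genome"), inherits(b, "gedt_genome"),
            a$codon_size == b$codon_size)
  lim <- codon_limits(config)
  out <- cpp_crossover(a$codons, b$codons, lim[["min"]], lim[["max"]],
                       as.integer(retries))
  list(gedt_genome(out$child1, a$codon_size),
       gedt_genome(out$child2, a$codon_size))
}

# parameter list handed to the C++ loops: chromosome limits in codon units
ga_params <- function(config) {
  par <- unclass(config)
  lim <- codon_limits(config)
  par$min_chromosome <- lim[["min"]]
  par$max_chromosome <- lim[["max"]]
  par
}

# shared result wrapper for evolve()/random_search()
search_result <- function(res, grammar, config, mode) {
  tree <- map_to_tree(res$best_codons, grammar, config$max_wraps)
  structure(list(best_tree = tree,
                 best_fitness = res$best_fitness,
                 best_generation = res$best_generation,
                 generations_run = res$generations_run,
                 n_evaluations = res$n_evaluations,
                 trace = data.frame(generation = seq_len(res$generations_run),
                                    best_fitness = res$trace_best,
                                    mean_fitness = res$trace_mean),
                 best_genome = gedt_genome(res$best_codons,
                                           config$codon_size_bits),
                 mode = mode),
            class = "gedt_search")
}

#' @export
print.gedt_search <- function(x, ...) {
  cat("GE search (", x$mode, "): best training balanced accuracy ",
      sprintf("%.4f", x$best_fitness), " at generation ", x$best_generation,
      " of ", x$generations_run, "\n", sep = "")
  if (!is.null(x$best_tree)) cat("  ", to_parse_string(x$best_tree), "\n")
  invisible(x)
}

#' Evolve a decision tree by grammatical evolution
#'
#' Runs the island-model genetic algorithm: the population is split across
#' `n_islands` equal subpopulations, each sensibly initialized. Every
#' generation, each island's individuals are mapped to trees and scored by
#' balanced accuracy on the training data; the next generation (of identical
#' size) is formed by copying the top `duplication_rate` fraction unchanged
#' (elitist duplication), and filling the remainder with offspring of
#' tournament-selected parents — recombined by one-point codon-boundary
#' crossover with probability `crossover_rate`, otherwise copied — which
#' then undergo per-bit mutation. Every `migration_interval` generations the
#' best individual of each island is broadcast to every other island,
#' replacing its worst residents. The run stops at a balanced accuracy of
#' 100% or after `generations` generations, and returns the best tree ever
#' seen (ties resolved toward the earliest generation, then the smaller
#' tree).
#'
#' @param train a [gedt_data] training dataset containing both classes.
#' @param config a [gedt_config].
#' @return An object of class `gedt_search`: a list with `best_tree`,
#'   `best_fitness`, `best_generation`, `generations_run`, `n_evaluations`,
#'   a per-generation `trace` (best-so-far and mean fitness) and
#'   `best_genome`.
#' @seealso [random_search()], [run_cv()]
#' @examples
#' ds <- simulate_dataset(solve_penetrance("BOX", 0.5, 0.3), 60, 60,
#'                        n_snps = 5)
#' cfg <- gedt_config(generations = 20, population_size = 60, n_islands = 2)
#' evolve(ds, cfg)
#' @export
evolve <- function(train, config = gedt_config()) {
  stopifnot(inherits(train, "gedt_data"))
  check_two_classes(train)
  config <- validate_config(unclass(config))
  grammar <- gedt_grammar(ncol(train$genotypes), config$codon_size_bits)
  res <- cpp_evolve(train$genotypes, label_int(train), grammar$n_snps,
                    ga_params(config))
  search_result(res, grammar, config, "gedt")
}

#' Random-search negative control
#'
#' Generates a fresh sensibly-initialized population at *every* generation —
#' no selection, crossover or mutation — evaluates each individual exactly
#' as [evolve()] does, and keeps the single best tree over all generations.
#' Under an identical configuration it spends the same number of fitness
#' evaluations as the genetic algorithm, making it the matched-budget
#' negative control.
#'
#' @inheritParams evolve
#' @return A `gedt_search` object (see [evolve()]).
#' @export
random_search <- function(train, config = gedt_config()) {
  stopifnot(inherits(train, "gedt_data"))
  check_two_classes(train)
  config <- validate_config(unclass(config))
  grammar <- gedt_grammar(ncol(train$genotypes), config$codon_size_bits)
  res <- cpp_random_search(train$genotypes, label_int(train), grammar$n_snps,
                           ga_params(config))
  search_result(res, grammar, config, "random")
}
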