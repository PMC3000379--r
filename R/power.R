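#' Classify a final model against the true functional loci
#'
#' Implements the two success definitions used for power estimation:
#' *conservative* — the final model contains exactly the two functional
#' loci, with no false positives or false negatives; *liberal* — both
#' functional loci are present, false positives tolerated (every
#' conservative success is also a liberal one). Anything that misses a
#' functional locus is a failure.
#'
#' @param final_loci integer vector of loci selected by the analysis.
#' @param true_loci the two simulated functional loci.
#' @return `"conservative"`, `"liberal_only"` or `"failure"`.
#' @export
classify_result <- function(final_loci, true_loci) {
  stopifnot(length(true_loci) == 2L)
  if (setequal(final_loci, true_loci)) return("conservative")
  if (all(true_loci %in% final_loci)) return("liberal_only")
  "failure"
}

#' Monte-Carlo power estimation over a simulation grid
#'
#' For each grid row, simulates `n_replicates` datasets from the solved
#' penetrance model, runs the chosen method's full cross-validation pipeline
#' on each, classifies every final model with [classify_result()], and
#' reports the conservative and liberal success proportions as percentages
#' with exact binomial 95% confidence intervals (so the Monte-Carlo
#' uncertainty of a scaled-down run is always visible next to the point
#' estimate).
#'
#' @param grid a data frame in [power_grid()] layout (subset rows to scale
#'   the experiment down).
#' @param method `"gedt"`, `"random"` or `"greedy"`.
#' @param config a [gedt_config] used by the GE searches (ignored by
#'   `"greedy"` except for `cv_folds`).
#' @param n_replicates datasets per grid row.
#' @param n_snps SNPs per dataset.
#' @param functional positions of the functional loci in the simulated
#'   datasets.
#' @param verbose print one line per grid row.
#' @return A data frame of class `gedt_power`, one row per grid row, with
#'   the grid coordinates, `method`, `n_replicates`,
#'   `conservative_successes`, `liberal_successes`,
#'   `conservative_power`/`liberal_power` (percent) and the conservative
#'   interval `ci_low`/`ci_high` (percent).
#' @export
estimate_power <- function(grid, method = c("gedt", "random", "greedy"),
                           config = gedt_config(), n_replicates = 100L,
                           n_snps = 100L, functional = c(1L, 2L),
                           verbose = FALSE) {
  method <- match.arg(method)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    model <- solve_penetrance(g$pattern, g$maf, g$h2)
    n_cons <- 0L
    n_lib <- 0L
    for (r in seq_len(n_replicates)) {
      ds <- simulate_dataset(model, g$n_cases, g$n_controls,
                             n_snps = n_snps, functional = functional)
      cv <- switch(method,
                   gedt = run_cv(ds, config, mode = "gedt"),
                   random = run_cv(ds, config, mode = "random"),
                   greedy = run_c45_cv(ds, cv_folds = config$cv_folds))
      cls <- classify_result(cv$final_loci, ds$functional)
      if (cls == "conservative") n_cons <- n_cons + 1L
      if (cls != "failure") n_lib <- n_lib + 1L
    }
    ci <- stats::binom.test(n_cons, n_replicates)$conf.int
    out[[i]] <- data.frame(
      model_id = g$model_id, h2 = g$h2, maf = g$maf, pattern = g$pattern,
      method = method, n_replicates = n_replicates,
      conservative_successes = n_cons, liberal_successes = n_lib,
      conservative_power = 100 * n_cons / n_replicates,
      liberal_power = 100 * n_lib / n_replicates,
      ci_low = 100 * ci[1L], ci_high = 100 * ci[2L],
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf(
        "model %d (%s h2=%g maf=%g): conservative %d/%d, liberal %d/%d",
        g$model_id, g$pattern, g$h2, g$maf, n_cons, n_replicates, n_lib,
        n_replicates))
  }
  res <- do.call(rbind, out)
  class(res) <- c("gedt_power", "data.frame")
  res
}
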