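#' Stratified cross-validation folds
#'
#' Partitions the individuals into `k` disjoint, exhaustive folds, each
#' holding approximately `1/k` of the cases and `1/k` of the controls.
#' Stratification guarantees both classes are present in every training and
#' test split, so balanced accuracy is always defined.
#'
#' @param ds a [gedt_data] dataset.
#' @param k number of folds; each class must have at least `k` members.
#' @return List of `k` integer index vectors (the test sets).
#' @export
make_folds <- function(ds, k = 10L) {
  stopifnot(inherits(ds, "gedt_data"))
  k <- as.integer(k)
  idx_case <- which(ds$labels == "+")
  idx_ctrl <- which(ds$labels == "-")
  if (length(idx_case) < k || length(idx_ctrl) < k)
    stop("each class needs at least k = ", k, " members (",
         length(idx_case), " cases, ", length(idx_ctrl), " controls)")
  assign_folds <- function(idx, order) {
    idx <- sample(idx)
    split(idx, factor(rep_len(order, length(idx)), levels = seq_len(k)))
  }
  # spreading the remainder individuals from opposite ends keeps total fold
  # sizes within one of each other as well as the per-class counts
  fc <- assign_folds(idx_case, seq_len(k))
  ft <- assign_folds(idx_ctrl, rev(seq_len(k)))
  lapply(seq_len(k), function(i) sort(c(fc[[i]], ft[[i]])))
}

# internal: dataset restricted to a row subset
subset_data <- function(ds, rows) {
  gedt_data(ds$genotypes[rows, , drop = FALSE], ds$labels[rows],
            snp_names = ds$snp_names, functional = ds$functional)
}

#' Cross-validated grammatical-evolution analysis
#'
#' Runs the full analysis protocol: the data are divided into `cv_folds`
#' stratified parts; for each fold the search ([evolve()] or
#' [random_search()]) is trained on the other folds and the resulting best
#' tree is scored on the held-out part (prediction balanced accuracy).
#' Cross-validation consistency then counts, for every SNP, the folds whose
#' best tree contains it; loci with majority support (consistency strictly
#' greater than `threshold`, default `cv_folds/2`) form the final model.
#'
#' @param ds a [gedt_data] dataset.
#' @param config a [gedt_config]; `config$cv_folds` sets the number of folds.
#' @param mode `"gedt"` for the genetic algorithm, `"random"` for the
#'   matched-budget random search.
#' @param threshold consistency needed (exclusive) for a locus to enter the
#'   final model; defaults to `cv_folds/2` (majority rule).
#' @return An object of class `gedt_cv`: a list with `folds` (a data frame
#'   of per-fold parse strings and training/prediction balanced accuracies),
#'   `consistency` (named integer vector over SNPs), `final_loci` (integer
#'   SNP indices) and `trees` (the per-fold best trees).
#' @seealso [final_model()], [run_c45_cv()], [estimate_power()]
#' @export
run_cv <- function(ds, config = gedt_config(), mode = c("gedt", "random"),
                   threshold = NULL) {
  stopifnot(inherits(ds, "gedt_data"))
  mode <- match.arg(mode)
  config <- validate_config(unclass(config))
  k <- config$cv_folds
  folds <- make_folds(ds, k)
  search_fun <- if (mode == "gedt") evolve else random_search
  trees <- vector("list", k)
  train_ba <- test_ba <- numeric(k)
  parse <- character(k)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train <- subset_data(ds, setdiff(seq_len(nrow(ds$genotypes)), test_idx))
    res <- search_fun(train, config)
    trees[[i]] <- res$best_tree
    train_ba[i] <- res$best_fitness
    test_ba[i] <- fitness(res$best_tree, subset_data(ds, test_idx))
    parse[i] <- if (is.null(res$best_tree)) NA_character_
                else to_parse_string(res$best_tree)
  }
  consistency <- cv_consistency(trees, ncol(ds$genotypes), ds$snp_names)
  final <- final_model(consistency, k, threshold)
  structure(list(folds = data.frame(fold = seq_len(k), tree = parse,
                                    train_ba = train_ba, test_ba = test_ba,
                                    stringsAsFactors = FALSE),
                 consistency = consistency, final_loci = final,
                 trees = trees, mode = mode, cv_folds = k,
                 snp_names = ds$snp_names),
            class = "gedt_cv")
}

# count, per SNP, the folds whose best tree contains it
cv_consistency <- function(trees, n_snps, snp_names = NULL) {
  counts <- integer(n_snps)
  for (t in trees)
    if (!is.null(t)) counts[variables_in(t)] <- counts[variables_in(t)] + 1L
  names(counts) <- if (is.null(snp_names)) paste0("V", seq_len(n_snps))
                   else snp_names
  counts
}

#' Final-model loci from cross-validation consistency
#'
#' Selects every locus whose consistency exceeds the majority threshold.
#' With the default `threshold = k/2`, a locus must appear in the best trees
#' of strictly more than half the folds; if no locus qualifies the final
#' model is empty. A threshold (rather than an argmax) lets the final model
#' contain several loci — e.g. both partners of an interacting pair.
#'
#' @param consistency named integer vector of per-SNP fold counts (as in
#'   [run_cv()]'s `consistency` element) or a `gedt_cv` object.
#' @param k number of cross-validation folds.
#' @param threshold exclusive lower bound on consistency; defaults to `k/2`.
#' @return Integer vector of selected SNP indices (possibly empty).
#' @export
final_model <- function(consistency, k = 10L, threshold = NULL) {
  if (inherits(consistency, "gedt_cv")) {
    k <- consistency$cv_folds
    consistency <- consistency$consistency
  }
  if (is.null(threshold)) threshold <- k / 2
  if (any(consistency < 0L | consistency > k))
    stop("consistency counts must lie in [0, k]")
  which(consistency > threshold)
}

#' @export
print.gedt_cv <- function(x, ...) {
  cat("Cross-validated GE decision-tree analysis (", x$mode, ", ",
      x$cv_folds, " folds)\n", sep = "")
  cat(sprintf("  mean training BA %.4f, mean prediction BA %.4f\n",
              mean(x$folds$train_ba), mean(x$folds$test_ba)))
  nz <- sort(x$consistency[x$consistency > 0L], decreasing = TRUE)
  if (length(nz))
    cat("  consistency:",
        paste0(names(nz), "=", nz, collapse = ", "), "\n")
  cat("  final loci:",
      if (length(x$final_loci)) paste(names(x$consistency)[x$final_loci],
                                      collapse = ", ") else "(none)", "\n")
  invisible(x)
}
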