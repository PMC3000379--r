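#' Confusion counts of a decision tree on a dataset
#'
#' Classifies every individual and tabulates true/false positives and
#' negatives, with `"+"` (case) as the positive class.
#'
#' @param tree a [gedt_tree][leaf_node].
#' @param ds a [gedt_data] dataset.
#' @return A named integer vector with elements `TP`, `FN`, `TN`, `FP`
#'   (class `gedt_confusion`). `TP + FN` equals the number of cases and
#'   `TN + FP` the number of controls.
#' @export
confusion <- function(tree, ds) {
  stopifnot(inherits(ds, "gedt_data"))
  pred <- classify(tree, ds$genotypes)
  obs <- ds$labels
  out <- c(TP = sum(pred == "+" & obs == "+"),
           FN = sum(pred == "-" & obs == "+"),
           TN = sum(pred == "-" & obs == "-"),
           FP = sum(pred == "+" & obs == "-"))
  structure(as.integer(out), names = names(out), class = "gedt_confusion")
}

#' Balanced accuracy
#'
#' The fitness metric: the arithmetic mean of sensitivity and specificity,
#' `1/2 * (TP/(TP+FN) + TN/(TN+FP))`. Robust to class imbalance — poor
#' performance in either class drags the score down — and equal to plain
#' classification accuracy when the data are class-balanced.
#'
#' @param x a `gedt_confusion` vector from [confusion()], or a named vector
#'   with elements `TP`, `FN`, `TN`, `FP`.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(x) {
  x <- x[c("TP", "FN", "TN", "FP")]
  if (any(is.na(x))) stop("need named counts TP, FN, TN, FP")
  n_case <- x[["TP"]] + x[["FN"]]
  n_ctrl <- x[["TN"]] + x[["FP"]]
  if (n_case == 0L || n_ctrl == 0L)
    stop("balanced accuracy undefined: a class is absent from the evaluation set")
  0.5 * (x[["TP"]] / n_case + x[["TN"]] / n_ctrl)
}

#' Fitness of a tree on a dataset
#'
#' Convenience wrapper: balanced accuracy of `tree`'s classifications on
#' `ds`. An invalid individual (a `NULL` tree, i.e. a genome whose mapping
#' exhausted its wrap budget) scores 0, the worst possible fitness, so
#' selection purges it.
#'
#' @param tree a [gedt_tree][leaf_node] or `NULL`.
#' @param ds a [gedt_data] dataset containing both classes.
#' @return Fitness in `[0, 1]`.
#' @export
fitness <- function(tree, ds) {
  if (is.null(tree)) return(0)
  balanced_accuracy(confusion(tree, ds))
}
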