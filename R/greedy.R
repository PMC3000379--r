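# Greedy gain-ratio decision-tree baseline (C4.5-style): hierarchical
# induction on 3-way genotype splits with subtree-replacement pruning under
# the pessimistic confidence-bound error estimate.

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Gain ratio of a genotype split
#'
#' Information gain of splitting the dataset on a SNP's three genotype
#' values, normalized by the split information (the entropy of the partition
#' sizes). Degenerate splits — a SNP constant across the subset, or one with
#' no information gain — score 0.
#'
#' @param ds a [gedt_data] dataset (or subset).
#' @param snp SNP column index.
#' @return The gain ratio (>= 0).
#' @export
split_gain_ratio <- function(ds, snp) {
  stopifnot(inherits(ds, "gedt_data"))
  g <- ds$genotypes[, snp]
  y <- label_int(ds)
  n <- length(y)
  if (n == 0L) return(0)
  counts <- vapply(0:2, function(gv) c(sum(g == gv & y == 1L),
                                       sum(g == gv & y == 0L)),
                   numeric(2L))  # 2 x 3: class by genotype
  sizes <- colSums(counts)
  h_class <- entropy_counts(c(sum(y == 1L), sum(y == 0L)))
  h_cond <- sum(vapply(1:3, function(j)
    sizes[j] / n * entropy_counts(counts[, j]), numeric(1L)))
  gain <- h_class - h_cond
  split_info <- entropy_counts(sizes)
  if (split_info <= 0 || gain <= 1e-12) return(0)
  gain / split_info
}

# vectorized gain ratios over all SNPs for a row subset (hot path)
gain_ratios_all <- function(geno, y, rows) {
  g <- geno[rows, , drop = FALSE]
  p <- ncol(g)
  yy <- y[rows]
  n <- length(rows)
  n_case <- sum(yy)
  case <- yy == 1L
  term <- function(x) ifelse(x > 0, -x * log2(x), 0)
  # entropy (bits) of a two-class split per SNP, from count vectors
  ent2 <- function(a, b) {
    tot <- a + b
    h <- numeric(length(tot))
    ok <- tot > 0
    h[ok] <- term(a[ok] / tot[ok]) + term(b[ok] / tot[ok])
    h
  }
  h_class <- entropy_counts(c(n_case, n - n_case))
  h_cond <- numeric(p)
  split_info <- numeric(p)
  for (gv in 0:2) {
    eq <- g == gv
    ca <- colSums(eq & case)
    tot <- colSums(eq)
    h_cond <- h_cond + tot / n * ent2(ca, tot - ca)
    split_info <- split_info + term(tot / n)
  }
  gain <- h_class - h_cond
  ifelse(split_info > 0 & gain > 1e-12, gain / split_info, 0)
}

#' Greedy gain-ratio tree induction
#'
#' Top-down hierarchical induction in the C4.5 mould: at each node the SNP
#' with the highest positive gain ratio is chosen and the data are split by
#' its three genotype values; recursion stops when a node is class-pure,
#' holds fewer than `min_leaf` individuals, or no split has positive gain.
#' Leaves are labelled by majority class, ties resolved toward the more
#' frequent class in the parent. Empty branches inherit the parent majority.
#'
#' @param ds a [gedt_data] dataset with both classes present.
#' @param min_leaf minimum individuals a node needs to be split further
#'   (default 2).
#' @return A [gedt_tree][leaf_node].
#' @seealso [prune_subtree_replacement()], [run_c45_cv()]
#' @export
build_greedy <- function(ds, min_leaf = 2L) {
  stopifnot(inherits(ds, "gedt_data"))
  check_two_classes(ds)
  geno <- ds$genotypes
  y <- label_int(ds)
  grow <- function(rows, parent_major) {
    n_case <- sum(y[rows])
    n <- length(rows)
    major <- if (n_case * 2L > n) "+"
             else if (n_case * 2L < n) "-"
             else parent_major
    if (n < min_leaf || n_case == 0L || n_case == n)
      return(leaf_node(major))
    gr <- gain_ratios_all(geno, y, rows)
    if (max(gr) <= 0) return(leaf_node(major))
    v <- which.max(gr)
    kids <- lapply(0:2, function(gv) {
      sub <- rows[geno[rows, v] == gv]
      if (length(sub) == 0L) leaf_node(major) else grow(sub, major)
    })
    split_node(v, kids[[1L]], kids[[2L]], kids[[3L]])
  }
  root_major <- if (sum(y) * 2L >= length(y)) "+" else "-"
  grow(seq_along(y), root_major)
}

# C4.5 pessimistic error estimate: observed error count e out of n corrected
# to the upper confidence bound at confidence level cf (expected errors).
pessimistic_errors <- function(e, n, cf = 0.25) {
  if (n == 0) return(0)
  if (e == 0) return(n * (1 - cf^(1 / n)))
  if (e + 0.5 >= n) return(n)
  z <- qnorm(1 - cf)
  f <- (e + 0.5) / n
  ub <- (f + z^2 / (2 * n) +
           z * sqrt(f / n - f^2 / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  ub * n
}

#' Subtree-replacement pruning
#'
#' Bottom-up pass over a fitted tree: each internal node is replaced by a
#' majority-class leaf whenever the pessimistic error estimate of that leaf
#' (the C4.5 confidence-factor upper bound at confidence `cf`) does not
#' exceed the summed pessimistic errors of the subtree's leaves. The pruned
#' tree is never larger than the input, and its training error can only
#' increase.
#'
#' @param tree a [gedt_tree][leaf_node] fitted on `ds`.
#' @param ds the training [gedt_data].
#' @param cf confidence factor (default 0.25).
#' @return The pruned [gedt_tree][leaf_node].
#' @export
prune_subtree_replacement <- function(tree, ds, cf = 0.25) {
  stopifnot(inherits(tree, "gedt_tree"), inherits(ds, "gedt_data"))
  geno <- ds$genotypes
  y <- label_int(ds)
  # returns list(tree, pess_err) for the row subset reaching the node
  prune <- function(node, rows) {
    n <- length(rows)
    n_case <- sum(y[rows])
    major <- if (n_case * 2L >= n) "+" else "-"
    e_leaf <- min(n_case, n - n_case)
    leaf_err <- pessimistic_errors(e_leaf, n, cf)
    if (node$leaf) {
      e <- if (node$class == "+") n - n_case else n_case
      return(list(tree = node, err = pessimistic_errors(e, n, cf)))
    }
    sub_err <- 0
    kids <- vector("list", 3L)
    for (g in 0:2) {
      sub <- rows[geno[rows, node$variable] == g]
      pr <- prune(node$children[[g + 1L]], sub)
      kids[[g + 1L]] <- pr$tree
      sub_err <- sub_err + pr$err
    }
    if (leaf_err <= sub_err)
      list(tree = leaf_node(major), err = leaf_err)
    else
      list(tree = split_node(node$variable, kids[[1L]], kids[[2L]],
                             kids[[3L]]),
           err = sub_err)
  }
  prune(tree, seq_along(y))$tree
}

#' Cross-validated greedy-tree analysis
#'
#' The same 10-fold protocol, cross-validation consistency and
#' majority-threshold final-model rule as [run_cv()], with the greedy
#' gain-ratio learner ([build_greedy()] followed by
#' [prune_subtree_replacement()]) fitted in each fold. Deterministic for a
#' given dataset and fold assignment (the learner involves no random
#' search).
#'
#' @param ds a [gedt_data] dataset.
#' @param cv_folds number of folds.
#' @param min_leaf,cf learner parameters, see [build_greedy()] and
#'   [prune_subtree_replacement()].
#' @param threshold final-model consistency threshold (see [final_model()]).
#' @return A `gedt_cv` object (see [run_cv()]).
#' @export
run_c45_cv <- function(ds, cv_folds = 10L, min_leaf = 2L, cf = 0.25,
                       threshold = NULL) {
  stopifnot(inherits(ds, "gedt_data"))
  k <- as.integer(cv_folds)
  folds <- make_folds(ds, k)
  trees <- vector("list", k)
  train_ba <- test_ba <- numeric(k)
  parse <- character(k)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train <- subset_data(ds, setdiff(seq_len(nrow(ds$genotypes)), test_idx))
    t0 <- build_greedy(train, min_leaf = min_leaf)
    t1 <- prune_subtree_replacement(t0, train, cf = cf)
    trees[[i]] <- t1
    train_ba[i] <- fitness(t1, train)
    test_ba[i] <- fitness(t1, subset_data(ds, test_idx))
    parse[i] <- to_parse_string(t1)
  }
  consistency <- cv_consistency(trees, ncol(ds$genotypes), ds$snp_names)
  final <- final_model(consistency, k, threshold)
  structure(list(folds = data.frame(fold = seq_len(k), tree = parse,
                                    train_ba = train_ba, test_ba = test_ba,
                                    stringsAsFactors = FALSE),
                 consistency = consistency, final_loci = final,
                 trees = trees, mode = "greedy", cv_folds = k,
                 snp_names = ds$snp_names),
            class = "gedt_cv")
}
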