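test_that("gain ratio is maximal for a perfectly separating SNP", {
  # genotype 0 <-> control, 2 <-> case, balanced: gain 1 bit, split info 1
  geno <- cbind(c(rep(0L, 10L), rep(2L, 10L)), rep(1L, 20L))
  ds <- gedt_data(geno, rep(c("-", "+"), each = 10L))
  expect_equal(split_gain_ratio(ds, 1L), 1)
  # constant SNP: degenerate split, no information
  expect_equal(split_gain_ratio(ds, 2L), 0)
})

test_that("gain ratio matches a brute-force entropy computation", {
  # 6 individuals; genotype x class counts chosen to be non-trivial
  geno <- cbind(c(0L, 0L, 1L, 1L, 2L, 2L))
  y <- c("+", "-", "+", "+", "-", "-")
  ds <- gedt_data(geno, y)
  # independent oracle: enumerate entropies straight from the definition
  h <- function(p) sum(vapply(p[p > 0], function(q) -q * log2(q), numeric(1)))
  h_class <- h(c(3, 3) / 6)
  h_cond <- (2 / 6) * h(c(1, 1) / 2) + (2 / 6) * h(c(2, 0) / 2) +
    (2 / 6) * h(c(0, 2) / 2)
  split_info <- h(c(2, 2, 2) / 6)
  expect_equal(split_gain_ratio(ds, 1L),
               (h_class - h_cond) / split_info)
})

test_that("greedy induction recovers a single perfectly predictive SNP", {
  set.seed(428)
  ds <- make_v1_data(60L, n_snps = 6L)
  tr <- build_greedy(ds)
  expect_equal(tree_depth(tr), 1L)
  expect_equal(variables_in(tr), 1L)
  expect_equal(fitness(tr, ds), 1)
})

test_that("label-independent SNPs at tiny n can leave a single leaf", {
  ds <- gedt_data(matrix(c(0L, 0L, 1L, 1L), 4L, 1L), c("+", "+", "-", "+"))
  tr <- prune_subtree_replacement(build_greedy(ds), ds)
  expect_equal(tree_size(tr), 1L)
})

test_that("pruning collapses pure and single-class subtrees, never grows", {
  set.seed(429)
  # already a leaf: identity
  ds0 <- make_noise_data(10L, 2L)
  expect_equal(to_parse_string(prune_subtree_replacement(L("+"), ds0)), "(+)")
  # node whose children all predict the same class collapses
  geno <- matrix(sample(0:2, 60L, TRUE), 30L, 2L)
  ds1 <- gedt_data(geno, rep(c("+", "-"), 15L))
  same <- N3(1, L("+"), L("+"), L("+"))
  expect_equal(tree_size(prune_subtree_replacement(same, ds1)), 1L)
  # pruning can only shrink trees and only worsen training fit
  for (i in 1:10) {
    ds <- make_noise_data(25L, 6L)
    full <- build_greedy(ds)
    pruned <- prune_subtree_replacement(full, ds)
    expect_lte(tree_size(pruned), tree_size(full))
    expect_lte(fitness(pruned, ds), fitness(full, ds))
  }
})

test_that("pure XOR epistasis defeats greedy hierarchical induction", {
  set.seed(430)
  m <- solve_penetrance("XOR", 0.5, 0.05)
  hits <- 0L
  for (i in 1:5) {
    ds <- simulate_dataset(m, 250L, 250L)
    cv <- run_c45_cv(ds)
    if (classify_result(cv$final_loci, ds$functional) == "conservative")
      hits <- hits + 1L
  }
  expect_equal(hits, 0L)
})

test_that("greedy CV is deterministic given the fold assignment", {
  set.seed(431)
  ds <- make_v1_data(80L, n_snps = 5L)
  set.seed(7); a <- run_c45_cv(ds, cv_folds = 5L)
  set.seed(7); b <- run_c45_cv(ds, cv_folds = 5L)
  expect_identical(a$folds, b$folds)
  expect_equal(unname(a$final_loci), 1L)
})

test_that("greedy has high power on a strong single-SNP main effect", {
  set.seed(432)
  # dominant single-locus disease model embedded among noise
  n <- 200L
  geno <- matrix(sample(0:2, n * 10L, TRUE), n, 10L)
  risk <- ifelse(geno[, 3L] >= 1L, 0.9, 0.1)
  labels <- ifelse(runif(n) < risk, "+", "-")
  ds <- gedt_data(geno, labels)
  cv <- run_c45_cv(ds)
  expect_true(3L %in% cv$final_loci)
})
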