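test_that("folds are stratified, disjoint, exhaustive and reproducible", {
  set.seed(424)
  ds <- make_noise_data(125L, 3L)
  folds <- make_folds(ds, 10L)
  expect_length(folds, 10L)
  sizes <- lengths(folds)
  expect_true(all(sizes == 25L))
  n_cases <- vapply(folds, function(f) sum(ds$labels[f] == "+"), integer(1L))
  expect_true(all(n_cases %in% c(12L, 13L)))
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_len(250L))
  set.seed(99); f1 <- make_folds(ds, 10L)
  set.seed(99); f2 <- make_folds(ds, 10L)
  expect_identical(f1, f2)
  small <- make_noise_data(4L, 3L)
  expect_error(make_folds(small, 10L), "at least k")
})

test_that("consistency counts folds containing each variable exactly", {
  trees <- list(N3(7, L("+"), L("-"), L("+")),
                N3(7, N3(2, L("+"), L("-"), L("+")), L("-"), L("+")),
                L("-"),
                NULL)
  counts <- gedt:::cv_consistency(trees, 8L)
  expect_equal(unname(counts[7L]), 2L)
  expect_equal(unname(counts[2L]), 1L)
  expect_equal(sum(counts), 3L)
})

test_that("the final model applies the majority-consistency rule", {
  cons <- setNames(rep(0L, 10L), paste0("V", 1:10))
  cons[c("V1", "V2", "V8")] <- c(10L, 9L, 1L)
  expect_equal(final_model(cons, k = 10L), c(V1 = 1L, V2 = 2L))
  cons2 <- setNames(rep(2L, 10L), paste0("V", 1:10))
  expect_length(final_model(cons2, k = 10L), 0L)
  cons3 <- setNames(rep(0L, 10L), paste0("V", 1:10))
  cons3[1:3] <- c(10L, 6L, 6L)
  expect_equal(unname(final_model(cons3, k = 10L)), 1:3)
  expect_error(final_model(setNames(11L, "V1"), k = 10L), "\\[0, k\\]")
})

test_that("run_cv records per-fold models whose consistency it reports", {
  set.seed(425)
  ds <- make_v1_data(80L, n_snps = 4L)
  cfg <- gedt_config(generations = 40L, population_size = 60L,
                     n_islands = 2L, migration_interval = 10L, cv_folds = 5L)
  cv <- run_cv(ds, cfg)
  expect_s3_class(cv, "gedt_cv")
  expect_equal(nrow(cv$folds), 5L)
  manual <- integer(4L)
  for (t in cv$trees)
    if (!is.null(t)) manual[variables_in(t)] <- manual[variables_in(t)] + 1L
  expect_equal(unname(cv$consistency), manual)
  # the deterministic V1 signal should be found in every fold
  expect_equal(unname(cv$consistency["V1"]), 5L)
  expect_true(1L %in% cv$final_loci)
  expect_true(all(cv$folds$train_ba == 1))
})

test_that("held-out labels cannot influence a fold's trained model", {
  set.seed(426)
  ds <- make_noise_data(30L, 4L)
  train_idx <- 1:48
  test_idx <- 49:60
  train <- gedt:::subset_data(ds, train_idx)
  cfg <- tiny_config()
  set.seed(55); a <- evolve(train, cfg)
  # permute the held-out labels; the training partition is untouched
  ds2 <- ds
  ds2$labels[test_idx] <- rev(ds2$labels[test_idx])
  train2 <- gedt:::subset_data(ds2, train_idx)
  set.seed(55); b <- evolve(train2, cfg)
  expect_identical(to_parse_string(a$best_tree), to_parse_string(b$best_tree))
})

test_that("prediction accuracy is centred on 1/2 when labels are pure noise", {
  set.seed(427)
  cfg <- gedt_config(generations = 10L, population_size = 30L,
                     n_islands = 2L, migration_interval = 5L, cv_folds = 5L)
  mean_ba <- replicate(30, {
    ds <- make_noise_data(30L, 5L)
    mean(run_cv(ds, cfg)$folds$test_ba)
  })
  expect_equal(mean(mean_ba), 0.5, tolerance = 0.03)
})
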