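test_that("tournament selection returns the fittest of the sampled k", {
  set.seed(414)
  # with k covering the whole population the best must win
  fit <- c(0.6, 0.8)
  picks <- replicate(50, tournament_select(fit, k = 50L))
  expect_true(all(picks == 2L))
  # k = 1 is uniform random selection
  picks1 <- replicate(3000, tournament_select(c(0.1, 0.9), k = 1L))
  expect_gt(mean(picks1 == 1L), 0.4)
  expect_lt(mean(picks1 == 1L), 0.6)
})

test_that("k = 2 tournament wins match the order-statistics closed form", {
  set.seed(415)
  m <- 5L
  fit <- seq_len(m) / m  # distinct fitnesses, index m is best
  p_best <- 1 - ((m - 1) / m)^2  # P(best sampled at least once)
  draws <- replicate(1e5, tournament_select(fit, k = 2L))
  expect_equal(mean(draws == m), p_best, tolerance = 0.015)
})

test_that("one-point crossover swaps tails and conserves codon totals", {
  cfg <- gedt_config()
  set.seed(416)
  a <- gedt_genome(rep(1L, 20L))
  b <- gedt_genome(rep(2L, 20L))
  for (i in 1:25) {
    kids <- crossover_genomes(a, b, cfg)
    expect_equal(length(kids[[1L]]) + length(kids[[2L]]), 40L)
    # each child is a prefix of one parent followed by a suffix of the other
    c1 <- transcribe(kids[[1L]])
    runs <- rle(c1)$values
    expect_lte(length(runs), 2L)
  }
  # crossing a genome with itself creates no new codon content (cut points
  # are drawn independently, so only lengths can differ)
  kids <- crossover_genomes(a, a, cfg)
  expect_true(all(transcribe(kids[[1L]]) == 1L))
  expect_true(all(transcribe(kids[[2L]]) == 1L))
  expect_equal(length(kids[[1L]]) + length(kids[[2L]]), 40L)
  # offspring always respect the chromosome limits
  lim <- gedt:::codon_limits(cfg)
  short <- gedt_genome(rep(3L, lim[["min"]]))
  long <- gedt_genome(rep(4L, lim[["max"]]))
  for (i in 1:25) {
    kids <- crossover_genomes(short, long, cfg)
    lens <- vapply(kids, length, integer(1L))
    expect_true(all(lens >= lim[["min"]] & lens <= lim[["max"]]))
  }
})

test_that("mutation flips bits at the requested rate", {
  g <- gedt_genome(sample(0:255, 100L, TRUE))
  expect_identical(transcribe(mutate_genome(g, 0)), transcribe(g))
  comp <- transcribe(mutate_genome(g, 1))
  expect_identical(comp, bitwXor(transcribe(g), 255L))
  # mean flips over repeated trials matches the binomial expectation
  set.seed(417)
  flips <- replicate(4000, {
    m <- mutate_genome(g, 0.01)
    popcount8(bitwXor(transcribe(m), transcribe(g)))
  })
  expect_equal(mean(flips), 800 * 0.01, tolerance = 0.15)
  expect_length(transcribe(mutate_genome(g, 0.5)), 100L)
})

test_that("evolution solves a single-SNP deterministic dataset exactly", {
  set.seed(418)
  ds <- make_v1_data(100L)
  res <- evolve(ds, gedt_config(generations = 100L, population_size = 100L,
                                n_islands = 2L, migration_interval = 10L))
  expect_equal(res$best_fitness, 1.0)
  expect_true(1L %in% variables_in(res$best_tree))
})

test_that("identical seeds give identical evolutionary traces", {
  set.seed(419)
  ds <- make_noise_data(30L, 5L)
  cfg <- tiny_config()
  set.seed(77); a <- evolve(ds, cfg)
  set.seed(77); b <- evolve(ds, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(to_parse_string(a$best_tree), to_parse_string(b$best_tree))
  set.seed(78); ra <- random_search(ds, cfg)
  set.seed(78); rb <- random_search(ds, cfg)
  expect_identical(ra$trace, rb$trace)
})

test_that("best-ever fitness is non-decreasing across generations", {
  set.seed(420)
  for (i in 1:20) {
    ds <- make_noise_data(20L, 4L)
    res <- evolve(ds, tiny_config())
    expect_true(all(diff(res$trace$best_fitness) >= 0))
    expect_equal(max(res$trace$best_fitness), res$best_fitness)
  }
})

test_that("random search matches the GA's evaluation budget", {
  set.seed(421)
  ds <- make_noise_data(25L, 6L)
  cfg <- tiny_config()
  ev <- evolve(ds, cfg)
  rs <- random_search(ds, cfg)
  expect_equal(ev$n_evaluations,
               ev$generations_run * cfg$population_size)
  expect_equal(rs$n_evaluations,
               rs$generations_run * cfg$population_size)
  # running maximum property of the random-search trace
  expect_true(all(diff(rs$trace$best_fitness) >= 0))
})

test_that("a single island without migration is a plain generational GA", {
  set.seed(422)
  ds <- make_v1_data(60L)
  cfg <- gedt_config(generations = 60L, population_size = 60L,
                     n_islands = 1L, migration_interval = 0L)
  res <- evolve(ds, cfg)
  expect_equal(res$best_fitness, 1.0)
})

test_that("the GA finds a purely epistatic interaction the greedy path cannot", {
  # XOR signal at high heritability: the best evolved tree must use both
  # functional loci and beat every single-locus tree's training fitness
  set.seed(423)
  m <- solve_penetrance("XOR", 0.5, 0.4)
  ds <- simulate_dataset(m, 100L, 100L, n_snps = 10L)
  res <- evolve(ds, gedt_config(generations = 150L, population_size = 150L,
                                n_islands = 2L))
  expect_true(all(c(1L, 2L) %in% variables_in(res$best_tree)))
  expect_gt(res$best_fitness, 0.75)
})
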