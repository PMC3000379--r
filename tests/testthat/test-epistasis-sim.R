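test_that("heritability follows the penetrance-scale variance formula", {
  # constant table: no genetic variance at all
  flat <- penetrance_model("BOX", c(x = 0.3, y = 0.3), maf = 0.5)
  expect_equal(heritability(flat), 0)
  # XOR with x=1, y=z=0 at maf 0.5: K = 1/2, Var = 1/4, h2 = 1, and the
  # marginal penetrance is 1/2 at every genotype of both loci
  xor1 <- penetrance_model("XOR", c(x = 1, y = 0, z = 0), maf = 0.5)
  expect_equal(heritability(xor1), 1)
  expect_equal(prevalence(xor1), 0.5)
  expect_equal(unname(marginal_penetrance(xor1, 1)), rep(0.5, 3L))
  expect_equal(unname(marginal_penetrance(xor1, 2)), rep(0.5, 3L))
  # hand-computed 9-cell oracle at maf 0.5, HWE weights (1/4, 1/2, 1/4)
  w <- c(0.25, 0.5, 0.25)
  pg <- outer(w, w)
  K <- sum(pg * xor1$table)
  expect_equal(sum(pg * (xor1$table - K)^2) / (K * (1 - K)),
               heritability(xor1))
  # degenerate prevalence errors
  allone <- penetrance_model("BOX", c(x = 1, y = 1), maf = 0.25)
  expect_error(heritability(allone), "degenerate")
})

test_that("symmetric patterns are invariant to swapping the two loci", {
  for (pat in c("XOR", "BOX")) {
    m <- solve_penetrance(pat, 0.25, 0.05)
    expect_equal(m$table, t(m$table), ignore_attr = TRUE)
    expect_equal(marginal_penetrance(m, 1), marginal_penetrance(m, 2))
  }
})

test_that("BOX and MOD instances carry single-locus main effects", {
  for (pat in c("BOX", "MOD")) {
    m <- solve_penetrance(pat, 0.25, 0.05)
    expect_gt(diff(range(marginal_penetrance(m, 1))), 1e-3)
  }
})

test_that("the solver hits every grid heritability to 1e-6, XOR staying pure", {
  grid <- power_grid()
  grid <- grid[grid$n_cases == 125L, ]  # the 30 base simulation settings
  expect_equal(nrow(grid), 30L)
  for (i in seq_len(nrow(grid))) {
    m <- solve_penetrance(grid$pattern[i], grid$maf[i], grid$h2[i])
    expect_lt(abs(heritability(m) - grid$h2[i]), 1e-6)
    expect_equal(prevalence(m), 0.5)
    # the x symbol marks the published low-risk cells
    expect_lt(m$values[["x"]], m$values[["y"]])
    expect_true(all(m$table >= 0 & m$table <= 1))
    # cells sharing a pattern symbol share a value
    sym <- gedt:::PENETRANCE_PATTERNS[[grid$pattern[i]]]
    for (s in unique(as.vector(sym)))
      expect_equal(diff(range(m$table[sym == s])), 0)
    if (grid$pattern[i] == "XOR") {
      expect_lt(diff(range(marginal_penetrance(m, 1))), 1e-8)
      expect_lt(diff(range(marginal_penetrance(m, 2))), 1e-8)
    }
  }
  # closed-form oracle at maf 0.5, prevalence 1/2: the XOR deviation
  # direction is (-1, 1, 1)/4 over masses (1/2, 1/4, 1/4), so
  # x = 1/2 - sqrt(h2)/2 and y = z = 1/2 + sqrt(h2)/2
  m10 <- solve_penetrance("XOR", 0.5, 0.10)
  expect_equal(unname(m10$values),
               0.5 + c(-1, 1, 1) * sqrt(0.10) / 2, tolerance = 1e-9)
  expect_error(solve_penetrance("XOR", 0.25, 0.9), "feasible")
})

test_that("simulated datasets have the published dimensions and quotas", {
  set.seed(433)
  m <- solve_penetrance("XOR", 0.5, 0.10)
  ds <- simulate_dataset(m)
  expect_equal(dim(ds), c(250L, 100L))
  expect_equal(sum(ds$labels == "+"), 125L)
  expect_equal(sum(ds$labels == "-"), 125L)
  expect_equal(ds$functional, c(1L, 2L))
  ds2 <- simulate_dataset(m, 250L, 250L, n_snps = 100L)
  expect_equal(dim(ds2), c(500L, 100L))
  degenerate <- penetrance_model("BOX", c(x = 0, y = 0), maf = 0.5)
  expect_error(simulate_dataset(degenerate, 10L, 10L, n_snps = 3L,
                                max_draws = 1e4),
               "quota unreachable")
})

test_that("noise SNP genotypes follow Hardy-Weinberg proportions", {
  set.seed(434)
  m <- solve_penetrance("BOX", 0.25, 0.05)
  ds <- simulate_dataset(m, 20000L, 80000L, n_snps = 3L)
  counts <- tabulate(ds$genotypes[, 3L] + 1L, 3L)
  expected <- 1e5 * gedt:::hwe_weights(0.25)
  x2 <- sum((counts - expected)^2 / expected)
  expect_lt(x2, qchisq(0.999, df = 2L))
})

test_that("case genotypes at the functional loci follow Bayes' rule", {
  set.seed(435)
  m <- solve_penetrance("XOR", 0.5, 0.10)
  ds <- simulate_dataset(m, 1e5, 0L, n_snps = 2L)
  w <- gedt:::hwe_weights(0.5)
  pg <- outer(w, w)
  K <- prevalence(m)
  exp_p <- pg * m$table / K  # P(g | case), rows g2, cols g1
  obs <- table(factor(ds$genotypes[, 2L], 0:2),
               factor(ds$genotypes[, 1L], 0:2))
  nz <- exp_p > 0
  x2 <- sum((obs[nz] - 1e5 * exp_p[nz])^2 / (1e5 * exp_p[nz]))
  expect_equal(sum(obs[!nz]), 0L)
  expect_lt(x2, qchisq(0.999, df = sum(nz) - 1L))
})

test_that("grid simulation writes byte-identical replicates and a manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  grid <- power_grid()[c(1L, 3L), ]
  set.seed(436)
  man1 <- simulate_grid(dir1, grid, n_replicates = 2L, n_snps = 8L)
  set.seed(436)
  man2 <- simulate_grid(dir2, grid, n_replicates = 2L, n_snps = 8L)
  expect_equal(nrow(man1), 4L)
  expect_identical(man1, man2)
  for (f in man1$file)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  back <- read_gedt_data(file.path(dir1, man1$file[1L]))
  expect_equal(dim(back), c(250L, 8L))
})

test_that("the default grid mirrors the published model numbering", {
  grid <- power_grid()
  expect_equal(nrow(grid), 40L)
  expect_equal(grid$pattern[c(1L, 11L, 21L, 31L)],
               c("XOR", "BOX", "MOD", "XOR"))
  expect_equal(grid$h2[19L], 0.10)
  expect_equal(grid$maf[19L], 0.25)
  expect_equal(grid$n_cases[31:40], rep(250L, 10L))
})
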