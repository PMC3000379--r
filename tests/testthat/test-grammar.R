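test_that("transcription reads codons as unsigned big-endian integers", {
  expect_equal(transcribe(genome_from_bits(c(0, 0, 0, 0, 0, 1, 1, 1))), 7L)
  bits2 <- c(0, 0, 0, 0, 0, 0, 1, 0,  0, 0, 0, 0, 0, 0, 1, 1)
  expect_equal(transcribe(genome_from_bits(bits2)), c(2L, 3L))
  allzero <- gedt_genome(rep(0L, 50L))
  expect_equal(transcribe(allzero), rep(0L, 50L))
  # bits round-trip through the genome container
  expect_equal(genome_bits(genome_from_bits(bits2)), as.integer(bits2))
})

test_that("the MOD rule picks alternatives by codon value modulo count", {
  expect_equal(select_rule(7, 2), 1L)
  expect_equal(select_rule(6, 2), 0L)
  expect_equal(select_rule(5, 3), 2L)
})

test_that("mapping follows the leftmost derivation with hand-traced oracle", {
  g3 <- gedt_grammar(3)
  # class-only derivation: 3 mod 2 = 1 -> <class>, 4 mod 2 = 0 -> '+'
  t1 <- map_to_tree(c(3, 4), g3)
  expect_equal(to_parse_string(t1), "(+)")
  # hand-traced: 2->recursive, 1->V2, then three class leaves +, -, -
  t2 <- map_to_tree(c(2, 1, 3, 0, 5, 1, 7, 1), g3)
  expect_equal(to_parse_string(t2), "(V2 0:(+) 1:(-) 2:(-))")
  # all-even single codon recurses forever: invalid after the wrap budget
  expect_null(map_to_tree(c(0), g3, max_wraps = 2))
})

test_that("C++ mapping agrees with an independent R interpreter", {
  set.seed(402)
  cfg <- gedt_config(population_size = 60L)
  gr <- gedt_grammar(7L)
  pop <- sensible_init(gr, cfg)
  # also exercise wrapped and invalid genomes via random codon strings
  rnd <- lapply(1:60, function(i) sample(0:255, sample(7:40, 1), TRUE))
  for (codons in c(lapply(pop, transcribe), rnd)) {
    ref <- ref_map(codons, 7L, 2L)
    got <- map_to_tree(codons, gr, 2L)
    if (is.null(ref)) {
      expect_null(got)
    } else {
      expect_equal(to_parse_string(got), to_parse_string(ref$tree))
    }
  }
})

test_that("mapping is neutral to adding multiples of the alternative count", {
  set.seed(403)
  gr <- gedt_grammar(5L)
  pop <- sensible_init(gr, gedt_config(population_size = 30L))
  for (g in pop[1:15]) {
    codons <- transcribe(g)
    ref <- ref_map(codons, 5L)
    base <- to_parse_string(ref$tree)
    # bump one consumed codon by k * n_alternatives, staying inside 8 bits
    row <- ref$trace[sample.int(nrow(ref$trace), 1L), ]
    pos <- row[["position"]]; na <- row[["n_alt"]]
    k <- max(1L, (255L - codons[pos]) %/% na)
    if (k >= 1L) {
      mod <- codons
      mod[pos] <- mod[pos] + k * na
      expect_equal(to_parse_string(map_to_tree(mod, gr)), base)
    }
  }
})

test_that("sensible initialization yields only valid trees, half at full depth", {
  set.seed(404)
  cfg <- gedt_config()  # population 500
  gr <- gedt_grammar(20L)
  pop <- sensible_init(gr, cfg)
  expect_length(pop, 500L)
  trees <- lapply(pop, map_to_tree, grammar = gr, max_wraps = cfg$max_wraps)
  expect_equal(sum(vapply(trees, is.null, logical(1L))), 0L)
  depths <- vapply(trees, tree_depth, integer(1L))
  # the "full" half is built to the maximum depth exactly (grow trees may
  # reach it too by chance)
  expect_gte(sum(depths == cfg$sensible_init_max_depth), 250L)
  expect_true(all(depths <= cfg$sensible_init_max_depth))
  lim <- gedt:::codon_limits(cfg)
  sizes <- vapply(pop, length, integer(1L))
  expect_true(all(sizes >= lim[["min"]] & sizes <= lim[["max"]]))
})

test_that("encode -> map round trip reproduces every initialized tree", {
  set.seed(405)
  cfg <- gedt_config(population_size = 40L)
  gr <- gedt_grammar(9L)
  pop <- sensible_init(gr, cfg)
  for (g in pop) {
    t0 <- map_to_tree(g, gr, cfg$max_wraps)
    g2 <- encode_tree(t0, gr, cfg)
    t1 <- map_to_tree(g2, gr, cfg$max_wraps)
    expect_equal(to_parse_string(t1), to_parse_string(t0))
  }
})

test_that("initialization and mapping are deterministic under a seed", {
  cfg <- gedt_config(population_size = 50L)
  gr <- gedt_grammar(10L)
  set.seed(406); a <- sensible_init(gr, cfg)
  set.seed(406); b <- sensible_init(gr, cfg)
  expect_identical(a, b)
  codons <- transcribe(a[[1L]])
  expect_identical(to_parse_string(map_to_tree(codons, gr)),
                   to_parse_string(map_to_tree(codons, gr)))
})

test_that("the grammar enforces codon addressability and alternative counts", {
  gr <- gedt_grammar(100L)
  expect_equal(unname(gr$n_alternatives[c("S", "pseudoV", "v", "class")]),
               c(1L, 2L, 100L, 2L))
  expect_error(gedt_grammar(300L, codon_size_bits = 8L), "cannot address")
  expect_output(print(gr), "pseudoV")
})
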