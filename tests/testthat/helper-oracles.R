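# Shared fixtures and independent oracles used across the test files.

# Reference implementation of the genotype-phenotype mapping, written
# independently of the package's C++ engine: a plain recursive-descent
# interpreter of the grammar that also records, for every codon it consumes,
# the genome position used and the alternative count of the non-terminal.
# Returns NULL for an invalid (wrap-budget-exhausted) derivation.
ref_map <- function(codons, n_snps, max_wraps = 2L) {
  pos <- 0L
  wraps <- 0L
  len <- length(codons)
  trace <- list()
  failed <- FALSE
  take <- function(n_alt) {
    if (pos == len) {
      if (wraps >= max_wraps) {
        failed <<- TRUE
        return(NA_integer_)
      }
      wraps <<- wraps + 1L
      pos <<- 0L
    }
    v <- codons[pos + 1L]
    trace[[length(trace) + 1L]] <<- c(position = pos + 1L, n_alt = n_alt)
    pos <<- pos + 1L
    v %% n_alt
  }
  expand <- function() {
    alt <- take(2L)  # pseudoV
    if (failed) return(NULL)
    if (alt == 1L) {
      cls <- take(2L)  # class: alternative 0 is '+'
      if (failed) return(NULL)
      return(leaf_node(if (cls == 0L) "+" else "-"))
    }
    v <- take(n_snps)
    if (failed) return(NULL)
    kids <- vector("list", 3L)
    for (g in 1:3) {
      kids[[g]] <- expand()
      if (failed) return(NULL)
    }
    split_node(v + 1L, kids[[1L]], kids[[2L]], kids[[3L]])
  }
  tree <- expand()
  if (failed) return(NULL)
  list(tree = tree, trace = do.call(rbind, trace))
}

# balanced two-class dataset with labels independent of the genotypes
make_noise_data <- function(n_per_class, n_snps, maf = 0.3) {
  w <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  n <- 2L * n_per_class
  geno <- matrix(sample(0:2, n * n_snps, TRUE, prob = w), n, n_snps)
  gedt_data(geno, rep(c("+", "-"), each = n_per_class))
}

# dataset whose class is a deterministic function of one SNP (V1 == 2)
make_v1_data <- function(n, n_snps = 5L) {
  geno <- matrix(sample(0:2, n * n_snps, TRUE), n, n_snps)
  # ensure both classes occur
  geno[1L, 1L] <- 2L
  geno[2L, 1L] <- 0L
  gedt_data(geno, ifelse(geno[, 1L] == 2L, "+", "-"))
}

# quick tree literals
L <- function(cl) leaf_node(cl)
N3 <- function(v, a, b, c) split_node(v, a, b, c)

# small config for fast GA runs in unit tests
tiny_config <- function(...) {
  gedt_config(generations = 15L, population_size = 30L, n_islands = 2L,
              migration_interval = 5L, ...)
}

# counts set bits of codon-value differences (for mutation-rate checks)
popcount8 <- local({
  tab <- vapply(0:255, function(x) sum(bitwAnd(x, 2^(0:7)) > 0), numeric(1))
  function(x) sum(tab[x + 1L])
})
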