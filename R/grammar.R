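#' The GEDT grammar
#'
#' The context-free grammar `{N, T, P, S}` used to map binary genomes onto
#' decision trees for a dataset with `n_snps` SNP attributes. Non-terminals
#' are `S`, `pseudoV`, `v`, `val_0`, `val_1`, `val_2` and `class`; terminals
#' are the genotype values `0/1/2`, the classes `+`/`-` and the SNP
#' variables `V1..Vn`. The productions are
#'
#' ```
#' S       := <pseudoV>
#' pseudoV := <v> <val_0> <pseudoV> <val_1> <pseudoV> <val_2> <pseudoV>
#'          | <class>
#' val_0   := 0
#' val_1   := 1
#' val_2   := 2
#' class   := + | -
#' v       := V1 | V2 | ... | Vn
#' ```
#'
#' `pseudoV`'s first alternative creates an internal node (a SNP test with
#' one subtree per genotype value); its second terminates a branch with a
#' class leaf.
#'
#' @param n_snps number of SNP attributes; must not exceed `2^codon_size_bits`
#'   or the MOD mapping rule could never address every variable.
#' @param codon_size_bits bits per codon (used only for the addressability
#'   check).
#' @return An object of class `gedt_grammar` with element `n_alternatives`,
#'   the alternative count per non-terminal.
#' @export
gedt_grammar <- function(n_snps, codon_size_bits = 8L) {
  n_snps <- as.integer(n_snps)
  if (n_snps < 1L) stop("n_snps must be >= 1")
  if (n_snps > 2^codon_size_bits)
    stop("n_snps = ", n_snps, " exceeds 2^codon_size_bits = ",
         2^codon_size_bits, "; a codon cannot address every SNP")
  structure(list(n_snps = n_snps,
                 start = "S",
                 n_alternatives = c(S = 1L, pseudoV = 2L, v = n_snps,
                                    val_0 = 1L, val_1 = 1L, val_2 = 1L,
                                    class = 2L)),
            class = "gedt_grammar")
}

#' @export
print.gedt_grammar <- function(x, ...) {
  cat("GEDT grammar over", x$n_snps, "SNP variables (BNF):\n")
  cat("  (1) S       := <pseudoV>\n")
  cat("  (2) pseudoV := <v> <val_0> <pseudoV> <val_1> <pseudoV>",
      "<val_2> <pseudoV> | <class>\n")
  cat("  (3) val_0   := 0\n  (4) val_1   := 1\n  (5) val_2   := 2\n")
  cat("  (6) class   := + | -\n")
  cat("  (7) v       := V1 | ... | V", x$n_snps, "\n", sep = "")
  invisible(x)
}

#' Binary genomes of fixed-width codons
#'
#' A genome is a variable-length binary string read in consecutive
#' `codon_size`-bit blocks ("codons"). `gedt_genome()` builds one from codon
#' integer values; `genome_from_bits()` from a raw 0/1 bit vector whose
#' length must be a multiple of `codon_size`.
#'
#' @param codons integer vector of codon values in `[0, 2^codon_size - 1]`.
#' @param bits integer/logical vector of bits, most significant bit of each
#'   codon first.
#' @param codon_size bits per codon.
#' @return An object of class `gedt_genome`.
#' @export
gedt_genome <- function(codons, codon_size = 8L) {
  codons <- as.integer(codons)
  codon_size <- as.integer(codon_size)
  if (length(codons) < 1L) stop("genome must contain at least one codon")
  if (any(codons < 0L | codons >= 2^codon_size))
    stop("codon values must lie in [0, 2^codon_size - 1]")
  structure(list(codons = codons, codon_size = codon_size),
            class = "gedt_genome")
}

#' @rdname gedt_genome
#' @export
genome_from_bits <- function(bits, codon_size = 8L) {
  bits <- as.integer(bits)
  if (!all(bits %in% 0:1)) stop("bits must be 0/1")
  if (length(bits) == 0L || length(bits) %% codon_size != 0L)
    stop("bit-string length must be a positive multiple of codon_size")
  mat <- matrix(bits, nrow = codon_size)  # one column per codon, MSB first
  codons <- as.integer(colSums(mat * 2^((codon_size - 1L):0)))
  gedt_genome(codons, codon_size)
}

#' @rdname gedt_genome
#' @param genome a `gedt_genome`.
#' @export
genome_bits <- function(genome) {
  stopifnot(inherits(genome, "gedt_genome"))
  k <- genome$codon_size
  as.integer(vapply(genome$codons,
                    function(cv) as.integer((cv %/% 2^((k - 1L):0)) %% 2L),
                    integer(k)))
}

#' @export
print.gedt_genome <- function(x, ...) {
  cat("GE genome: ", length(x$codons), " codons x ", x$codon_size,
      " bits\n", sep = "")
  invisible(x)
}

#' @export
length.gedt_genome <- function(x) length(x$codons)

#' Transcribe a genome into its codon integer sequence
#'
#' Each consecutive `codon_size`-bit block is read as an unsigned big-endian
#' integer.
#'
#' @param genome a [gedt_genome].
#' @return Integer vector of codon values.
#' @export
transcribe <- function(genome) {
  stopifnot(inherits(genome, "gedt_genome"))
  genome$codons
}

#' The MOD production-selection rule
#'
#' `rule = codon_value MOD n_alternatives`: the 0-based index of the grammar
#' alternative chosen by a codon.
#'
#' @param codon_value non-negative codon integer value.
#' @param n_alternatives number of alternatives of the non-terminal being
#'   expanded (>= 1).
#' @return 0-based alternative index.
#' @export
select_rule <- function(codon_value, n_alternatives) {
  stopifnot(n_alternatives >= 1L, all(codon_value >= 0))
  as.integer(codon_value %% n_alternatives)
}

#' Map a genome onto a decision tree
#'
#' Performs the genotype-to-phenotype mapping: codons are consumed left to
#' right while expanding the leftmost unresolved non-terminal, each codon
#' choosing an alternative through the MOD rule. Non-terminals with a single
#' alternative (`S`, `val_0`, `val_1`, `val_2`) expand without consuming a
#' codon. When the codons run out the sequence wraps around to the start, at
#' most `max_wraps` times; a derivation still incomplete after the wrap
#' budget yields an invalid individual, returned as `NULL` (such individuals
#' receive fitness 0 during evolution).
#'
#' @param genome a [gedt_genome], or a plain integer vector of codon values.
#' @param grammar a [gedt_grammar].
#' @param max_wraps non-negative wrap budget.
#' @return A [gedt_tree][leaf_node], or `NULL` for an invalid mapping.
#' @export
map_to_tree <- function(genome, grammar, max_wraps = 2L) {
  stopifnot(inherits(grammar, "gedt_grammar"))
  codons <- if (inherits(genome, "gedt_genome")) genome$codons
            else as.integer(genome)
  flat_to_tree(cpp_map(codons, grammar$n_snps, as.integer(max_wraps)))
}

#' Encode a decision tree into a genome
#'
#' Inverse of [map_to_tree()]: writes, for every codon-consuming decision of
#' the derivation that produces `tree`, the bare alternative index, then pads
#' the genome with uniform random (unused) codons up to `min_chromosome`.
#' `map_to_tree(encode_tree(t, ...), ...)` reproduces `t` exactly.
#'
#' @param tree a [gedt_tree][leaf_node].
#' @param grammar a [gedt_grammar].
#' @param config a [gedt_config] supplying the chromosome-size limits and
#'   codon size.
#' @return A [gedt_genome].
#' @export
encode_tree <- function(tree, grammar, config = gedt_config()) {
  stopifnot(inherits(tree, "gedt_tree"), inherits(grammar, "gedt_grammar"))
  enc <- function(node) {
    if (node$leaf) c(1L, if (node$class == "+") 0L else 1L)
    else c(0L, node$variable - 1L,
           unlist(lapply(node$children, enc), use.names = FALSE))
  }
  codons <- enc(tree)
  lim <- codon_limits(config)
  if (any(codons >= 2^config$codon_size_bits))
    stop("tree variable index does not fit in a codon")
  if (length(codons) > lim[["max"]])
    stop("tree encoding needs ", length(codons),
         " codons, above the max_chromosome limit of ", lim[["max"]])
  pad <- lim[["min"]] - length(codons)
  if (pad > 0L)
    codons <- c(codons,
                as.integer(floor(runif(pad) * 2^config$codon_size_bits)))
  gedt_genome(codons, config$codon_size_bits)
}

#' Sensible initialization of a genome population
#'
#' Builds `config$population_size` decision trees directly from the grammar
#' — half "full" trees grown to `sensible_init_max_depth` by always choosing
#' the recursive rule until leaves are forced, half "grow" trees of a random
#' depth no greater than the maximum — and then converts each tree into
#' codons. Every genome in the returned population therefore maps to a
#' complete, valid tree.
#'
#' @param grammar a [gedt_grammar].
#' @param config a [gedt_config].
#' @return List of [gedt_genome] objects of length `config$population_size`.
#' @export
sensible_init <- function(grammar, config = gedt_config()) {
  stopifnot(inherits(grammar, "gedt_grammar"),
            inherits(config, "gedt_config"))
  if (config$sensible_init_max_depth < 1L)
    stop("sensible_init_max_depth must be >= 1")
  lim <- codon_limits(config)
  raw <- cpp_sensible_init(config$population_size, grammar$n_snps,
                           config$sensible_init_max_depth,
                           lim[["min"]], lim[["max"]],
                           config$codon_size_bits)
  lapply(raw, gedt_genome, codon_size = config$codon_size_bits)
}
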