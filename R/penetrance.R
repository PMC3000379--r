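# Two-locus penetrance models. A model is a 3x3 table f[g2+1, g1+1] of
# disease probabilities over the genotype combinations of two bi-allelic
# loci (genotypes coded 0/1/2 = copies of the minor allele, i.e. AA/Aa/aa
# columns and BB/Bb/bb rows), plus the minor allele frequency that sets the
# Hardy-Weinberg genotype weights.

# symbol placements of the three published epistasis patterns
# (columns AA Aa aa; rows BB Bb bb)
PENETRANCE_PATTERNS <- list(
  XOR = matrix(c("y", "x", "y",
                 "x", "z", "x",
                 "y", "x", "y"), 3L, 3L, byrow = TRUE),
  BOX = matrix(c("x", "x", "x",
                 "x", "y", "y",
                 "x", "y", "y"), 3L, 3L, byrow = TRUE),
  MOD = matrix(c("x", "y", "y",
                 "x", "x", "y",
                 "y", "y", "x"), 3L, 3L, byrow = TRUE))

#' Two-locus penetrance model
#'
#' Builds a penetrance model from symbol values and one of the three
#' epistasis patterns:
#'
#' * `XOR` — pure epistasis (no single-locus main effects); risk depends on
#'   being heterozygous at exactly one of the two loci.
#' * `BOX` — symmetric interaction with main effects at both loci.
#' * `MOD` — an asymmetric, modified-XOR risk pattern with a main effect in
#'   addition to the interaction.
#'
#' Cells sharing a pattern symbol share a value; e.g. the XOR table is
#' `rbind(c(y,x,y), c(x,z,x), c(y,x,y))` over columns AA/Aa/aa and rows
#' BB/Bb/bb.
#'
#' @param pattern `"XOR"`, `"BOX"` or `"MOD"`.
#' @param values named list/vector of symbol values in `[0, 1]` (`x`, `y`
#'   and, for XOR, `z`).
#' @param maf minor allele frequency in `(0, 0.5]`, shared by both loci.
#' @return An object of class `penetrance_model` with elements `pattern`,
#'   `table` (3x3 matrix), `values` and `maf`.
#' @seealso [solve_penetrance()], [heritability()], [simulate_dataset()]
#' @export
penetrance_model <- function(pattern, values, maf) {
  pattern <- match.arg(pattern, names(PENETRANCE_PATTERNS))
  sym <- PENETRANCE_PATTERNS[[pattern]]
  need <- sort(unique(as.vector(sym)))
  values <- unlist(values)
  if (!all(need %in% names(values)))
    stop(pattern, " pattern needs symbol values for: ",
         paste(need, collapse = ", "))
  if (any(values[need] < 0 | values[need] > 1))
    stop("penetrance values must lie in [0, 1]")
  if (maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  tab <- matrix(values[sym], 3L, 3L,
                dimnames = list(c("BB", "Bb", "bb"), c("AA", "Aa", "aa")))
  structure(list(pattern = pattern, table = tab,
                 values = values[need], maf = maf),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(x$pattern, " penetrance model, MAF ", x$maf, ", heritability ",
      sprintf("%.4f", heritability(x)), ", prevalence ",
      sprintf("%.4f", prevalence(x)), "\n", sep = "")
  print(round(x$table, 4L))
  invisible(x)
}

# HWE genotype probabilities for 0/1/2 copies of the minor allele
hwe_weights <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Prevalence, heritability and marginal penetrance of a model
#'
#' With genotype probabilities `P(g1, g2)` from Hardy-Weinberg proportions
#' at the model's minor allele frequency, `prevalence()` returns
#' `K = sum P(g) f(g)`; `heritability()` returns the broad-sense
#' heritability on the penetrance scale,
#' `sum P(g) (f(g) - K)^2 / (K (1 - K))`; and `marginal_penetrance()`
#' returns the three single-locus disease probabilities
#' `P(disease | genotype at locus)`, averaging over the other locus. A flat
#' marginal at both loci is the signature of pure epistasis.
#'
#' @param model a [penetrance_model].
#' @param locus 1 (columns, locus A) or 2 (rows, locus B).
#' @return `prevalence()`, `heritability()`: a single number;
#'   `marginal_penetrance()`: a numeric 3-vector named by genotype value.
#' @export
heritability <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  w <- hwe_weights(model$maf)
  pg <- outer(w, w)  # rows g2 (B), cols g1 (A): P(g2) * P(g1)
  K <- sum(pg * model$table)
  if (K <= 0 || K >= 1)
    stop("degenerate model: prevalence is ", K,
         " (nobody or everybody affected)")
  sum(pg * (model$table - K)^2) / (K * (1 - K))
}

#' @rdname heritability
#' @export
prevalence <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  w <- hwe_weights(model$maf)
  sum(outer(w, w) * model$table)
}

#' @rdname heritability
#' @export
marginal_penetrance <- function(model, locus) {
  stopifnot(inherits(model, "penetrance_model"), locus %in% 1:2)
  w <- hwe_weights(model$maf)
  m <- if (locus == 1L) colSums(model$table * w)  # weight rows (locus B)
       else colSums(t(model$table) * w)           # weight columns (locus A)
  names(m) <- as.character(0:2)
  m
}

#' Solve a penetrance pattern for a target heritability
#'
#' The published tables give only the symbol placements, not numeric
#' penetrances; this solver recovers a concrete table for any requested
#' effect size. Penetrances are written as deviations around a fixed
#' prevalence, `f = K + s d`, where `d` assigns one deviation per pattern
#' symbol and the scale `s` sets the effect size:
#'
#' * `d` is chosen prevalence-neutral (the HWE-weighted mean deviation is
#'   zero, so the population prevalence is exactly `K`), and for `XOR` it
#'   additionally satisfies the flat-marginal constraint at both loci, so
#'   XOR instances stay purely epistatic at any effect size;
#' * the sign convention follows the published pattern descriptions: the
#'   `x` cells are the low-risk cells (exactly one heterozygous locus for
#'   XOR; the AA column and BB row for BOX; for MOD, the asymmetric `y`
#'   cells carry the elevated risk);
#' * `s` then follows in closed form from
#'   `h2 = s^2 Var(d) / (K (1 - K))`.
#'
#' The default prevalence `K = 1/2` maximizes the phenotypic variance
#' `K (1 - K)`, so the target heritability is the sole knob controlling the
#' genotype-phenotype association strength; every genotype combination
#' retains a nonzero disease probability (phenocopies exist at every
#' effect size in the simulated grid, as in real complex-disease data).
#'
#' @param pattern `"XOR"`, `"BOX"` or `"MOD"`.
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @param target_h2 target broad-sense heritability in `(0, 1)`.
#' @param prevalence population disease prevalence `K` of the solved model.
#' @return A [penetrance_model] whose [heritability()] equals `target_h2`
#'   within `1e-6` and whose [prevalence()] equals `prevalence`; for XOR,
#'   the marginal penetrance spread is below `1e-8` at both loci.
#' @export
solve_penetrance <- function(pattern, maf, target_h2, prevalence = 0.5) {
  pattern <- match.arg(pattern, names(PENETRANCE_PATTERNS))
  if (target_h2 <= 0 || target_h2 >= 1)
    stop("target_h2 must lie in (0, 1)")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  K <- prevalence
  sym <- PENETRANCE_PATTERNS[[pattern]]
  w <- hwe_weights(maf)
  pg <- outer(w, w)
  symbols <- sort(unique(as.vector(sym)))  # "x", "y" (and "z" for XOR)
  mass <- vapply(symbols, function(s) sum(pg[sym == s]), numeric(1L))
  if (pattern == "XOR") {
    # deviation direction orthogonal to both the prevalence constraint and
    # the flat-marginal constraint x(2h1-1) + y(1-h1) - z h1 = 0
    h1 <- 2 * maf * (1 - maf)
    flat <- c(2 * h1 - 1, 1 - h1, -h1)
    d <- c(mass[2L] * flat[3L] - mass[3L] * flat[2L],
           mass[3L] * flat[1L] - mass[1L] * flat[3L],
           mass[1L] * flat[2L] - mass[2L] * flat[1L])
    if (d[1L] > 0) d <- -d  # x is the low-risk symbol
  } else {
    d <- c(-mass[["y"]], mass[["x"]])  # x low risk, y elevated
  }
  names(d) <- symbols
  v_d <- sum(mass * d^2)  # Var(f)/s^2, since the mean deviation is zero
  s <- sqrt(target_h2 * K * (1 - K) / v_d)
  # largest scale keeping every penetrance inside [0, 1]
  s_max <- min(ifelse(d > 0, (1 - K) / d, K / -d))
  if (s > s_max) {
    h2_max <- s_max^2 * v_d / (K * (1 - K))
    stop("target heritability ", target_h2, " infeasible for ", pattern,
         " at maf ", maf, " and prevalence ", K,
         "; feasible range is (0, ", sprintf("%.6f", h2_max), "]")
  }
  model <- penetrance_model(pattern, K + s * d, maf)
  model$target_h2 <- target_h2
  if (abs(heritability(model) - target_h2) > 1e-6)
    stop("solver failed to reach the target heritability")
  model
}
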