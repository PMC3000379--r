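#' Simulate a case-control dataset under a two-locus penetrance model
#'
#' Emulates penetrance-table case-control simulation: every SNP's genotype
#' is drawn independently from Hardy-Weinberg proportions, disease status is
#' assigned with probability `f(g1, g2)` read from the penetrance table at
#' the two functional loci, and individuals are accumulated by rejection
#' sampling until exactly `n_cases` cases and `n_controls` controls are
#' collected. Noise SNPs are independent of the outcome by construction (and
#' are drawn only for retained individuals, which leaves the joint
#' distribution unchanged).
#'
#' @param model a [penetrance_model] (see [solve_penetrance()]).
#' @param n_cases,n_controls required number of cases and controls.
#' @param n_snps total SNP count; all but the two functional loci are noise.
#' @param functional positions of the two functional SNPs (default columns
#'   1 and 2).
#' @param noise_maf minor allele frequency of the noise SNPs (defaults to
#'   the model's MAF).
#' @param max_draws cap on genotype draws before giving up (guards against
#'   near-degenerate penetrance tables).
#' @return A [gedt_data] with `n_cases + n_controls` rows, `n_snps` columns
#'   and `functional` recorded.
#' @examples
#' m <- solve_penetrance("XOR", maf = 0.5, target_h2 = 0.1)
#' ds <- simulate_dataset(m, 125, 125)
#' ds
#' @export
simulate_dataset <- function(model, n_cases = 125L, n_controls = 125L,
                             n_snps = 100L, functional = c(1L, 2L),
                             noise_maf = NULL, max_draws = 1e7) {
  stopifnot(inherits(model, "penetrance_model"))
  n_snps <- as.integer(n_snps)
  functional <- as.integer(functional)
  if (length(functional) != 2L || functional[1L] == functional[2L] ||
      any(functional < 1L | functional > n_snps))
    stop("functional must be two distinct SNP positions in [1, n_snps]")
  if (is.null(noise_maf)) noise_maf <- model$maf
  w <- hwe_weights(model$maf)
  g1_keep <- integer(0L); g2_keep <- integer(0L); y_keep <- integer(0L)
  need_case <- as.integer(n_cases); need_ctrl <- as.integer(n_controls)
  drawn <- 0
  batch <- max(1000L, 4L * (need_case + need_ctrl))
  while (need_case > 0L || need_ctrl > 0L) {
    if (drawn >= max_draws)
      stop("case/control quota unreachable within ", max_draws,
           " genotype draws (prevalence ", sprintf("%.4g", prevalence(model)),
           ")")
    g1 <- sample.int(3L, batch, replace = TRUE, prob = w) - 1L
    g2 <- sample.int(3L, batch, replace = TRUE, prob = w) - 1L
    drawn <- drawn + batch
    f <- model$table[cbind(g2 + 1L, g1 + 1L)]
    is_case <- runif(batch) < f
    # accept, in draw order, cases/controls still needed; discard the rest
    ci <- which(is_case)
    vi <- which(!is_case)
    keep <- sort(c(ci[seq_len(min(length(ci), need_case))],
                   vi[seq_len(min(length(vi), need_ctrl))]))
    need_case <- need_case - sum(is_case[keep])
    need_ctrl <- need_ctrl - sum(!is_case[keep])
    g1_keep <- c(g1_keep, g1[keep]); g2_keep <- c(g2_keep, g2[keep])
    y_keep <- c(y_keep, as.integer(is_case[keep]))
  }
  n <- length(y_keep)
  geno <- matrix(0L, n, n_snps)
  noise_cols <- setdiff(seq_len(n_snps), functional)
  if (length(noise_cols)) {
    wn <- hwe_weights(noise_maf)
    geno[, noise_cols] <- sample.int(3L, n * length(noise_cols),
                                     replace = TRUE, prob = wn) - 1L
  }
  geno[, functional[1L]] <- g1_keep
  geno[, functional[2L]] <- g2_keep
  gedt_data(geno, ifelse(y_keep == 1L, "+", "-"), functional = functional)
}

#' Default simulation grid
#'
#' The 40-point experimental grid: model ids 1-30 cross the three penetrance
#' patterns (XOR, BOX, MOD) with heritabilities 1, 2.5, 5, 7.5 and 10% and
#' minor allele frequencies 0.25 and 0.5 at 125 cases + 125 controls; ids
#' 31-40 repeat the XOR rows at 250 cases + 250 controls.
#'
#' @return A data frame with columns `model_id`, `pattern`, `h2`, `maf`,
#'   `n_cases`, `n_controls`.
#' @export
power_grid <- function() {
  base <- expand.grid(maf = c(0.25, 0.5),
                      h2 = c(0.01, 0.025, 0.05, 0.075, 0.10),
                      pattern = c("XOR", "BOX", "MOD"),
                      stringsAsFactors = FALSE)[, 3:1]
  grid <- rbind(cbind(base, n_cases = 125L, n_controls = 125L),
                cbind(base[base$pattern == "XOR", ],
                      n_cases = 250L, n_controls = 250L))
  cbind(model_id = seq_len(nrow(grid)), grid, row.names = NULL)
}

#' Simulate a replicate grid to disk
#'
#' Writes `n_replicates` datasets for every row of `grid` (default: the full
#' 40-model [power_grid()]), plus a tab-delimited `manifest.tsv` recording
#' each file's grid coordinates and RNG seed. Re-running with the same
#' master seed (via `set.seed()` before the call) reproduces byte-identical
#' files.
#'
#' @param out_dir output directory (created if missing).
#' @param grid a data frame in [power_grid()] layout.
#' @param n_replicates datasets per grid point.
#' @param n_snps total SNPs per dataset.
#' @return Invisibly, the manifest data frame.
#' @export
simulate_grid <- function(out_dir, grid = power_grid(), n_replicates = 100L,
                          n_snps = 100L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    model <- solve_penetrance(g$pattern, g$maf, g$h2)
    for (r in seq_len(n_replicates)) {
      seed <- sample.int(.Machine$integer.max, 1L)
      set.seed(seed)
      ds <- simulate_dataset(model, g$n_cases, g$n_controls, n_snps = n_snps)
      fname <- sprintf("model%02d_rep%03d.txt", g$model_id, r)
      write_gedt_data(ds, file.path(out_dir, fname))
      rows[[length(rows) + 1L]] <-
        data.frame(file = fname, model_id = g$model_id, pattern = g$pattern,
                   h2 = g$h2, maf = g$maf, n_cases = g$n_cases,
                   n_controls = g$n_controls, replicate = r, seed = seed,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
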