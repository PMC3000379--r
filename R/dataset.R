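#' Case-control SNP genotype dataset
#'
#' Container for a genetic association dataset: an individuals-by-SNPs matrix
#' of bi-allelic genotypes coded 0/1/2 (copies of the minor allele: AA, Aa,
#' aa) and a binary class label per individual, `"+"` for cases and `"-"` for
#' controls. Genotype coding makes no genetic-model assumption, so downstream
#' analysis is genetically nonparametric.
#'
#' @param genotypes integer matrix, individuals in rows, SNPs in columns,
#'   every value in `{0, 1, 2}`.
#' @param labels character (or 0/1 numeric) vector of class labels, one per
#'   row of `genotypes`; `"+"`/1 = case, `"-"`/0 = control.
#' @param snp_names optional character vector of SNP identifiers; defaults to
#'   `V1..Vn`.
#' @param functional optional integer vector of SNP column indices known to be
#'   disease-associated (available for simulated data only).
#' @return An object of class `gedt_data`: a list with elements `genotypes`,
#'   `labels`, `snp_names` and `functional`.
#' @seealso [read_gedt_data()], [write_gedt_data()], [simulate_dataset()]
#' @examples
#' ds <- gedt_data(matrix(c(0L, 2L, 1L, 1L), 2, 2), c("+", "-"))
#' ds
#' @export
gedt_data <- function(genotypes, labels, snp_names = NULL, functional = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.numeric(labels)) labels <- ifelse(labels == 1, "+", "-")
  labels <- as.character(labels)
  if (nrow(genotypes) != length(labels))
    stop("number of genotype rows (", nrow(genotypes),
         ") does not match number of labels (", length(labels), ")")
  if (nrow(genotypes) < 1L || ncol(genotypes) < 1L)
    stop("dataset must contain at least one individual and one SNP")
  bad <- which(!(genotypes %in% 0:2), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(genotypes))
    stop("invalid genotype value ", genotypes[bad[1L]], " at row ", rc[1L],
         ", SNP column ", rc[2L], " (genotypes must be 0, 1 or 2)")
  }
  if (!all(labels %in% c("+", "-")))
    stop("labels must be '+'/'-' (or 1/0)")
  if (is.null(snp_names)) snp_names <- paste0("V", seq_len(ncol(genotypes)))
  if (length(snp_names) != ncol(genotypes))
    stop("snp_names length does not match the number of SNP columns")
  if (!is.null(functional)) {
    functional <- sort(unique(as.integer(functional)))
    if (any(functional < 1L | functional > ncol(genotypes)))
      stop("functional locus indices out of range")
  }
  colnames(genotypes) <- snp_names
  structure(list(genotypes = genotypes, labels = labels,
                 snp_names = snp_names, functional = functional),
            class = "gedt_data")
}

#' @export
print.gedt_data <- function(x, ...) {
  cat("Case-control SNP dataset: ", nrow(x$genotypes), " individuals (",
      sum(x$labels == "+"), " cases, ", sum(x$labels == "-"), " controls), ",
      ncol(x$genotypes), " SNPs\n", sep = "")
  if (!is.null(x$functional))
    cat("Functional loci:", paste0(x$snp_names[x$functional], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.gedt_data <- function(x) dim(x$genotypes)

# internal: labels as 0/1 integers (1 = case)
label_int <- function(ds) as.integer(ds$labels == "+")

# check that a training partition is usable
check_two_classes <- function(ds) {
  if (length(unique(ds$labels)) < 2L)
    stop("dataset contains a single class; both cases and controls required")
  invisible(ds)
}

#' Read a case-control genotype dataset
#'
#' Reads the package's tab-delimited dataset format: an optional header row,
#' then one row per individual with the class in the first column (1 = case,
#' 0 = control) and 0/1/2 genotypes in the remaining columns.
#'
#' @param path path to a tab-delimited text file.
#' @return A [gedt_data] object, with row order preserved.
#' @seealso [write_gedt_data()]
#' @export
read_gedt_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  header <- !all(grepl("^[0-9]+$", first))
  tab <- read.table(path, header = header, sep = "\t",
                    colClasses = "integer", check.names = FALSE)
  if (ncol(tab) < 2L) stop("dataset file needs a class column and >= 1 SNP")
  cls <- tab[[1L]]
  if (!all(cls %in% 0:1))
    stop("class column must be 0/1; found value ", cls[which(!cls %in% 0:1)[1L]])
  geno <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!(geno %in% 0:2))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(geno))
    stop("invalid genotype value ", geno[bad[1L]], " at data row ", rc[1L],
         ", SNP column ", rc[2L])
  }
  snp_names <- if (header) colnames(tab)[-1L] else NULL
  ds <- gedt_data(geno, ifelse(cls == 1L, "+", "-"), snp_names = snp_names)
  check_two_classes(ds)
  ds
}

#' Write a case-control genotype dataset
#'
#' Writes the tab-delimited format read by [read_gedt_data()]: a header row
#' (`class` followed by SNP names) and one row per individual, class first
#' (1 = case, 0 = control). Output bytes are deterministic for a given
#' dataset, so `read_gedt_data(write_gedt_data(ds, f))` reproduces `ds`.
#'
#' @param ds a [gedt_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gedt_data <- function(ds, path) {
  stopifnot(inherits(ds, "gedt_data"))
  if (nrow(ds$genotypes) < 1L) stop("refusing to write an empty dataset")
  tab <- cbind(class = label_int(ds), ds$genotypes)
  con <- file(path, open = "wb")  # fixed newline convention on all platforms
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  writeLines(apply(tab, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
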