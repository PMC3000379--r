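#' Decision trees over SNP genotypes
#'
#' A `gedt_tree` is a ternary decision tree: each internal node tests one SNP
#' and has exactly three children, one per genotype value (0, 1, 2 copies of
#' the minor allele); each leaf predicts a class, `"+"` (case) or `"-"`
#' (control). A bare leaf is a legal tree — it arises from the grammar's
#' class-only derivation and covers datasets where one class dominates.
#'
#' `leaf_node()` and `split_node()` are the two constructors.
#'
#' @param class leaf class, `"+"` or `"-"`.
#' @param variable 1-based SNP index tested at the node.
#' @param child0,child1,child2 subtrees followed when the individual's
#'   genotype at `variable` is 0, 1 or 2.
#' @return A `gedt_tree` object.
#' @examples
#' t <- split_node(2, leaf_node("+"), leaf_node("-"), leaf_node("-"))
#' to_parse_string(t)
#' @export
leaf_node <- function(class) {
  stopifnot(class %in% c("+", "-"))
  structure(list(leaf = TRUE, class = class), class = "gedt_tree")
}

#' @rdname leaf_node
#' @export
split_node <- function(variable, child0, child1, child2) {
  variable <- as.integer(variable)
  stopifnot(variable >= 1L, inherits(child0, "gedt_tree"),
            inherits(child1, "gedt_tree"), inherits(child2, "gedt_tree"))
  structure(list(leaf = FALSE, variable = variable,
                 children = list(child0, child1, child2)),
            class = "gedt_tree")
}

#' Classify individuals with a decision tree
#'
#' Descends from the root, at each internal node following the edge labelled
#' with the individual's genotype at the node's SNP, and returns the class of
#' the leaf reached.
#'
#' @param tree a [gedt_tree][leaf_node].
#' @param genotypes either a single individual's genotype vector or an
#'   individuals-by-SNPs matrix (or a [gedt_data] object).
#' @return A character vector of predicted classes (`"+"`/`"-"`), one per
#'   individual.
#' @export
classify <- function(tree, genotypes) {
  stopifnot(inherits(tree, "gedt_tree"))
  if (inherits(genotypes, "gedt_data")) genotypes <- genotypes$genotypes
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1L)
  p <- ncol(genotypes)
  used <- variables_in(tree)
  if (length(used) && max(used) > p)
    stop("tree tests SNP V", max(used), " but data has only ", p, " SNPs")
  one <- function(node, g) {
    while (!node$leaf) node <- node$children[[g[node$variable] + 1L]]
    node$class
  }
  vapply(seq_len(nrow(genotypes)), function(i) one(tree, genotypes[i, ]),
         character(1L))
}

#' Render a decision tree as a parse string
#'
#' Produces an unambiguous prefix rendering, e.g.
#' `"(V2 0:(+) 1:(-) 2:(-))"`; [parse_tree()] inverts it.
#'
#' @param tree a [gedt_tree][leaf_node].
#' @return A single character string.
#' @export
to_parse_string <- function(tree) {
  stopifnot(inherits(tree, "gedt_tree"))
  if (tree$leaf) return(paste0("(", tree$class, ")"))
  kids <- vapply(tree$children, to_parse_string, character(1L))
  paste0("(V", tree$variable, " 0:", kids[1L], " 1:", kids[2L],
         " 2:", kids[3L], ")")
}

#' @rdname to_parse_string
#' @param text a parse string produced by `to_parse_string()`.
#' @export
parse_tree <- function(text) {
  pos <- 1L
  chars <- strsplit(text, "")[[1L]]
  expect <- function(ch) {
    if (pos > length(chars) || chars[pos] != ch)
      stop("malformed parse string at position ", pos, ": expected '", ch, "'")
    pos <<- pos + 1L
  }
  skip_ws <- function() while (pos <= length(chars) && chars[pos] == " ")
    pos <<- pos + 1L
  node <- function() {
    expect("(")
    if (chars[pos] %in% c("+", "-")) {
      cls <- chars[pos]; pos <<- pos + 1L
      expect(")")
      return(leaf_node(cls))
    }
    expect("V")
    digs <- character(0L)
    while (chars[pos] %in% as.character(0:9)) {
      digs <- c(digs, chars[pos]); pos <<- pos + 1L
    }
    kids <- vector("list", 3L)
    for (g in 0:2) {
      skip_ws()
      expect(as.character(g)); expect(":")
      kids[[g + 1L]] <- node()
    }
    expect(")")
    split_node(as.integer(paste(digs, collapse = "")),
               kids[[1L]], kids[[2L]], kids[[3L]])
  }
  out <- node()
  if (pos != length(chars) + 1L) stop("trailing text in parse string")
  out
}

#' Tree introspection helpers
#'
#' `variables_in()` returns the distinct SNP indices tested at internal
#' nodes; `tree_depth()` returns 0 for a leaf and 1 plus the maximum child
#' depth otherwise; `tree_size()` counts nodes (internal + leaves).
#'
#' @param tree a [gedt_tree][leaf_node].
#' @return `variables_in()`: sorted integer vector; `tree_depth()`,
#'   `tree_size()`: a single integer.
#' @export
variables_in <- function(tree) {
  stopifnot(inherits(tree, "gedt_tree"))
  if (tree$leaf) return(integer(0L))
  sort(unique(c(tree$variable,
                unlist(lapply(tree$children, variables_in)))))
}

#' @rdname variables_in
#' @export
tree_depth <- function(tree) {
  stopifnot(inherits(tree, "gedt_tree"))
  if (tree$leaf) return(0L)
  1L + max(vapply(tree$children, tree_depth, integer(1L)))
}

#' @rdname variables_in
#' @export
tree_size <- function(tree) {
  stopifnot(inherits(tree, "gedt_tree"))
  if (tree$leaf) return(1L)
  1L + sum(vapply(tree$children, tree_size, integer(1L)))
}

#' Render a decision tree as IF-THEN rules
#'
#' One rule per root-to-leaf path, e.g. `IF V2 = 0 AND V7 = 2 THEN +`.
#'
#' @param tree a [gedt_tree][leaf_node].
#' @param snp_names optional SNP names used instead of `V<k>`.
#' @return Character vector of rules.
#' @export
to_if_then <- function(tree, snp_names = NULL) {
  stopifnot(inherits(tree, "gedt_tree"))
  nm <- function(v) if (is.null(snp_names)) paste0("V", v) else snp_names[v]
  walk <- function(node, conds) {
    if (node$leaf) {
      lhs <- if (length(conds)) paste(conds, collapse = " AND ") else "TRUE"
      return(paste0("IF ", lhs, " THEN ", node$class))
    }
    unlist(lapply(0:2, function(g)
      walk(node$children[[g + 1L]],
           c(conds, paste0(nm(node$variable), " = ", g)))))
  }
  walk(tree, character(0L))
}

#' @export
print.gedt_tree <- function(x, ...) {
  cat("Decision tree (depth ", tree_depth(x), ", ", tree_size(x),
      " nodes):\n  ", to_parse_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.gedt_tree <- function(x, ...) to_parse_string(x)

# internal: flat C++ representation (var/cls/kid vectors) -> nested gedt_tree
flat_to_tree <- function(flat) {
  if (!isTRUE(flat$valid)) return(NULL)
  build <- function(i) {
    if (flat$var[i + 1L] < 0L)
      return(leaf_node(if (flat$cls[i + 1L] == 1L) "+" else "-"))
    split_node(flat$var[i + 1L] + 1L,
               build(flat$kid[3L * i + 1L]),
               build(flat$kid[3L * i + 2L]),
               build(flat$kid[3L * i + 3L]))
  }
  build(0L)
}
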