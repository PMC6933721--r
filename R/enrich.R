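## Over-representation analysis of a gene list against GMT gene-set
## collections via the hypergeometric upper tail, with Benjamini-Hochberg
## adjustment within each category.

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (gene symbols); duplicates
#'   within a set are removed.
#' @param category Category tag recycled over the sets (e.g. `"BP"`,
#'   `"CC"`, `"MF"`, `"pathway"`), or a vector with one tag per set.
#' @return A list of class `gene_set_collection` with `sets` and
#'   `category`.
#' @export
gene_set_collection <- function(sets, category = "pathway") {
  if (is.null(names(sets)) && length(sets) > 0) {
    abort("gene_set_collection: sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    abort("gene_set_collection: set names must be unique")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) {
    abort("gene_set_collection: sets must be nonempty")
  }
  category <- rep_len(as.character(category), length(sets))
  names(category) <- names(sets)
  structure(list(sets = sets, category = category),
            class = "gene_set_collection")
}

#' Read a GMT file
#'
#' Standard GMT dialect: one set per line,
#' `name TAB description TAB gene1 TAB gene2 ...`. Duplicate genes within a
#' set are dropped.
#'
#' @param path GMT file path.
#' @param category Category tag applied to every set in the file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, category = "pathway") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(gene_set_collection(stats::setNames(list(), character()),
                               character()))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort("read_gmt: malformed line %d (found %d fields, need >= 3)",
            i, length(fields))
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets, category)
}

#' Write a GMT file
#'
#' @param sets Named list of gene vectors or a [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Hypergeometric upper-tail p-value
#'
#' Probability of observing `k` or more list genes in a set of size `K`
#' when `n` genes are drawn from a universe of `N`:
#' `p = sum_{i=k..min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`, evaluated on the
#' log scale.
#'
#' @param k Overlap count.
#' @param K Set size within the universe.
#' @param n List size within the universe.
#' @param N Universe size.
#' @return The upper-tail p-value (1 when `k = 0`).
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    abort("hypergeom_test: inconsistent counts (k=%s K=%s n=%s N=%s)",
          k, K, n, N)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis
#'
#' Tests each set of a collection for enrichment of `deg_genes` within
#' `universe` by [hypergeom_test()]; q-values are Benjamini-Hochberg
#' adjusted within each category. Genes outside the universe are ignored
#' on both sides.
#'
#' @param deg_genes Character vector of genes of interest (e.g. the DEG
#'   list); must be contained in `universe`.
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of all testable genes (e.g. every gene
#'   of the post-collapse expression matrix).
#' @param alpha Significance threshold on the raw p-value.
#' @return A data frame with columns `set`, `category`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `significant`, ordered by `p`.
#' @export
enrich <- function(deg_genes, collection, universe, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  deg_genes <- unique(deg_genes)
  outside <- setdiff(deg_genes, universe)
  if (length(outside)) {
    abort("enrich: %d gene(s) of interest are outside the universe",
          length(outside))
  }
  N <- length(universe)
  n <- length(deg_genes)
  res <- data.frame(
    set = names(collection$sets),
    category = unname(collection$category),
    stringsAsFactors = FALSE
  )
  res$K <- vapply(collection$sets,
                  function(s) length(intersect(s, universe)), integer(1))
  res$k <- vapply(collection$sets,
                  function(s) length(intersect(s, deg_genes)), integer(1))
  res$n <- n
  res$N <- N
  res$p <- mapply(hypergeom_test, res$k, res$K, res$n, res$N)
  res$q <- NA_real_
  for (cat in unique(res$category)) {
    sel <- res$category == cat
    res$q[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$set), c("set", "category", "k", "K", "n", "N",
                                      "p", "q", "significant")]
  rownames(res) <- NULL
  res
}
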