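## Epigenetically driven gene screening: match samples across the two
## omics layers, test every (network gene, promoter CpG) pair for negative
## Pearson correlation between expression and M-value, assemble the mixed
## gene-gene-CpG network, rank genes by degree / harmonic closeness /
## betweenness, and select hubs as the intersection of the three top lists.

#' Match samples between expression and methylation data
#'
#' @param expr An [expression_data].
#' @param meth A [methylation_data].
#' @return Character vector of shared sample ids in expression order.
#' @export
match_samples <- function(expr, meth) {
  stopifnot(inherits(expr, "expression_data"),
            inherits(meth, "methylation_data"))
  shared <- intersect(colnames(expr$values), colnames(meth$values))
  if (length(shared) == 0) {
    abort("match_samples: no shared sample ids between the two data sets")
  }
  colnames(expr$values)[colnames(expr$values) %in% shared]
}

#' Pearson correlation test
#'
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`
#' with a two-sided p-value from `t = r sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (`p = 0` at `|r| = 1`).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both nonconstant.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("pearson_test: lengths differ")
  n <- length(x)
  if (n < 3) abort("pearson_test: need at least 3 observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    abort("pearson_test: correlation undefined for a constant vector")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Screen for negative promoter-methylation / expression correlation
#'
#' For every network gene and every promoter CpG annotated to it, computes
#' the Pearson correlation between the gene's expression and the CpG's
#' M-value over the matched samples, and keeps pairs with `r < 0` and
#' `p < alpha` (two-sided). Genes retaining at least one pair are the
#' epigenetically driven genes.
#'
#' @param expr A gene-level [expression_data].
#' @param meth A [methylation_data] on the M scale, already restricted to
#'   promoter probes.
#' @param network_genes Genes of the pathway network to screen.
#' @param alpha Significance threshold.
#' @return Data frame (the driver table) with columns `gene`, `cpg`, `r`,
#'   `p`, `n`, ordered by `p`; summary counts are attached as attribute
#'   `screen_summary` (genes screened, genes without promoter CpGs, pairs
#'   tested, pairs retained).
#' @export
screen_negative <- function(expr, meth, network_genes, alpha = 0.05) {
  stopifnot(inherits(expr, "expression_data"),
            inherits(meth, "methylation_data"))
  if (meth$scale != "M") abort("screen_negative: methylation must be on the M scale")
  if (!(alpha >= 0 && alpha <= 1)) abort("screen_negative: alpha must lie in [0, 1]")
  matched <- match_samples(expr, meth)
  if (length(matched) < 3) abort("screen_negative: need at least 3 matched samples")
  genes <- intersect(network_genes, rownames(expr$values))
  probes <- meth$probes[meth$probes$gene_symbol %in% genes, , drop = FALSE]
  empty <- data.frame(gene = character(), cpg = character(), r = numeric(),
                      p = numeric(), n = integer(), stringsAsFactors = FALSE)
  summary <- list(genes_screened = length(genes),
                  genes_without_cpg = length(genes) -
                    length(unique(probes$gene_symbol)),
                  pairs_tested = nrow(probes), pairs_retained = 0L,
                  driver_genes = 0L)
  if (nrow(probes) == 0 || alpha == 0) {
    attr(empty, "screen_summary") <- summary
    return(empty)
  }
  n <- length(matched)
  E <- expr$values[probes$gene_symbol, matched, drop = FALSE]
  M <- meth$values[probes$probe_id, matched, drop = FALSE]
  zscore_rows <- function(A) {
    mu <- rowMeans(A)
    ss <- sqrt(rowSums((A - mu)^2))
    (A - mu) / ifelse(ss == 0, NA_real_, ss)
  }
  r <- rowSums(zscore_rows(E) * zscore_rows(M))
  r <- pmax(-1, pmin(1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(abs(r) == 1, 0, 2 * stats::pt(-abs(tt), df = n - 2))
  tab <- data.frame(gene = probes$gene_symbol, cpg = probes$probe_id,
                    r = unname(r), p = unname(p), n = n,
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$r) & tab$r < 0 & tab$p < alpha, , drop = FALSE]
  tab <- tab[order(tab$p, tab$gene, tab$cpg), , drop = FALSE]
  rownames(tab) <- NULL
  summary$pairs_retained <- nrow(tab)
  summary$driver_genes <- length(unique(tab$gene))
  attr(tab, "screen_summary") <- summary
  tab
}

#' Build the gene-gene-CpG network
#'
#' Gene nodes are the driver genes of the screen; gene-gene edges are the
#' pathway-graph edges among them; each retained (gene, CpG) pair adds a
#' CpG node connected to its gene.
#'
#' @param pathway A `pathway_graph` (see [parse_kgml()], [merge_graphs()]).
#' @param drivers A nonempty driver table from [screen_negative()].
#' @return A list of class `gene_cpg_network` with `genes`, `cpgs`, and
#'   `edges` (data frame `from`, `to`, `type` in `gene-gene` /
#'   `gene-cpg`).
#' @export
build_network <- function(pathway, drivers) {
  stopifnot(inherits(pathway, "pathway_graph"))
  if (nrow(drivers) == 0) abort("build_network: empty driver table")
  genes <- sort(unique(drivers$gene))
  gg <- pathway$edges[pathway$edges$from %in% genes &
                        pathway$edges$to %in% genes, c("from", "to"),
                      drop = FALSE]
  gc <- data.frame(from = drivers$gene, to = drivers$cpg,
                   stringsAsFactors = FALSE)
  edges <- rbind(
    if (nrow(gg)) cbind(gg, type = "gene-gene", stringsAsFactors = FALSE),
    cbind(gc, type = "gene-cpg", stringsAsFactors = FALSE)
  )
  rownames(edges) <- NULL
  structure(list(genes = genes, cpgs = sort(unique(drivers$cpg)),
                 edges = edges),
            class = "gene_cpg_network")
}

#' @export
print.gene_cpg_network <- function(x, ...) {
  cat(sprintf("gene_cpg_network: %d genes, %d CpGs, %d gene-gene + %d gene-CpG edges\n",
              length(x$genes), length(x$cpgs),
              sum(x$edges$type == "gene-gene"),
              sum(x$edges$type == "gene-cpg")))
  invisible(x)
}

gene_cpg_igraph <- function(net) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(net$genes, net$cpgs),
                     type = c(rep("gene", length(net$genes)),
                              rep("cpg", length(net$cpgs))))
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    igraph::E(g)$type <- net$edges$type
  }
  g
}

#' Node centralities of the gene-gene-CpG network
#'
#' Computed on the full mixed graph and reported for the gene nodes:
#' degree (incident edge count), closeness in the harmonic form
#' (`sum over other nodes of 1 / distance`, with `1/Inf = 0`, well defined
#' on disconnected graphs), and unnormalized shortest-path betweenness
#' over unordered node pairs. Each metric also gets a dense rank
#' (largest value = rank 1, ties share a rank).
#'
#' @param net A `gene_cpg_network` from [build_network()].
#' @return Data frame with columns `gene`, `degree`, `closeness`,
#'   `betweenness`, `rank_degree`, `rank_closeness`, `rank_betweenness`.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "gene_cpg_network"))
  g <- gene_cpg_igraph(net)
  if (igraph::vcount(g) == 0) abort("centralities: empty network")
  deg <- igraph::degree(g)
  clo <- igraph::harmonic_centrality(g, normalized = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE)
  sel <- names(deg) %in% net$genes
  tab <- data.frame(
    gene = names(deg)[sel],
    degree = unname(deg[sel]),
    closeness = unname(clo[sel]),
    betweenness = unname(btw[sel]),
    stringsAsFactors = FALSE
  )
  tab$rank_degree <- dense_rank_desc(tab$degree)
  tab$rank_closeness <- dense_rank_desc(tab$closeness)
  tab$rank_betweenness <- dense_rank_desc(tab$betweenness)
  tab <- tab[order(tab$rank_degree, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Select hub genes
#'
#' Intersects the top lists of the three centrality metrics. In `"count"`
#' mode a top list contains the genes with dense rank at most `k` (so ties
#' at the k-th rank are all included); in `"fraction"` mode `k` is
#' replaced by `ceiling(fraction * number of gene nodes)`. Deterministic
#' and invariant to the row order of the table.
#'
#' @param table Centrality table from [centralities()].
#' @param k Top-list depth (`"count"` mode).
#' @param mode `"count"` (top k) or `"fraction"` (top `fraction` of gene
#'   nodes).
#' @param fraction Fraction for `"fraction"` mode.
#' @return Character vector of hub genes, ordered by degree rank; empty
#'   (with a warning) when the intersection is empty.
#' @export
select_hubs <- function(table, k = 10, mode = c("count", "fraction"),
                        fraction = 0.1) {
  mode <- match.arg(mode)
  if (mode == "fraction") {
    k <- max(1L, ceiling(fraction * nrow(table)))
  }
  if (!is_count(k)) abort("select_hubs: k must be a positive count")
  if (mode == "count" && nrow(table) < k) {
    abort("select_hubs: fewer than k = %d gene nodes", k)
  }
  top <- function(rank_col) table$gene[table[[rank_col]] <= k]
  hubs <- Reduce(intersect, list(top("rank_degree"), top("rank_closeness"),
                                 top("rank_betweenness")))
  if (length(hubs) == 0) {
    warnf("select_hubs: the three top-%d lists have an empty intersection", k)
    return(character())
  }
  ord <- order(table$rank_degree[match(hubs, table$gene)], hubs)
  hubs[ord]
}

#' Export a gene-gene-CpG network
#'
#' GraphML with a `type` node attribute (`gene` / `cpg`) and a `type`
#' edge attribute.
#'
#' @param net A `gene_cpg_network`.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "gene_cpg_network"))
  igraph::write_graph(gene_cpg_igraph(net), path, format = "graphml")
}
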