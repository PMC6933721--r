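## KGML pathway XML parsing, pathway-graph merging and topology summaries.
## A pathway graph is an undirected simple graph over gene symbols: no
## self-loops, each unordered pair stored once, with relation subtypes and
## source-pathway provenance accumulated as attributes.

pathway_graph <- function(nodes, edges) {
  edges <- edges[, c("from", "to", "relation", "pathways"), drop = FALSE]
  structure(list(nodes = sort(unique(nodes)), edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d genes, %d interactions from %d pathway(s)\n",
              length(x$nodes), nrow(x$edges),
              length(unique(unlist(strsplit(x$edges$pathways, ";"))))))
  invisible(x)
}

#' Parse a KGML pathway document into a gene interaction graph
#'
#' Extracts `entry`, `relation` and `group` elements. A gene entry expands
#' to all gene accessions listed in its `name` attribute, mapped to
#' symbols through `id_to_symbol`; a group entry expands to the union of
#' its member entries' genes. Every relation between two entries yields the
#' Cartesian set of gene-gene edges between the two expansions, with
#' directionality discarded and self-loops dropped. Entries with no
#' mappable accession and relations referencing unknown entries are
#' skipped with a warning.
#'
#' @param x KGML source: a file path, an XML string, or an `xml2` document.
#' @param id_to_symbol Named character vector mapping KGML gene accessions
#'   (e.g. `"hsa:3119"`) to gene symbols.
#' @param relation_types Optional character vector of relation subtype
#'   names to keep (default: all relations).
#' @return A `pathway_graph`: list with `nodes` (gene symbols, including
#'   genes without interactions) and `edges` (data frame `from`, `to`,
#'   `relation`, `pathways`).
#' @export
parse_kgml <- function(x, id_to_symbol, relation_types = NULL) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  if (is.na(xml2::xml_name(doc)) || xml2::xml_name(doc) != "pathway") {
    abort("parse_kgml: root element is not <pathway>")
  }
  pathway_id <- xml2::xml_attr(doc, "name")
  if (is.na(pathway_id)) pathway_id <- "unknown"

  entries <- xml2::xml_find_all(doc, "entry")
  entry_genes <- list()    # entry id -> character vector of symbols
  group_members <- list()  # entry id -> member entry ids
  for (e in entries) {
    id <- xml2::xml_attr(e, "id")
    type <- xml2::xml_attr(e, "type")
    if (identical(type, "gene")) {
      accs <- strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]]
      accs <- accs[nzchar(accs)]
      syms <- unname(id_to_symbol[accs])
      if (anyNA(syms)) {
        warnf("parse_kgml: entry %s in %s has unmappable accession(s): %s",
              id, pathway_id, paste(accs[is.na(syms)], collapse = ", "))
      }
      entry_genes[[id]] <- unique(syms[!is.na(syms)])
    } else if (identical(type, "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(e, "component"), "id")
      group_members[[id]] <- comp
    }
    ## other entry types (compound, map, ...) carry no gene edges
  }
  expand <- function(id) {
    if (id %in% names(group_members)) {
      unique(unlist(lapply(group_members[[id]], expand)))
    } else if (id %in% names(entry_genes)) {
      entry_genes[[id]]
    } else {
      NULL
    }
  }

  relations <- xml2::xml_find_all(doc, "relation")
  from <- character()
  to <- character()
  rel <- character()
  known <- c(names(entry_genes), names(group_members))
  for (r in relations) {
    e1 <- xml2::xml_attr(r, "entry1")
    e2 <- xml2::xml_attr(r, "entry2")
    if (!(e1 %in% known) || !(e2 %in% known)) {
      warnf("parse_kgml: relation %s-%s in %s references unknown entry; skipped",
            e1, e2, pathway_id)
      next
    }
    subtype <- xml2::xml_attr(xml2::xml_find_first(r, "subtype"), "name")
    if (is.na(subtype)) subtype <- xml2::xml_attr(r, "type")
    if (!is.null(relation_types) && !(subtype %in% relation_types)) next
    g1 <- expand(e1)
    g2 <- expand(e2)
    if (!length(g1) || !length(g2)) next
    pairs <- expand.grid(from = g1, to = g2, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    from <- c(from, pairs$from)
    to <- c(to, pairs$to)
    rel <- c(rel, rep(subtype, nrow(pairs)))
  }
  edges <- canonical_edges(from, to)
  edges$relation <- rel
  edges$pathways <- rep(pathway_id, nrow(edges))
  edges <- collapse_parallel_edges(edges)
  nodes <- unique(c(unlist(entry_genes, use.names = FALSE),
                    edges$from, edges$to))
  pathway_graph(nodes, edges)
}

## Merge parallel edges: one row per unordered pair, relation subtypes and
## pathway provenance accumulated as ';'-separated unique lists.
collapse_parallel_edges <- function(edges) {
  if (nrow(edges) == 0) {
    return(data.frame(from = character(), to = character(),
                      relation = character(), pathways = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(edges$from, edges$to, sep = "|")
  join <- function(x) paste(sort(unique(unlist(strsplit(x, ";")))),
                            collapse = ";")
  out <- data.frame(
    from = tapply(edges$from, key, `[`, 1),
    to = tapply(edges$to, key, `[`, 1),
    relation = tapply(edges$relation, key, join),
    pathways = tapply(edges$pathways, key, join),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge pathway graphs
#'
#' Node and edge union; an edge appearing in several pathways is stored
#' once with concatenated pathway provenance and relation subtypes.
#'
#' @param graphs List of `pathway_graph` objects (length >= 1).
#' @return The merged `pathway_graph`.
#' @export
merge_graphs <- function(graphs) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  if (length(graphs) == 0) abort("merge_graphs: need at least one graph")
  stopifnot(all(vapply(graphs, inherits, logical(1), "pathway_graph")))
  edges <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  nodes <- unique(unlist(lapply(graphs, `[[`, "nodes")))
  pathway_graph(nodes, collapse_parallel_edges(edges))
}

#' Degree distribution of a pathway graph
#'
#' Exact node-degree counts, plus the least-squares slope of log10
#' frequency against log10 degree over degrees with nonzero counts
#' (a descriptive power-law summary; `NA` when fewer than two distinct
#' positive degrees exist).
#'
#' @param graph A `pathway_graph`.
#' @return A list with `degrees` (named vector, per node), `histogram`
#'   (data frame `degree`, `count`) and `loglog_slope`.
#' @export
degree_distribution <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (length(graph$nodes) == 0) abort("degree_distribution: empty graph")
  deg <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  tab <- table(c(graph$edges$from, graph$edges$to))
  deg[names(tab)] <- as.integer(tab)
  hist <- as.data.frame(table(degree = deg), stringsAsFactors = FALSE)
  hist$degree <- as.integer(hist$degree)
  names(hist)[2] <- "count"
  pos <- hist[hist$degree > 0, , drop = FALSE]
  slope <- if (nrow(pos) >= 2) {
    unname(stats::coef(stats::lm(log10(pos$count) ~ log10(pos$degree)))[2])
  } else {
    NA_real_
  }
  list(degrees = deg, histogram = hist, loglog_slope = slope)
}

## igraph view of a pathway graph (used by centrality computations and
## GraphML export)
pathway_igraph <- function(graph) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(graph$nodes)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
    igraph::E(g)$relation <- graph$edges$relation
    igraph::E(g)$pathways <- graph$edges$pathways
  }
  g
}

#' Export a pathway graph
#'
#' `write_sif()` writes the simple-interaction format
#' (`from TAB relation TAB to`); `write_graphml()` writes GraphML with the
#' relation and pathway-provenance edge attributes.
#'
#' @param graph A `pathway_graph`.
#' @param path Output file path.
#' @export
write_sif <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  lines <- sprintf("%s\t%s\t%s", graph$edges$from, graph$edges$relation,
                   graph$edges$to)
  writeLines(lines, path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "pathway_graph"))
  igraph::write_graph(pathway_igraph(graph), path, format = "graphml")
}
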