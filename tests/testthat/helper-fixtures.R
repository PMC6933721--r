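# Small builders and independent brute-force oracles shared by the tests.

make_probes <- function(ids, genes = "g1", region = "TSS200",
                        chrom = "chr1", snp = FALSE, crosshyb = FALSE) {
  data.frame(probe_id = ids,
             gene_symbol = rep_len(genes, length(ids)),
             region_class = rep_len(region, length(ids)),
             chromosome = rep_len(chrom, length(ids)),
             flag_snp = rep_len(snp, length(ids)),
             flag_crosshyb = rep_len(crosshyb, length(ids)),
             stringsAsFactors = FALSE)
}

make_samples <- function(ids, condition = "GDM") {
  data.frame(sample_id = ids, condition = rep_len(condition, length(ids)),
             stringsAsFactors = FALSE)
}

make_meth <- function(values, scale = "beta", probes = NULL, samples = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cg%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(probes)) probes <- make_probes(rownames(values))
  if (is.null(samples)) samples <- make_samples(colnames(values))
  methylation_data(values, probes, samples, scale = scale)
}

make_expr <- function(values, conditions = NULL, level = "gene",
                      probe_to_gene = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(conditions)) {
    half <- ceiling(ncol(values) / 2)
    conditions <- rep(c("GDM", "control"),
                      c(half, ncol(values) - half))
  }
  expression_data(values, make_samples(colnames(values), conditions),
                  level = level, probe_to_gene = probe_to_gene)
}

## assign default probe/sample dimnames to a bare matrix
named_matrix <- function(v, prefix = c("cg", "s")) {
  if (is.null(rownames(v))) {
    rownames(v) <- sprintf("%s%03d", prefix[1], seq_len(nrow(v)))
  }
  if (is.null(colnames(v))) {
    colnames(v) <- sprintf("%s%02d", prefix[2], seq_len(ncol(v)))
  }
  v
}

## canonical sorted edge keys for set comparisons
edge_set <- function(edges) {
  sort(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
             sep = "|"))
}

## ---- independent oracles ---------------------------------------------------

## brute-force kNN imputation (double loop, pairwise-complete mean squared
## difference, skip neighbours missing in the target sample)
oracle_knn_impute <- function(X, k) {
  n <- nrow(X)
  out <- X
  for (i in seq_len(n)) {
    for (s in seq_len(ncol(X))) {
      if (!is.na(X[i, s])) next
      d <- vapply(seq_len(n), function(j) {
        if (j == i) return(Inf)
        sh <- !is.na(X[i, ]) & !is.na(X[j, ])
        if (!any(sh)) return(Inf)
        mean((X[i, sh] - X[j, sh])^2)
      }, numeric(1))
      ord <- order(d, seq_len(n))
      nb <- ord[!is.na(X[ord, s]) & is.finite(d[ord])]
      out[i, s] <- mean(X[nb[seq_len(min(k, length(nb)))], s])
    }
  }
  out
}

## exact hypergeometric upper tail by explicit enumeration in log space
oracle_hypergeom <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## all-pairs BFS centralities (degree, harmonic closeness, betweenness by
## path-count enumeration over unordered pairs), independent of igraph
oracle_centralities <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(stats::setNames(seq_len(n), nodes), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    a <- match(edges$from[r], nodes)
    b <- match(edges$to[r], nodes)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(src) {
    dist <- rep(Inf, n)
    sigma <- rep(0, n)
    dist[src] <- 0
    sigma[src] <- 1
    frontier <- src
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(seq_len(n), bfs)
  dist <- do.call(rbind, lapply(sp, `[[`, "dist"))
  sigma <- do.call(rbind, lapply(sp, `[[`, "sigma"))
  degree <- vapply(adj, length, integer(1))
  closeness <- vapply(seq_len(n), function(u) {
    d <- dist[u, -u]
    sum(1 / d[is.finite(d)])
  }, numeric(1))
  betweenness <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        betweenness[v] <- betweenness[v] +
          sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  data.frame(node = nodes, degree = degree, closeness = closeness,
             betweenness = betweenness, stringsAsFactors = FALSE)
}

## AUC by explicit pairwise concordance with half credit for ties
oracle_auc <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  total <- 0
  for (p in ps) total <- total + sum(p > ns) + 0.5 * sum(p == ns)
  total / (length(ps) * length(ns))
}

## random simple undirected graph as an edge data frame
random_graph_edges <- function(n, p = 0.2) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(from = nodes[pairs[1, keep]], to = nodes[pairs[2, keep]],
             stringsAsFactors = FALSE)
}
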