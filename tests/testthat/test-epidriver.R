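test_that("sample matching returns the intersection in expression order", {
  ex <- make_expr(matrix(1:9, 3, 3, dimnames = list(NULL, c("a", "b", "c"))))
  mk_meth_cols <- function(cols) {
    make_meth(matrix(0.5, 2, length(cols), dimnames = list(NULL, cols)))
  }
  expect_equal(match_samples(ex, mk_meth_cols(c("c", "a", "b"))),
               c("a", "b", "c"))
  expect_equal(match_samples(ex, mk_meth_cols(c("b", "c", "d"))), c("b", "c"))
  expect_error(match_samples(ex, mk_meth_cols(c("x", "y"))), "no shared")
})

test_that("Pearson test matches the closed formula and the stats reference", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_test(x, -x)$r, -1)
  expect_equal(pearson_test(x, -x)$p, 0)

  res <- pearson_test(x, c(2, 1, 4, 3, 6))
  expect_equal(res$r, 10 / sqrt(10 * 14.8), tolerance = 1e-12)

  orth <- pearson_test(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(orth$r, 0)
  expect_equal(orth$p, 1)

  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "constant")

  set.seed(21)
  for (i in 1:5) {
    a <- stats::rnorm(12)
    b <- stats::rnorm(12)
    mine <- pearson_test(a, b)
    ref <- stats::cor.test(a, b)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the negative-correlation screen keeps planted couplings and drops nulls", {
  set.seed(99)
  n <- 30
  samples <- sprintf("s%02d", 1:n)
  e <- matrix(stats::rnorm(3 * n, mean = 8), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), samples))
  m <- matrix(stats::rnorm(3 * n), nrow = 3,
              dimnames = list(c("cg1", "cg2", "cg3"), samples))
  m[1, ] <- -2 * e["gA", ] + stats::rnorm(n, sd = 0.3)  # strong coupling
  m[2, ] <- 2 * e["gB", ] + stats::rnorm(n, sd = 0.3)   # positive: excluded
  probes <- make_probes(c("cg1", "cg2", "cg3"),
                        genes = c("gA", "gB", "gC"))
  meth <- make_meth(m, scale = "M", probes = probes,
                    samples = make_samples(samples))
  ex <- make_expr(e)
  tab <- screen_negative(ex, meth, c("gA", "gB", "gC"))
  expect_equal(tab$gene, "gA")
  expect_equal(tab$cpg, "cg1")
  expect_lt(tab$r, 0)
  expect_equal(tab$n, n)

  expect_equal(nrow(screen_negative(ex, meth, c("gA", "gB", "gC"),
                                    alpha = 0)), 0)
  sm <- attr(tab, "screen_summary")
  expect_equal(sm$pairs_tested, 3)
  expect_equal(sm$driver_genes, 1)
})

test_that("screen correlations equal per-pair Pearson tests", {
  set.seed(14)
  n <- 20
  samples <- sprintf("s%02d", 1:n)
  genes <- paste0("g", 1:4)
  e <- matrix(stats::rnorm(4 * n), nrow = 4, dimnames = list(genes, samples))
  cpgs <- paste0("cg", 1:8)
  m <- matrix(stats::rnorm(8 * n), nrow = 8, dimnames = list(cpgs, samples))
  probes <- make_probes(cpgs, genes = rep(genes, each = 2))
  meth <- make_meth(m, scale = "M", probes = probes,
                    samples = make_samples(samples))
  tab <- screen_negative(make_expr(e), meth, genes, alpha = 1)
  expect_equal(nrow(tab), sum(sapply(seq_len(8), function(i) {
    pearson_test(e[probes$gene_symbol[i], ], m[i, ])$r < 0
  })))
  for (i in seq_len(nrow(tab))) {
    ref <- pearson_test(e[tab$gene[i], samples], m[tab$cpg[i], samples])
    expect_equal(tab$r[i], ref$r, tolerance = 1e-12)
    expect_equal(tab$p[i], ref$p, tolerance = 1e-12)
  }
})

test_that("gene-gene-CpG network assembly counts nodes and edges correctly", {
  pg <- structure(list(
    nodes = c("gA", "gB", "gC"),
    edges = data.frame(from = c("gA", "gB"), to = c("gB", "gC"),
                       relation = "activation", pathways = "p1",
                       stringsAsFactors = FALSE)),
    class = "pathway_graph")
  drivers <- data.frame(gene = c("gA", "gB"), cpg = c("cg1", "cg2"),
                        r = -0.5, p = 0.01, n = 10, stringsAsFactors = FALSE)
  net <- build_network(pg, drivers)
  expect_equal(length(net$genes) + length(net$cpgs), 4)
  expect_equal(nrow(net$edges), 3)   # gA-gB plus two CpG edges
  expect_false(any(net$edges$from == "gC" | net$edges$to == "gC"))

  ## isolated driver keeps only its CpG edge
  lone <- build_network(pg, data.frame(gene = "gC", cpg = "cg9", r = -0.4,
                                       p = 0.02, n = 10,
                                       stringsAsFactors = FALSE))
  expect_equal(nrow(lone$edges), 1)
  expect_equal(lone$edges$type, "gene-cpg")

  expect_error(build_network(pg, drivers[0, ]), "empty driver")
})

test_that("centralities agree with hand-computed closeness and betweenness", {
  ## star: center with 5 leaves -> betweenness C(5,2) = 10
  star_edges <- data.frame(from = rep("hub", 5), to = paste0("leaf", 1:5),
                           stringsAsFactors = FALSE)
  net_star <- structure(list(genes = unique(c(star_edges$from,
                                              star_edges$to)),
                             cpgs = character(),
                             edges = cbind(star_edges, type = "gene-gene",
                                           stringsAsFactors = FALSE)),
                        class = "gene_cpg_network")
  cs <- centralities(net_star)
  expect_equal(cs$betweenness[cs$gene == "hub"], 10)
  expect_equal(cs$degree[cs$gene == "hub"], 5)
  expect_equal(cs$closeness[cs$gene == "leaf1"], 1 + 4 * 0.5)

  ## path a-b-c: closeness(b) = 2, closeness(a) = 1.5
  net_path <- structure(list(genes = c("a", "b", "c"), cpgs = character(),
                             edges = data.frame(from = c("a", "b"),
                                                to = c("b", "c"),
                                                type = "gene-gene",
                                                stringsAsFactors = FALSE)),
                        class = "gene_cpg_network")
  cp <- centralities(net_path)
  expect_equal(cp$closeness[cp$gene == "b"], 2)
  expect_equal(cp$closeness[cp$gene == "a"], 1.5)
  expect_equal(cp$betweenness[cp$gene == "b"], 1)

  ## path a-b-c-d: betweenness(b) = betweenness(c) = 2
  net4 <- structure(list(genes = letters[1:4], cpgs = character(),
                         edges = data.frame(from = c("a", "b", "c"),
                                            to = c("b", "c", "d"),
                                            type = "gene-gene",
                                            stringsAsFactors = FALSE)),
                    class = "gene_cpg_network")
  c4 <- centralities(net4)
  expect_equal(c4$betweenness[c4$gene == "b"], 2)
  expect_equal(c4$betweenness[c4$gene == "c"], 2)
})

test_that("centralities agree with the all-pairs BFS oracle on random graphs", {
  set.seed(17)
  for (i in 1:5) {
    n <- sample(6:20, 1)
    edges <- random_graph_edges(n, p = 0.25)
    if (nrow(edges) == 0) next
    nodes <- sort(unique(c(edges$from, edges$to)))
    net <- structure(list(genes = nodes, cpgs = character(),
                          edges = cbind(edges, type = "gene-gene",
                                        stringsAsFactors = FALSE)),
                     class = "gene_cpg_network")
    mine <- centralities(net)
    oracle <- oracle_centralities(nodes, edges)
    ord <- match(mine$gene, oracle$node)
    expect_equal(mine$degree, oracle$degree[ord])
    expect_equal(mine$closeness, oracle$closeness[ord], tolerance = 1e-9)
    expect_equal(mine$betweenness, oracle$betweenness[ord], tolerance = 1e-9)
  }
})

test_that("hub selection intersects dense-ranked top lists deterministically", {
  tab <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    degree = c(9, 7, 7, 3, 1),
    closeness = c(5.5, 5.0, 4.0, 4.5, 1.0),
    betweenness = c(20, 18, 2, 19, 0),
    stringsAsFactors = FALSE)
  tab$rank_degree <- gdmdiag:::dense_rank_desc(tab$degree)
  tab$rank_closeness <- gdmdiag:::dense_rank_desc(tab$closeness)
  tab$rank_betweenness <- gdmdiag:::dense_rank_desc(tab$betweenness)

  ## k = 1: g1 dominates every metric
  expect_equal(select_hubs(tab, k = 1), "g1")
  ## k = 2 by hand: degree top2 {g1,g2,g3} (dense tie), closeness {g1,g2},
  ## betweenness {g1,g4} -> intersection {g1}
  expect_equal(select_hubs(tab, k = 2), "g1")
  ## k = n: everything
  expect_setequal(select_hubs(tab, k = 5), tab$gene)
  ## row order invariance
  shuf <- tab[c(4, 2, 5, 1, 3), ]
  expect_equal(select_hubs(shuf, k = 2), select_hubs(tab, k = 2))
  ## fraction mode: top 40% of 5 genes = top 2 ranks
  expect_equal(select_hubs(tab, mode = "fraction", fraction = 0.4), "g1")
})
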