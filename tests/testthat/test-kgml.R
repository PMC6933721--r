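kgml_fixture <- function(body) {
  paste0("<?xml version=\"1.0\"?>\n<pathway name=\"path:test01\" org=\"t\">\n",
         body, "\n</pathway>")
}

test_map <- c("t:1" = "GENE_A", "t:2" = "GENE_B", "t:3" = "GENE_C",
              "t:4" = "GENE_D")

test_that("a minimal two-entry relation yields one undirected edge", {
  xml <- kgml_fixture(paste(
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:2" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--"/></relation>',
    sep = "\n"))
  g <- parse_kgml(xml, test_map)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$from, "GENE_A")
  expect_equal(g$edges$to, "GENE_B")
  expect_equal(g$edges$relation, "activation")
  expect_setequal(g$nodes, c("GENE_A", "GENE_B"))
})

test_that("group entries expand to their members' pairwise relations", {
  xml <- kgml_fixture(paste(
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:2" type="gene"/>',
    '<entry id="3" name="t:3" type="gene"/>',
    '<entry id="10" type="group"><component id="1"/><component id="2"/></entry>',
    '<relation entry1="10" entry2="3" type="PPrel"><subtype name="binding/association" value="--"/></relation>',
    sep = "\n"))
  g <- parse_kgml(xml, test_map)
  expect_equal(edge_set(g$edges),
               c("GENE_A|GENE_C", "GENE_B|GENE_C"))
})

test_that("multi-alias entries expand to one edge per alias", {
  xml <- kgml_fixture(paste(
    '<entry id="1" name="t:1 t:2" type="gene"/>',
    '<entry id="2" name="t:3" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--"/></relation>',
    sep = "\n"))
  g <- parse_kgml(xml, test_map)
  expect_equal(edge_set(g$edges), c("GENE_A|GENE_C", "GENE_B|GENE_C"))
})

test_that("unknown relations and unmappable accessions are skipped with warnings", {
  xml <- kgml_fixture(paste(
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:999" type="gene"/>',
    '<relation entry1="1" entry2="5" type="PPrel"><subtype name="activation" value="--"/></relation>',
    sep = "\n"))
  expect_warning(expect_warning(g <- parse_kgml(xml, test_map),
                                "unmappable"),
                 "unknown entry")
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$nodes, "GENE_A")
})

test_that("parsing is insensitive to entry order", {
  a <- kgml_fixture(paste(
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:2" type="gene"/>',
    '<entry id="3" name="t:3" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--"/></relation>',
    '<relation entry1="3" entry2="1" type="PPrel"><subtype name="inhibition" value="--"/></relation>',
    sep = "\n"))
  b <- kgml_fixture(paste(
    '<entry id="3" name="t:3" type="gene"/>',
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:2" type="gene"/>',
    '<relation entry1="3" entry2="1" type="PPrel"><subtype name="inhibition" value="--"/></relation>',
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--"/></relation>',
    sep = "\n"))
  ga <- parse_kgml(a, test_map)
  gb <- parse_kgml(b, test_map)
  expect_identical(ga$edges, gb$edges)
  expect_identical(ga$nodes, gb$nodes)
})

test_that("merging graphs unions edges with provenance and is idempotent", {
  g3 <- parse_kgml(kgml_fixture(paste(
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:2" type="gene"/>',
    '<entry id="3" name="t:3" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--"/></relation>',
    '<relation entry1="2" entry2="3" type="PPrel"><subtype name="activation" value="--"/></relation>',
    '<relation entry1="1" entry2="3" type="PPrel"><subtype name="activation" value="--"/></relation>',
    sep = "\n")), test_map)
  xml4 <- paste0(
    "<?xml version=\"1.0\"?>\n<pathway name=\"path:test02\" org=\"t\">\n",
    paste('<entry id="1" name="t:1" type="gene"/>',
          '<entry id="2" name="t:2" type="gene"/>',
          '<entry id="3" name="t:3" type="gene"/>',
          '<entry id="4" name="t:4" type="gene"/>',
          '<relation entry1="1" entry2="2" type="PPrel"><subtype name="inhibition" value="--"/></relation>',
          '<relation entry1="1" entry2="4" type="PPrel"><subtype name="activation" value="--"/></relation>',
          '<relation entry1="2" entry2="4" type="PPrel"><subtype name="activation" value="--"/></relation>',
          '<relation entry1="3" entry2="4" type="PPrel"><subtype name="activation" value="--"/></relation>',
          sep = "\n"),
    "\n</pathway>")
  g4 <- parse_kgml(xml4, test_map)

  self <- merge_graphs(list(g3, g3))
  expect_identical(self$edges[, c("from", "to")], g3$edges[, c("from", "to")])

  merged <- merge_graphs(list(g3, g4))
  ## 3 + 4 edges sharing exactly one pair -> 6 by inclusion-exclusion
  expect_equal(nrow(merged$edges), 6)
  shared <- merged$edges[merged$edges$from == "GENE_A" &
                           merged$edges$to == "GENE_B", ]
  expect_equal(shared$pathways, "path:test01;path:test02")
  expect_equal(shared$relation, "activation;inhibition")
})

test_that("degree distributions are exact and the degree sum is twice the edges", {
  star <- parse_kgml(kgml_fixture(paste(
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:2" type="gene"/>',
    '<entry id="3" name="t:3" type="gene"/>',
    '<entry id="4" name="t:4" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--"/></relation>',
    '<relation entry1="1" entry2="3" type="PPrel"><subtype name="activation" value="--"/></relation>',
    '<relation entry1="1" entry2="4" type="PPrel"><subtype name="activation" value="--"/></relation>',
    sep = "\n")), test_map)
  dd <- degree_distribution(star)
  expect_equal(unname(dd$degrees["GENE_A"]), 3)
  expect_equal(dd$histogram$count[dd$histogram$degree == 1], 3)
  expect_equal(sum(dd$degrees), 2 * nrow(star$edges))

  ## complete graph on 4 nodes: all degrees 3
  cfg <- synth_config(n_genes = 30, n_pathways = 2, n_deg_up_case = 5,
                      n_deg_up_control = 3, n_drivers = 4, n_hub_drivers = 4,
                      n_network_genes = 20, seed = 4)
  kg <- generate_kgml(cfg, sprintf("G%04d", 1:30))
  graphs <- lapply(kg$xml, parse_kgml, id_to_symbol = kg$id_to_symbol)
  net <- merge_graphs(graphs)
  dd2 <- degree_distribution(net)
  expect_equal(sum(dd2$degrees), 2 * nrow(net$edges))
})

test_that("network exports round-trip through SIF and GraphML", {
  g <- parse_kgml(kgml_fixture(paste(
    '<entry id="1" name="t:1" type="gene"/>',
    '<entry id="2" name="t:2" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel"><subtype name="activation" value="--"/></relation>',
    sep = "\n")), test_map)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, sif)
  expect_equal(readLines(sif), "GENE_A\tactivation\tGENE_B")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 1)
  expect_setequal(igraph::V(back)$name, c("GENE_A", "GENE_B"))
})
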