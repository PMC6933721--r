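small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 150, n_pathways = 5, n_deg_up_case = 40,
         n_deg_up_control = 20, n_drivers = 8, n_hub_drivers = 4,
         n_network_genes = 80, n_cases_external = 4,
         n_controls_external = 20),
    list(...))
  do.call(synth_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(synth_config(n_hub_drivers = 30, n_drivers = 20),
               "n_hub_drivers")
  expect_error(synth_config(n_deg_up_case = 1000, n_deg_up_control = 500,
                            n_genes = 1200), "exceed n_genes")
  expect_error(synth_config(n_cases_expr = 50, n_cases_meth = 41), "subset")
  expect_error(synth_config(logfc_range = c(2, 1)), "logfc_range")
  expect_error(synth_config(driver_r_target = 0.5), "driver_r_target")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  ## planted-effect counts of zero are legal (null configurations)
  expect_s3_class(synth_config(n_deg_up_case = 0, n_deg_up_control = 0,
                               n_drivers = 0, n_hub_drivers = 0),
                  "synth_config")
})

test_that("cohort structure matches the configured design", {
  cfg <- small_cfg(seed = 2)
  sim <- generate_cohort(cfg)
  expect_equal(ncol(sim$meth$values), 82)
  expect_equal(ncol(sim$expr$values), 55)
  expect_equal(sum(sim$expr$samples$condition == "GDM"), 30)
  expect_equal(sum(sim$expr$samples$condition == "control"), 25)
  ## expression samples are a subset of methylation samples
  expect_true(all(colnames(sim$expr$values) %in% colnames(sim$meth$values)))
  ## ground-truth invariants
  expect_true(all(sim$truth$hub_genes %in% sim$truth$driver_pairs$gene))
  prom <- sim$meth$probes[sim$meth$probes$region_class %in%
                            c("TSS1500", "TSS200", "5UTR", "1stExon"), ]
  expect_true(all(unique(sim$truth$driver_pairs$gene) %in% prom$gene_symbol))
  ## planted DEG counts
  expect_equal(sum(sim$truth$deg_genes$direction == "up_in_GDM"), 40)
  expect_equal(sum(sim$truth$deg_genes$direction == "up_in_control"), 20)
  expect_true(all(sim$truth$deg_genes$log2_fc[
    sim$truth$deg_genes$direction == "up_in_control"] < 0))
})

test_that("a zero missing rate yields complete matrices", {
  sim <- generate_cohort(small_cfg(missing_rate = 0, seed = 3))
  expect_false(anyNA(sim$meth$values))
  expect_false(anyNA(sim$expr$values))
})

test_that("without planted drivers there is no methylation-expression coupling", {
  sim <- generate_cohort(small_cfg(n_drivers = 0, n_hub_drivers = 0,
                                   missing_rate = 0, seed = 4))
  expect_equal(nrow(sim$truth$driver_pairs), 0)
  m <- beta_to_m(sim$meth)
  matched <- match_samples(sim$expr, m)
  set.seed(1)
  idx <- sample(nrow(m$values), 60)
  rs <- vapply(idx, function(i) {
    g <- m$probes$gene_symbol[i]
    stats::cor(sim$expr$values[g, matched], m$values[i, matched])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("driver couplings hit the target correlation on the default design", {
  sim <- generate_cohort(synth_config(seed = 1))
  m <- beta_to_m(sim$meth)
  matched <- match_samples(sim$expr, m)
  dp <- sim$truth$driver_pairs
  rs <- mapply(function(g, cpg) {
    stats::cor(sim$expr$values[g, matched], m$values[cpg, matched],
               use = "complete.obs")
  }, dp$gene, dp$cpg)
  expect_lt(abs(mean(rs) - (-0.6)), 0.15)
  expect_true(all(rs < 0))
})

test_that("promoter CpG counts follow the calibrated truncated geometric", {
  sim <- generate_cohort(synth_config(seed = 6))
  prom <- sim$meth$probes[sim$meth$probes$region_class %in%
                            c("TSS1500", "TSS200", "5UTR", "1stExon"), ]
  cnt <- table(prom$gene_symbol)
  expect_true(all(cnt <= 30))
  ## >= 80% of genes with any promoter CpG have fewer than 20
  expect_gte(mean(cnt < 20), 0.80)
  ## most genes have at least one promoter CpG
  expect_gt(length(cnt) / 1200, 0.85)
})

test_that("generation is deterministic given the seed", {
  cfg <- small_cfg(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ka <- generate_kgml(cfg, rownames(a$expr$values))
  kb <- generate_kgml(cfg, rownames(b$expr$values))
  expect_identical(ka, kb)
  c <- generate_cohort(small_cfg(seed = 12))
  expect_false(identical(a$meth$values, c$meth$values))
})

test_that("generated KGML round-trips exactly through the parser", {
  ## minimal fixture: no hubs, single-edge attachment
  cfg <- synth_config(n_genes = 3, n_pathways = 1, n_deg_up_case = 0,
                      n_deg_up_control = 0, n_drivers = 0, n_hub_drivers = 0,
                      n_network_genes = 3, ba_m = 1, seed = 5)
  kg <- generate_kgml(cfg, c("GA", "GB", "GC"))
  expect_length(kg$xml, 1)
  g <- parse_kgml(kg$xml[[1]], kg$id_to_symbol)
  expect_equal(edge_set(g$edges), edge_set(kg$true_edges))

  ## default-shaped generation: union of parsed pathways = truth
  cfg2 <- small_cfg(seed = 7)
  sim <- generate_cohort(cfg2)
  kg2 <- generate_kgml(cfg2, rownames(sim$expr$values))
  graphs <- lapply(kg2$xml, parse_kgml, id_to_symbol = kg2$id_to_symbol)
  net <- merge_graphs(graphs)
  expect_equal(edge_set(net$edges), edge_set(kg2$true_edges))

  ## hub seeding: the maximum-degree node is a planted hub
  dd <- degree_distribution(net)
  expect_true(names(which.max(dd$degrees)) %in%
                sprintf("G%04d", 1:4))
  expect_lt(dd$loglog_slope, 0)
})

test_that("group and alias constructs appear in the emitted KGML", {
  cfg <- small_cfg(seed = 8)
  kg <- generate_kgml(cfg, sprintf("G%04d", 1:150))
  all_xml <- paste(kg$xml, collapse = "\n")
  expect_match(all_xml, "type=\"group\"")
  expect_match(all_xml, "name=\"syn:[0-9]+ syn:[0-9]+\"")
})

test_that("written artifacts are readable plain text", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_cfg(seed = 9), dir = dir)
  expect_true(file.exists(file.path(dir, "meth_beta.tsv")))
  meth <- read_methylation_tsv(file.path(dir, "meth_beta.tsv"),
                               file.path(dir, "probe_annotation.tsv"),
                               file.path(dir, "meth_samples.tsv"))
  expect_equal(meth$values, sim$meth$values)
  expect_equal(meth$probes$flag_snp, sim$meth$probes$flag_snp)
  expr <- read_expression_tsv(file.path(dir, "expr_matrix.tsv"),
                              file.path(dir, "expr_samples.tsv"))
  expect_equal(expr$values, sim$expr$values, tolerance = 1e-12)
  gmt <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(length(gmt$sets), length(sim$kgml$pathway_sets))
  kfiles <- list.files(file.path(dir, "kgml"), full.names = TRUE)
  expect_length(kfiles, 5)
  g <- parse_kgml(kfiles[1], sim$kgml$id_to_symbol)
  expect_s3_class(g, "pathway_graph")
})
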