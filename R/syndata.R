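## Synthetic paired-cohort generator. Emulates the study design the workflow
## targets: a 41 + 41 placental methylation cohort (450K-style promoter CpG
## annotation, bimodal beta values, blacklist flags, missingness), a matched
## 30 + 25 expression cohort whose sample ids are a subset of the methylation
## ids, planted differentially expressed genes, genes whose promoter
## methylation is negatively coupled to their expression, a scale-free
## pathway network with planted hub genes emitted as KGML XML, and an
## external validation cohort (6 GDM / 177 control).

#' Synthetic study configuration
#'
#' Holds every knob of the synthetic-data generator. Defaults reproduce the
#' study design the workflow was built around: methylation cohorts of 41 GDM
#' and 41 control samples, an expression cohort of 30 GDM and 25 control
#' samples drawn from the same individuals, 1200 genes of which 300 are
#' planted up in GDM and 165 up in control, 20 genes with promoter
#' methylation negatively coupled to expression (target Pearson r -0.6), 10
#' of them planted as pathway-network hubs, and an external cohort of
#' 6 GDM / 177 control samples.
#'
#' @param n_cases_meth,n_controls_meth Methylation cohort sizes.
#' @param n_cases_expr,n_controls_expr Expression cohort sizes; must not
#'   exceed the methylation sizes (expression samples are a subset).
#' @param n_genes Number of genes.
#' @param n_pathways Number of KGML pathway files to emit.
#' @param n_deg_up_case,n_deg_up_control Planted DEG counts up-regulated in
#'   GDM and in control respectively.
#' @param n_drivers Genes with a promoter CpG negatively coupled to
#'   expression ("epigenetically driven" ground truth).
#' @param n_hub_drivers Drivers additionally planted as network hubs
#'   (must be <= `n_drivers`).
#' @param logfc_range Interval the planted |log2 fold-changes| are drawn
#'   from, log2 scale.
#' @param driver_r_target Target Pearson correlation (negative) between a
#'   driver gene's expression and its coupled promoter CpG M-values.
#' @param missing_rate Fraction of methylation matrix entries set missing.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param n_network_genes Size of the pathway-network gene pool (first
#'   `n_network_genes` genes; contains all drivers and planted DEGs).
#' @param baseline_mean,baseline_sd Per-gene baseline expression
#'   distribution, log2 scale.
#' @param noise_sd Per-sample expression noise standard deviation (log2).
#' @param hub_effect_sd Planted hub-gene case-control effect size in units
#'   of `noise_sd` (so the default 1.5 means a log2 fold-change of
#'   `1.5 * noise_sd`).
#' @param cpg_geom_p Success probability of the truncated geometric promoter
#'   CpG count distribution; the default puts about 82.5% of genes with at
#'   least one CpG below 20 CpGs.
#' @param cpg_max Hard cap on promoter CpGs per gene.
#' @param prob_gene_has_cpg Probability a gene has any promoter CpG.
#' @param nonpromoter_frac Extra gene-body/3'UTR probes, as a fraction of
#'   the promoter probe count.
#' @param flag_snp_rate,flag_crosshyb_rate,sex_chrom_rate Rates of the three
#'   blacklist conditions among non-coupled probes.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate distributions
#'   (maternal age in years, pre-pregnancy BMI in kg/m^2).
#' @param age_shift,bmi_shift Additive covariate shift applied to true GDM
#'   samples (default 0: a matched cohort).
#' @param n_cases_external,n_controls_external External validation cohort
#'   sizes.
#' @param ba_m Edges attached per node during preferential-attachment
#'   network growth.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_cases_meth = 41, n_controls_meth = 41,
                         n_cases_expr = 30, n_controls_expr = 25,
                         n_genes = 1200, n_pathways = 30,
                         n_deg_up_case = 300, n_deg_up_control = 165,
                         n_drivers = 20, n_hub_drivers = 10,
                         logfc_range = c(0.5, 2.0),
                         driver_r_target = -0.6,
                         missing_rate = 0.02, seed = 1L,
                         n_network_genes = 600,
                         baseline_mean = 8, baseline_sd = 1.5,
                         noise_sd = 0.7, hub_effect_sd = 1.5,
                         cpg_geom_p = 0.0876, cpg_max = 30,
                         prob_gene_has_cpg = 0.93,
                         nonpromoter_frac = 0.25,
                         flag_snp_rate = 0.02, flag_crosshyb_rate = 0.01,
                         sex_chrom_rate = 0.02,
                         age_mean = 33.3, age_sd = 4.75,
                         bmi_mean = 26.5, bmi_sd = 5.6,
                         age_shift = 0, bmi_shift = 0,
                         n_cases_external = 6, n_controls_external = 177,
                         ba_m = 2) {
  cfg <- as.list(environment())
  pos <- c("n_cases_meth", "n_controls_meth", "n_cases_expr",
           "n_controls_expr", "n_genes", "n_pathways", "ba_m",
           "n_cases_external", "n_controls_external")
  for (f in pos) {
    if (!is_count(cfg[[f]])) abort("synth_config: %s must be a positive count", f)
  }
  nonneg <- c("n_deg_up_case", "n_deg_up_control", "n_drivers",
              "n_hub_drivers", "n_network_genes")
  for (f in nonneg) {
    if (!is_count(cfg[[f]], allow_zero = TRUE)) {
      abort("synth_config: %s must be a non-negative count", f)
    }
  }
  if (cfg$n_hub_drivers > cfg$n_drivers) {
    abort("synth_config: n_hub_drivers must not exceed n_drivers")
  }
  if (cfg$n_drivers > cfg$n_genes) {
    abort("synth_config: n_drivers must not exceed n_genes")
  }
  if (cfg$n_deg_up_case + cfg$n_deg_up_control > cfg$n_genes) {
    abort("synth_config: planted DEG counts exceed n_genes")
  }
  if (cfg$n_cases_expr > cfg$n_cases_meth ||
      cfg$n_controls_expr > cfg$n_controls_meth) {
    abort("synth_config: expression cohort must be a subset of the methylation cohort")
  }
  if (cfg$n_network_genes > cfg$n_genes) cfg$n_network_genes <- cfg$n_genes
  if (cfg$n_network_genes < cfg$n_drivers) {
    abort("synth_config: n_network_genes must cover all drivers")
  }
  if (!(length(cfg$logfc_range) == 2 && cfg$logfc_range[1] > 0 &&
        diff(cfg$logfc_range) >= 0)) {
    abort("synth_config: logfc_range must be an increasing positive interval")
  }
  if (!(cfg$driver_r_target < 0 && cfg$driver_r_target > -1)) {
    abort("synth_config: driver_r_target must lie in (-1, 0)")
  }
  if (!is_fraction(cfg$missing_rate) || cfg$missing_rate >= 1) {
    abort("synth_config: missing_rate must lie in [0, 1)")
  }
  if (!is_count(cfg$seed, allow_zero = TRUE)) {
    abort("synth_config: seed must be an integer")
  }
  structure(cfg, class = "synth_config")
}

syn_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

syn_sample_ids <- function(config) {
  list(case = sprintf("GDM%02d", seq_len(config$n_cases_meth)),
       control = sprintf("CTL%02d", seq_len(config$n_controls_meth)))
}

## Deterministic planted identities: gene labels are arbitrary in a
## simulator, so hubs are genes 1..n_hub_drivers, drivers genes 1..n_drivers,
## DEGs the first n_deg_up_case + n_deg_up_control genes, and the pathway
## gene pool the first n_network_genes genes. This lets generate_cohort()
## and generate_kgml() agree on identities through the config alone.
planted_identities <- function(config) {
  genes <- syn_gene_ids(config$n_genes)
  list(
    genes = genes,
    hubs = genes[seq_len(config$n_hub_drivers)],
    drivers = genes[seq_len(config$n_drivers)],
    up_case = genes[seq_len(config$n_deg_up_case)],
    up_control = if (config$n_deg_up_control > 0) {
      genes[config$n_deg_up_case + seq_len(config$n_deg_up_control)]
    } else {
      character()
    }
  )
}

#' Generate a paired synthetic methylation / expression cohort
#'
#' Expression is simulated directly on the normalized log2 scale: per-gene
#' baselines are Normal(`baseline_mean`, `baseline_sd`), per-sample noise
#' Normal(0, `noise_sd`), and planted DEGs shift the GDM group mean by a
#' signed log2 fold-change drawn from `logfc_range` (hub drivers use a fixed
#' effect of `hub_effect_sd * noise_sd`). Expression is generated for every
#' methylation sample; the emitted expression cohort is a random subset of
#' those samples, so downstream sample matching is nontrivial. Promoter CpG
#' counts per gene follow a truncated geometric distribution; non-coupled
#' CpG beta values come from an equal-weight Beta(2, 8) / Beta(8, 2)
#' mixture, while each driver gene's coupled CpGs are generated on the
#' M-value scale as a negative linear function of that gene's expression
#' with noise calibrated so the expected Pearson correlation is
#' `driver_r_target`. Missing entries are injected into the methylation
#' matrix at `missing_rate`, and a small fraction of non-coupled probes
#' carry sex-chromosome, SNP or cross-hybridization blacklist flags.
#'
#' @param config A [synth_config()].
#' @return A list with elements `meth` ([methylation_data] on the beta
#'   scale), `expr` ([expression_data], gene level), `external`
#'   ([expression_data] for the external validation cohort), and `truth`, a
#'   list of planted ground truth: `deg_genes` (gene, direction, log2_fc),
#'   `driver_pairs` (gene, cpg, slope), `hub_genes`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ids <- planted_identities(config)
  samp <- syn_sample_ids(config)
  with_seed(config$seed, generate_cohort_impl(config, ids, samp))
}

generate_cohort_impl <- function(config, ids, samp) {
  genes <- ids$genes
  n_genes <- config$n_genes
  meth_ids <- c(samp$case, samp$control)
  is_case <- c(rep(TRUE, config$n_cases_meth),
               rep(FALSE, config$n_controls_meth))
  n_meth <- length(meth_ids)

  ## --- planted effects -----------------------------------------------------
  lfc <- numeric(n_genes)
  names(lfc) <- genes
  if (config$n_deg_up_case > 0) {
    lfc[ids$up_case] <- stats::runif(length(ids$up_case),
                                     config$logfc_range[1],
                                     config$logfc_range[2])
  }
  if (config$n_deg_up_control > 0) {
    lfc[ids$up_control] <- -stats::runif(length(ids$up_control),
                                         config$logfc_range[1],
                                         config$logfc_range[2])
  }
  if (config$n_hub_drivers > 0 && config$n_deg_up_case >= config$n_hub_drivers) {
    ## hubs sit inside the up-in-GDM block with a fixed, known effect size
    lfc[ids$hubs] <- config$hub_effect_sd * config$noise_sd
  }

  ## --- expression over every methylation sample ---------------------------
  baseline <- stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
  E <- matrix(stats::rnorm(n_genes * n_meth, 0, config$noise_sd),
              nrow = n_genes, dimnames = list(genes, meth_ids))
  E <- E + baseline + outer(lfc, as.numeric(is_case))

  ## expression cohort: random subset of methylation samples, meth order kept
  expr_cases <- sort(sample(seq_along(samp$case), config$n_cases_expr))
  expr_controls <- sort(sample(seq_along(samp$control), config$n_controls_expr))
  expr_ids <- c(samp$case[expr_cases], samp$control[expr_controls])

  ## --- covariates ----------------------------------------------------------
  meta <- data.frame(
    sample_id = meth_ids,
    condition = ifelse(is_case, "GDM", "control"),
    age = stats::rnorm(n_meth, config$age_mean, config$age_sd) +
      config$age_shift * is_case,
    bmi = stats::rnorm(n_meth, config$bmi_mean, config$bmi_sd) +
      config$bmi_shift * is_case,
    stringsAsFactors = FALSE
  )

  ## --- probe annotation ----------------------------------------------------
  has_cpg <- stats::rbinom(n_genes, 1, config$prob_gene_has_cpg) == 1
  cpg_n <- ifelse(has_cpg,
                  pmin(1L + stats::rgeom(n_genes, config$cpg_geom_p),
                       config$cpg_max),
                  0L)
  if (config$n_drivers > 0) {
    cpg_n[seq_len(config$n_drivers)] <- pmax(cpg_n[seq_len(config$n_drivers)], 1L)
  }
  prom_gene <- rep(genes, cpg_n)
  n_prom <- length(prom_gene)
  n_nonprom <- round(config$nonpromoter_frac * n_prom)
  nonprom_gene <- if (n_nonprom > 0) sample(genes, n_nonprom, replace = TRUE)
                  else character()
  probe_gene <- c(prom_gene, nonprom_gene)
  n_probes <- length(probe_gene)
  probes <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(n_probes)),
    gene_symbol = probe_gene,
    region_class = c(
      sample(PROMOTER_CLASSES, n_prom, replace = TRUE,
             prob = c(0.35, 0.30, 0.20, 0.15)),
      sample(NONPROMOTER_CLASSES, max(n_nonprom, 0), replace = TRUE,
             prob = c(0.7, 0.3))
    ),
    chromosome = ifelse(stats::runif(n_probes) < config$sex_chrom_rate,
                        sample(c("chrX", "chrY"), n_probes, replace = TRUE),
                        paste0("chr", sample(1:22, n_probes, replace = TRUE))),
    flag_snp = stats::runif(n_probes) < config$flag_snp_rate,
    flag_crosshyb = stats::runif(n_probes) < config$flag_crosshyb_rate,
    stringsAsFactors = FALSE
  )

  ## --- driver gene / CpG coupling ------------------------------------------
  driver_pairs <- data.frame(gene = character(), cpg = character(),
                             slope = numeric(), stringsAsFactors = FALSE)
  if (config$n_drivers > 0) {
    n_coupled <- 1L + stats::rbinom(config$n_drivers, 1L, 0.3)
    for (i in seq_len(config$n_drivers)) {
      g <- ids$drivers[i]
      cands <- which(probes$gene_symbol == g &
                       probes$region_class %in% PROMOTER_CLASSES)
      take <- cands[seq_len(min(n_coupled[i], length(cands)))]
      driver_pairs <- rbind(driver_pairs, data.frame(
        gene = g, cpg = probes$probe_id[take], slope = -1,
        stringsAsFactors = FALSE))
      ## coupled probes must survive the blacklist / promoter filters
      probes$chromosome[take] <- paste0("chr", sample(1:22, length(take),
                                                      replace = TRUE))
      probes$flag_snp[take] <- FALSE
      probes$flag_crosshyb[take] <- FALSE
    }
  }

  ## --- methylation beta matrix ---------------------------------------------
  beta <- matrix(NA_real_, nrow = n_probes, ncol = n_meth,
                 dimnames = list(probes$probe_id, meth_ids))
  hyper <- stats::runif(n_probes) < 0.5  # mixture component per probe
  shp1 <- ifelse(hyper, 8, 2)
  shp2 <- ifelse(hyper, 2, 8)
  beta[] <- stats::rbeta(n_probes * n_meth, rep(shp1, n_meth), rep(shp2, n_meth))
  if (nrow(driver_pairs) > 0) {
    r <- abs(config$driver_r_target)
    for (j in seq_len(nrow(driver_pairs))) {
      e <- E[driver_pairs$gene[j], ]
      sd_e <- stats::sd(e)
      sd_eta <- sd_e * sqrt(1 / r^2 - 1)
      intercept <- stats::rnorm(1, 0, 0.5)
      m <- intercept - (e - mean(e)) + stats::rnorm(n_meth, 0, sd_eta)
      beta[driver_pairs$cpg[j], ] <- stats::plogis(m * log(2))
    }
  }
  if (config$missing_rate > 0) {
    beta[stats::runif(length(beta)) < config$missing_rate] <- NA_real_
  }

  ## --- external validation cohort ------------------------------------------
  n_ext <- config$n_cases_external + config$n_controls_external
  ext_ids <- sprintf("EXT%03d", seq_len(n_ext))
  ext_case <- c(rep(TRUE, config$n_cases_external),
                rep(FALSE, config$n_controls_external))
  Eext <- matrix(stats::rnorm(n_genes * n_ext, 0, config$noise_sd),
                 nrow = n_genes, dimnames = list(genes, ext_ids))
  Eext <- Eext + baseline + outer(lfc, as.numeric(ext_case))
  ext_meta <- data.frame(
    sample_id = ext_ids,
    condition = ifelse(ext_case, "GDM", "control"),
    age = stats::rnorm(n_ext, config$age_mean, config$age_sd) +
      config$age_shift * ext_case,
    bmi = stats::rnorm(n_ext, config$bmi_mean, config$bmi_sd) +
      config$bmi_shift * ext_case,
    stringsAsFactors = FALSE
  )

  deg <- data.frame(
    gene = c(ids$up_case, ids$up_control),
    direction = c(rep("up_in_GDM", length(ids$up_case)),
                  rep("up_in_control", length(ids$up_control))),
    log2_fc = lfc[c(ids$up_case, ids$up_control)],
    stringsAsFactors = FALSE
  )
  rownames(deg) <- NULL

  list(
    meth = methylation_data(beta, probes, meta, scale = "beta"),
    expr = expression_data(E[, expr_ids, drop = FALSE],
                           meta[meta$sample_id %in% expr_ids, , drop = FALSE],
                           level = "gene"),
    external = expression_data(Eext, ext_meta, level = "gene"),
    truth = list(deg_genes = deg, driver_pairs = driver_pairs,
                 hub_genes = ids$hubs)
  )
}

#' Generate synthetic KGML pathway files
#'
#' Grows a scale-free gene interaction network by preferential attachment:
#' the planted hub genes form a fully connected seed, every other gene of
#' the network pool then joins in random order with `ba_m` edges attached
#' preferentially by degree, so the hubs end up with the highest degrees.
#' Edges are partitioned across `n_pathways` KGML documents (entry /
#' relation elements). One pathway additionally contains a `group` entry
#' whose members relate to a third entry, and one contains an entry listing
#' two gene aliases, exercising parser expansion; the implied pairwise
#' edges are part of the returned truth.
#'
#' @param config A [synth_config()].
#' @param gene_ids Gene symbols the network may draw from (the first
#'   `n_network_genes` of them form the pool); typically
#'   `rownames(cohort$expr$values)`.
#' @return A list with `xml` (named character vector of KGML documents),
#'   `true_edges` (data frame `from`/`to`, the exact expected edge set of
#'   the merged network), `id_to_symbol` (named character vector mapping
#'   KGML accessions to gene symbols), and `pathway_sets` (named list of
#'   the genes of each pathway, usable as a gene-set collection).
#' @export
generate_kgml <- function(config, gene_ids) {
  stopifnot(inherits(config, "synth_config"))
  if (length(gene_ids) == 0) abort("generate_kgml: gene_ids must be nonempty")
  with_seed(config$seed + 7919L, generate_kgml_impl(config, gene_ids))
}

generate_kgml_impl <- function(config, gene_ids) {
  n_pool <- min(config$n_network_genes, length(gene_ids))
  if (n_pool < 2) abort("generate_kgml: need at least 2 genes in the pool")
  pool <- gene_ids[seq_len(n_pool)]
  n_hub <- min(config$n_hub_drivers, n_pool)

  ## seed component: complete graph over the hubs (or the first two genes)
  seed_nodes <- if (n_hub >= 2) seq_len(n_hub) else 1:2
  seed_pairs <- utils::combn(seed_nodes, 2)
  from <- seed_pairs[1, ]
  to <- seed_pairs[2, ]
  degree <- tabulate(c(from, to), nbins = n_pool)
  active <- seed_nodes
  rest <- setdiff(seq_len(n_pool), seed_nodes)
  for (v in rest[sample.int(length(rest))]) {
    m <- min(config$ba_m, length(active))
    targets <- active[sample.int(length(active), m, prob = degree[active])]
    from <- c(from, rep(v, m))
    to <- c(to, targets)
    degree[v] <- degree[v] + m
    degree[targets] <- degree[targets] + 1L
    active <- c(active, v)
  }
  edges <- canonical_edges(pool[from], pool[to])
  edges$pathway <- sample(config$n_pathways, nrow(edges), replace = TRUE)
  subtypes <- c("activation", "inhibition", "binding/association")
  edges$relation <- sample(subtypes, nrow(edges), replace = TRUE)

  ## special constructs (group entry; entry with two gene aliases); their
  ## implied pairwise edges join the truth but are encoded only through the
  ## group / alias elements, exercising parser expansion
  genes_in <- function(p) unique(c(edges$from[edges$pathway == p],
                                   edges$to[edges$pathway == p]))
  grp <- NULL
  p1 <- genes_in(1L)
  if (length(p1) >= 3) {
    grp <- list(pathway = 1L, members = p1[1:2], partner = p1[3])
  }
  alias <- NULL
  p2 <- min(2L, config$n_pathways)
  g2 <- genes_in(p2)
  if (length(g2) >= 3) {
    alias <- list(pathway = p2, aliases = g2[1:2], partner = g2[3])
  }
  construct_edges <- function(x) {
    if (is.null(x)) return(NULL)
    canonical_edges(c(x[[2]][1], x[[2]][2]), rep(x$partner, 2))
  }
  extra <- rbind(construct_edges(grp), construct_edges(alias))

  id_of <- stats::setNames(sprintf("syn:%d", seq_len(n_pool)), pool)
  id_to_symbol <- stats::setNames(pool, unname(id_of))

  xml <- character(config$n_pathways)
  names(xml) <- sprintf("synpath%02d", seq_len(config$n_pathways))
  pathway_sets <- vector("list", config$n_pathways)
  names(pathway_sets) <- names(xml)
  for (p in seq_len(config$n_pathways)) {
    sub <- edges[edges$pathway == p, , drop = FALSE]
    g_p <- if (!is.null(grp) && grp$pathway == p) grp
    a_p <- if (!is.null(alias) && alias$pathway == p) alias
    xml[p] <- build_kgml_document(names(xml)[p], p, sub, id_of, g_p, a_p)
    pathway_sets[[p]] <- sort(unique(c(
      sub$from, sub$to,
      if (!is.null(g_p)) c(g_p$members, g_p$partner),
      if (!is.null(a_p)) c(a_p$aliases, a_p$partner))))
  }

  all_edges <- rbind(edges[, c("from", "to")], extra)
  true_edges <- unique(canonical_edges(all_edges$from, all_edges$to))
  true_edges <- true_edges[true_edges$from != true_edges$to, , drop = FALSE]
  true_edges <- true_edges[order(true_edges$from, true_edges$to), ]
  rownames(true_edges) <- NULL
  list(xml = xml, true_edges = true_edges, id_to_symbol = id_to_symbol,
       pathway_sets = pathway_sets[lengths(pathway_sets) > 0])
}

## Serialize one synthetic pathway as KGML. `edges` rows carry from/to gene
## symbols and a relation subtype and become plain entry-entry relations.
## The optional `group` construct adds a KGML group entry whose components
## relate to a partner entry; the optional `alias` construct adds one gene
## entry naming two accessions, related to a partner entry.
build_kgml_document <- function(name, number, edges, id_of,
                                group = NULL, alias = NULL) {
  genes <- unique(c(edges$from, edges$to,
                    if (!is.null(group)) c(group$members, group$partner),
                    if (!is.null(alias)) alias$partner))
  entry_id <- stats::setNames(seq_along(genes), genes)
  next_id <- length(genes) + 1L
  lines <- c(
    "<?xml version=\"1.0\"?>",
    sprintf("<pathway name=\"path:%s\" org=\"syn\" number=\"%02d\" title=\"Synthetic pathway %02d\">",
            name, number, number)
  )
  for (g in genes) {
    lines <- c(lines, sprintf(
      "  <entry id=\"%d\" name=\"%s\" type=\"gene\"/>",
      entry_id[[g]], id_of[[g]]))
  }
  relation <- function(e1, e2, subtype) {
    sprintf(paste0(
      "  <relation entry1=\"%d\" entry2=\"%d\" type=\"PPrel\">\n",
      "    <subtype name=\"%s\" value=\"--&gt;\"/>\n  </relation>"),
      e1, e2, subtype)
  }
  rel_lines <- character()
  if (nrow(edges) > 0) {
    rel_lines <- mapply(relation, entry_id[edges$from], entry_id[edges$to],
                        edges$relation)
  }
  if (!is.null(alias)) {
    alias_entry <- next_id
    next_id <- next_id + 1L
    lines <- c(lines, sprintf(
      "  <entry id=\"%d\" name=\"%s %s\" type=\"gene\"/>",
      alias_entry, id_of[[alias$aliases[1]]], id_of[[alias$aliases[2]]]))
    rel_lines <- c(rel_lines,
                   relation(alias_entry, entry_id[[alias$partner]],
                            "activation"))
  }
  if (!is.null(group)) {
    group_entry <- next_id
    comp <- vapply(group$members, function(g) entry_id[[g]], integer(1))
    lines <- c(lines,
               sprintf("  <entry id=\"%d\" type=\"group\">", group_entry),
               sprintf("    <component id=\"%d\"/>", comp),
               "  </entry>")
    rel_lines <- c(rel_lines,
                   relation(group_entry, entry_id[[group$partner]],
                            "activation"))
  }
  paste(c(lines, rel_lines, "</pathway>"), collapse = "\n")
}

#' Generate and optionally write a complete synthetic study
#'
#' Convenience wrapper running [generate_cohort()] and [generate_kgml()]
#' and, when `dir` is given, writing every artifact as plain text:
#' methylation beta matrix, probe annotation, sample metadata, expression
#' matrix and metadata, external-cohort matrix and metadata, KGML XML files,
#' a GMT file of the synthetic pathway gene sets, the KGML accession-to-
#' symbol mapping, and the ground truth as JSON.
#'
#' @inheritParams generate_cohort
#' @param dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return A list with `meth`, `expr`, `external`, `truth` (as
#'   [generate_cohort()], with `truth$true_edges` added), and `kgml` (as
#'   [generate_kgml()]).
#' @export
simulate_study <- function(config, dir = NULL) {
  cohort <- generate_cohort(config)
  kgml <- generate_kgml(config, rownames(cohort$expr$values))
  cohort$truth$true_edges <- kgml$true_edges
  out <- c(cohort, list(kgml = kgml))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(cohort$meth$values, file.path(dir, "meth_beta.tsv"),
                     id_col = "probe_id")
    write_tsv_base(cohort$meth$probes, file.path(dir, "probe_annotation.tsv"))
    write_tsv_base(cohort$meth$samples, file.path(dir, "meth_samples.tsv"))
    write_matrix_tsv(cohort$expr$values, file.path(dir, "expr_matrix.tsv"),
                     id_col = "gene")
    write_tsv_base(cohort$expr$samples, file.path(dir, "expr_samples.tsv"))
    write_matrix_tsv(cohort$external$values,
                     file.path(dir, "external_matrix.tsv"), id_col = "gene")
    write_tsv_base(cohort$external$samples,
                   file.path(dir, "external_samples.tsv"))
    kdir <- file.path(dir, "kgml")
    dir.create(kdir, showWarnings = FALSE)
    for (nm in names(kgml$xml)) {
      writeLines(kgml$xml[[nm]], file.path(kdir, paste0(nm, ".xml")))
    }
    write_tsv_base(data.frame(accession = names(kgml$id_to_symbol),
                              gene_symbol = unname(kgml$id_to_symbol),
                              stringsAsFactors = FALSE),
                   file.path(dir, "id_to_symbol.tsv"))
    write_gmt(kgml$pathway_sets, file.path(dir, "pathways.gmt"))
    jsonlite::write_json(out$truth, file.path(dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  out
}
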