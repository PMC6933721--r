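## two well-separated Gaussian clouds in d dimensions
separable_data <- function(n_per = 15, d = 10, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d, mean = gap), n_per))
  rownames(x) <- sprintf("s%02d", seq_len(2 * n_per))
  colnames(x) <- sprintf("g%02d", seq_len(d))
  list(x = x, labels = rep(c("control", "GDM"), each = n_per))
}

test_that("sample splits are seeded, stratified and validated", {
  samples <- make_samples(sprintf("s%02d", 1:55),
                          rep(c("GDM", "control"), c(30, 25)))
  sp1 <- split_samples(samples, c(GDM = 15, control = 12), seed = 7)
  sp2 <- split_samples(samples, c(GDM = 15, control = 12), seed = 7)
  expect_identical(sp1$train, sp2$train)
  expect_equal(length(sp1$train), 27)
  expect_equal(length(sp1$validation), 28)
  vcond <- samples$condition[match(sp1$validation, samples$sample_id)]
  expect_equal(sum(vcond == "GDM"), 15)
  expect_equal(sum(vcond == "control"), 13)

  expect_error(split_samples(samples, c(GDM = 31, control = 12)),
               "infeasible")
  expect_error(split_samples(samples, c(GDM = 30, control = 25)), "empty")
})

test_that("the SVM separates separable clouds and rejects degenerate input", {
  d <- separable_data()
  model <- train_svm(d$x, d$labels, folds = 10, seed = 3)
  expect_equal(model$cv_accuracy, 1.0)
  ## training evaluation of a separable problem is perfect
  ev <- evaluate(model, d$x, d$labels)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$auc, 1.0)

  expect_error(train_svm(d$x, rep("GDM", nrow(d$x))), "single class")
})

test_that("permuted labels give chance-level cross-validation accuracy", {
  d <- separable_data(n_per = 14, seed = 5)
  set.seed(42)
  accs <- vapply(1:20, function(i) {
    train_svm(d$x, sample(d$labels), folds = 10, seed = i)$cv_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("AUC matches pairwise concordance including tie handling", {
  ## hand example: positives (0.9, 0.6), negatives (0.7, 0.5) -> 3/4
  expect_equal(auc_score(c(0.9, 0.6, 0.7, 0.5),
                         c("GDM", "GDM", "control", "control")), 0.75)
  expect_equal(auc_score(c(1, 1, 1, 1), c("GDM", "GDM", "control", "control")),
               0.5)
  expect_equal(auc_score(c(5, 4, 3, 2), c("GDM", "GDM", "control", "control")),
               1.0)

  set.seed(12)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    scores <- round(stats::rnorm(n), sample(0:1, 1))  # force frequent ties
    pos <- stats::runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_score(scores, pos), oracle_auc(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  set.seed(6)
  scores <- stats::rnorm(40)
  labels <- rep(c("GDM", "control"), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                        levels = c("control", "GDM"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
})

test_that("confusion-derived metrics satisfy their identities", {
  d <- separable_data(n_per = 10, gap = 1.2, seed = 9)  # overlapping clouds
  model <- train_svm(d$x, d$labels, folds = 5, seed = 2)
  ev <- evaluate(model, d$x, d$labels)
  total <- ev$tp + ev$fp + ev$tn + ev$fn
  expect_equal(total, nrow(d$x))
  expect_equal(ev$accuracy, (ev$tp + ev$tn) / total)
  expect_equal(ev$sensitivity, ev$tp / (ev$tp + ev$fn))
  expect_equal(ev$specificity, ev$tn / (ev$tn + ev$fp))
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))

  expect_error(evaluate(model, d$x[, 1:5], d$labels), "feature alignment")
})

test_that("stability resampling is degenerate at frac = 1 and all-normal models", {
  d <- separable_data(seed = 4)
  model <- train_svm(d$x, d$labels, folds = 5, seed = 1)
  normals <- d$x[d$labels == "control", ]
  ## a separable model never calls the training normals GDM
  stab <- stability_resample(model, normals, frac = 0.5, reps = 100, seed = 8)
  expect_true(all(stab$counts == 0))
  expect_equal(stab$mode, 0)
  ## frac = 1: every replicate is the same draw
  stab1 <- stability_resample(model, normals, frac = 1, reps = 20, seed = 8)
  expect_equal(length(unique(stab1$counts)), 1)
})

test_that("covariate comparison flags perfect confounds and degenerate groups", {
  set.seed(10)
  d <- separable_data(seed = 11)
  model <- train_svm(d$x, d$labels, folds = 5, seed = 1)
  score <- gdmdiag:::decision_scores(model, d$x)
  pred <- ifelse(score > 0, "GDM", "control")
  covs <- data.frame(confound = score, noise = stats::rnorm(length(score)))
  cmp <- compare_covariates(pred, covs)
  expect_lt(cmp$p[cmp$covariate == "confound"], 1e-6)
  expect_gt(cmp$p[cmp$covariate == "noise"], 0.001)

  cmp2 <- compare_covariates(rep("control", 10),
                             data.frame(age = stats::rnorm(10)))
  expect_false(cmp2$computable)
  expect_true(is.na(cmp2$p))
})

test_that("covariate shifts in the generator propagate to predicted groups", {
  cfg <- synth_config(seed = 5, age_shift = 3, n_cases_external = 60,
                      n_controls_external = 120, n_genes = 300,
                      n_deg_up_case = 60, n_deg_up_control = 30,
                      n_drivers = 10, n_hub_drivers = 5,
                      n_network_genes = 150)
  sim <- generate_cohort(cfg)
  hubs <- sim$truth$hub_genes
  feats <- t(sim$expr$values[hubs, ])
  labs <- sim$expr$samples$condition
  model <- train_svm(feats, labs, folds = 10, seed = 2)
  fx <- t(sim$external$values[hubs, ])
  pred <- predict(model, fx)
  cmp <- compare_covariates(pred, sim$external$samples[, "age", drop = FALSE])
  expect_gt(cmp$mean_pred_gdm, cmp$mean_pred_normal)
})
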