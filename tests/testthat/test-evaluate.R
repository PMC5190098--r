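test_that("the printed metric corner cases hold exactly", {
  m <- function(np, nn, mp, fp) compute_metrics(confusion_counts(np, nn, mp, fp))
  expect_equal(m(10, 20, 0, 5)$sn, 1)          # no true site missed
  expect_equal(m(10, 20, 10, 5)$sn, 0)         # every true site missed
  expect_equal(m(10, 20, 3, 0)$sp, 1)          # no non-site mispredicted
  expect_equal(m(10, 20, 3, 20)$sp, 0)         # every non-site mispredicted
  perfect <- m(50, 50, 0, 0)
  expect_equal(perfect$acc, 1); expect_equal(perfect$mcc, 1)
  worst <- m(50, 50, 50, 50)
  expect_equal(worst$acc, 0); expect_equal(worst$mcc, -1)
  random <- m(200, 300, 100, 150)              # half of each class wrong
  expect_equal(random$acc, 0.5); expect_equal(random$mcc, 0)
})

test_that("the intuitive MCC equals the standard Matthews formula", {
  withr::with_seed(1234, {
    checked <- 0
    while (checked < 1000) {
      np <- sample(1:50, 1); nn <- sample(1:50, 1)
      mp <- sample(0:np, 1); fp <- sample(0:nn, 1)
      ref <- oracle_mcc(np, nn, mp, fp)
      if (!is.finite(ref)) next  # all-one-class predictions: no defined MCC
      got <- compute_metrics(confusion_counts(np, nn, mp, fp))$mcc
      expect_equal(got, ref, tolerance = 1e-12)
      checked <- checked + 1
    }
  })
})

test_that("MCC is 0 with a warning when all predictions fall in one class", {
  expect_warning(rep <- compute_metrics(confusion_counts(10, 20, 10, 0)),
                 "denominator")
  expect_equal(rep$mcc, 0)
})

test_that("invalid confusion counts are rejected", {
  expect_error(confusion_counts(0, 20, 0, 0), ">= 1")
  expect_error(confusion_counts(10, 0, 0, 0), ">= 1")
  expect_error(confusion_counts(10, 20, 11, 0), "exceed")
  expect_error(confusion_counts(10, 20, 0, 21), "exceed")
})

test_that("ROC endpoints and AUC behave on degenerate score patterns", {
  labels <- c(1, 1, 0, 0)
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), labels)
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(rep(0.5, 4), labels)
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "both classes")
  # curve runs from (0,0) to (1,1)
  expect_equal(unlist(perfect$points[1, c("fpr", "tpr")], use.names = FALSE),
               c(0, 0))
  expect_equal(unlist(perfect$points[nrow(perfect$points), c("fpr", "tpr")],
                      use.names = FALSE), c(1, 1))
})

test_that("trapezoidal AUC equals the concordant-pair statistic", {
  withr::with_seed(88, {
    for (rep in 1:10) {
      labels <- c(rep(1, 8), rep(0, 12))
      scores <- round(runif(20), 1)  # coarse grid forces ties
      if (length(unique(labels)) < 2) next
      expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(89, {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.4)
    labels[1] <- 1; labels[2] <- 0
    base <- roc_curve(scores, labels)$auc
    expect_equal(roc_curve(exp(3 * scores), labels)$auc, base)
    expect_equal(roc_curve(rank(scores), labels)$auc, base)
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(90, {
    scores <- c(runif(15, 0.3, 1), runif(25, 0, 0.7))
    labels <- c(rep(1, 15), rep(0, 25))
    ours <- roc_curve(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("strict jackknife matches a hand-enumerated leave-one-out run", {
  withr::with_seed(303, {
    ds <- make_bm(rand_windows(3, 2), rand_windows(3, 2), xi = 2)
  })
  cfg <- forest_config(n_trees = 25, seed = 6)
  rep <- jackknife(ds, cfg, protocol = "strict", threshold = 0.5)

  # oracle: enumerate the folds manually, refitting everything per fold
  windows <- c(ds$positives$window, ds$negatives$window)
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- numeric(6)
  for (i in 1:6) {
    tr_pos <- windows[setdiff(1:3, i)]
    tr_neg <- windows[setdiff(4:6, i)]
    sub <- make_bm(tr_pos, tr_neg, xi = 2)
    model <- fit_model(sub)
    enc <- encode_dataset(sub, model)
    forest <- train_forest(enc$features, enc$labels, cfg)
    scores[i] <- predict_scores(forest, encode(windows[i], model))
  }
  expect_equal(rep$scores, scores)
  expect_equal(rep$counts$miss_pos, sum(scores[1:3] < 0.5))
  expect_equal(rep$counts$false_pos, sum(scores[4:6] >= 0.5))
})

test_that("strict jackknife separates a strongly coupled synthetic benchmark", {
  spec <- generator_spec(n_proteins = 40, length_range = c(100, 140),
                         site_density = 0.5, coupling_strength = 1,
                         concentration = 0.3, seed = 11)
  ds <- generate_benchmark(spec)$dataset
  rep <- jackknife(ds, forest_config(seed = 5), protocol = "strict")
  expect_gte(rep$acc, 0.95)
  expect_gte(rep$auc, 0.98)
})

test_that("jackknife is deterministic for a fixed seed and dataset", {
  withr::with_seed(404, {
    ds <- make_bm(rand_windows(6, 2), rand_windows(8, 2), xi = 2)
  })
  cfg <- forest_config(n_trees = 40, seed = 3)
  r1 <- jackknife(ds, cfg, protocol = "strict")
  r2 <- jackknife(ds, cfg, protocol = "strict")
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$mcc, r2$mcc)
})

test_that("jackknife refuses subsets that are too small", {
  withr::with_seed(405, {
    ds <- make_bm(rand_windows(1, 2), rand_windows(5, 2), xi = 2)
  })
  expect_error(jackknife(ds, forest_config()), "at least 2")
})

test_that("stratified folds partition the samples with balanced label ratios", {
  folds <- hydroxysite:::stratified_folds(npos = 21, nneg = 79, k = 5, seed = 2)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), 1:100)          # every sample exactly once
  expect_equal(sum(lengths(folds)), 100)
  pos_per_fold <- vapply(folds, function(f) sum(f <= 21), numeric(1))
  expect_true(all(abs(pos_per_fold - 21 / 5) <= 1))  # within one sample
})

test_that("k-fold with k equal to the dataset size reproduces the jackknife", {
  withr::with_seed(505, {
    ds <- make_bm(rand_windows(5, 2), rand_windows(7, 2), xi = 2)
  })
  cfg <- forest_config(n_trees = 30, seed = 9)
  # random tiny windows carry no real signal; degenerate-MCC warnings are
  # expected and irrelevant to the fold-equivalence property
  jk <- suppressWarnings(jackknife(ds, cfg, protocol = "strict"))
  kf <- suppressWarnings(kfold(ds, k = 12, forest_config = cfg,
                               protocol = "strict"))
  expect_identical(kf$scores, jk$scores)
  expect_identical(kf$acc, jk$acc)
  expect_error(kfold(ds, k = 13, forest_config = cfg), "\\[2, 12\\]")
  expect_error(kfold(ds, k = 1, forest_config = cfg), "\\[2, 12\\]")
})

test_that("every sample is tested exactly once in k-fold evaluation", {
  spec <- generator_spec(xi = 3, n_proteins = 10, length_range = c(60, 90),
                         site_density = 0.4, seed = 21)
  ds <- generate_benchmark(spec)$dataset
  rep <- kfold(ds, 5, forest_config(n_trees = 40, seed = 2),
               protocol = "paper_style", seed = 3)
  expect_false(anyNA(rep$scores))
  expect_length(rep$scores, nrow(ds$positives) + nrow(ds$negatives))
})

test_that("window-size selection sweeps xi and reports per-xi metrics", {
  spec <- generator_spec(xi = 3, n_proteins = 10, length_range = c(60, 90),
                         site_density = 0.5, coupling_strength = 1,
                         concentration = 0.3, seed = 101)
  gen <- generate_proteins(spec)

  one <- select_window_size(gen$proteins, "P", 2,
                            forest_config(n_trees = 40, seed = 1),
                            method = "kfold", k = 3)
  expect_equal(nrow(one), 1)
  expect_equal(one$xi, 2)

  # window lengths in the per-xi datasets are 2*xi+1
  for (xi in c(1, 3)) {
    ds <- build_benchmark(gen$proteins, "P", xi)
    expect_true(all(nchar(c(ds$positives$window, ds$negatives$window)) ==
                      2 * xi + 1))
  }
})

test_that("accuracy at the generating radius beats a too-narrow window", {
  # coupling confined to +/-3 of the center: xi = 3 sees all of it, xi = 1
  # only the innermost flanks
  accs <- vapply(1:5, function(s) {
    spec <- generator_spec(xi = 3, n_proteins = 25, length_range = c(60, 90),
                           site_density = 0.5, coupling_strength = 1,
                           concentration = 0.3, seed = 100 + s)
    gen <- generate_proteins(spec)
    tab <- select_window_size(gen$proteins, "P", c(1, 3),
                              forest_config(n_trees = 60, seed = 1),
                              protocol = "strict", method = "kfold", k = 3,
                              seed = 1)
    tab$acc
  }, numeric(2))
  expect_gte(mean(accs[2, ]), mean(accs[1, ]))
})
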