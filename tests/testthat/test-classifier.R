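test_that("a separable two-cluster dataset is fit perfectly", {
  ds <- separable_dataset(40, seed = 41)
  bundle <- train_model(ds, train_config("linear", scheme = "AAC", seed = 1),
                        threshold = 0)
  xy <- list(seq = c(ds$positives$seq, ds$negatives$seq),
             y = rep(c(1, 0), each = 40))
  sc <- score_peptides(bundle, xy$seq)
  m <- compute_metrics(confusion_counts(sc, xy$y, 0))
  expect_equal(unname(m["Acc"]), 100)
})

test_that("scores are deterministic and orientation is positive-up", {
  ds <- separable_dataset(25, seed = 42)
  cfg <- train_config("rbf", scheme = "DPC", seed = 3)
  b1 <- train_model(ds, cfg, threshold = 0)
  b2 <- train_model(ds, cfg, threshold = 0)
  probe <- c(strrep("AD", 6), strrep("KL", 6))
  expect_identical(score_peptides(b1, probe), score_peptides(b2, probe))
  sc <- score_peptides(b1, probe)
  expect_gt(sc[1], sc[2])   # composition-positive peptide scores higher
})

test_that("training refuses degenerate datasets", {
  ds <- separable_dataset(10, seed = 43)
  ds$negatives <- ds$negatives[0, ]
  expect_error(train_model(ds, train_config()), "single-label")
})

test_that("permuted labels yield near-zero cross-validated MCC", {
  ds <- separable_dataset(60, seed = 44)
  pool <- c(ds$positives$seq, ds$negatives$seq)
  perm <- withr::with_seed(5, sample(pool))
  null_ds <- build_one_vs_rest(
    list(IgE = peptide_set(perm[1:60], label = "IgE"),
         nonBCE = peptide_set(perm[61:120], label = "nonBCE")), "IgE")
  cv <- cross_validate(null_ds, train_config("linear", scheme = "AAC"),
                       folds = 5, seed = 6)
  expect_lt(abs(cv$best$metrics$MCC), 0.45)   # small-n null fluctuation
  expect_lt(cv$auc, 0.75)
})

test_that("the AAP scale is fitted inside the training data only", {
  ds <- separable_dataset(30, seed = 45)
  bundle <- train_model(ds, train_config("linear", scheme = "AAP"),
                        threshold = 0)
  expect_s3_class(bundle$artifacts$aap_scale, "aap_scale")
  # removing peptides changes the fitted scale -> it is data-dependent,
  # so cross_validate must refit it per fold (leak check)
  sub <- ds
  sub$positives <- ds$positives[1:15, ]
  sub$negatives <- ds$negatives[1:15, ]
  b2 <- train_model(sub, train_config("linear", scheme = "AAP"),
                    threshold = 0)
  expect_false(identical(bundle$artifacts$aap_scale$scaled,
                         b2$artifacts$aap_scale$scaled))
  cv <- cross_validate(ds, train_config("linear", scheme = "AAP"),
                       folds = 3, seed = 1)
  expect_gt(cv$auc, 0.99)   # separable data stays separable under AAP
})

test_that("grid tuning ranks configurations by cross-validated MCC", {
  ds <- separable_dataset(25, seed = 46)
  lone <- list(train_config("linear", scheme = "AAC"))
  got <- tune_grid(ds, lone, folds = 3, seed = 1)
  expect_identical(got$best, lone[[1]])
  # a wildly overfit rbf width collapses test-fold scores; linear wins
  grid <- list(train_config("rbf", gamma = 1000, scheme = "AAC"),
               train_config("linear", scheme = "AAC"))
  got2 <- tune_grid(ds, grid, folds = 3, seed = 1)
  expect_equal(got2$best$kernel, "linear")
  expect_equal(nrow(got2$report), 2L)
  expect_true(all(c("MCC", "Acc", "AUC") %in% names(got2$report)))
  expect_error(tune_grid(ds, list(), folds = 3), "empty")
})

test_that("class assignment is thresholded, non-exclusive and monotone", {
  ds <- separable_dataset(30, seed = 47)
  cfg <- train_config("linear", scheme = "AAC", seed = 1)
  bundle_a <- train_model(ds, cfg, threshold = 0)
  bundle_b <- train_model(ds, cfg, threshold = 0)
  bundle_b$class_name <- "IgG"
  probe <- peptide_set(c(strrep("AE", 6), strrep("KM", 6)),
                       id = c("hit", "miss"))
  calls <- assign_classes(probe, list(bundle_a, bundle_b))
  # identical models above threshold -> both classes reported (tie rule)
  expect_setequal(calls$class[calls$id == "hit"], c("IgE", "IgG"))
  expect_false("miss" %in% calls$id)
  # raising a class threshold never adds that class
  lo <- assign_classes(probe, list(bundle_a), thresholds = c(IgE = -5))
  hi <- assign_classes(probe, list(bundle_a), thresholds = c(IgE = 5))
  expect_true(all(hi$id %in% lo$id))
  none <- assign_classes(probe, list(bundle_a), thresholds = c(IgE = 1e6))
  expect_equal(nrow(none), 0L)
})

test_that("bundles survive a save/load round trip", {
  ds <- separable_dataset(20, seed = 48)
  bundle <- train_model(ds, train_config("linear", scheme = "AAC"),
                        threshold = 0)
  f <- withr::local_tempfile(fileext = ".rds")
  save_bundle(bundle, f)
  back <- load_bundle(f)
  probe <- random_peptides(10, seed = 49)
  expect_identical(score_peptides(back, probe),
                   score_peptides(bundle, probe))
})
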