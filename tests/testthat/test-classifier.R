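test_that("a compositionally separated fixture trains to low OOB error", {
  fit <- train_layer(tiny_sep_table, 1, fast_config)
  expect_lte(fit$oob_error, 0.1)
  expect_identical(fit$provenance$mtry, floor(sqrt(102)))
})

test_that("label-permuted training data gives chance-level OOB error", {
  perm <- tiny_sep_table
  set.seed(77)
  perm$layer1 <- sample(perm$layer1)
  fit <- train_layer(perm, 1, fast_config)
  n <- nrow(perm)
  se <- sqrt(0.25 / n)
  expect_lt(abs(fit$oob_error - 0.5), 3 * se + 1e-12)
})

test_that("training and prediction are reproducible given the seed", {
  f1 <- train_layer(tiny_sep_table, 1, forest_config(n_trees = 60, seed = 9))
  f2 <- train_layer(tiny_sep_table, 1, forest_config(n_trees = 60, seed = 9))
  expect_identical(f1$oob_error, f2$oob_error)
  p1 <- predict(f1, tiny_null_table)
  p2 <- predict(f2, tiny_null_table)
  expect_identical(p1, p2)
})

test_that("layer 2 trains on strength-labelled enhancers only", {
  fit <- train_layer(tiny_sep_table, 2, fast_config)
  expect_identical(fit$provenance$n_train,
                   sum(tiny_sep_table$layer1 == "enhancer"))
  mixed <- tiny_sep_table
  mixed$layer2[which(mixed$layer1 == "enhancer")[1:5]] <- "unknown"
  expect_warning(fit2 <- train_layer(mixed, 2, fast_config), "unknown strength")
  expect_identical(fit2$provenance$n_train, fit$provenance$n_train - 5L)
})

test_that("single-class input and a one-tree forest behave as specified", {
  sub <- tiny_sep_table[tiny_sep_table$layer1 == "enhancer", ]
  expect_error(train_layer(sub, 1, fast_config), "single class")
  one <- train_layer(tiny_sep_table, 1, forest_config(n_trees = 1, seed = 2))
  expect_s3_class(one, "fitted_layer")
  expect_true(is.na(one$oob_error) || (one$oob_error >= 0 && one$oob_error <= 1))
})

test_that("the OOB curve is deterministic, bounded and stabilises with trees", {
  cur <- oob_curve(tiny_sep_table, 1, c(10, 50, 100), fast_config)
  expect_identical(nrow(cur), 3L)
  expect_true(all(cur$oob_error >= 0 & cur$oob_error <= 1))
  cur2 <- oob_curve(tiny_sep_table, 1, c(10, 50, 100), fast_config)
  expect_identical(cur, cur2)
  cur3 <- oob_curve(tiny_sep_table, 1, c(5, 100), fast_config)
  expect_lte(cur3$oob_error[2], cur3$oob_error[1] + 0.02)
})

test_that("successive halving returns a deterministic winner inside the space", {
  cfg <- forest_config(n_trees = 50, search_space = c(5, 500), seed = 4)
  won <- tune_n_estimators(tiny_sep_table, 1, cfg, n_candidates = 4)
  expect_true(won >= 5 && won <= 500)
  expect_identical(won, tune_n_estimators(tiny_sep_table, 1, cfg, n_candidates = 4))
  single <- forest_config(n_trees = 50, search_space = c(100, 100), seed = 4)
  expect_identical(tune_n_estimators(tiny_sep_table, 1, single), 100L)
})

test_that("cascade predictions apply layer 2 only to layer-1 positives", {
  model <- train_cascade(tiny_sep_table, fast_config)
  sep <- predict(model, tiny_sep_table, mode = "layers_separate")
  expect_named(sep, c("layer1", "layer2"))
  expect_true(all(sep$layer1$score >= 0 & sep$layer1$score <= 1))
  cas <- predict(model, tiny_sep_table, mode = "cascade")
  expect_true(all(cas$label %in% c("non_enhancer", "weak_enhancer", "strong_enhancer")))
  neg <- cas$layer1_score < 0.5
  expect_true(all(cas$label[neg] == "non_enhancer"))
  expect_true(all(is.na(cas$layer2_score[neg])))
  pos_strong <- !neg & cas$layer2_score >= 0.5
  expect_true(all(cas$label[pos_strong] == "strong_enhancer"))
})

test_that("models survive a save/load round trip with identical predictions", {
  model <- train_cascade(tiny_sep_table, fast_config)
  d <- withr::local_tempdir()
  save_model(model, d)
  expect_true(file.exists(file.path(d, "provenance.json")))
  back <- load_model(d)
  expect_identical(predict(back, tiny_null_table, mode = "cascade"),
                   predict(model, tiny_null_table, mode = "cascade"))
})

test_that("a feature-layout mismatch is reported with the offending block", {
  model <- train_cascade(tiny_sep_table, fast_config)
  x <- feature_matrix(tiny_sep_table)
  colnames(x)[95] <- "bogus"
  expect_error(predict(model, x), "aapiv")
})
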