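test_that("source-grouped split is disjoint, exhaustive and seeded", {
  # 20 sources x 5 samples: a 0.9 fraction gives exactly 90/10
  d <- data.frame(source_id = rep(1:20, each = 5), label_um = runif(100, 0, 8))
  sp <- split_dataset(d, 0.9, seed = 1)
  expect_equal(nrow(sp$train), 90)
  expect_equal(nrow(sp$test), 10)
  expect_length(intersect(sp$train$source_id, sp$test$source_id), 0)
  both <- rbind(sp$train, sp$test)
  expect_equal(sort(as.numeric(rownames(both))), 1:100)
  expect_identical(split_dataset(d, 0.9, seed = 1), sp)
  expect_false(identical(split_dataset(d, 0.9, seed = 2)$test$source_id,
                         sp$test$source_id))
  expect_error(split_dataset(data.frame(source_id = rep(1, 10)), 0.9),
               "single source")
  expect_error(split_dataset(d, 1.2), "train_fraction")
})

test_that("test resampling matches the training label distribution", {
  set.seed(5)
  train <- data.frame(label_um = rbeta(2000, 2, 5) * 8)
  test <- data.frame(label_um = runif(400, 0, 8))
  rs <- resample_test_to_train(train, test, n_bins = 20, seed = 3)
  expect_equal(nrow(rs), 400)
  expect_true(all(rs$label_um %in% test$label_um))
  expect_identical(resample_test_to_train(train, test, n_bins = 20, seed = 3), rs)
  # chi-square goodness of fit of resampled labels against train frequencies
  edges <- seq(0, 8, length.out = 21)
  p_tr <- tabulate(cut(train$label_um, edges, labels = FALSE), 20) / 2000
  pvals <- vapply(1:5, function(s) {
    r <- resample_test_to_train(train, test, n_bins = 20, seed = s)
    cnt <- tabulate(cut(r$label_um, edges, labels = FALSE), 20)
    keep <- p_tr > 0
    suppressWarnings(chisq.test(cnt[keep], p = p_tr[keep] / sum(p_tr[keep]))$p.value)
  }, numeric(1))
  expect_gt(sum(pvals > 0.01), 3)

  # n_bins = 1 reduces to a plain bootstrap of the test set
  b <- resample_test_to_train(train, test, n_bins = 1, seed = 9)
  expect_equal(nrow(b), 400)
  expect_true(all(b$label_um %in% test$label_um))

  # a populated train bin with no test members is skipped with a warning
  test2 <- data.frame(label_um = runif(100, 4, 8))
  expect_warning(resample_test_to_train(train, test2, n_bins = 20, seed = 1),
                 "no test members")
})

test_that("the regressor closes the loop on noiseless cylinder projections", {
  cfg0 <- clean_config(seed = 5)
  d <- generate_transect_dataset(cfg0, 600, augment = FALSE, empty_fraction = 0)
  sp <- split_dataset(d, 0.9, seed = 2)
  m <- train_estimator(sp$train, list(seed = 1))
  rep <- evaluate_estimator(m, sp$test)
  expect_lt(rep$rmse_um, 0.2)
  expect_gt(rep$r_squared, 0.99)
  # monotone response over a radius sweep
  sweep_r <- seq(0.5, 7, by = 0.25)
  ds <- generate_transect_dataset(cfg0, length(sweep_r), labels_um = sweep_r,
                                  augment = FALSE, center_jitter = FALSE)
  expect_gt(cor(predict(m, ds), sweep_r, method = "spearman"), 0.99)
  # predictions are clamped non-negative
  expect_true(all(predict(m, ds) >= 0))
})

test_that("label noise sets the achievable error floor", {
  cfg <- quick_config(seed = 11)
  d <- generate_transect_dataset(cfg, 2000, label_noise_sd_um = 0.3, seed = 11)
  sp <- split_dataset(d, 0.9, seed = 3)
  m <- train_estimator(sp$train, list(seed = 1))
  expect_gte(evaluate_estimator(m, sp$test)$rmse_um, 0.25)
})

test_that("training is deterministic and order-invariant", {
  d <- generate_transect_dataset(quick_config(seed = 13), 600)
  sp <- split_dataset(d, 0.9, seed = 1)
  m1 <- train_estimator(sp$train, list(seed = 1))
  m2 <- train_estimator(sp$train[sample(nrow(sp$train)), ], list(seed = 1))
  e1 <- evaluate_estimator(m1, sp$test)
  e2 <- evaluate_estimator(m2, sp$test)
  expect_equal(e1$rmse_um, e2$rmse_um, tolerance = 1e-8)
  expect_error(train_estimator(sp$train[1:10, ]), "at least 50")
  bad <- sp$train
  bad$p001[1] <- NA
  expect_error(train_estimator(bad), "non-finite")
})

test_that("gradient-boosted variant also learns the mapping", {
  cfg <- quick_config(seed = 17)
  d <- generate_transect_dataset(cfg, 1200)
  sp <- split_dataset(d, 0.9, seed = 4)
  m <- train_estimator(sp$train, list(method = "xgb", seed = 1, nrounds = 150))
  expect_lt(evaluate_estimator(m, sp$test)$rmse_um, 0.6)
})

test_that("evaluation metrics follow their definitions", {
  # perfect predictor and mean-only predictor on a 5-sample fixture
  cfg0 <- clean_config(seed = 5)
  labs <- c(1, 2, 3, 4, 5)
  d <- generate_transect_dataset(cfg0, 5, labels_um = labs, augment = FALSE,
                                 center_jitter = FALSE)
  fake <- structure(list(method = "lm",
                         fit = c(`(Intercept)` = mean(labs),
                                 setNames(rep(0, 8),
                                          colnames(transect_features(d)))),
                         feature_names = colnames(transect_features(d)),
                         config = list(pixel_size_um = 2), n_train = 5),
                    class = "radius_estimator")
  rep_mean <- evaluate_estimator(fake, d)
  # mean-only predictor: R^2 = 0, rmse = population sd of labels
  expect_equal(rep_mean$r_squared, 0)
  expect_equal(rep_mean$rmse_um, sqrt(mean((labs - mean(labs))^2)))

  # hand-computed on the same fixture with predictions (1.5, 2, 2.5, 4.5, 5.5)
  pred <- c(1.5, 2, 2.5, 4.5, 5.5)
  rmse_hand <- sqrt(mean((pred - labs)^2))    # = sqrt(0.25+0+0.25+0.25+0.25)/5
  r2_hand <- 1 - sum((pred - labs)^2) / sum((labs - 3)^2)
  expect_equal(rmse_hand, sqrt(1 / 5))
  expect_equal(r2_hand, 1 - 1 / 10)

  # zero label variance flags undefined R^2
  d0 <- generate_transect_dataset(cfg0, 5, labels_um = rep(2, 5), augment = FALSE)
  expect_warning(r0 <- evaluate_estimator(fake, d0), "zero label variance")
  expect_true(is.na(r0$r_squared))
})

test_that("per-edge aggregation recovers radii and drops empty transects", {
  cfg <- quick_config(seed = 19)
  d <- generate_transect_dataset(cfg, 2000)
  sp <- split_dataset(d, 0.9, seed = 1)
  m <- train_estimator(sp$train, list(seed = 1))
  set.seed(23)
  radii <- runif(40, 1, 6)
  et <- simulate_edge_transects(cfg, radii, n_per_edge = 5, seed = 9)
  pr <- predict_network_radii(m, et)
  expect_equal(nrow(pr), 40)
  expect_lt(sqrt(mean((pr$radius_um - radii)^2)), 0.5)

  # edges whose transects are all empty background get radius 0
  et0 <- simulate_edge_transects(clean_config(seed = 5), rep(0, 3),
                                 n_per_edge = 4, seed = 2)
  pr0 <- predict_network_radii(m, et0)
  expect_equal(pr0$radius_um, rep(0, 3))
  expect_equal(pr0$n_used, rep(0, 3))

  # aggregation over constant predictions returns that constant
  expect_equal(predict_network_radii(m, et, aggregate = function(x) 4.2)$radius_um,
               rep(4.2, 40))
})
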