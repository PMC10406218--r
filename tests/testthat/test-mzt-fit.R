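# End-to-end model behaviour on small cohorts.

fit_small <- function(seed = 141, ...) {
  co <- separable_cohort(seed = seed)
  pairs <- split_train_test(enumerate_pairs(co$metadata), 0.8,
                            seed = seed + 1)
  fit <- mzt_fit(co$table, pairs = pairs, distance = "jaccard",
                 interval = "short",
                 ga = ga_config(population_size = 200,
                                max_generations = 300, seed = seed + 2),
                 ...)
  list(cohort = co, pairs = pairs, fit = fit)
}

test_that("the fitted model separates a separable cohort and improves on all features", {
  s <- fit_small()
  fit <- s$fit
  expect_equal(fit$auc_selected, 1)
  expect_gte(fit$auc_selected, fit$auc_all)
  expect_equal(fit$diagnostics$train_tmax$youden, 1)
  expect_gte(fit$diagnostics$test_tmax$youden, 0.9)
  # Youden identity holds in every reported diagnostic
  for (d in fit$diagnostics)
    expect_equal(d$youden, d$sensitivity + d$specificity - 1)
  # the optimal threshold interval brackets the reported point
  expect_gt(fit$tmax$threshold, fit$tmax$lower)
  expect_lt(fit$tmax$threshold, fit$tmax$upper)
})

test_that("summary, coef and fitted expose the model's tables", {
  s <- fit_small(seed = 151)
  fit <- s$fit
  sm <- summary(fit)$table
  expect_equal(nrow(sm), 4)  # train/test x T_max/LR=1
  expect_setequal(sm$data_set, c("training", "test"))
  expect_equal(sm$youden, sm$sensitivity + sm$specificity - 1)
  mask <- coef(fit)
  expect_equal(length(mask), ncol(s$cohort$table))
  expect_true(all(mask %in% 0:1))
  expect_equal(sum(mask), fit$n_selected)
  tr <- fitted(fit)
  expect_true(all(c("distance", "lr") %in% names(tr)))
})

test_that("predict reproduces the training LRs and classifies by the chosen threshold", {
  s <- fit_small(seed = 161)
  fit <- s$fit
  train <- s$pairs[s$pairs$interval == "short" &
                     s$pairs$split == "train", ]
  pred <- predict(fit, s$cohort$table, train)
  expect_equal(pred$lr, fit$train$lr)
  expect_equal(pred$decision,
               ifelse(pred$lr > fit$tmax$threshold, "Self", "MZT"))
  pred_unit <- predict(fit, s$cohort$table, train, threshold = "unit")
  expect_equal(pred_unit$decision,
               ifelse(pred_unit$lr > 1, "Self", "MZT"))
})

test_that("a fit without test pairs is flagged and covers training only", {
  co <- separable_cohort(n_twin_pairs = 4, n_features = 100, seed = 171)
  pairs <- enumerate_pairs(co$metadata)
  pairs$split <- "train"
  fit <- mzt_fit(co$table, pairs = pairs, distance = "jaccard",
                 interval = "short", mask = rep(1L, ncol(co$table)))
  expect_false(fit$has_test)
  expect_null(fit$test)
  expect_null(fit$diagnostics$test_tmax)
  expect_output(print(fit), "training set only")
})

test_that("a degenerate KDE group aborts with the group named", {
  co <- separable_cohort(n_twin_pairs = 2, n_features = 60, seed = 181)
  pairs <- split_train_test(enumerate_pairs(co$metadata), 0.8, seed = 182)
  # a mask of one ubiquitous shared-core feature makes every distance 0
  core <- which(co$truth$labels$label == "shared_core")[1]
  mask <- rep(0L, ncol(co$table))
  mask[core] <- 1L
  expect_error(mzt_fit(co$table, pairs = pairs, distance = "jaccard",
                       interval = "short", mask = mask),
               "zero variance in group Self/short")
})

test_that("the configuration sweep reports every cell and is deterministic", {
  co <- separable_cohort(n_twin_pairs = 5, n_features = 120, seed = 191)
  pairs <- split_train_test(enumerate_pairs(co$metadata), 0.8, seed = 192)
  groups <- paste0("OTU", (seq_len(ncol(co$table)) - 1) %/% 3 + 1)
  tabs <- list(ASV = co$table, OTU = aggregate_features(co$table, groups))
  ga <- ga_config(population_size = 40, max_generations = 15)
  sweep1 <- run_model_sweep(tabs, pairs, ga = ga, seed = 193)
  sweep2 <- run_model_sweep(tabs, pairs, ga = ga, seed = 193)
  expect_identical(sweep1, sweep2)
  expect_equal(nrow(sweep1), 2 * 3 * 2)
  expect_true(all(is.na(sweep1$error)))
  # feature selection never loses to the all-features baseline
  expect_true(all(sweep1$ga_best_auc >= sweep1$auc_all))
  # exactly one chosen configuration per interval
  expect_equal(sum(sweep1$chosen[sweep1$interval == "short"]), 1)
  expect_equal(sum(sweep1$chosen[sweep1$interval == "long"]), 1)
  # a single-cell sweep has a single row
  one <- run_model_sweep(tabs["ASV"], pairs, ga = ga,
                         distances = "jaccard", intervals = "short",
                         seed = 194)
  expect_equal(nrow(one), 1)
  expect_true(one$chosen)
})

test_that("a failing sweep cell is recorded without stopping the sweep", {
  co <- separable_cohort(n_twin_pairs = 3, n_features = 60, seed = 201)
  pairs <- split_train_test(enumerate_pairs(co$metadata), 0.8, seed = 202)
  # drop all long-interval training pairs to break those cells
  broken <- pairs[!(pairs$interval == "long" & pairs$split == "train"), ]
  sweep <- run_model_sweep(list(ASV = co$table), broken,
                           ga = ga_config(population_size = 20,
                                          max_generations = 5),
                           distances = "jaccard", seed = 203)
  long_row <- sweep[sweep$interval == "long", ]
  expect_false(is.na(long_row$error))
  short_row <- sweep[sweep$interval == "short", ]
  expect_true(is.na(short_row$error))
  expect_false(is.na(short_row$ga_best_auc))
})
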