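# A hand-built two-twin-pair toy: one feature differs only between twins
# (constant within each individual), one is ubiquitous, one is noise that
# separates nothing. The discriminative mask must reach AUC 1 by Jaccard.
toy_cohort <- function() {
  # samples: pair 1 (A1 A2 B1 B2), pair 2 (A1 A2 B1 B2)
  ids <- c("S1A1", "S1A2", "S1B1", "S1B2",
           "S2A1", "S2A2", "S2B1", "S2B2")
  disc <- c(1, 1, 0, 0, 0, 0, 1, 1)   # carried by 1A and 2B
  ubiq <- rep(1, 8)
  noise <- c(1, 0, 1, 0, 0, 1, 0, 1)  # toggles within individuals
  counts <- cbind(disc, ubiq, noise) * 5L
  tab <- feature_table(counts, ids, c("disc", "ubiq", "noise"))
  meta <- data.frame(
    sample_id = ids,
    twin_pair = rep(1:2, each = 4),
    individual = rep(rep(c("A", "B"), each = 2), 2),
    time_point = rep(1:2, 4),
    month_offset = rep(c(0, 1), 4), stringsAsFactors = FALSE)
  pairs <- enumerate_pairs(meta)
  list(table = tab, pairs = pairs)
}

test_that("fitness is the rank AUC of masked distances, with degenerate masks pinned", {
  toy <- toy_cohort()
  # only the ubiquitous feature: every Jaccard distance 0, total tie
  expect_equal(ga_fitness(c(0, 1, 0), toy$pairs, toy$table, "jaccard"), 0.5)
  # the all-zero mask carries no information
  expect_equal(ga_fitness(c(0, 0, 0), toy$pairs, toy$table, "jaccard"), 0)
  # the planted discriminative feature separates Self from MZT perfectly
  expect_equal(ga_fitness(c(1, 0, 0), toy$pairs, toy$table, "jaccard"), 1)
  # by enumeration: with that mask all Self distances are 0, all MZT are 1
  d <- pair_distances(toy$table, toy$pairs, "jaccard", c(1, 0, 0))
  expect_true(all(d[toy$pairs$relationship == "Self"] == 0))
  expect_true(all(d[toy$pairs$relationship == "MZT"] == 1))
  only_self <- toy$pairs[toy$pairs$relationship == "Self", ]
  expect_error(ga_fitness(c(1, 0, 0), only_self, toy$table, "jaccard"),
               "both Self and MZT")
})

test_that("parent selection eliminates the low tail and samples proportionally to fitness", {
  set.seed(81)
  # 10 individuals, 10% elimination: exactly the single worst is barred
  fit <- c(0.30, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 0.90, 0.95)
  sel <- ga_select_parents(fit, 5000, 0.10)
  expect_false(1 %in% sel)
  expect_equal(sort(unique(sel)), 2:10)
  # survivors [1.0, 0.0]: the zero-fitness survivor is never drawn
  sel2 <- ga_select_parents(c(1.0, 0.0), 200, 0)
  expect_true(all(sel2 == 1))
  # equal fitness: both survivors drawn about equally often
  sel3 <- ga_select_parents(c(0.1, 0.5, 0.5), 4000, 1 / 3)
  expect_false(1 %in% sel3)
  expect_lt(abs(mean(sel3 == 2) - 0.5), 0.05)
  # all-zero survivors fall back to uniform sampling
  sel4 <- ga_select_parents(c(0, 0, 0), 3000, 1 / 3)
  expect_setequal(unique(sel4), 2:3)
})

test_that("uniform crossover inherits each gene from either parent with probability 1/2", {
  p <- rep(c(0L, 1L), 10)
  expect_equal(ga_crossover(p, p), p)
  set.seed(82)
  father <- rep(1L, 10000)
  mother <- rep(0L, 10000)
  child <- ga_crossover(father, mother)
  expect_gt(mean(child), 0.48)
  expect_lt(mean(child), 0.52)
  set.seed(99); a <- ga_crossover(father, mother)
  set.seed(99); b <- ga_crossover(father, mother)
  expect_identical(a, b)
  expect_error(ga_crossover(c(1, 0), c(1, 0, 1)), "length")
})

test_that("mutation flips genes independently at the given rate", {
  m <- rbinom(50, 1, 0.5)
  expect_equal(ga_mutate(m, 0), m)
  expect_equal(ga_mutate(m, 1), 1 - m)
  set.seed(83)
  big <- rep(0L, 10000)
  flips <- sum(ga_mutate(big, 0.01))
  expect_gte(flips, 60)   # binomial(10000, 0.01) 99.99% band
  expect_lte(flips, 140)
})

test_that("the GA recovers a perfect mask on a separable cohort", {
  co <- separable_cohort(seed = 91)
  pairs <- split_train_test(enumerate_pairs(co$metadata), 0.8, seed = 92)
  train <- pairs[pairs$interval == "short" & pairs$split == "train", ]
  # the ground-truth discriminative mask separates perfectly by construction
  planted <- as.integer(co$truth$labels$label == "discriminative")
  expect_equal(ga_fitness(planted, train, co$table, "jaccard"), 1)
  res <- run_ga(ga_config(population_size = 100, max_generations = 300,
                          seed = 93), train, co$table, "jaccard")
  expect_equal(res$terminated_by, "target_fitness")
  expect_equal(res$best_fitness, 1)
  expect_gte(res$best_fitness,
             ga_fitness(rep(1L, ncol(co$table)), train, co$table,
                        "jaccard"))
})

test_that("GA bookkeeping: best-ever fitness, trajectory, and degenerate limits", {
  toy <- toy_cohort()
  cfg0 <- ga_config(population_size = 20, max_generations = 0,
                    target_fitness = 2, seed = 7)
  r0 <- run_ga(cfg0, toy$pairs, toy$table, "jaccard")
  expect_equal(r0$generation_reached, 0)
  expect_equal(length(r0$trajectory), 1)
  expect_equal(r0$terminated_by, "max_generations")
  # target 0 is met by the initial population immediately
  rt <- run_ga(ga_config(population_size = 20, max_generations = 100,
                         target_fitness = 0, seed = 7),
               toy$pairs, toy$table, "jaccard")
  expect_equal(rt$generation_reached, 0)
  expect_equal(rt$terminated_by, "target_fitness")
  # determinism and best-ever consistency on a run that must iterate
  co <- separable_cohort(n_twin_pairs = 4, n_features = 80, seed = 94)
  pairs <- split_train_test(enumerate_pairs(co$metadata), 0.8, seed = 95)
  train <- pairs[pairs$interval == "short" & pairs$split == "train", ]
  cfg <- ga_config(population_size = 40, max_generations = 25,
                   target_fitness = 1.01, seed = 96)
  a <- run_ga(cfg, train, co$table, "jaccard")
  b <- run_ga(cfg, train, co$table, "jaccard")
  expect_identical(a, b)
  expect_equal(a$best_fitness, max(a$trajectory))
  expect_equal(length(a$trajectory), a$generation_reached + 1)
  # best-ever is non-decreasing: recompute from the trajectory
  expect_true(all(diff(cummax(a$trajectory)) >= 0))
})

test_that("the GA-selected mask is enriched for planted discriminative features", {
  co <- separable_cohort(seed = 101)
  pairs <- split_train_test(enumerate_pairs(co$metadata), 0.8, seed = 102)
  train <- pairs[pairs$interval == "short" & pairs$split == "train", ]
  res <- run_ga(ga_config(population_size = 200, max_generations = 300,
                          seed = 103), train, co$table, "jaccard")
  planted <- co$truth$labels$label == "discriminative"
  obs <- sum(res$best_mask[planted])
  set.seed(104)
  null <- replicate(2000, sum(sample(res$best_mask)[planted]))
  p_perm <- (sum(null >= obs) + 1) / 2001
  expect_lt(p_perm, 0.01)
})

test_that("GA results serialize to JSON with the mask as a 0/1 string", {
  toy <- toy_cohort()
  res <- run_ga(ga_config(population_size = 10, max_generations = 2,
                          seed = 3), toy$pairs, toy$table, "jaccard")
  path <- withr::local_tempfile(fileext = ".json")
  write_ga_result(res, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$best_mask,
               paste(res$best_mask, collapse = ""))
  expect_equal(parsed$best_fitness, res$best_fitness)
  expect_equal(parsed$trajectory, res$trajectory)
})
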