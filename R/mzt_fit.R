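#' Fit a twin-identification model
#'
#' Fits the full evidence model for one time-interval class: an optional
#' genetic-algorithm feature-selection stage maximizing the rank-AUC
#' separation of Self and MZT training pairs, followed by Gaussian kernel
#' density estimation of the masked distance distribution in each group
#' and likelihood-ratio evaluation with two decision thresholds — the
#' Youden-optimal threshold `T_max` found on the training set, and the
#' neutral-evidence threshold `LR = 1`.
#'
#' @param table A [feature_table] of counts.
#' @param meta Sample metadata (`sample_id`, `twin_pair`, `individual`,
#'   `time_point`, `month_offset`). Ignored when `pairs` is supplied.
#' @param pairs Optional pair data frame carrying `relationship`,
#'   `interval` and `split` columns; when `NULL`, pairs are enumerated
#'   from `meta` and split with [split_train_test()].
#' @param distance Distance kind: `"jaccard"`, `"braycurtis"` or
#'   `"hellinger"`.
#' @param interval `"short"` or `"long"`; the model is fit within one
#'   interval class.
#' @param mask Optional fixed binary feature mask; when supplied the GA is
#'   skipped.
#' @param ga A [ga_config()] controlling feature selection, or `NULL` to
#'   use all features.
#' @param split_ratio Training fraction when pairs are enumerated here.
#' @param seed Seed for the split and the GA when their configs carry none.
#' @return An object of class `mzt_fit` with components including `mask`
#'   (selected features), `auc_all` and `auc_selected` (training AUC before
#'   and after selection), `kde_self`/`kde_mzt`, `train`/`test` pair tables
#'   with distances and LRs, `tmax` (Youden-optimal threshold with its
#'   optimal interval), and `diagnostics` (training and test results at
#'   both thresholds). Supports `print()`, `summary()`, `coef()`,
#'   `fitted()`, `predict()` and `plot()`.
#' @seealso [run_model_sweep()] to compare distance/table configurations.
#' @export
mzt_fit <- function(table, meta = NULL, pairs = NULL,
                    distance = c("jaccard", "braycurtis", "hellinger"),
                    interval = c("short", "long"), mask = NULL, ga = NULL,
                    split_ratio = 0.8, seed = NULL) {
  distance <- match.arg(distance)
  interval <- match.arg(interval)
  stopifnot(inherits(table, "feature_table"))
  if (is.null(pairs)) {
    if (is.null(meta)) stop("either 'meta' or 'pairs' must be supplied")
    pairs <- split_train_test(enumerate_pairs(meta), split_ratio, seed)
  }
  if (is.null(pairs$split)) stop("pairs carry no train/test split")
  pairs <- pairs[pairs$interval == interval, , drop = FALSE]
  if (!nrow(pairs)) stop("no pairs in interval class '", interval, "'")
  train <- pairs[pairs$split == "train", , drop = FALSE]
  test <- pairs[pairs$split == "test", , drop = FALSE]

  all_mask <- rep(1L, ncol(table))
  auc_all <- ga_fitness(all_mask, train, table, distance)
  ga_result <- NULL
  if (is.null(mask)) {
    if (!is.null(ga)) {
      if (is.null(ga$seed) && !is.null(seed)) ga$seed <- seed
      ga_result <- run_ga(ga, train, table, distance)
      mask <- ga_result$best_mask
    } else {
      mask <- all_mask
    }
  }
  if (length(mask) != ncol(table))
    stop("mask length does not match the feature table")
  auc_selected <- ga_fitness(mask, train, table, distance)

  train$distance <- pair_distances(table, train, distance, mask)
  is_self <- train$relationship == "Self"
  kde_self <- kde_model(train$distance[is_self],
                        group = paste0("Self/", interval))
  kde_mzt <- kde_model(train$distance[!is_self],
                       group = paste0("MZT/", interval))
  train$lr <- likelihood_ratio(kde_self, kde_mzt, train$distance)

  tmax <- best_youden_threshold(train$lr[is_self], train$lr[!is_self])
  diagnostics <- list(
    train_tmax = evaluate_decision(train, tmax$threshold),
    train_unit = evaluate_decision(train, 1))

  has_test <- nrow(test) > 0
  if (has_test) {
    test$distance <- pair_distances(table, test, distance, mask)
    test$lr <- likelihood_ratio(kde_self, kde_mzt, test$distance)
    diagnostics$test_tmax <- evaluate_decision(test, tmax$threshold)
    diagnostics$test_unit <- evaluate_decision(test, 1)
  }

  structure(list(distance = distance, interval = interval,
                 mask = stats::setNames(as.integer(mask), colnames(table)),
                 n_selected = sum(mask), n_features = ncol(table),
                 auc_all = auc_all, auc_selected = auc_selected,
                 ga = ga_result, kde_self = kde_self, kde_mzt = kde_mzt,
                 tmax = tmax, train = train,
                 test = if (has_test) test else NULL,
                 has_test = has_test, diagnostics = diagnostics),
            class = "mzt_fit")
}

#' @export
print.mzt_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Twin-identification model (%s distance, %s interval)\n",
    "  features: %d of %d selected%s\n",
    "  training AUC: %.4f (all features %.4f)\n",
    "  T_max = %.4g (optimal in [%.4g, %.4g]); training YI %.4f\n"),
    x$distance, x$interval, x$n_selected, x$n_features,
    if (is.null(x$ga)) "" else " by genetic algorithm",
    x$auc_selected, x$auc_all,
    x$tmax$threshold, x$tmax$lower, x$tmax$upper,
    x$diagnostics$train_tmax$youden))
  if (!x$has_test)
    cat("  no test pairs: diagnostics cover the training set only\n")
  invisible(x)
}

#' @export
summary.mzt_fit <- function(object, ...) {
  d <- object$diagnostics
  rows <- list(
    list("training", "T_max", d$train_tmax),
    list("training", "LR=1", d$train_unit))
  if (object$has_test)
    rows <- c(rows, list(list("test", "T_max", d$test_tmax),
                         list("test", "LR=1", d$test_unit)))
  out <- do.call(rbind, lapply(rows, function(r) {
    diag <- r[[3]]
    data.frame(data_set = r[[1]], threshold_kind = r[[2]],
               threshold = diag$threshold,
               sensitivity = diag$sensitivity,
               specificity = diag$specificity, youden = diag$youden,
               misjudged = if (length(diag$misjudged))
                 paste(diag$misjudged, collapse = "; ") else "none",
               stringsAsFactors = FALSE)
  }))
  structure(list(fit = object, table = out), class = "summary.mzt_fit")
}

#' @export
print.summary.mzt_fit <- function(x, ...) {
  print(x$fit)
  cat("\nDiagnostics:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mzt_fit <- function(object, ...) object$mask

#' @export
fitted.mzt_fit <- function(object, ...) object$train

#' Predict likelihood ratios for new sample pairs
#'
#' Computes the fitted model's masked distance, likelihood ratio and
#' Self/MZT decision for each pair.
#'
#' @param object An [mzt_fit()] model.
#' @param table A [feature_table] with the same features as the training
#'   table.
#' @param pairs Data frame with `sample_a`, `sample_b` columns.
#' @param threshold `"tmax"` (the fitted Youden-optimal threshold) or
#'   `"unit"` (LR = 1).
#' @param ... Unused.
#' @return `pairs` with added `distance`, `lr` and `decision` columns.
#' @export
predict.mzt_fit <- function(object, table, pairs,
                            threshold = c("tmax", "unit"), ...) {
  threshold <- match.arg(threshold)
  thr <- if (threshold == "tmax") object$tmax$threshold else 1
  if (ncol(table) != object$n_features)
    stop("feature table does not match the fitted model")
  pairs$distance <- pair_distances(table, pairs, object$distance,
                                   object$mask)
  pairs$lr <- likelihood_ratio(object$kde_self, object$kde_mzt,
                               pairs$distance)
  pairs$decision <- ifelse(pairs$lr > thr, "Self", "MZT")
  pairs
}

#' Plot the fitted group densities
#'
#' Draws the Self and MZT kernel density curves over the masked distance
#' axis, with rugs of the training distances and the distance(s) at which
#' LR crosses the fitted `T_max` threshold omitted for clarity.
#'
#' @param x An [mzt_fit()] model.
#' @param n Grid resolution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mzt_fit <- function(x, n = 512, ...) {
  vals <- c(x$kde_self$values, x$kde_mzt$values)
  pad <- 3 * max(x$kde_self$h, x$kde_mzt$h)
  grid <- seq(min(vals) - pad, max(vals) + pad, length.out = n)
  fs <- kde_density(x$kde_self, grid)
  fm <- kde_density(x$kde_mzt, grid)
  graphics::plot(grid, fs, type = "l", col = "steelblue", lwd = 2,
                 xlab = sprintf("%s distance (%s interval)", x$distance,
                                x$interval),
                 ylab = "density", ylim = c(0, max(fs, fm)), ...)
  graphics::lines(grid, fm, col = "firebrick", lwd = 2)
  graphics::rug(x$kde_self$values, col = "steelblue")
  graphics::rug(x$kde_mzt$values, col = "firebrick", side = 3)
  graphics::legend("topright", legend = c("Self", "MZT"), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Sweep model configurations
#'
#' Runs the feature-selection stage for every combination of feature
#' table, distance kind and interval class, and reports the training AUC
#' with all features, the GA-selected best AUC and the number of selected
#' features for each cell. Within each interval the best configuration is
#' flagged (highest GA AUC, ties broken toward fewer selected features).
#' Failed cells are recorded with the error message and do not stop the
#' sweep.
#'
#' @param tables Named list of [feature_table]s on the same samples (e.g.
#'   an ASV-level table and an OTU-like aggregation).
#' @param pairs Pair data frame with `relationship`, `interval`, `split`.
#' @param ga A [ga_config()] template; each cell derives its own seed from
#'   `seed` so cells are independent but reproducible.
#' @param distances,intervals Configuration axes to sweep.
#' @param seed Base seed.
#' @return Data frame: `table`, `distance`, `interval`, `auc_all`,
#'   `ga_best_auc`, `n_selected`, `generations`, `chosen`, `error`.
#' @export
run_model_sweep <- function(tables, pairs, ga = ga_config_desk(),
                            distances = c("jaccard", "braycurtis",
                                          "hellinger"),
                            intervals = c("short", "long"),
                            seed = NULL) {
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_along(tables))
  grid <- expand.grid(table = names(tables), distance = distances,
                      interval = intervals, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    out <- data.frame(cell, auc_all = NA_real_, ga_best_auc = NA_real_,
                      n_selected = NA_integer_, generations = NA_integer_,
                      chosen = FALSE, error = NA_character_,
                      stringsAsFactors = FALSE)
    tryCatch({
      tab <- tables[[cell$table]]
      train <- pairs[pairs$interval == cell$interval &
                       pairs$split == "train", , drop = FALSE]
      cfg <- ga
      if (!is.null(seed)) cfg$seed <- seed + i
      out$auc_all <- ga_fitness(rep(1L, ncol(tab)), train, tab,
                                cell$distance)
      res <- run_ga(cfg, train, tab, cell$distance)
      out$ga_best_auc <- res$best_fitness
      out$n_selected <- sum(res$best_mask)
      out$generations <- res$generation_reached
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  for (iv in unique(res$interval)) {
    idx <- which(res$interval == iv & !is.na(res$ga_best_auc))
    if (!length(idx)) next
    best <- idx[order(-res$ga_best_auc[idx], res$n_selected[idx])][1L]
    res$chosen[best] <- TRUE
  }
  res
}
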