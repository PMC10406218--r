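#' Chao 1 richness estimator
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F_k` is the number of
#' features observed exactly `k` times. When there are no singletons
#' (`F1 = 0`) the estimate collapses to the observed richness, as happens
#' after rare-feature filtering guarantees a minimum count above 2.
#'
#' @param counts Non-negative count vector for one sample.
#' @return Chao 1 estimate (0 for an all-zero vector).
#' @examples
#' chao1(c(5, 3, 1, 1))  # 4 + 2*1/2 = 5
#' @export
chao1 <- function(counts) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  if (s_obs == 0L) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator. Features are split at
#' `rare_cutoff` into abundant (`count > rare_cutoff`) and rare sets;
#' with `N_rare` the total reads in rare features,
#' `C_ACE = 1 - F1 / N_rare` is the sample coverage and
#' `gamma^2 = max(S_rare / C_ACE * sum(k (k-1) F_k) /
#' (N_rare (N_rare - 1)) - 1, 0)` the coefficient of variation, giving
#' `ACE = S_abund + S_rare / C_ACE + F1 / C_ACE * gamma^2`.
#' When `F1 = 0` every term collapses and the estimate equals the observed
#' richness regardless of `C_ACE` and `gamma^2` — the behaviour seen on
#' tables whose rare features were filtered out.
#'
#' @param counts Non-negative count vector for one sample.
#' @param rare_cutoff Largest count still counted as rare (default 10).
#' @return ACE estimate (0 for an all-zero vector).
#' @export
ace <- function(counts, rare_cutoff = 10) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  if (s_obs == 0L) return(0)
  f1 <- sum(counts == 1)
  if (f1 == 0) return(s_obs)  # estimator collapses to observed richness
  rare <- counts[counts <= rare_cutoff]
  s_abund <- sum(counts > rare_cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0)
    stop("ACE undefined: all rare features are singletons")
  k <- seq_len(rare_cutoff)
  fk <- vapply(k, function(i) sum(rare == i), numeric(1))
  gamma2 <- max(s_rare / c_ace * sum(k * (k - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Shannon-Wiener diversity index
#'
#' `-sum(p_i log p_i)` over features with positive counts (natural log).
#'
#' @param counts Non-negative count vector for one sample.
#' @return Shannon index (>= 0; 0 for at most one positive feature).
#' @export
shannon <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Simpson index
#'
#' In the dominance convention used by mothur,
#' `D = sum(n_i (n_i - 1)) / (N (N - 1))`: the probability that two reads
#' drawn without replacement belong to the same feature. Higher values
#' mean lower diversity. [simpson_complement()] gives `1 - D`
#' (Gini-Simpson) for workflows that prefer the ascending convention.
#'
#' @param counts Non-negative count vector for one sample.
#' @return Simpson index in `[0, 1]`.
#' @examples
#' simpson(c(2, 2))  # (2 + 2) / (4 * 3) = 1/3
#' @export
simpson <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(if (n == 1) 1 else 0)
  sum(counts * (counts - 1)) / (n * (n - 1))
}

#' @rdname simpson
#' @export
simpson_complement <- function(counts) 1 - simpson(counts)

#' Alpha-diversity table
#'
#' Computes observed richness, Chao 1, ACE, Shannon and Simpson (dominance
#' form) for every sample of a feature table.
#'
#' @param table A [feature_table].
#' @param rare_cutoff Passed to [ace()].
#' @return Data frame: `sample_id`, `observed`, `chao1`, `ace`, `shannon`,
#'   `simpson`.
#' @export
alpha_diversity <- function(table, rare_cutoff = 10) {
  stopifnot(inherits(table, "feature_table"))
  x <- unclass(table)
  data.frame(
    sample_id = rownames(x),
    observed = apply(x, 1, function(v) sum(v > 0)),
    chao1 = apply(x, 1, chao1),
    ace = apply(x, 1, ace, rare_cutoff = rare_cutoff),
    shannon = apply(x, 1, shannon),
    simpson = apply(x, 1, simpson),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired comparison with a normality gate
#'
#' Compares two paired sets of per-individual values (e.g. an alpha index
#' at two time points). A Shapiro-Wilk test is run on the paired
#' differences; if its p-value exceeds `normality_alpha` a paired t-test
#' is used, otherwise a Wilcoxon signed-rank test. When all differences
#' are zero neither test is defined and the comparison p-value is reported
#' as 1 (no evidence of any shift).
#'
#' @param values_a,values_b Numeric vectors of equal length >= 3, paired by
#'   individual.
#' @param normality_alpha Gate level for the Shapiro-Wilk p-value
#'   (default 0.05).
#' @return A list: `normality_p`, `comparison_p`, `test_used` (`"T"` for
#'   paired t-test, `"R"` for Wilcoxon signed-rank, `"none"` when all
#'   differences are zero).
#' @export
paired_compare <- function(values_a, values_b, normality_alpha = 0.05) {
  if (length(values_a) != length(values_b))
    stop("paired value vectors differ in length")
  if (length(values_a) < 3L)
    stop("at least 3 pairs are required")
  d <- values_b - values_a
  if (all(d == 0))
    return(list(normality_p = NA_real_, comparison_p = 1,
                test_used = "none"))
  norm_p <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
  if (norm_p > normality_alpha) {
    p <- stats::t.test(values_a, values_b, paired = TRUE)$p.value
    test <- "T"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = TRUE)$p.value)
    test <- "R"
  }
  list(normality_p = norm_p, comparison_p = p, test_used = test)
}

#' Paired alpha-diversity comparisons across time points
#'
#' For each alpha index and each pair of time points, compares the
#' per-individual values with [paired_compare()], reproducing the layout
#' of a paired time-point comparison table (Shapiro-Wilk p, comparison p,
#' and which test ran).
#'
#' @param alpha Data frame from [alpha_diversity()].
#' @param meta Sample metadata (`sample_id`, `twin_pair`, `individual`,
#'   `time_point`).
#' @param indices Which alpha columns to compare.
#' @return Data frame: `index`, `tp_a`, `tp_b`, `normality_p`,
#'   `comparison_p`, `test_used`.
#' @export
compare_timepoints <- function(alpha, meta,
                               indices = c("chao1", "ace", "shannon",
                                           "simpson")) {
  m <- merge(alpha, meta, by = "sample_id")
  m$ind_id <- paste(m$twin_pair, m$individual)
  tps <- sort(unique(m$time_point))
  out <- list()
  for (idx in indices) {
    for (i in seq_along(tps)) for (j in seq_along(tps)) {
      if (j <= i) next
      a <- m[m$time_point == tps[i], c("ind_id", idx)]
      b <- m[m$time_point == tps[j], c("ind_id", idx)]
      b <- b[match(a$ind_id, b$ind_id), ]
      cmp <- paired_compare(a[[idx]], b[[idx]])
      out[[length(out) + 1L]] <- data.frame(
        index = idx, tp_a = tps[i], tp_b = tps[j],
        normality_p = cmp$normality_p, comparison_p = cmp$comparison_p,
        test_used = cmp$test_used, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
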