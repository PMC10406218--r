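check_mask <- function(mask, n) {
  if (is.null(mask)) return(rep(TRUE, n))
  if (length(mask) != n)
    stop("mask length ", length(mask), " does not match ", n, " features")
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (0/1)")
  mask > 0
}

#' Jaccard distance between two samples
#'
#' One minus the fraction of the feature union shared by both samples,
#' computed on presence/absence over the masked feature set. An empty
#' masked union (neither sample has any masked feature) is defined as
#' distance 0; mask selection elsewhere penalizes empty masks, so this
#' convention never drives feature selection.
#'
#' @param presence_a,presence_b Binary (or count) vectors of equal length;
#'   any positive value counts as present.
#' @param mask Optional binary feature mask; `NULL` uses all features.
#' @return Distance in `[0, 1]`.
#' @examples
#' jaccard_dist(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 1 - 2/4 = 0.5
#' @export
jaccard_dist <- function(presence_a, presence_b, mask = NULL) {
  if (length(presence_a) != length(presence_b))
    stop("presence vectors differ in length")
  m <- check_mask(mask, length(presence_a))
  a <- presence_a[m] > 0
  b <- presence_b[m] > 0
  union <- sum(a | b)
  if (union == 0) return(0)
  1 - sum(a & b) / union
}

#' Bray-Curtis distance between two samples
#'
#' Normalized sum of absolute count differences over the masked feature
#' set: `sum(|a - b|) / sum(a + b)`. If both masked vectors are all zero
#' the distance is defined as 0, with a warning.
#'
#' @param counts_a,counts_b Non-negative count vectors of equal length.
#' @param mask Optional binary feature mask.
#' @return Distance in `[0, 1]`.
#' @examples
#' bray_curtis_dist(c(1, 2, 3), c(3, 2, 1))  # 4/12
#' @export
bray_curtis_dist <- function(counts_a, counts_b, mask = NULL) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors differ in length")
  m <- check_mask(mask, length(counts_a))
  a <- counts_a[m]
  b <- counts_b[m]
  den <- sum(a + b)
  if (den == 0) {
    warning("both masked count vectors are all zero; distance defined as 0")
    return(0)
  }
  sum(abs(a - b)) / den
}

#' Hellinger distance between two samples
#'
#' Distance between relative abundance profiles:
#' `sqrt(0.5 * sum((a/sum(a) - b/sum(b))^2))`, where the normalizing totals
#' are taken over the *masked* feature set, i.e. over all features
#' considered. If a sample's masked total is zero its relative abundances
#' are taken as all zero (distance 0 when both are zero), with a warning.
#'
#' @param counts_a,counts_b Non-negative count vectors of equal length.
#' @param mask Optional binary feature mask.
#' @return Distance in `[0, 1]`.
#' @examples
#' hellinger_dist(c(3, 1), c(1, 3))  # 0.5
#' @export
hellinger_dist <- function(counts_a, counts_b, mask = NULL) {
  if (length(counts_a) != length(counts_b))
    stop("count vectors differ in length")
  m <- check_mask(mask, length(counts_a))
  a <- counts_a[m]
  b <- counts_b[m]
  ta <- sum(a); tb <- sum(b)
  if (ta == 0 || tb == 0)
    warning("a masked sample total is zero; its relative abundances are 0")
  ra <- if (ta > 0) a / ta else a * 0
  rb <- if (tb > 0) b / tb else b * 0
  sqrt(0.5 * sum((ra - rb)^2))
}

#' Distances for a set of sample pairs
#'
#' Computes the chosen beta-diversity distance for every row of a pair data
#' frame, over an optional feature mask. This is the vectorized workhorse
#' behind the genetic-algorithm fitness function.
#'
#' @param table A [feature_table].
#' @param pairs Data frame with `sample_a`, `sample_b` columns.
#' @param distance One of `"jaccard"`, `"braycurtis"`, `"hellinger"`.
#' @param mask Optional binary feature mask (length = number of features).
#' @return Numeric vector of distances, one per pair row.
#' @export
pair_distances <- function(table, pairs,
                           distance = c("jaccard", "braycurtis",
                                        "hellinger"),
                           mask = NULL) {
  distance <- match.arg(distance)
  stopifnot(inherits(table, "feature_table"))
  m <- check_mask(mask, ncol(table))
  ia <- match(pairs$sample_a, rownames(table))
  ib <- match(pairs$sample_b, rownames(table))
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a sample missing from the table")
  x <- unclass(table)[, m, drop = FALSE]
  A <- x[ia, , drop = FALSE]
  B <- x[ib, , drop = FALSE]
  if (distance == "jaccard") {
    pa <- A > 0; pb <- B > 0
    inter <- rowSums(pa & pb)
    union <- rowSums(pa) + rowSums(pb) - inter
    d <- ifelse(union == 0, 0, 1 - inter / union)
  } else if (distance == "braycurtis") {
    den <- rowSums(A + B)
    d <- ifelse(den == 0, 0, rowSums(abs(A - B)) / den)
  } else {
    ta <- rowSums(A); tb <- rowSums(B)
    ra <- A / ifelse(ta == 0, 1, ta)
    rb <- B / ifelse(tb == 0, 1, tb)
    d <- sqrt(0.5 * rowSums((ra - rb)^2))
  }
  unname(d)
}

#' Rank-based AUC between Self and MZT distances
#'
#' Area under the ROC curve via the rank-sum (Mann-Whitney) formula with
#' mid-ranks for ties. All distances are pooled and ranked ascending; if
#' `R_M` is the rank sum of the MZT group, then
#' `AUC = (R_M - n_M (n_M + 1) / 2) / (n_M * n_S)`. The AUC is 1 exactly
#' when every MZT distance strictly exceeds every Self distance.
#'
#' @param self_distances,mzt_distances Non-empty numeric vectors of
#'   distances for inner-individual (Self) and between-co-twin (MZT) pairs.
#' @return AUC in `[0, 1]`.
#' @examples
#' rank_auc(c(0.3, 0.6), c(0.4, 0.7))  # 0.75
#' @export
rank_auc <- function(self_distances, mzt_distances) {
  n_s <- length(self_distances)
  n_m <- length(mzt_distances)
  if (n_s == 0L || n_m == 0L)
    stop("both Self and MZT groups must be non-empty")
  r <- rank(c(mzt_distances, self_distances), ties.method = "average")
  r_m <- sum(r[seq_len(n_m)])
  (r_m - n_m * (n_m + 1) / 2) / (n_m * n_s)
}
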