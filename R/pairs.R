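#' Classify the collection interval of a sample pair
#'
#' Pairs collected at most `short_max` months apart are "short"; pairs at
#' least `long_min` months apart are "long". The study design leaves the
#' band in between empty, so a gap falling there is an error.
#'
#' @param month_a,month_b Month offsets of the two samples.
#' @param short_max Largest gap (months) still counted as short; default 2.
#' @param long_min Smallest gap counted as long; default 12.
#' @return `"short"` or `"long"` (vectorized over the inputs).
#' @examples
#' classify_interval(12, 14)  # "short"
#' classify_interval(0, 12)   # "long"
#' @export
classify_interval <- function(month_a, month_b, short_max = 2,
                              long_min = 12) {
  gap <- abs(month_a - month_b)
  out <- ifelse(gap <= short_max, "short",
                ifelse(gap >= long_min, "long", NA_character_))
  if (anyNA(out))
    stop("interval outside study design: gap of ", gap[which(is.na(out))[1]],
         " months is neither short (<= ", short_max,
         ") nor long (>= ", long_min, ")")
  out
}

#' Enumerate within-twin-pair sample pairs
#'
#' All unordered pairs of samples whose members belong to the same twin
#' pair. Pairs of samples from the same individual are labelled `Self`
#' (inner-individual); pairs from the two co-twins are labelled `MZT`.
#' Cross-twin-pair ("unrelated") pairs are deliberately not formed. With
#' the full design (2 individuals x 4 time points), each twin pair's 8
#' samples yield choose(8, 2) = 28 pairs.
#'
#' @param meta Sample metadata data frame (`sample_id`, `twin_pair`,
#'   `individual`, `time_point`, `month_offset`).
#' @param short_max,long_min Passed to [classify_interval()].
#' @return A data frame with columns `sample_a`, `sample_b` (canonically
#'   ordered so `sample_a` sorts first), `twin_pair`, `relationship`
#'   (`"Self"`/`"MZT"`), and `interval` (`"short"`/`"long"`).
#' @export
enumerate_pairs <- function(meta, short_max = 2, long_min = 12) {
  validate_metadata(meta)
  out <- lapply(split(meta, meta$twin_pair), function(g) {
    if (length(unique(g$individual)) != 2L)
      stop("twin pair ", g$twin_pair[1L], " has ",
           length(unique(g$individual)), " individuals; expected 2")
    idx <- utils::combn(nrow(g), 2L)
    i <- idx[1L, ]; j <- idx[2L, ]
    a <- g$sample_id[i]; b <- g$sample_id[j]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(
      sample_a = a, sample_b = b,
      twin_pair = g$twin_pair[1L],
      relationship = ifelse(g$individual[i] == g$individual[j],
                            "Self", "MZT"),
      interval = classify_interval(g$month_offset[i], g$month_offset[j],
                                   short_max, long_min),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Stratified train/test split of sample pairs
#'
#' Within each relationship x interval group, a uniformly random subset of
#' `round(ratio * group size)` pairs (round half-up) is assigned to the
#' training set and the remainder to the test set. With the full twin
#' design (60 Self-short, 60 Self-long, 100 MZT-short, 60 MZT-long pairs)
#' and the default 8:2 ratio this reproduces training-group sizes of
#' 48, 48, 80 and 48.
#'
#' @param pairs Pair data frame from [enumerate_pairs()].
#' @param ratio Training fraction; default 0.8.
#' @param seed RNG seed for the random assignment; `NULL` uses the current
#'   RNG state.
#' @return `pairs` with an added `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(pairs, ratio = 0.8, seed = NULL) {
  stopifnot(ratio >= 0, ratio <= 1)
  if (!is.null(seed)) set.seed(seed)
  pairs$split <- NA_character_
  groups <- interaction(pairs$relationship, pairs$interval, drop = TRUE)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) {
      warning("empty pair group ", g, "; skipped")
      next
    }
    n_train <- floor(ratio * length(idx) + 0.5)  # round half-up
    train <- sample(idx, n_train)
    pairs$split[idx] <- "test"
    pairs$split[train] <- "train"
  }
  pairs
}

#' Write sample pairs as TSV
#'
#' @param pairs Pair data frame (optionally with `split` and `distance`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
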