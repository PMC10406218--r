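#' Simulation configuration for a twin cohort
#'
#' Describes a longitudinal monozygotic-twin (MZT) saliva-microbiome study:
#' `n_twin_pairs` twin pairs, each with two individuals (A and B) sampled at
#' `n_timepoints` time points placed at `month_offsets` months. Features fall
#' into four latent classes:
#'
#' * *discriminative* — consistently carried by exactly one twin of each
#'   pair and absent in the co-twin; the signal the feature-selection stage
#'   is meant to recover;
#' * *shared core* — present in every individual at every time point;
#' * *transient* — presence toggles independently per sample (environmental
#'   noise);
#' * *absent* — the remainder; never observed.
#'
#' Temporal instability is modelled on the presence scale: each stable
#' (discriminative or core) feature's presence state flips in a given sample
#' with probability `presence_flip_prob`, plus `tp1_extra_flip_prob` at the
#' first time point, reflecting the drift of baseline samples taken a year
#' before the rest.
#'
#' @param n_twin_pairs Number of MZT pairs (default 10).
#' @param n_timepoints Samples per individual (default 4).
#' @param month_offsets Integer months of each time point, strictly
#'   increasing; default `c(0, 12, 13, 14)` (baseline plus three monthly
#'   follow-ups a year later).
#' @param n_features Number of candidate features (ASV-like units).
#' @param frac_discriminative,frac_shared_core,frac_transient Fractions of
#'   `n_features` in each class; their sum must be at most 1 (the remainder
#'   is never observed).
#' @param presence_flip_prob Per-sample probability that a stable feature's
#'   presence state flips.
#' @param tp1_extra_flip_prob Additional flip probability at time point 1.
#' @param transient_presence_prob Occupancy probability of a transient
#'   feature in any sample.
#' @param depth_mean Expected sequencing depth (reads per sample); the
#'   realized depth is Poisson. Default 76,338 reads, a realistic clean-read
#'   yield for 16S V3-V4 sequencing; test fixtures use far less.
#' @param concentration Dirichlet concentration for per-sample relative
#'   abundances of present features. Values below 1 give the skewed,
#'   dominance-heavy abundance profiles typical of saliva.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_twin_pairs = 10, n_timepoints = 4,
                       month_offsets = c(0, 12, 13, 14),
                       n_features = 300,
                       frac_discriminative = 0.10,
                       frac_shared_core = 0.40,
                       frac_transient = 0.30,
                       presence_flip_prob = 0.02,
                       tp1_extra_flip_prob = 0.10,
                       transient_presence_prob = 0.5,
                       depth_mean = 76338,
                       concentration = 0.5,
                       seed = NULL) {
  cfg <- list(n_twin_pairs = as.integer(n_twin_pairs),
              n_timepoints = as.integer(n_timepoints),
              month_offsets = as.integer(month_offsets),
              n_features = as.integer(n_features),
              frac_discriminative = frac_discriminative,
              frac_shared_core = frac_shared_core,
              frac_transient = frac_transient,
              presence_flip_prob = presence_flip_prob,
              tp1_extra_flip_prob = tp1_extra_flip_prob,
              transient_presence_prob = transient_presence_prob,
              depth_mean = depth_mean,
              concentration = concentration,
              seed = seed)
  fr <- c(cfg$frac_discriminative, cfg$frac_shared_core, cfg$frac_transient)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12)
    stop("class fractions must lie in [0,1] and sum to at most 1")
  if (length(cfg$month_offsets) != cfg$n_timepoints)
    stop("month_offsets must have one entry per time point")
  if (any(diff(cfg$month_offsets) <= 0))
    stop("month_offsets must be strictly increasing")
  probs <- c(cfg$presence_flip_prob, cfg$tp1_extra_flip_prob,
             cfg$transient_presence_prob)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0,1]")
  if (cfg$n_twin_pairs < 1 || cfg$n_timepoints < 1 || cfg$n_features < 1)
    stop("cohort dimensions must be positive")
  if (cfg$depth_mean <= 0 || cfg$concentration <= 0)
    stop("depth_mean and concentration must be positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a twin-cohort feature table
#'
#' Generates counts for `n_twin_pairs x 2 x n_timepoints` samples under the
#' model described in [sim_config()]. For each sample, the set of present
#' features is determined by the latent class structure plus presence-flip
#' noise; relative abundances over the present set are Dirichlet
#' (symmetric, parameter `concentration`) scaled by a per-feature
#' lognormal baseline weight shared across all samples, so that a feature
#' tends to be common or rare consistently; counts are multinomial at a
#' Poisson-distributed depth. One read is reserved for every present
#' feature so that presence in the latent model always coincides with a
#' positive count.
#'
#' Sample identifiers follow the `S<pair><individual><tp>` scheme, e.g.
#' `"S10A1"` is individual A of pair 10 at time point 1.
#'
#' All randomness is drawn from the global RNG after `set.seed(config$seed)`
#' (when a seed is given), in a fixed order: feature class labels, carrier
#' twins, baseline weights, then per-sample presence flips, Dirichlet draws
#' and counts in sample order. The same configuration and seed therefore
#' reproduce the cohort bit-identically.
#'
#' @param config A [sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{table}{[feature_table] of counts (samples x features).}
#'     \item{metadata}{data frame: `sample_id`, `twin_pair`, `individual`,
#'       `time_point`, `month_offset`.}
#'     \item{truth}{list with `labels` (data frame `feature_id`, `label` in
#'       discriminative/shared_core/transient/absent) and `carriers`
#'       (data frame `twin_pair`, `feature_id`, `carrier` in A/B for each
#'       discriminative feature).}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_twin_pairs = 2, n_features = 50,
#'                                      depth_mean = 2000, seed = 1))
#' dim(cohort$table)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- config$n_features
  np <- config$n_twin_pairs
  nt <- config$n_timepoints

  n_disc <- round(config$frac_discriminative * nf)
  n_core <- round(config$frac_shared_core * nf)
  n_trans <- round(config$frac_transient * nf)
  if (n_disc + n_core + n_trans > nf)
    n_trans <- nf - n_disc - n_core
  labels <- rep("absent", nf)
  labels[seq_len(n_disc)] <- "discriminative"
  labels[seq_len(n_core) + n_disc] <- "shared_core"
  labels[seq_len(n_trans) + n_disc + n_core] <- "transient"
  labels <- sample(labels)  # randomize positions
  feature_ids <- sprintf("ASV%d", seq_len(nf))
  disc_idx <- which(labels == "discriminative")
  core_idx <- which(labels == "shared_core")
  trans_idx <- which(labels == "transient")

  # which twin of each pair carries each discriminative feature
  carriers <- matrix(sample(c("A", "B"), np * length(disc_idx),
                            replace = TRUE),
                     nrow = np)

  # per-feature lognormal baseline weight, shared across samples
  base_weight <- stats::rlnorm(nf, meanlog = 0, sdlog = 1)

  meta <- expand.grid(time_point = seq_len(nt), individual = c("A", "B"),
                      twin_pair = seq_len(np), stringsAsFactors = FALSE)
  meta <- meta[, c("twin_pair", "individual", "time_point")]
  meta$month_offset <- config$month_offsets[meta$time_point]
  meta$sample_id <- sprintf("S%d%s%d", meta$twin_pair, meta$individual,
                            meta$time_point)
  meta <- meta[, c("sample_id", "twin_pair", "individual", "time_point",
                   "month_offset")]
  ns <- nrow(meta)

  counts <- matrix(0L, nrow = ns, ncol = nf)
  for (s in seq_len(ns)) {
    pair <- meta$twin_pair[s]
    ind <- meta$individual[s]
    tp <- meta$time_point[s]
    stable <- logical(nf)
    stable[core_idx] <- TRUE
    if (length(disc_idx))
      stable[disc_idx] <- carriers[pair, ] == ind
    flip_p <- config$presence_flip_prob +
      if (tp == 1L) config$tp1_extra_flip_prob else 0
    present <- stable
    stable_pos <- c(disc_idx, core_idx)
    if (flip_p > 0 && length(stable_pos)) {
      flips <- stats::runif(length(stable_pos)) < flip_p
      present[stable_pos] <- xor(present[stable_pos], flips)
    }
    if (length(trans_idx))
      present[trans_idx] <-
        stats::runif(length(trans_idx)) < config$transient_presence_prob
    k <- sum(present)
    if (k == 0L)
      stop("sample ", meta$sample_id[s], " has no present features; ",
           "increase class fractions or occupancy")
    depth <- stats::rpois(1L, config$depth_mean)
    if (depth < k) depth <- k
    g <- stats::rgamma(k, shape = config$concentration) *
      base_weight[present]
    rel <- g / sum(g)
    extra <- stats::rmultinom(1L, size = depth - k, prob = rel)[, 1L]
    counts[s, present] <- 1L + extra
  }

  table <- feature_table(counts, sample_ids = meta$sample_id,
                         feature_ids = feature_ids)
  truth <- list(
    labels = data.frame(feature_id = feature_ids, label = labels,
                        stringsAsFactors = FALSE),
    carriers = if (length(disc_idx)) data.frame(
      twin_pair = rep(seq_len(np), times = length(disc_idx)),
      feature_id = rep(feature_ids[disc_idx], each = np),
      carrier = as.vector(carriers),
      stringsAsFactors = FALSE
    ) else data.frame(twin_pair = integer(), feature_id = character(),
                      carrier = character(), stringsAsFactors = FALSE))
  list(table = table, metadata = meta, truth = truth)
}

#' Write ground-truth feature labels as TSV
#'
#' @param truth The `truth` component of a [simulate_cohort()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
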