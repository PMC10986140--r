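#' Specification for the synthetic 16S dataset generator
#'
#' The defaults emulate the structure of a caecal 16S study of two rabbit
#' groups: two groups of samples, thousands of sparse ASVs collapsible to
#' ~139 genera, per-sample depths in roughly the 10,863-62,439 read range
#' with mean about 29,490, and a dominant phylum near 87% relative
#' abundance. A configurable subset of features carries a between-group
#' shift expressed in units of the ALR variable's SD.
#'
#' @param n_per_group length-2 vector of samples per group (default the
#'   study-sized 31 + 40).
#' @param n_features number of ASV features.
#' @param n_genera number of genera the features collapse to.
#' @param depth_range min/max per-sample read totals.
#' @param depth_mean target mean read total.
#' @param dominant_fraction target relative-abundance share of the dominant
#'   phylum.
#' @param n_diff number of differential features (used when `diff_features`
#'   is NULL).
#' @param diff_features integer indices of differential features, or NULL to
#'   pick `n_diff` at random among eligible (non-reference) features.
#' @param delta_sd between-group ALR shift of each differential feature, in
#'   SD units (>= 0).
#' @param zero_inflation probability that a background feature's latent
#'   abundance is zeroed in a sample (sparsity emulation; differential and
#'   reference features are exempt so designed effects are realised).
#' @param base_log_abundance optional vector of per-feature log-scale
#'   location parameters (default: drawn Normal(0, 1.5)).
#' @param noise_sd SD of the per-sample per-feature log-abundance noise.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(31, 40), n_features = 2000,
                           n_genera = 139, depth_range = c(10863, 62439),
                           depth_mean = 29490, dominant_fraction = 0.87,
                           n_diff = 0, diff_features = NULL, delta_sd = 0,
                           zero_inflation = 0.3, base_log_abundance = NULL,
                           noise_sd = 0.8, seed = 1L) {
  stopifnot(length(n_per_group) == 2, delta_sd >= 0,
            depth_range[1] <= depth_mean, depth_mean <= depth_range[2],
            zero_inflation >= 0, zero_inflation < 1)
  if (any(n_per_group < 2)) stop("need at least 2 samples per group")
  if (!is.null(diff_features) && any(diff_features > n_features))
    stop("diff_features out of range")
  structure(list(n_per_group = n_per_group, n_features = n_features,
                 n_genera = n_genera, depth_range = depth_range,
                 depth_mean = depth_mean, dominant_fraction = dominant_fraction,
                 n_diff = n_diff, diff_features = diff_features,
                 delta_sd = delta_sd, zero_inflation = zero_inflation,
                 base_log_abundance = base_log_abundance, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic count table, taxonomy, metadata and effect truth
#'
#' Logistic-normal/multinomial model: each sample's latent feature
#' log-abundances are `base + group_shift + noise`, exponentiated, closed to
#' proportions and drawn through a multinomial at a depth sampled within
#' `depth_range` (a scaled Beta whose mean is `depth_mean`). Feature 1 is
#' forced to the lowest noise variance and carries no shift, so the
#' lowest-CV ALR reference rule lands on a stable, effect-free feature.
#' Group shifts are injected on the log scale as `delta_sd *
#' sqrt(noise_sd_j^2 + noise_sd_ref^2)`, the SD of the corresponding ALR
#' variable, so the designed effect is expressed in ALR SD units. Features
#' are assigned to `n_genera` genera across 11 phyla, with phylum 1's
#' features boosted so their expected share matches `dominant_fraction`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (ASV [count_table()]), `taxonomy`, `metadata`,
#'   and `truth` (data.frame `feature_id`, `delta_sd` with sign; 0 for null
#'   features).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- spec$n_features
  n <- sum(spec$n_per_group)
  feature_id <- sprintf("ASV_%04d", seq_len(p))
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- rep(c("G1", "G2"), spec$n_per_group)

  # taxonomy: genera spread over 11 phyla, phylum 1 dominant
  genus_of <- sort(rep_len(seq_len(spec$n_genera), p))
  phylum_of_genus <- rep_len(c(1, 1, 1, 2, 1, 3, 1, rep_len(4:11, 4)), spec$n_genera)
  tax <- parse_taxonomy(feature_id, sprintf(
    "d__Bacteria;p__Phylum_%02d;c__Class_%02d;o__Order_%02d;f__Family_%02d;g__Genus_%03d",
    phylum_of_genus[genus_of], phylum_of_genus[genus_of],
    genus_of %% 42 + 1, genus_of %% 65 + 1, genus_of))

  base <- spec$base_log_abundance
  if (is.null(base)) base <- stats::rnorm(p, 0, 1.5)
  # per-feature noise SD; feature 1 is the designed low-variance reference
  tau <- stats::runif(p, 0.6, 1.4) * spec$noise_sd
  tau[1] <- 0.05 * spec$noise_sd
  base[1] <- stats::median(base) + 1   # keep the reference comfortably abundant

  # boost the dominant phylum so its expected share ~= dominant_fraction
  dom <- phylum_of_genus[genus_of] == 1
  ev <- exp(base + tau^2 / 2)
  f <- spec$dominant_fraction
  base[dom] <- base[dom] + log(f * sum(ev[!dom]) / ((1 - f) * sum(ev[dom])))

  diff_idx <- spec$diff_features
  if (is.null(diff_idx) && spec$n_diff > 0) {
    # inject effects into detectable taxa: median count >~ 50 at the mean
    # depth; below that the count noise of the low-abundance tail (var ~
    # E[1/count] on the log scale) attenuates the designed ALR shift
    med_share <- exp(base) / sum(exp(base + tau^2 / 2))
    eligible <- setdiff(which(med_share > 50 / spec$depth_mean), 1L)
    if (length(eligible) < spec$n_diff)
      eligible <- setdiff(order(med_share, decreasing = TRUE)[seq_len(spec$n_diff + 1)], 1L)
    diff_idx <- sample(eligible, spec$n_diff)
  }
  diff_idx <- setdiff(as.integer(diff_idx), 1L)   # never shift the reference
  sign_of <- rep(0, p)
  if (length(diff_idx))
    sign_of[diff_idx] <- sample(c(-1, 1), length(diff_idx), replace = TRUE)
  # ALR(j | ref) has variance tau_j^2 + tau_1^2 from the latent noise plus
  # E[1/count] = exp(tau^2)/E[count] per side from the multinomial draw
  # (lognormal low-abundance tail); normalise the injected log-scale shift
  # by the full predicted ALR SD so the designed effect is realised in the
  # units the analysis measures
  ev2 <- exp(base + tau^2 / 2)
  ecount <- ev2 / sum(ev2) * spec$depth_mean
  alr_sd <- sqrt(tau^2 + tau[1]^2 +
                 exp(tau^2) / pmax(ecount, 1) + exp(tau[1]^2) / ecount[1])
  shift <- sign_of * spec$delta_sd * alr_sd

  dr <- spec$depth_range
  mean_frac <- (spec$depth_mean - dr[1]) / (dr[2] - dr[1])
  ab_total <- 4                               # Beta concentration for depth draw
  depths <- round(dr[1] + (dr[2] - dr[1]) *
                    stats::rbeta(n, mean_frac * ab_total, (1 - mean_frac) * ab_total))

  counts <- matrix(0, n, p, dimnames = list(sample_id, feature_id))
  zi_eligible <- sign_of == 0 & seq_len(p) != 1L
  for (i in seq_len(n)) {
    lam <- base + (group[i] == "G2") * shift + stats::rnorm(p, 0, tau)
    w <- exp(lam)
    drop <- zi_eligible & stats::runif(p) < spec$zero_inflation
    w[drop] <- 0
    counts[i, ] <- stats::rmultinom(1, depths[i], prob = w / sum(w))
  }
  list(table = count_table(counts, level = "ASV"),
       taxonomy = tax,
       metadata = data.frame(sample_id = sample_id, group = group,
                             stringsAsFactors = FALSE),
       truth = data.frame(feature_id = feature_id,
                          delta_sd = sign_of * spec$delta_sd,
                          stringsAsFactors = FALSE))
}

#' Realised between-group effect of one ALR variable, in SD units
#'
#' (mean ALR in group 1 - mean ALR in group 2) / pooled within-group SD of
#' ALR(feature | ref). Used to verify the generator's calibration.
#'
#' @param table a strictly positive [count_table()] (pseudocounted).
#' @param meta sample metadata (two groups).
#' @param ref reference feature ID.
#' @param feature numerator feature ID (different from `ref`).
#' @return numeric effect size in SD units.
#' @export
realized_effect <- function(table, meta, ref, feature) {
  assert_count_table(table)
  if (feature == ref) stop("feature must differ from the reference")
  if (any(table$counts <= 0)) stop("table has zeros; run add_pseudocount() first")
  g <- group_factor(table, meta)
  a <- log(table$counts[, feature]) - log(table$counts[, ref])
  v <- tapply(a, g, stats::var)
  n_g <- table(g)
  pooled <- sqrt(sum((n_g - 1) * v) / (sum(n_g) - 2))
  if (pooled <= .Machine$double.eps) stop("zero ALR variance for ", feature)
  unname(diff(rev(tapply(a, g, mean))) / pooled)
}

#' Write a generated dataset to TSV files
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(dataset$table, paths["counts"])
  write_taxonomy(dataset$taxonomy, paths["taxonomy"])
  utils::write.table(dataset$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
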