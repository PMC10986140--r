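#' Filter features by per-group prevalence
#'
#' Keeps exactly the features detected (nonzero) in at least `min_prev` of the
#' samples of *each* group. The threshold is inclusive: a feature present in
#' exactly 50% of each group survives the default. The comparison
#' `presence / n_group >= min_prev` is evaluated with a tiny absolute guard so
#' that fractions representable only approximately in binary (e.g. 0.1) do not
#' flip the inclusive boundary.
#'
#' @param table a [count_table()].
#' @param meta sample metadata (data.frame with `sample_id`, `group`).
#' @param min_prev required prevalence fraction per group, default 0.5.
#' @return A [count_table()] with the retained features; samples unchanged.
#' @export
prevalence_filter <- function(table, meta, min_prev = 0.5) {
  assert_count_table(table)
  g <- group_factor(table, meta)
  keep <- rep(TRUE, ncol(table$counts))
  for (lev in levels(g)) {
    rows <- table$counts[g == lev, , drop = FALSE]
    prev <- colSums(rows > 0) / nrow(rows)
    keep <- keep & (prev >= min_prev - 1e-9)
  }
  count_table(table$counts[, keep, drop = FALSE], level = table$level)
}

#' Add a pseudocount to every cell
#'
#' Used before log-ratio transformation to remove zeros.
#'
#' @param table a [count_table()].
#' @param value positive offset, default 1.
#' @return A list-like `count_table` whose counts are `counts + value`. The
#'   result keeps the `count_table` class but cells need not be integers if
#'   `value` is fractional.
#' @export
add_pseudocount <- function(table, value = 1) {
  assert_count_table(table)
  if (!is.numeric(value) || length(value) != 1 || value <= 0)
    stop("pseudocount must be a positive number")
  out <- table
  out$counts <- table$counts + value
  out
}

#' Collapse an ASV table to genus level
#'
#' ASVs sharing an identical lineage down to genus are summed. ASVs that are
#' unassigned at genus are grouped by their deepest assigned rank and labelled
#' `<rank>:<name>` (e.g. `order:Oscillospirales`), so mixed-rank labels stay
#' distinguishable from true genera. Per-sample totals are conserved exactly.
#'
#' @param table a [count_table()] at ASV level.
#' @param tax taxonomy map from [read_taxonomy()] / [parse_taxonomy()].
#' @return A genus-level [count_table()].
#' @export
collapse_to_genus <- function(table, tax) {
  assert_count_table(table)
  if (table$level != "ASV") stop("collapse_to_genus expects an ASV-level table")
  idx <- match(feature_ids(table), tax$feature_id)
  if (anyNA(idx))
    stop("ASVs missing from taxonomy: ",
         paste(feature_ids(table)[is.na(idx)], collapse = ", "))
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  lab <- character(length(idx))
  for (i in seq_along(idx)) {
    lin <- as.character(tax[idx[i], ranks])
    if (!is.na(lin[6])) {
      # full lineage down to genus defines the collapsed feature
      lab[i] <- paste(lin, collapse = ";")
    } else {
      deepest <- max(c(0L, which(!is.na(lin))))
      lab[i] <- if (deepest == 0L) "unassigned"
                else paste0(ranks[deepest], ":", lin[deepest])
    }
  }
  groups <- factor(lab, levels = unique(lab))
  collapsed <- t(rowsum(t(table$counts), groups))
  colnames(collapsed) <- levels(groups)
  count_table(collapsed, level = "genus")
}

#' Rarefy samples to an even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads;
#' samples whose total is below `depth` are dropped (and reported via a
#' message and the `dropped` attribute).
#'
#' @param table a [count_table()].
#' @param depth target depth (reads per sample), >= 1.
#' @param seed integer seed for reproducibility.
#' @return A [count_table()] of the retained samples, each summing to `depth`,
#'   with attribute `dropped` listing removed sample IDs.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  assert_count_table(table)
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("rarefaction depth ", depth, " exceeds every sample total")
  dropped <- sample_ids(table)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  m <- table$counts[keep, , drop = FALSE]
  set.seed(seed)
  out <- m
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (sum(x) == depth) next        # exhaustive draw: counts unchanged
    reads <- rep.int(seq_along(x), x)
    out[i, ] <- tabulate(sample(reads, depth), nbins = length(x))
  }
  res <- count_table(out, level = table$level)
  attr(res, "dropped") <- dropped
  res
}

#' PCA-based outlier screen
#'
#' Counts are converted to per-sample relative abundances and column-centered;
#' samples whose Euclidean distance from the score centroid in the first two
#' principal components exceeds `k_sd` times the standard deviation of those
#' distances are removed. Applied once, before the pseudocount/ALR steps.
#'
#' @param table a [count_table()], >= 3 samples.
#' @param k_sd removal threshold in SD units of the PC1-PC2 distances
#'   (default 3; `Inf` disables removal).
#' @return list with elements `table` (screened [count_table()]) and
#'   `removed` (character vector of removed sample IDs).
#' @export
pca_outlier_screen <- function(table, k_sd = 3) {
  assert_count_table(table)
  if (nrow(table$counts) < 3) stop("PCA screen needs at least 3 samples")
  rel <- table$counts / rowSums(table$counts)
  centred <- scale(rel, center = TRUE, scale = FALSE)
  sc <- stats::prcomp(centred, center = FALSE)$x
  sc <- sc[, seq_len(min(2, ncol(sc))), drop = FALSE]
  d <- sqrt(rowSums(sc^2))
  removed <- character(0)
  if (is.finite(k_sd)) {
    bad <- d > k_sd * stats::sd(d)
    removed <- sample_ids(table)[bad]
  }
  keep <- !(sample_ids(table) %in% removed)
  list(table = count_table(table$counts[keep, , drop = FALSE], level = table$level),
       removed = removed)
}
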