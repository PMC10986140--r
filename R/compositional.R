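#' Select the ALR reference feature by lowest coefficient of variation
#'
#' CV = SD / mean of each feature's *relative abundance* across samples
#' (proportions, not raw counts: raw-count CV is dominated by library size,
#' which the log-ratio analysis removes by design; set `use_proportions =
#' FALSE` for a raw-count sensitivity analysis). Ties are broken toward the
#' lexicographically first feature ID.
#'
#' @param table a strictly positive (pseudocounted) [count_table()].
#' @param use_proportions compute CV on per-sample proportions (default TRUE).
#' @return The reference feature ID (character scalar) with the per-feature
#'   CVs attached as attribute `cv`.
#' @export
select_alr_reference <- function(table, use_proportions = TRUE) {
  assert_count_table(table)
  if (any(table$counts <= 0))
    stop("table has zero cells; run add_pseudocount() first")
  m <- if (use_proportions) table$counts / rowSums(table$counts) else table$counts
  cv <- apply(m, 2, function(x) stats::sd(x) / mean(x))
  best <- cv[cv == min(cv)]
  ref <- sort(names(best))[1]
  if (length(best) > 1)
    message("select_alr_reference: ", length(best),
            " features tied at minimum CV; choosing '", ref, "'")
  attr(ref, "cv") <- cv
  ref
}

#' Additive log-ratio transformation
#'
#' ALR(j | ref) = log(x_j) - log(x_ref), natural logarithm, for every feature
#' j except the reference, giving j - 1 log-ratio variables. Row values are
#' invariant to per-sample scaling, so counts and proportions give identical
#' results.
#'
#' @param table a strictly positive [count_table()].
#' @param ref reference feature ID, present in the table.
#' @return An `alr_matrix`: samples x (features - 1) numeric matrix with
#'   attribute `ref_id`.
#' @export
alr_transform <- function(table, ref) {
  assert_count_table(table)
  if (any(table$counts <= 0))
    stop("nonpositive cells; run add_pseudocount() first")
  if (!ref %in% feature_ids(table)) stop("reference '", ref, "' not in table")
  lx <- log(table$counts)
  vals <- lx[, setdiff(feature_ids(table), ref), drop = FALSE] - lx[, ref]
  structure(vals, ref_id = ref, class = c("alr_matrix", "matrix"))
}

#' Invert an ALR matrix back to relative abundances
#'
#' Softmax-style closure: exact inverse of [alr_transform()] up to the
#' unit-sum constraint.
#'
#' @param alr an `alr_matrix`.
#' @return samples x features matrix of proportions (reference included).
#' @export
alr_inverse <- function(alr) {
  ref <- attr(alr, "ref_id")
  expd <- cbind(exp(unclass(alr)), 1)
  colnames(expd)[ncol(expd)] <- ref
  expd / rowSums(expd)
}

clr_transform <- function(table) {
  lx <- log(table$counts)
  lx - rowMeans(lx)
}

#' Procrustes correlation between the ALR and CLR sample configurations
#'
#' Verifies that the ALR geometry (which depends on the reference choice)
#' faithfully reproduces the full log-ratio geometry: the centered ALR
#' configuration is fitted to the centered CLR configuration of the same
#' table by orthogonal Procrustes with translation and uniform scaling.
#' The squared residual m2 is normalised by the target's total sum of
#' squares; correlation = sqrt(1 - m2). A well-chosen (low-CV, stable)
#' reference yields correlations near 1.
#'
#' @param alr an `alr_matrix`.
#' @param table the strictly positive [count_table()] it came from (same
#'   samples).
#' @return list with `correlation` and `m2`.
#' @export
procrustes_correlation <- function(alr, table) {
  assert_count_table(table)
  if (nrow(alr) < 3) stop("need at least 3 samples")
  if (!identical(rownames(alr), sample_ids(table)))
    stop("ALR matrix and table must share samples (same order)")
  m2 <- procrustes_fit(unclass(alr), clr_transform(table))$m2
  list(correlation = sqrt(max(0, 1 - m2)), m2 = m2)
}

# symmetric orthogonal Procrustes of two centered configurations;
# columns are padded with zeros to a common dimension
procrustes_fit <- function(x, y) {
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- scale(y, center = TRUE, scale = FALSE)
  k <- max(ncol(x), ncol(y))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  x <- pad(x); y <- pad(y)
  # normalise both to unit total sum of squares (symmetric form)
  x <- x / sqrt(sum(x^2))
  y <- y / sqrt(sum(y^2))
  sv <- svd(crossprod(y, x))$d
  m2 <- 1 - sum(sv)^2
  list(m2 = max(0, min(1, m2)))
}
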