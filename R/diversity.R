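#' Alpha diversity indices per sample
#'
#' Observed richness S (number of nonzero features), Shannon diversity H in
#' bits (base-2 log, the QIIME2 convention; configurable), and Pielou's
#' evenness J = H / log(S). J is undefined (NA) for single-taxon samples.
#'
#' @param table a [count_table()]; every sample must have reads.
#' @param base logarithm base for H (and the J normalisation), default 2.
#' @return data.frame with columns `sample_id`, `observed`, `shannon`,
#'   `pielou`.
#' @export
alpha_indices <- function(table, base = 2) {
  assert_count_table(table)
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("empty sample(s): ", paste(sample_ids(table)[totals == 0], collapse = ", "))
  res <- t(apply(table$counts, 1, function(x) {
    p <- x[x > 0] / sum(x)
    s <- length(p)
    h <- -sum(p * log(p, base = base))
    c(observed = s, shannon = h,
      pielou = if (s > 1) h / log(s, base = base) else NA_real_)
  }))
  data.frame(sample_id = sample_ids(table), res, row.names = NULL)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction; p-value from the chi-square approximation
#' with (number of groups - 1) degrees of freedom.
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels, one per value; >= 2 nonempty groups.
#' @return list with `statistic` (H), `p_value`, `df`, `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) == 0)) stop("empty group")
  if (any(table(g) == 1))
    message("kruskal_wallis: group of size 1 present; test is low-powered")
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) {             # all values identical
    h <- 0
    p <- 1
  } else {
    h <- h / correction
    p <- stats::pchisq(h, df = nlevels(g) - 1, lower.tail = FALSE)
  }
  list(statistic = h, p_value = p, df = nlevels(g) - 1,
       method = "Kruskal-Wallis")
}

new_dist_matrix <- function(d, ids) {
  dimnames(d) <- list(ids, ids)
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v)).
#'
#' @param table a [count_table()] with positive sample totals.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\], class
#'   `dist_matrix`.
#' @export
bray_curtis <- function(table) {
  assert_count_table(table)
  m <- table$counts
  if (any(rowSums(m) == 0)) stop("empty sample")
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <-
      1 - 2 * sum(pmin(m[i, ], m[j, ])) / (sum(m[i, ]) + sum(m[j, ]))
  }
  new_dist_matrix(d, sample_ids(table))
}

#' Jaccard distance matrix (presence/absence)
#'
#' d(A, B) = 1 - |A intersect B| / |A union B| on feature supports.
#'
#' @inheritParams bray_curtis
#' @return symmetric `dist_matrix` with entries in \[0, 1\].
#' @export
jaccard <- function(table) {
  assert_count_table(table)
  pa <- table$counts > 0
  if (any(rowSums(pa) == 0)) stop("empty sample")
  n <- nrow(pa)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    inter <- sum(pa[i, ] & pa[j, ])
    union <- sum(pa[i, ] | pa[j, ])
    d[i, j] <- d[j, i] <- 1 - inter / union
  }
  new_dist_matrix(d, sample_ids(table))
}

permanova_f <- function(d2, g) {
  # pseudo-F from squared distances via the Huygens decomposition
  n <- length(g)
  a <- nlevels(g)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

perm_pvalue <- function(observed, null) (sum(null >= observed) + 1) / (length(null) + 1)

#' PERMANOVA: permutational test of group location in a distance matrix
#'
#' Pseudo-F from squared distances; p-value by permutation of group labels
#' with the add-one estimator (r + 1) / (n_perm + 1).
#'
#' @param dm distance matrix from [bray_curtis()] / [jaccard()] (or any
#'   symmetric matrix with matching sample IDs).
#' @param meta sample metadata with two groups, each >= 2 samples.
#' @param n_perm number of label permutations, default 999.
#' @param seed integer seed.
#' @return list with `statistic` (pseudo-F), `p_value`, `n_permutations`,
#'   `seed`, `method`.
#' @export
permanova <- function(dm, meta, n_perm = 999, seed = 1L) {
  g <- dist_groups(dm, meta)
  d2 <- unclass(dm)^2
  f_obs <- permanova_f(d2, g)
  set.seed(seed)
  null <- replicate(n_perm, permanova_f(d2, sample(g)))
  list(statistic = f_obs, p_value = perm_pvalue(f_obs, null),
       n_permutations = n_perm, seed = seed, method = "PERMANOVA")
}

dist_groups <- function(dm, meta) {
  ids <- rownames(dm)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  g <- factor(meta$group[idx])
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs >= 2 samples")
  g
}

#' PERMDISP: permutational test of multivariate dispersion homogeneity
#'
#' Samples are embedded by principal coordinates analysis on the axes with
#' positive eigenvalues; each sample's Euclidean distance to its group spatial
#' centroid is the dispersion measure. The F statistic of a one-way ANOVA on
#' those distances is compared against permutations of their group labels.
#'
#' @inheritParams permanova
#' @return list with `statistic` (dispersion F), `p_value`,
#'   `n_permutations`, `seed`, `method`, and `group_means` (mean
#'   centroid-distance per group).
#' @export
permdisp <- function(dm, meta, n_perm = 999, seed = 1L) {
  g <- dist_groups(dm, meta)
  n <- nrow(dm)
  # Gower-centred double-centering of -d^2/2; positive-eigenvalue axes
  a <- -0.5 * unclass(dm)^2
  j <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(j %*% a %*% j, symmetric = TRUE)
  pos <- e$values > sqrt(.Machine$double.eps) * max(abs(e$values), 1)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  dcent <- numeric(n)
  for (lev in levels(g)) {
    idx <- which(g == lev)
    centroid <- colMeans(coords[idx, , drop = FALSE])
    dcent[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2, centroid)^2))
  }
  f_stat <- function(vals, grp) {
    m <- tapply(vals, grp, mean)
    ng <- tabulate(grp)
    ssb <- sum(ng * (m - mean(vals))^2)
    ssw <- sum((vals - m[grp])^2)
    if (ssw <= .Machine$double.eps * max(1, ssb)) {
      if (ssb <= .Machine$double.eps) return(0)   # no dispersion differences at all
      return(Inf)
    }
    (ssb / (nlevels(grp) - 1)) / (ssw / (length(vals) - nlevels(grp)))
  }
  f_obs <- f_stat(dcent, g)
  set.seed(seed)
  null <- replicate(n_perm, f_stat(dcent, sample(g)))
  p <- if (f_obs == 0) 1 else perm_pvalue(f_obs, null)
  list(statistic = f_obs, p_value = p, n_permutations = n_perm, seed = seed,
       method = "PERMDISP", group_means = tapply(dcent, g, mean))
}

#' Write a labelled square distance matrix to TSV
#' @param dm a `dist_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), unclass(dm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
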