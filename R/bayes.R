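#' Gibbs sampler configuration
#'
#' Defaults follow the standard single-variable run: 50,000 iterations,
#' thinning lag 10, burn-in 1,000, 4 chains with over-dispersed variance
#' starts for the R-hat diagnostic.
#'
#' @param iterations total Gibbs iterations per chain.
#' @param lag thinning interval (>= 1).
#' @param burn_in discarded initial iterations (< iterations).
#' @param chains number of chains (>= 1; >= 2 recommended for R-hat).
#' @param seed integer seed.
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(iterations = 50000, lag = 10, burn_in = 1000,
                         chains = 4, seed = 1L) {
  stopifnot(burn_in < iterations, lag >= 1, chains >= 1)
  structure(list(iterations = as.integer(iterations), lag = as.integer(lag),
                 burn_in = as.integer(burn_in), chains = as.integer(chains),
                 seed = as.integer(seed)),
            class = "gibbs_config")
}

#' Gibbs sampling for the two-group Bayesian linear model
#'
#' Model: y = mu + beta * group + e, e ~ Normal(0, sigma2), with flat
#' (noninformative) priors on the fixed effects and on the residual
#' variance. Location parameters are drawn jointly from their Normal full
#' conditional and sigma2 from its conditional under the Jeffreys 1/sigma2
#' reference prior, inverse-gamma(n/2, SSE/2) -- the choice whose marginal
#' posterior for `beta` is exactly Student-t with n - 2 degrees of freedom.
#' Chains start from over-dispersed residual variances; burn-in is discarded
#' and the remainder thinned by `lag`. `beta` is the mean of the second
#' group level minus the first.
#'
#' @param y numeric vector of per-sample values (one ALR variable).
#' @param groups two-level labels, each group >= 2 samples.
#' @param cfg a [gibbs_config()].
#' @return list with `draws` (pooled matrix over chains, columns `mu`,
#'   `beta`, `sigma2`), `chains` (list of per-chain matrices), `levels`
#'   (group level order: beta = level2 - level1).
#' @export
gibbs_two_group <- function(y, groups, cfg = gibbs_config()) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("need exactly two groups")
  if (any(table(g) < 2)) stop("each group needs >= 2 samples")
  if (length(y) - 2 <= 0) stop("zero residual degrees of freedom")
  ind <- as.integer(g) - 1L
  set.seed(cfg$seed)
  disp <- exp(seq(-2, 2, length.out = max(cfg$chains, 2)))[seq_len(cfg$chains)]
  chains <- lapply(seq_len(cfg$chains), function(i)
    gibbs_lm_chain(y, ind, cfg$iterations, cfg$burn_in, cfg$lag,
                   sigma2_start = stats::var(y) * disp[i]))
  list(draws = do.call(rbind, chains), chains = chains, levels = levels(g))
}

#' Summarise posterior draws of a group difference
#'
#' meanDiff is the posterior mean of the group difference divided by the
#' variable's sample SD; P0 is the posterior probability that the
#' difference lies on the side of zero indicated by the sign of its mean;
#' PEP = (1 - P0) / 0.5; hpd95 is the shortest interval holding 95% of the
#' draws, in SD units.
#'
#' @param draws matrix from [gibbs_two_group()] (column `beta` used) or a
#'   numeric vector of difference draws.
#' @param y_sd the variable's sample SD (> 0) used for scaling.
#' @return list with `mean_diff_sd`, `P0`, `pep`, `hpd95` (length-2 vector).
#' @export
summarize_posterior <- function(draws, y_sd) {
  b <- if (is.matrix(draws)) draws[, "beta"] else as.numeric(draws)
  if (length(b) < 100) stop("need >= 100 retained draws")
  if (!is.numeric(y_sd) || y_sd <= 0) stop("y_sd must be positive")
  m <- mean(b)
  p0 <- if (m >= 0) mean(b > 0) else mean(b < 0)
  # if the mean and the median straddle zero the larger side is reported,
  # keeping P0 in [0.5, 1] as defined
  p0 <- max(p0, 1 - p0)
  pep <- min(1, (1 - p0) / 0.5)
  list(mean_diff_sd = m / y_sd, P0 = p0, pep = pep, hpd95 = hpd_interval(b) / y_sd)
}

# shortest interval containing prob of the sorted draws
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  k <- max(1, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Split-chain R-hat convergence diagnostic
#'
#' Each chain is split in half; the potential scale reduction factor is
#' computed over the split halves. Values near 1 indicate convergence; the
#' default decision threshold is 1.05.
#'
#' @param chains list of numeric vectors (one per chain) or matrices (each
#'   column diagnosed separately).
#' @param threshold convergence cut-off (default 1.05).
#' @return list with `rhat` (named if inputs are matrices) and `converged`.
#' @export
rhat <- function(chains, threshold = 1.05) {
  if (is.matrix(chains[[1]])) {
    params <- colnames(chains[[1]])
    r <- vapply(params, function(p)
      rhat(lapply(chains, function(ch) ch[, p]), threshold)$rhat, 0)
    return(list(rhat = r, converged = all(r <= threshold)))
  }
  len <- min(lengths(chains))
  if (length(chains) < 1 || len < 100)
    stop("need chains of >= 100 retained draws (>= 50 per split half)")
  half <- len %/% 2
  splits <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(half)], ch[seq(half + 1, 2 * half)])), recursive = FALSE)
  m <- length(splits); n <- half
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, stats::var, 0)
  b <- n * stats::var(means)
  w <- mean(vars)
  r <- if (w <= .Machine$double.eps) 1 else sqrt(((n - 1) / n * w + b / n) / w)
  list(rhat = r, converged = r <= threshold)
}

#' Cumulative-PEP relevance selection (Bayesian FDR control)
#'
#' Variables are sorted by ascending PEP (ties broken by larger
#' |meanDiff|); the running mean of the sorted PEPs approximates the false
#' discovery rate of each prefix. The largest prefix whose cumulative mean
#' is at or below `threshold` is selected.
#'
#' @param summaries data.frame with columns `variable_id`, `pep`,
#'   `mean_diff_sd` (as produced by [differential_abundance()]), or a list
#'   of [summarize_posterior()] results with a `variable_id` each.
#' @param threshold cumulative-PEP cut-off (default 0.05).
#' @return character vector of selected variable IDs (possibly empty).
#' @export
cumulative_pep_selection <- function(summaries, threshold = 0.05) {
  df <- as.data.frame(summaries)
  ord <- order(df$pep, -abs(df$mean_diff_sd))
  peps <- df$pep[ord]
  cum <- cumsum(peps) / seq_along(peps)
  sel <- which(cum <= threshold + 1e-12)
  if (length(sel) == 0) return(character(0))
  df$variable_id[ord][seq_len(max(sel))]
}

#' Bayesian differential abundance over the variables of an ALR matrix
#'
#' Runs [gibbs_two_group()] on every ALR variable, summarises the posterior
#' of the group difference in SD units, checks convergence by split-chain
#' R-hat (one re-run with doubled iterations if needed), applies
#' cumulative-PEP selection across variables, and finally flags selected
#' variables whose |meanDiff| exceeds `effect_floor` (the reporting filter
#' for biologically sizeable shifts).
#'
#' @param alr an `alr_matrix` (samples x variables).
#' @param meta sample metadata (two groups).
#' @param cfg a [gibbs_config()].
#' @param threshold cumulative-PEP threshold (default 0.05).
#' @param effect_floor minimum |meanDiff| (SD units) for the `sizeable`
#'   flag (default 0.5).
#' @return data.frame, one row per variable: `variable_id`, `mean_diff_sd`,
#'   `P0`, `pep`, `hpd95_lower`, `hpd95_upper`, `rhat_beta`, `converged`,
#'   `cumulative_pep` (in PEP order; NA ordering preserved per variable),
#'   `relevant` (cumulative-PEP selected), `sizeable` (relevant and above
#'   the effect floor).
#' @export
differential_abundance <- function(alr, meta, cfg = gibbs_config(),
                                   threshold = 0.05, effect_floor = 0.5) {
  m <- unclass(alr)
  idx <- match(rownames(m), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata")
  groups <- factor(meta$group[idx])
  rows <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    yj <- m[, j]
    cfg_j <- cfg
    cfg_j$seed <- cfg$seed + j          # independent, reproducible per-variable streams
    fit <- gibbs_two_group(yj, groups, cfg_j)
    conv <- rhat(lapply(fit$chains, function(ch) ch[, "beta"]))
    if (!conv$converged) {              # one retry with doubled iterations
      cfg_j$iterations <- cfg_j$iterations * 2L
      fit <- gibbs_two_group(yj, groups, cfg_j)
      conv <- rhat(lapply(fit$chains, function(ch) ch[, "beta"]))
    }
    s <- summarize_posterior(fit$draws, stats::sd(yj))
    rows[[j]] <- data.frame(variable_id = colnames(m)[j],
                            mean_diff_sd = s$mean_diff_sd, P0 = s$P0,
                            pep = s$pep, hpd95_lower = s$hpd95[1],
                            hpd95_upper = s$hpd95[2], rhat_beta = conv$rhat,
                            converged = conv$converged)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$pep, -abs(out$mean_diff_sd))
  out$cumulative_pep[ord] <- cumsum(out$pep[ord]) / seq_along(ord)
  out$relevant <- out$variable_id %in% cumulative_pep_selection(out, threshold)
  out$sizeable <- out$relevant & abs(out$mean_diff_sd) > effect_floor
  out
}
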