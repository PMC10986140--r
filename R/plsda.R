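#' Fit a two-class PLS-DA model by NIPALS
#'
#' Predictors are auto-scaled (centered, unit variance); the class vector is
#' encoded as a centered two-column indicator matrix. Components are
#' extracted by the iterative NIPALS algorithm with X-deflation, which makes
#' the score vectors mutually orthogonal. Class centroids and the pooled
#' within-class covariance of the training scores are stored for
#' Mahalanobis-distance classification.
#'
#' @param X numeric matrix, samples x variables (e.g. an `alr_matrix`).
#' @param y two-level factor (or coercible), one label per row of X.
#' @param ncomp number of components to extract (capped at
#'   `min(nrow(X) - 1, ncol(X))`; extraction also stops early if the X
#'   residual is exhausted).
#' @param scale auto-scale X columns to unit variance (default TRUE).
#' @return A `plsda_model` list: scaling vectors, weights `W`, X-loadings
#'   `P`, Y-loadings `C`, scores `T`, per-component explained Y-variance
#'   `ssy`, class `levels`, `variable_ids`, `ncomp`.
#' @export
fit_plsda <- function(X, y, ncomp, scale = TRUE) {
  X <- as_plain_matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("PLS-DA here is two-class; got ", nlevels(y), " level(s)")
  if (any(table(y) < 2)) stop("each class needs >= 2 samples")
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  sdv <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(sdv < 1e-12)) {
    bad <- colnames(X)[sdv < 1e-12]
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  E <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  F_ <- scale(Y, center = TRUE, scale = FALSE)
  A <- min(ncomp, n - 1, p)
  W <- matrix(0, p, A); P <- matrix(0, p, A); C <- matrix(0, 2, A)
  Tm <- matrix(0, n, A); ssy <- numeric(A)
  a <- 0
  for (comp in seq_len(A)) {
    u <- F_[, which.max(colSums(F_^2))]
    if (sum(u^2) < 1e-12) break
    t_old <- rep(Inf, n)
    for (iter in 1:500) {
      w <- crossprod(E, u) / sum(u^2)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      t_ <- as.vector(E %*% w)
      cc <- crossprod(F_, t_) / sum(t_^2)
      u <- as.vector(F_ %*% cc) / sum(cc^2)
      if (sqrt(sum((t_ - t_old)^2)) < 1e-10 * sqrt(sum(t_^2))) break
      t_old <- t_
    }
    if (sqrt(sum(w^2)) < 1e-12 || sum(t_^2) < 1e-12) break
    pl <- crossprod(E, t_) / sum(t_^2)
    a <- a + 1
    W[, a] <- w; P[, a] <- pl; C[, a] <- cc; Tm[, a] <- t_
    ssy[a] <- sum(cc^2) * sum(t_^2)      # Y-variance captured by this component
    E <- E - tcrossprod(t_, pl)
    F_ <- F_ - tcrossprod(t_, cc)
  }
  if (a == 0) stop("no component could be extracted (X residual exhausted)")
  keep <- seq_len(a)
  structure(list(mu = mu, sdv = sdv, scale = scale,
                 W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
                 C = C[, keep, drop = FALSE], T = Tm[, keep, drop = FALSE],
                 ssy = ssy[keep], y = y, levels = levels(y),
                 variable_ids = colnames(X), ncomp = a),
            class = "plsda_model")
}

as_plain_matrix <- function(X) {
  m <- unclass(as.matrix(X))
  attr(m, "ref_id") <- NULL
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  m
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d components, %d variables, classes %s/%s\n",
              x$ncomp, length(x$variable_ids), x$levels[1], x$levels[2]))
  invisible(x)
}

# project new samples into score space, truncated at ncomp components,
# reproducing the NIPALS deflation sequence
plsda_scores <- function(model, Xnew, ncomp = model$ncomp) {
  Xnew <- as_plain_matrix(Xnew)
  if (!all(model$variable_ids %in% colnames(Xnew)))
    stop("new data lacks model variables")
  E <- sweep(sweep(Xnew[, model$variable_ids, drop = FALSE], 2, model$mu),
             2, model$sdv, "/")
  k <- min(ncomp, model$ncomp)
  Tm <- matrix(0, nrow(E), k)
  for (a in seq_len(k)) {
    Tm[, a] <- E %*% model$W[, a]
    E <- E - tcrossprod(Tm[, a], model$P[, a])
  }
  Tm
}

# centroids and pooled within-class covariance of the training scores,
# truncated at ncomp
score_geometry <- function(model, ncomp = model$ncomp) {
  k <- min(ncomp, model$ncomp)
  Tm <- model$T[, seq_len(k), drop = FALSE]
  cent <- lapply(model$levels, function(l) colMeans(Tm[model$y == l, , drop = FALSE]))
  names(cent) <- model$levels
  pooled <- matrix(0, k, k)
  for (l in model$levels) {
    Ti <- Tm[model$y == l, , drop = FALSE]
    pooled <- pooled + crossprod(sweep(Ti, 2, colMeans(Ti)))
  }
  pooled <- pooled / (nrow(Tm) - 2)
  if (k == 1) pooled <- matrix(pooled, 1, 1)
  inv <- tryCatch({
    if (rcond(pooled) < 1e-10) stop("near-singular")
    solve(pooled)
  }, error = function(e) {
    ridge <- 1e-8 * sum(diag(pooled))
    if (isTRUE(getOption("micropls.verbose")))
      message("predict: near-singular score covariance; ridge ", signif(ridge, 3), " added")
    solve(pooled + diag(ridge, k))
  })
  list(centroids = cent, inv_cov = inv, ncomp = k)
}

#' Classify samples with a fitted PLS-DA model
#'
#' New samples are projected into the training score space and assigned to
#' the class whose centroid is nearest under the Mahalanobis metric of the
#' pooled within-class score covariance. Exact ties go to the
#' alphabetically first class label.
#'
#' @param object a `plsda_model`.
#' @param Xnew matrix with the model's variables.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.plsda_model <- function(object, Xnew, ncomp = object$ncomp, ...) {
  geom <- score_geometry(object, ncomp)
  Tm <- plsda_scores(object, Xnew, geom$ncomp)
  d2 <- sapply(object$levels, function(l) {
    diff <- sweep(Tm, 2, geom$centroids[[l]])
    rowSums((diff %*% geom$inv_cov) * diff)
  })
  d2 <- matrix(d2, ncol = 2, dimnames = list(NULL, object$levels))
  lv <- sort(object$levels)                       # tie -> first alphabetically
  pick <- ifelse(d2[, lv[1]] <= d2[, lv[2]], lv[1], lv[2])
  factor(pick, levels = object$levels)
}

#' Confusion counts for a two-class prediction
#'
#' @param truth,predicted factors over the same two levels.
#' @param positive label treated as the positive class (default: first
#'   level of `truth`).
#' @return list of class `confusion_counts` with integer `TP`, `FP`, `TN`,
#'   `FN` and the `positive` label.
#' @export
confusion_counts <- function(truth, predicted, positive = levels(factor(truth))[1]) {
  truth <- factor(truth); predicted <- factor(predicted, levels = levels(truth))
  pos <- truth == positive
  list2cc(TP = sum(pos & predicted == positive),
          FP = sum(!pos & predicted == positive),
          TN = sum(!pos & predicted != positive),
          FN = sum(pos & predicted != positive),
          positive = positive)
}

list2cc <- function(TP, FP, TN, FN, positive) {
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN),
                 positive = positive), class = "confusion_counts")
}

#' Balanced error rate
#'
#' BER = 0.5 * (FP / (TN + FP) + FN / (FN + TP)): the average of the two
#' per-class error rates, insensitive to class imbalance.
#'
#' @param c a `confusion_counts` object (or list with TP/FP/TN/FN).
#' @return BER in \[0, 1\].
#' @export
balanced_error_rate <- function(c) {
  if ((c$TN + c$FP) == 0 || (c$FN + c$TP) == 0)
    stop("empty class: BER undefined")
  0.5 * (c$FP / (c$TN + c$FP) + c$FN / (c$FN + c$TP))
}

stratified_folds <- function(y, folds) {
  y <- factor(y)
  if (any(table(y) < folds))
    stop("each class needs at least ", folds, " samples for ", folds, "-fold CV")
  f <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

# one stratified CV pass: per-fold confusion at each candidate ncomp
cv_pass <- function(X, y, folds, max_ncomp, scale = TRUE) {
  fold_of <- stratified_folds(y, folds)
  res <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- fold_of != k
    fit <- fit_plsda(X[tr, , drop = FALSE], y[tr], ncomp = max_ncomp, scale = scale)
    per_ncomp <- lapply(seq_len(fit$ncomp), function(a) {
      pred <- predict(fit, X[!tr, , drop = FALSE], ncomp = a)
      confusion_counts(y[!tr], pred, positive = levels(factor(y))[1])
    })
    res[[k]] <- per_ncomp
  }
  res
}

#' Cross-validated component selection by balanced error rate
#'
#' Stratified k-fold cross-validation, repeated; for every candidate
#' component count the mean and SD of the per-fold BER are recorded. The
#' chosen count is the smallest whose mean BER lies within one SD of the
#' global minimum (parsimony-first one-SD rule).
#'
#' @param X predictor matrix; `y` two-level labels.
#' @param y class labels.
#' @param max_ncomp largest component count to consider (default 10).
#' @param folds folds per repeat (default 4, stratified).
#' @param repeats CV repeats (default 100).
#' @param seed integer seed.
#' @param scale auto-scale X (default TRUE).
#' @return A `cv_report` list: `ber_mean`, `ber_sd` (per component count),
#'   `chosen_ncomp`, `folds`, `repeats`, `seed`.
#' @export
cross_validate <- function(X, y, max_ncomp = 10, folds = 4, repeats = 100,
                           seed = 1L, scale = TRUE) {
  X <- as_plain_matrix(X); y <- factor(y)
  set.seed(seed)
  bers <- NULL
  for (r in seq_len(repeats)) {
    pass <- cv_pass(X, y, folds, max_ncomp, scale)
    amax <- min(vapply(pass, length, 1L))
    fold_ber <- t(vapply(pass, function(pf)
      vapply(seq_len(amax), function(a) balanced_error_rate(pf[[a]]), 0),
      numeric(amax)))
    if (amax == 1) fold_ber <- matrix(fold_ber, ncol = 1)
    bers <- if (is.null(bers)) fold_ber else {
      a <- min(ncol(bers), ncol(fold_ber))
      rbind(bers[, seq_len(a), drop = FALSE], fold_ber[, seq_len(a), drop = FALSE])
    }
  }
  ber_mean <- colMeans(bers)
  ber_sd <- apply(bers, 2, stats::sd)
  best <- which.min(ber_mean)
  chosen <- min(which(ber_mean <= ber_mean[best] + ber_sd[best]))
  structure(list(ber_mean = ber_mean, ber_sd = ber_sd, chosen_ncomp = chosen,
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_report")
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a ), with SS_a
#' the Y-variance explained by component a and p the number of variables;
#' mean(VIP^2) = 1 by construction.
#'
#' @param model a fitted `plsda_model`.
#' @return named numeric vector of VIP scores (one per variable).
#' @export
vip <- function(model) {
  W <- model$W
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  p <- nrow(W)
  v <- sqrt(p * as.vector(wn^2 %*% model$ssy) / sum(model$ssy))
  names(v) <- model$variable_ids
  v
}

#' Iterative VIP-filtered PLS-DA model selection
#'
#' Repeats: cross-validate the component count, fit, keep variables with
#' VIP > 1, refit and re-validate. A shrinkage step is accepted if its mean
#' BER did not increase by more than one SD of the previous accepted BER;
#' the loop stops at rejection, at a fixed point (variable set unchanged),
#' when selection would empty the variable set (warning; previous model
#' kept), or when the BER plateaus -- once shrinking no longer strictly
#' improves the cross-validated BER the model has reached its highest
#' classification performance and further VIP filtering would only discard
#' informative variables.
#'
#' @inheritParams cross_validate
#' @return list with `model` (final accepted `plsda_model`), `cv` (its
#'   `cv_report`), `selected` (variable IDs), and `history` (per-iteration
#'   variable count, chosen ncomp, mean and SD of BER).
#' @export
iterative_vip_selection <- function(X, y, max_ncomp = 10, folds = 4,
                                    repeats = 100, seed = 1L, scale = TRUE) {
  X <- as_plain_matrix(X); y <- factor(y)
  vars <- colnames(X)
  accepted <- NULL
  history <- list()
  iter_seed <- seed
  repeat {
    iter_seed <- iter_seed + 1L
    cv <- cross_validate(X[, vars, drop = FALSE], y, max_ncomp, folds,
                         repeats, seed = iter_seed, scale = scale)
    ber <- cv$ber_mean[cv$chosen_ncomp]
    if (!is.null(accepted) && ber > accepted$ber + accepted$ber_sd)
      break                                   # shrinkage degraded the model: reject it
    improved <- is.null(accepted) || ber < accepted$ber
    model <- fit_plsda(X[, vars, drop = FALSE], y, cv$chosen_ncomp, scale = scale)
    accepted <- list(model = model, cv = cv, vars = vars,
                     ber = ber, ber_sd = cv$ber_sd[cv$chosen_ncomp])
    history[[length(history) + 1]] <-
      data.frame(n_vars = length(vars), ncomp = cv$chosen_ncomp,
                 ber_mean = ber, ber_sd = accepted$ber_sd)
    if (!improved) break                      # BER plateaued: highest performance reached
    sel <- names(which(vip(model) > 1))
    if (length(sel) == 0) {
      warning("VIP selection emptied the variable set; keeping previous model")
      break
    }
    if (setequal(sel, vars)) break
    vars <- sel
  }
  list(model = accepted$model, cv = accepted$cv, selected = accepted$vars,
       history = do.call(rbind, history))
}

#' Final classification performance by repeated cross-validation
#'
#' Repeated stratified CV of the selected model specification (its variables
#' and component count); confusion counts are aggregated over all repeats
#' and folds, and per-class true-positive rates TP/(TP+FN) are derived.
#'
#' @param X predictor matrix (all variables; the model's subset is used).
#' @param y class labels.
#' @param model a `plsda_model` supplying `variable_ids` and `ncomp`.
#' @param folds folds per repeat (default 4).
#' @param repeats CV repeats (default 10000).
#' @param seed integer seed.
#' @return list with `confusion` (aggregated `confusion_counts`),
#'   `class_rates` (named per-class true-positive rates), `ber`, `repeats`,
#'   `seed`.
#' @export
final_performance <- function(X, y, model, folds = 4, repeats = 10000, seed = 1L) {
  X <- as_plain_matrix(X)[, model$variable_ids, drop = FALSE]
  y <- factor(y)
  set.seed(seed)
  agg <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (r in seq_len(repeats)) {
    pass <- cv_pass(X, y, folds, model$ncomp, scale = model$scale)
    for (pf in pass) {
      cc <- pf[[min(model$ncomp, length(pf))]]
      agg <- agg + c(TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN)
    }
  }
  pos <- levels(y)[1]; neg <- levels(y)[2]
  cc <- list2cc(agg["TP"], agg["FP"], agg["TN"], agg["FN"], positive = pos)
  rates <- c(agg[["TP"]] / (agg[["TP"]] + agg[["FN"]]),
             agg[["TN"]] / (agg[["TN"]] + agg[["FP"]]))
  names(rates) <- c(pos, neg)
  list(confusion = cc, class_rates = rates, ber = balanced_error_rate(cc),
       repeats = repeats, seed = seed)
}

#' Permutation test of PLS-DA classification performance
#'
#' Class labels are permuted (class sizes preserved), the cross-validated
#' classification is re-run on each permutation, and the null distribution
#' of the mean per-class true-positive rate is compared with the observed
#' rate using the add-one p-value estimator.
#'
#' @inheritParams final_performance
#' @param n_perm number of label permutations (default 10000).
#' @return A `permutation_report` list: `observed_rates`, `observed_mean`,
#'   `null_rates` (n_perm x 2 matrix), `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(X, y, model, n_perm = 10000, folds = 4, seed = 1L) {
  X <- as_plain_matrix(X)[, model$variable_ids, drop = FALSE]
  y <- factor(y)
  set.seed(seed)
  one_cv_rates <- function(labels) {
    pass <- cv_pass(X, labels, folds, model$ncomp, scale = model$scale)
    agg <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (pf in pass) {
      cc <- pf[[min(model$ncomp, length(pf))]]
      agg <- agg + c(TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN)
    }
    c(agg[["TP"]] / (agg[["TP"]] + agg[["FN"]]),
      agg[["TN"]] / (agg[["TN"]] + agg[["FP"]]))
  }
  obs <- one_cv_rates(y)
  null <- t(replicate(n_perm, one_cv_rates(sample(y))))
  colnames(null) <- levels(y)
  names(obs) <- levels(y)
  p <- (sum(rowMeans(null) >= mean(obs)) + 1) / (n_perm + 1)
  structure(list(observed_rates = obs, observed_mean = mean(obs),
                 null_rates = null, p_value = p, n_permutations = n_perm,
                 seed = seed),
            class = "permutation_report")
}
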