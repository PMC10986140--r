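# small in-code fixtures shared across test files

toy_table <- function(m = NULL, level = "ASV") {
  if (is.null(m)) {
    m <- matrix(c(6, 2, 0, 4,
                  2, 2, 1, 0,
                  3, 0, 5, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), paste0("f", 1:4)))
  }
  count_table(m, level = level)
}

toy_meta <- function(ids, groups) data.frame(sample_id = ids, group = groups,
                                             stringsAsFactors = FALSE)

random_table <- function(n = 6, p = 8, lambda = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  m[rowSums(m) == 0, 1] <- 1    # no empty samples
  count_table(m)
}

# two clearly separated Gaussian classes in q informative variables
separable_xy <- function(n_per = 10, p = 5, q = p, delta = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  X[seq_len(n_per), seq_len(q)] <- X[seq_len(n_per), seq_len(q)] + delta
  y <- factor(rep(c("A", "B"), each = n_per))
  list(X = X, y = y)
}

# small but complete pipeline configuration used across workflow tests
small_cfg <- function(delta = 2, n_diff = 10, seed = 5, out = NULL) {
  pipeline_config(
    synthetic = synthetic_spec(n_per_group = c(16, 16), n_features = 120,
                               n_genera = 20, depth_range = c(2000, 6000),
                               depth_mean = 4000, n_diff = n_diff,
                               delta_sd = delta, seed = seed),
    comparison = "TEST", rarefaction_depth = 1500, cv_repeats = 8,
    final_repeats = 10, n_permutations = 19, diversity_permutations = 99,
    gibbs = gibbs_config(iterations = 6000, burn_in = 500, chains = 2, seed = 1),
    seed = seed, output_dir = out)
}

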