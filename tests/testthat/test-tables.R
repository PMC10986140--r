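test_that("count table constructor enforces its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(count_table(m), "count_table")
  m_neg <- m; m_neg[1, 2] <- -1
  expect_error(count_table(m_neg), "negative count.*'a'.*'y'")
  m_dup <- m; rownames(m_dup) <- c("a", "a")
  expect_error(count_table(m_dup), "duplicate sample")
  m_frac <- m; m_frac[1, 1] <- 1.5
  expect_error(count_table(m_frac), "integer-valued")
})

test_that("TSV round-trip is the identity, both orientations", {
  tb <- random_table(5, 7, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tb, path)
  back <- read_count_table(path)
  expect_identical(back$counts, tb$counts)

  # transposed dialect
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(feature_id = colnames(tb$counts), t(tb$counts), check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_count_table(tpath, orientation = "features-as-rows")
  expect_identical(back_t$counts, tb$counts)
})

test_that("read_count_table names the offending cell on parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t3\toops", "s2\t1\t2"), path)
  expect_error(read_count_table(path), "'oops'.*'s1'.*'f2'")
  expect_error(read_count_table("/nonexistent/file.tsv"), "no such file")
})

test_that("prevalence filter applies the inclusive per-group rule", {
  meta <- toy_meta(paste0("s", 1:4), c("A", "A", "B", "B"))
  m <- matrix(c(1, 5, 0, 1,   # f1: 50% in A (1 of 2), 100% in B -> kept? A: s1=1,s2=5 both>0
                0, 3, 0, 2,
                4, 1, 3, 0,
                2, 0, 1, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:4)))
  # per feature presence: f1 A=2/2 B=2/2; f2 A=1/2 B=1/2; f3 A=2/2 B=2/2(s3=3,s4=1)?
  tb <- count_table(m)
  out <- prevalence_filter(tb, meta, 0.5)
  # f4: A presence 2/2 (2,0 -> s1=1? recompute from matrix columns)
  pres <- sapply(c(A = 1, B = 3), function(i) colSums(m[i:(i + 1), ] > 0) / 2)
  expected <- colnames(m)[pres[, 1] >= 0.5 & pres[, 2] >= 0.5]
  expect_identical(colnames(out$counts), expected)
  # exactly-50% presence in each group is retained (inclusive rule)
  expect_true("f2" %in% colnames(out$counts))
  # present everywhere in one group, absent in the other -> removed
  m2 <- m; m2[, 2] <- c(3, 4, 0, 0)
  out2 <- prevalence_filter(count_table(m2), meta, 0.5)
  expect_false("f2" %in% colnames(out2$counts))
  # idempotence
  expect_identical(prevalence_filter(out, meta, 0.5)$counts, out$counts)
  # sample set unchanged
  expect_identical(rownames(out$counts), rownames(m))
})

test_that("pseudocount shifts every cell and rejects nonpositive values", {
  tb <- toy_table()
  out <- add_pseudocount(tb, 1)
  expect_equal(out$counts, tb$counts + 1)
  expect_true(all(out$counts > 0))
  expect_equal(min(out$counts), min(tb$counts) + 1)
  zeros <- count_table(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(unname(add_pseudocount(zeros, 1)$counts), matrix(1, 2, 2))
  expect_error(add_pseudocount(tb, 0), "positive")
  # after the pseudocount no feature can fail a prevalence screen
  meta <- toy_meta(paste0("s", 1:3), c("A", "A", "B"))
  expect_equal(ncol(prevalence_filter(out, meta, 1)$counts), ncol(out$counts))
})

test_that("genus collapsing sums lineages and conserves totals", {
  m <- matrix(c(3, 4, 5,
                1, 0, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  tb <- count_table(m)
  tax <- parse_taxonomy(c("a1", "a2", "a3"),
                        c("d__B;p__F;c__C;o__O;f__X;g__G1",
                          "d__B;p__F;c__C;o__O;f__X;g__G1",
                          "d__B;p__F;c__C;o__Oscillospirales"))
  out <- collapse_to_genus(tb, tax)
  expect_equal(ncol(out$counts), 2)
  expect_equal(unname(out$counts[, 1]), c(3 + 4, 1 + 0))       # same genus summed
  expect_true("order:Oscillospirales" %in% colnames(out$counts))  # mixed-rank label
  expect_equal(rowSums(out$counts), rowSums(tb$counts))        # conservation
  expect_identical(out$level, "genus")
  # all distinct genera -> relabeled identity
  tax2 <- parse_taxonomy(c("a1", "a2", "a3"),
                         sprintf("d__B;p__F;c__C;o__O;f__X;g__G%d", 1:3))
  out2 <- collapse_to_genus(tb, tax2)
  expect_equal(unname(out2$counts), unname(tb$counts))
  # missing taxonomy entries are named
  expect_error(collapse_to_genus(tb, tax[1:2, ]), "a3")
})

test_that("rarefaction subsamples exactly, reproducibly, and drops shallow samples", {
  tb <- random_table(5, 10, lambda = 30, seed = 7)
  depth <- min(rowSums(tb$counts)) - 5
  r1 <- rarefy(tb, depth, seed = 42)
  r2 <- rarefy(tb, depth, seed = 42)
  expect_identical(r1$counts, r2$counts)                # bit-reproducible
  expect_true(all(rowSums(r1$counts) == depth))
  expect_true(all(r1$counts <= tb$counts))              # without replacement
  # sample with total exactly depth passes through unchanged
  m <- tb$counts; m[1, ] <- 0; m[1, 1:4] <- c(depth - 3, 1, 1, 1)
  ex <- rarefy(count_table(m), depth, seed = 1)
  expect_equal(unname(ex$counts[1, ]), unname(m[1, ]))
  # under-depth samples dropped and reported
  m2 <- tb$counts; m2[2, ] <- 0; m2[2, 1] <- depth - 1
  expect_message(r3 <- rarefy(count_table(m2), depth, seed = 1), "dropping 1 sample")
  expect_identical(attr(r3, "dropped"), rownames(m2)[2])
  expect_error(rarefy(tb, 10 * sum(tb$counts), seed = 1), "exceeds every sample")
})

test_that("rarefied counts match the hypergeometric expectation", {
  m <- matrix(c(40, 30, 20, 10), 1, 4,
              dimnames = list("s1", paste0("f", 1:4)))
  m <- rbind(m, s2 = c(25, 25, 25, 25))
  tb <- count_table(m)
  depth <- 50
  n_seeds <- 1000
  sims <- vapply(seq_len(n_seeds),
                 function(s) rarefy(tb, depth, seed = s)$counts["s1", "f1"], 0)
  expected <- depth * 40 / 100
  # hypergeometric variance, SE of the Monte-Carlo mean
  v <- depth * 0.4 * 0.6 * (100 - depth) / (100 - 1)
  expect_lt(abs(mean(sims) - expected), 3 * sqrt(v / n_seeds))
})

test_that("PCA outlier screen removes constructed outliers and nothing else", {
  set.seed(5)
  n <- 40
  m <- matrix(rpois(n * 12, 50), n, 12,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:12)))
  tb <- count_table(m)
  # homogeneous cloud, generous threshold: nothing removed
  res <- pca_outlier_screen(tb, k_sd = 6)
  expect_length(res$removed, 0)
  # k_sd = Inf is the identity
  res_inf <- pca_outlier_screen(tb, k_sd = Inf)
  expect_identical(res_inf$table$counts, tb$counts)
  # one sample with a wildly different composition is removed
  m_out <- m; m_out[3, ] <- c(5000, rep(1, 11))
  res_out <- pca_outlier_screen(count_table(m_out), k_sd = 3)
  expect_identical(res_out$removed, "s03")
  expect_error(pca_outlier_screen(count_table(m[1:2, ])), "3 samples")
})
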