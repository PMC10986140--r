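#' Pipeline configuration for a two-group comparison
#'
#' Collects every tunable of the end-to-end analysis. Either the three input
#' paths (`counts`, `taxonomy`, `metadata`) or a [synthetic_spec()] must be
#' supplied.
#'
#' @param counts,taxonomy,metadata TSV paths (see [read_count_table()],
#'   [read_taxonomy()], [read_metadata()]); `taxonomy` may be NULL when no
#'   genus collapsing is requested.
#' @param synthetic a [synthetic_spec()] instead of input files.
#' @param comparison name used in reports (e.g. "DLINES").
#' @param rarefaction_depth even depth for the diversity branch.
#' @param min_prev per-group prevalence threshold (default 0.5).
#' @param pseudocount offset added before log-ratios (default 1).
#' @param k_sd PCA outlier-screen threshold in SD units (default 3).
#' @param max_ncomp,folds,cv_repeats PLS-DA cross-validation settings
#'   (defaults 10 components, fourfold, 100 repeats).
#' @param final_repeats repeats for the final confusion matrix (default
#'   10000).
#' @param n_permutations label permutations for the PLS-DA permutation test
#'   (default 10000).
#' @param diversity_permutations permutations for PERMANOVA/PERMDISP
#'   (default 999).
#' @param gibbs a [gibbs_config()].
#' @param pep_threshold cumulative-PEP threshold (default 0.05).
#' @param effect_floor |meanDiff| reporting floor in SD units (default 0.5).
#' @param bayes_all_variables run the Bayesian stage on all ALR variables
#'   instead of only the PLS-DA-selected ones (default FALSE, mirroring the
#'   reference workflow).
#' @param seed master seed; stage seeds are derived from it.
#' @param output_dir directory for report files, or NULL to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                            synthetic = NULL, comparison = "comparison",
                            rarefaction_depth = 10000, min_prev = 0.5,
                            pseudocount = 1, k_sd = 3, max_ncomp = 10,
                            folds = 4, cv_repeats = 100, final_repeats = 10000,
                            n_permutations = 10000,
                            diversity_permutations = 999,
                            gibbs = gibbs_config(), pep_threshold = 0.05,
                            effect_floor = 0.5, bayes_all_variables = FALSE,
                            seed = 1L, output_dir = NULL) {
  if (is.null(synthetic) && (is.null(counts) || is.null(metadata)))
    stop("supply either input paths (counts + metadata) or a synthetic spec")
  stopifnot(min_prev >= 0, min_prev <= 1, pseudocount > 0,
            pep_threshold > 0, pep_threshold <= 1, effect_floor >= 0)
  cfg <- list(counts = counts, taxonomy = taxonomy, metadata = metadata,
              synthetic = synthetic, comparison = comparison,
              rarefaction_depth = rarefaction_depth, min_prev = min_prev,
              pseudocount = pseudocount, k_sd = k_sd, max_ncomp = max_ncomp,
              folds = folds, cv_repeats = cv_repeats,
              final_repeats = final_repeats, n_permutations = n_permutations,
              diversity_permutations = diversity_permutations, gibbs = gibbs,
              pep_threshold = pep_threshold, effect_floor = effect_floor,
              bayes_all_variables = bayes_all_variables,
              seed = as.integer(seed), output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

load_inputs <- function(cfg, level = "ASV") {
  if (!is.null(cfg$synthetic)) {
    ds <- generate_dataset(cfg$synthetic)
  } else {
    ds <- list(table = read_count_table(cfg$counts, level = level),
               taxonomy = if (!is.null(cfg$taxonomy)) read_taxonomy(cfg$taxonomy),
               metadata = read_metadata(cfg$metadata),
               truth = NULL)
  }
  ds
}

stage_seed <- function(cfg, offset) (cfg$seed * 97L + offset) %% .Machine$integer.max

diversity_branch <- function(table, meta, cfg) {
  rare <- rarefy(table, cfg$rarefaction_depth, seed = stage_seed(cfg, 11L))
  meta_r <- meta[meta$sample_id %in% sample_ids(rare), , drop = FALSE]
  alpha <- alpha_indices(rare)
  g <- meta_r$group[match(alpha$sample_id, meta_r$sample_id)]
  alpha_tests <- lapply(c("observed", "shannon", "pielou"), function(ix) {
    ok <- !is.na(alpha[[ix]])
    kruskal_wallis(alpha[[ix]][ok], g[ok])
  })
  names(alpha_tests) <- c("observed", "shannon", "pielou")
  beta <- list()
  for (metric in c("bray_curtis", "jaccard")) {
    dm <- if (metric == "bray_curtis") bray_curtis(rare) else jaccard(rare)
    pmv <- permanova(dm, meta_r, n_perm = cfg$diversity_permutations,
                     seed = stage_seed(cfg, 13L))
    pdp <- permdisp(dm, meta_r, n_perm = cfg$diversity_permutations,
                    seed = stage_seed(cfg, 17L))
    beta[[metric]] <- list(
      permanova = pmv, permdisp = pdp,
      # a significant dispersion test invalidates the location verdict
      verdict = if (pdp$p_value < 0.05) "discarded (PERMDISP significant)"
                else if (pmv$p_value < 0.05) "significant" else "not significant")
  }
  list(rarefied = rare, dropped = attr(rare, "dropped"), alpha = alpha,
       alpha_tests = alpha_tests, beta = beta)
}

discriminant_branch <- function(table, meta, cfg) {
  filtered <- prevalence_filter(table, meta, cfg$min_prev)
  screened <- pca_outlier_screen(filtered, cfg$k_sd)
  meta_s <- meta[meta$sample_id %in% sample_ids(screened$table), , drop = FALSE]
  pseudo <- add_pseudocount(screened$table, cfg$pseudocount)
  ref <- select_alr_reference(pseudo)
  alr <- alr_transform(pseudo, ref)
  proc <- procrustes_correlation(alr, pseudo)
  y <- factor(meta_s$group[match(rownames(alr), meta_s$sample_id)])
  sel <- iterative_vip_selection(alr, y, max_ncomp = cfg$max_ncomp,
                                 folds = cfg$folds, repeats = cfg$cv_repeats,
                                 seed = stage_seed(cfg, 23L))
  perf <- final_performance(alr, y, sel$model, folds = cfg$folds,
                            repeats = cfg$final_repeats,
                            seed = stage_seed(cfg, 29L))
  perm <- permutation_test(alr, y, sel$model, n_perm = cfg$n_permutations,
                           folds = cfg$folds, seed = stage_seed(cfg, 31L))
  list(filtered = filtered, removed_outliers = screened$removed,
       reference = as.character(ref), alr = alr, procrustes = proc,
       selection = sel, performance = perf, permutation = perm,
       metadata = meta_s)
}

#' Run the full two-group comparison pipeline
#'
#' Executes the three branches on one count table: (1) diversity — rarefy,
#' alpha indices with Kruskal-Wallis, Bray-Curtis/Jaccard with PERMANOVA and
#' PERMDISP (a location verdict is discarded when the dispersion test is
#' significant); (2) discriminant — prevalence filter, PCA outlier screen,
#' pseudocount, ALR with Procrustes check, iterative VIP-filtered PLS-DA,
#' final confusion matrix and permutation test; (3) Bayesian differential
#' abundance on the PLS-DA-selected ALR variables. Rarefaction is used only
#' by the diversity branch.
#'
#' @param cfg a [pipeline_config()].
#' @param level run at `"ASV"` (default) or `"genus"` level (requires
#'   taxonomy when collapsing is needed).
#' @return A `comparison_report` list with elements `comparison`, `config`,
#'   `data`, `diversity`, `discriminant`, `bayes`, and `seeds`; written to
#'   `cfg$output_dir` as TSV/JSON when configured.
#' @export
run_comparison <- function(cfg, level = c("ASV", "genus")) {
  level <- match.arg(level)
  stopifnot(inherits(cfg, "pipeline_config"))
  ds <- tryCatch(load_inputs(cfg), error = function(e)
    stop("stage 'load': ", conditionMessage(e), call. = FALSE))
  table <- ds$table
  if (level == "genus") {
    if (is.null(ds$taxonomy)) stop("stage 'collapse': taxonomy required")
    table <- collapse_to_genus(table, ds$taxonomy)
  }
  run_stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' [", cfg$comparison, "]: ", conditionMessage(e),
         call. = FALSE))
  div <- run_stage("diversity", diversity_branch(table, ds$metadata, cfg))
  disc <- run_stage("plsda", discriminant_branch(table, ds$metadata, cfg))
  bayes_vars <- if (cfg$bayes_all_variables) colnames(disc$alr)
                else disc$selection$selected
  alr_sub <- disc$alr[, bayes_vars, drop = FALSE]
  gibbs <- cfg$gibbs
  gibbs$seed <- stage_seed(cfg, 37L)
  da <- run_stage("bayes", differential_abundance(
    structure(alr_sub, class = c("alr_matrix", "matrix")),
    disc$metadata, gibbs, cfg$pep_threshold, cfg$effect_floor))
  report <- structure(
    list(comparison = cfg$comparison, level = level, config = cfg,
         data = ds, diversity = div, discriminant = disc, bayes = da,
         seeds = list(master = cfg$seed)),
    class = "comparison_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' Collapse to genus level and rerun the pipeline
#'
#' Runs [run_comparison()] at genus level and cross-references the two
#' levels' selected variables: for every selected genus, which of its
#' selected ASVs (if any) were picked by the ASV-level model.
#'
#' @param cfg a [pipeline_config()] (taxonomy required).
#' @param asv_report an existing ASV-level `comparison_report`, or NULL to
#'   compute it.
#' @return list with `asv`, `genus` (the two reports) and `cross_reference`
#'   (data.frame genus, n_selected_asv).
#' @export
collapse_and_rerun <- function(cfg, asv_report = NULL) {
  if (is.null(asv_report)) asv_report <- run_comparison(cfg, level = "ASV")
  genus_report <- run_comparison(cfg, level = "genus")
  tax <- asv_report$data$taxonomy
  sel_asv <- asv_report$discriminant$selection$selected
  sel_gen <- genus_report$discriminant$selection$selected
  genus_of_asv <- genus_label(tax)[match(sel_asv, tax$feature_id)]
  xref <- data.frame(genus = sel_gen,
                     n_selected_asv = vapply(sel_gen, function(gl)
                       sum(genus_of_asv == gl, na.rm = TRUE), 0L),
                     row.names = NULL)
  list(asv = asv_report, genus = genus_report, cross_reference = xref)
}

# collapsed-feature label of each taxonomy row, mirroring collapse_to_genus
genus_label <- function(tax) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  apply(tax[ranks], 1, function(lin) {
    if (!is.na(lin[6])) return(paste(lin, collapse = ";"))
    deepest <- max(c(0L, which(!is.na(lin))))
    if (deepest == 0L) "unassigned" else paste0(ranks[deepest], ":", lin[deepest])
  })
}

#' Write a comparison report bundle to disk
#'
#' Emits alpha records, distance test results, CV/permutation summaries and
#' the differential-abundance table as TSV/JSON under `dir`, plus a
#' `manifest.json` embedding the config (with its hash) and all seeds.
#'
#' @param report a `comparison_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  cfg$synthetic <- unclass(cfg$synthetic)
  cfg$gibbs <- unclass(cfg$gibbs)
  cfg$output_dir <- NULL    # where a run is written must not change what it contains
  manifest <- list(comparison = report$comparison, level = report$level,
                   config = unclass(cfg), config_hash = rlang::hash(cfg),
                   seed = report$seeds$master,
                   reference = report$discriminant$reference,
                   procrustes = report$discriminant$procrustes,
                   removed_outliers = report$discriminant$removed_outliers,
                   dropped_by_rarefaction = report$diversity$dropped,
                   alpha_tests = report$diversity$alpha_tests,
                   beta = lapply(report$diversity$beta, function(b)
                     list(permanova_p = b$permanova$p_value,
                          permdisp_p = b$permdisp$p_value,
                          verdict = b$verdict)),
                   class_rates = as.list(report$discriminant$performance$class_rates),
                   permutation_p = report$discriminant$permutation$p_value)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  utils::write.table(report$diversity$alpha, file.path(dir, "alpha.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$discriminant$selection$history,
                     file.path(dir, "cv_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(variable_id = report$discriminant$selection$selected),
                     file.path(dir, "selected_variables.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$bayes, file.path(dir, "differential_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
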