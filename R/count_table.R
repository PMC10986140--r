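#' Construct a count table
#'
#' The universal substrate of the pipeline: a samples x features matrix of
#' non-negative integer abundances with unique sample and feature identifiers,
#' tagged with the taxonomic level of its features.
#'
#' @param counts numeric matrix, samples in rows, features in columns. Must be
#'   non-negative and integer-valued; dimnames supply the identifiers.
#' @param level feature level, `"ASV"` or `"genus"`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix with dimnames) and `level`.
#' @export
count_table <- function(counts, level = c("ASV", "genus")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs sample (row) and feature (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at sample '", rownames(counts)[bad[1]],
         "', feature '", colnames(counts)[bad[2]], "'")
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integer-valued")
  storage.mode(counts) <- "double"   # doubles carry integer counts exactly; avoids 32-bit overflow on totals
  structure(list(counts = counts, level = level), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d %s features, %s total reads\n",
              nrow(x$counts), ncol(x$counts), x$level,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

sample_ids <- function(table) rownames(table$counts)
feature_ids <- function(table) colnames(table$counts)

assert_count_table <- function(table) {
  if (!inherits(table, "count_table")) stop("expected a count_table")
  invisible(table)
}

#' Read a count table from TSV
#'
#' The native dialect has samples as rows (first column sample IDs, header row
#' feature IDs); `orientation = "features-as-rows"` reads the transposed
#' dialect used by some exporters.
#'
#' @param path TSV file path.
#' @param level feature level of the table.
#' @param orientation `"samples-as-rows"` (default) or `"features-as-rows"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, level = "ASV",
                             orientation = c("samples-as-rows", "features-as-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", m[bad[1], bad[2]], "' at row '", ids[bad[1]],
         "', column '", colnames(m)[bad[2]], "' in ", path)
  }
  rownames(num) <- ids
  if (orientation == "features-as-rows") num <- t(num)
  count_table(num, level = level)
}

#' Write a count table to TSV (samples as rows)
#'
#' @param table a [count_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  assert_count_table(table)
  df <- data.frame(sample_id = sample_ids(table),
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, group) from TSV
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return data.frame with character columns `sample_id`, `group`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata needs columns sample_id and group")
  validate_metadata(df)
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample IDs in metadata")
  meta
}

#' Align metadata with a table and check the two-group contract
#' @noRd
group_factor <- function(table, meta) {
  idx <- match(sample_ids(table), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(sample_ids(table)[is.na(idx)], collapse = ", "))
  g <- factor(meta$group[idx])
  if (nlevels(g) != 2)
    stop("exactly two group levels required, found: ",
         paste(levels(g), collapse = ", "))
  if (any(table(g) == 0)) stop("a group has zero samples")
  g
}

#' Read a taxonomy map from TSV
#'
#' Two columns: feature ID and a semicolon-separated lineage string in the
#' QIIME2 style (`d__...;p__...;c__...;o__...;f__...;g__...`). Ranks absent
#' from the string are treated as unassigned.
#'
#' @param path TSV file path (header row required; first two columns used).
#' @return data.frame with columns `feature_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`; unassigned ranks are `NA`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  parse_taxonomy(df[[1]], df[[2]])
}

#' Build a taxonomy map from lineage strings
#'
#' @param feature_id character vector of feature IDs.
#' @param lineage character vector of semicolon-separated lineage strings.
#' @return data.frame as in [read_taxonomy()].
#' @export
parse_taxonomy <- function(feature_id, lineage) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  prefix <- c("d__", "p__", "c__", "o__", "f__", "g__")
  parts <- strsplit(lineage, ";", fixed = TRUE)
  out <- matrix(NA_character_, length(feature_id), length(ranks),
                dimnames = list(NULL, ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    for (r in seq_along(ranks)) {
      hit <- p[startsWith(p, prefix[r])]
      if (length(hit)) {
        val <- sub(prefix[r], "", hit[1], fixed = TRUE)
        if (nzchar(val)) out[i, r] <- val
      }
    }
  }
  data.frame(feature_id = feature_id, out, stringsAsFactors = FALSE)
}

#' Write a taxonomy map to TSV (lineage-string dialect)
#' @param tax taxonomy data.frame from [parse_taxonomy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  prefix <- c("d__", "p__", "c__", "o__", "f__", "g__")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  lineage <- apply(tax[ranks], 1, function(v) {
    keep <- !is.na(v)
    paste0(prefix[keep], v[keep], collapse = ";")
  })
  utils::write.table(data.frame(feature_id = tax$feature_id, lineage = lineage),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
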