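# Readers/writers for count matrices, coverage tables and trees.

#' Read / write a feature-by-genome count matrix
#'
#' TSV with features as rows; first column `feature_id`, remaining columns
#' one per genome. All entries must be non-negative integers.
#'
#' @param path file path.
#' @return integer matrix with feature rownames and genome colnames.
#' @export
read_count_matrix <- function(path) {
  .check_file(path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) g_abort("count matrix has no genome columns", "no_genomes", path = path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  validate_count_matrix(m)
}

#' @rdname read_count_matrix
#' @param m count matrix.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: non-negative integer entries and unique
#' row/column labels.
#' @param m matrix to validate.
#' @return the matrix, in integer storage mode.
#' @export
validate_count_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    g_abort("count matrix must have row and column labels", "unlabelled_matrix")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    g_abort("count matrix labels must be unique", "duplicate_labels")
  if (any(is.na(m)) || any(m < 0))
    g_abort("counts must be non-negative", "negative_counts")
  if (any(m != round(m)))
    g_abort("counts must be integers", "non_integer_counts")
  storage.mode(m) <- "integer"
  m
}

#' Construct a validated coverage table
#'
#' Sample-by-genome mapped-read counts plus per-sample totals and per-genome
#' lengths; the substrate of presence/absence and relative-abundance calls.
#' Unmapped reads are allowed (row sums may fall short of the total), but no
#' single cell may exceed its sample's total.
#'
#' @param mapped_reads integer matrix, samples in rows, genomes in columns.
#' @param total_reads named per-sample totals (> 0).
#' @param genome_lengths named per-genome lengths in bp (> 0).
#' @return object of class `coverage_table`.
#' @export
coverage_table <- function(mapped_reads, total_reads, genome_lengths) {
  if (ncol(mapped_reads) == 0L) g_abort("coverage table has no genomes", "no_genomes")
  if (nrow(mapped_reads) == 0L) g_abort("coverage table has no samples", "no_samples")
  if (any(mapped_reads != round(mapped_reads)) || any(mapped_reads < 0))
    g_abort("mapped read counts must be non-negative integers", "non_integer_counts")
  storage.mode(mapped_reads) <- "double"  # counts can exceed .Machine$integer.max
  total_reads <- total_reads[rownames(mapped_reads)]
  genome_lengths <- genome_lengths[colnames(mapped_reads)]
  if (any(is.na(total_reads)) || any(total_reads <= 0))
    g_abort("every sample needs a positive total_reads", "bad_totals",
            sample_id = rownames(mapped_reads)[is.na(total_reads) | total_reads <= 0])
  if (any(is.na(genome_lengths)) || any(genome_lengths <= 0))
    g_abort("every genome needs a positive length", "bad_lengths")
  bad <- which(mapped_reads > matrix(total_reads, nrow(mapped_reads),
                                     ncol(mapped_reads)), arr.ind = TRUE)
  if (nrow(bad))
    g_abort("mapped reads exceed sample total", "mapped_exceeds_total",
            sample_id = rownames(mapped_reads)[bad[, 1L]],
            genome_id = colnames(mapped_reads)[bad[, 2L]])
  structure(list(mapped_reads = mapped_reads,
                 total_reads = total_reads,
                 genome_lengths = genome_lengths),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("<coverage_table> %d samples x %d genomes\n",
              nrow(x$mapped_reads), ncol(x$mapped_reads)))
  invisible(x)
}

#' Read / write a coverage table
#'
#' Format: `##genome_length <genome> <bp>` header lines, then a TSV body with
#' columns `sample_id`, `total_reads` and one column per genome holding
#' mapped-read counts.
#' @param path file path.
#' @return a [coverage_table()].
#' @export
read_coverage <- function(path) {
  .check_file(path)
  lines <- readLines(path)
  pragma <- grep("^##genome_length\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "##")]
  df <- read.delim(text = paste(body, collapse = "\n"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "total_reads") %in% names(df)))
    g_abort("coverage table needs sample_id and total_reads columns",
            "bad_coverage_table", path = path)
  gcols <- setdiff(names(df), c("sample_id", "total_reads"))
  if (!length(gcols)) g_abort("coverage table has no genomes", "no_genomes", path = path)
  if (!length(pragma))
    g_abort("coverage table lacks ##genome_length header lines",
            "bad_coverage_table", path = path)
  parts <- strsplit(pragma, "\t", fixed = TRUE)
  lens <- stats::setNames(as.numeric(vapply(parts, `[`, "", 3L)),
                          vapply(parts, `[`, "", 2L))
  m <- as.matrix(df[, gcols, drop = FALSE])
  rownames(m) <- df$sample_id
  coverage_table(m, stats::setNames(df$total_reads, df$sample_id), lens)
}

#' @rdname read_coverage
#' @param cov a [coverage_table()].
#' @export
write_coverage <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##genome_length\t%s\t%d", names(cov$genome_lengths),
                     as.integer(cov$genome_lengths)), con)
  df <- data.frame(sample_id = rownames(cov$mapped_reads),
                   total_reads = cov$total_reads,
                   cov$mapped_reads, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cov)
}

#' Read a rooted tree with branch lengths from a newick file
#'
#' Missing branch lengths default to zero with a logged warning; duplicate
#' tip labels and malformed newick raise typed errors.
#' @param path newick file.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  .check_file(path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) g_abort(paste0("newick parse failure: ",
                                                    conditionMessage(e)),
                                             "tree_parse", path = path))
  if (is.null(tr)) g_abort("newick parse failure", "tree_parse", path = path)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree an `ape::phylo` object.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    g_abort("duplicate tip labels", "duplicate_tips",
            tip = unique(tree$tip.label[duplicated(tree$tip.label)]))
  if (is.null(tree$edge.length)) {
    g_warn("tree has no branch lengths; defaulting to 0", "no_branch_lengths")
    g_log("branch lengths missing, set to 0", level = "WARN")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    g_abort("branch lengths must be >= 0", "negative_branch_lengths")
  tree
}
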