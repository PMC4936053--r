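# CAZy family profiling: count and percent matrices per genome, plus the
# normalisations consumed by guild inference (median-of-ratios size factors
# and a shifted-log variance-stabilising transform for display/clustering).

#' Build a CAZy family-by-genome count matrix
#'
#' The counting unit is gene-by-family: a gene annotated with k distinct
#' CAZy families contributes 1 to each of the k rows (dbCAN-style
#' annotations are domain-level). Rows are the families observed in at
#' least one genome, sorted; columns follow the input order.
#'
#' @param annotations list of [genome_annotation()] objects.
#' @return integer count matrix (families x genomes).
#' @export
build_cazy_matrix <- function(annotations) {
  stopifnot(length(annotations) >= 1L)
  ids <- vapply(annotations, function(a) a$genome_id, "")
  if (anyDuplicated(ids))
    g_abort("duplicate genome ids", "duplicate_genome", genome_id = ids[duplicated(ids)])
  per <- lapply(annotations, function(a) {
    h <- a$hits[a$hits$namespace == "CAZY", c("gene_id", "accession")]
    h <- unique(h)  # one count per gene x family
    table(h$accession)
  })
  fams <- sort(unique(unlist(lapply(per, names))))
  m <- matrix(0L, length(fams), length(ids), dimnames = list(fams, ids))
  for (j in seq_along(per)) m[names(per[[j]]), j] <- as.integer(per[[j]])
  empty <- colSums(m) == 0L
  if (any(empty))
    g_warn(paste("genomes with no CAZy-annotated genes:",
                 paste(ids[empty], collapse = ", ")), "empty_genome")
  validate_count_matrix(m)
}

#' Convert counts to percent-of-CAZy profiles
#'
#' Each genome column is expressed as a percentage of that genome's total
#' CAZy gene count, so columns sum to 100 for genomes with at least one
#' CAZy gene. All-zero columns stay zero, with a warning.
#'
#' @param m count matrix (families x genomes).
#' @return numeric matrix of percentages, same shape as `m`.
#' @export
percent_of_cazy <- function(m) {
  tot <- colSums(m)
  if (any(tot == 0))
    g_warn(paste("all-zero genome columns:",
                 paste(colnames(m)[tot == 0], collapse = ", ")), "empty_genome")
  sweep(m, 2, ifelse(tot == 0, 1, tot), "/") * 100
}

#' Median-of-ratios size factors
#'
#' The normalisation of count-based differential abundance models: per
#' genome, the median ratio of its counts to the per-family geometric mean
#' across genomes, rescaled so the size factors have geometric mean 1.
#' Families with a zero anywhere carry no information under the default
#' reference; when no family is positive in every genome the function
#' either stops (default) or, with `fallback = "positive"`, computes each
#' family's geometric mean over its positive counts only.
#'
#' @param m count matrix (families x genomes).
#' @param fallback `"error"` or `"positive"`.
#' @return named numeric vector of per-genome size factors (> 0).
#' @export
size_factors <- function(m, fallback = c("error", "positive")) {
  fallback <- match.arg(fallback)
  lm <- log(m)
  ref <- rowMeans(lm)            # -Inf where any zero
  usable <- is.finite(ref)
  if (!any(usable)) {
    if (fallback == "error")
      g_abort(paste("no family has nonzero counts in every genome;",
                    "rerun with fallback = 'positive' to use a",
                    "positive-count pseudo-reference"), "no_reference_features")
    g_log("size_factors: using positive-count pseudo-reference", level = "WARN")
    ref <- apply(lm, 1L, function(r) mean(r[is.finite(r)]))
    usable <- is.finite(ref)
  }
  s <- apply(lm[usable, , drop = FALSE], 2L, function(col) {
    d <- col - ref[usable]
    exp(median(d[is.finite(d)]))
  })
  if (any(!is.finite(s)) || any(s <= 0))
    g_abort("degenerate size factors", "no_reference_features")
  s / exp(mean(log(s)))
}

#' Shifted-log variance stabilisation
#'
#' `log2(count / s_g + 1)` on size-factor-normalised counts: a monotone
#' stand-in for a fitted variance-stabilising transform, used for
#' clustering, heatmaps and ordination only — inference runs on raw counts.
#'
#' @param m count matrix.
#' @param s size factors from [size_factors()].
#' @return numeric matrix.
#' @export
stabilize <- function(m, s = size_factors(m)) {
  stopifnot(all(s > 0), length(s) == ncol(m))
  log2(sweep(m, 2, s, "/") + 1)
}

#' Most abundant families for display
#'
#' The heatmap scope used for guild visualisation: the `n` most abundant
#' families (by total count across genomes) matching `pattern`, ties broken
#' lexicographically.
#'
#' @param m count matrix.
#' @param n number of families to keep.
#' @param pattern regular expression on family ids (default: glycoside
#'   hydrolase families).
#' @return character vector of family ids.
#' @export
top_families <- function(m, n = 30L, pattern = "^GH") {
  keep <- grep(pattern, rownames(m), value = TRUE)
  tot <- rowSums(m[keep, , drop = FALSE])
  ord <- order(-tot, keep)
  utils::head(keep[ord], n)
}
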