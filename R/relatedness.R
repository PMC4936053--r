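# Genome relatedness: fragment-based average nucleotide identity (the Goris
# ANIb procedure), reciprocal-best-hit average amino acid identity, and
# single-linkage partitioning of a pairwise percent matrix.

#' Parameters for fragment-based ANI
#'
#' The Goris criteria: 1020-bp consecutive fragments, a fragment retained
#' when its best local alignment reaches >= 30 % identity over >= 70 % of
#' the fragment length; identity is computed over all alignment columns,
#' gaps included. Alignment scoring: match +1, mismatch -2, gap open -5,
#' gap extend -2 (affine; the opening position costs `gap_open`).
#'
#' @param fragment_len fragment length in bp (>= 100).
#' @param min_identity,min_aln_frac retention thresholds in (0, 1].
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return an `ani_params` list.
#' @export
ani_params <- function(fragment_len = 1020L, min_identity = 0.30,
                       min_aln_frac = 0.70, match = 1L, mismatch = -2L,
                       gap_open = -5L, gap_extend = -2L) {
  if (fragment_len < 100L) g_abort("fragment_len must be >= 100", "bad_params")
  if (min_identity <= 0 || min_identity > 1 || min_aln_frac <= 0 || min_aln_frac > 1)
    g_abort("retention fractions must be in (0, 1]", "bad_params")
  structure(as.list(environment()), class = "ani_params")
}

DNA_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

.encode_dna <- function(x) {
  v <- DNA_CODE[strsplit(toupper(x), "")[[1]]]
  v[is.na(v)] <- 4L
  unname(v)
}

.revcomp_code <- function(v) {
  # A<->T, C<->G in code space; N stays N
  comp <- c(3L, 2L, 1L, 0L, 4L)
  rev(comp[v + 1L])
}

.load_dna <- function(x) {
  # accepts a file path, a Biostrings set, or character contig sequences;
  # returns list of integer-coded contigs
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet"))
    x <- as.character(x)
  lapply(unname(as.character(x)), .encode_dna)
}

.dna_score_matrix <- function(p) {
  sm <- matrix(p$mismatch, 5L, 5L)
  diag(sm) <- p$match
  sm[5L, ] <- sm[, 5L] <- p$mismatch  # N matches nothing
  storage.mode(sm) <- "integer"
  sm
}

# Best local alignment of a (short) query against a (long) target:
# score-only pass to find the optimum end, then a windowed traceback. The
# window is query length + 600 bp, wider than any positive-scoring local
# alignment can span under the affine penalties used here.
.align_fragment <- function(frag, target, sm, p) {
  be <- .sw_best_end(frag, target, sm, p$gap_open, p$gap_extend)
  if (be[1L] <= 0L)
    return(list(score = 0L, identity = 0, coverage = 0))
  lo <- max(1L, be[3L] - (length(frag) + 600L))
  tb <- .sw_traceback(frag, target[lo:be[3L]], sm, p$gap_open, p$gap_extend)
  list(score = tb$score,
       identity = if (tb$aln_len > 0) tb$matches / tb$aln_len else 0,
       coverage = (tb$qend - tb$qstart + 1L) / length(frag))
}

.ani_one_direction <- function(query_contigs, target, sm, p) {
  ids <- numeric(0)
  n_frag <- 0L
  for (ctg in query_contigs) {
    n_full <- length(ctg) %/% p$fragment_len
    if (n_full == 0L) next
    for (k in seq_len(n_full)) {
      n_frag <- n_frag + 1L
      frag <- ctg[((k - 1L) * p$fragment_len + 1L):(k * p$fragment_len)]
      fwd <- .align_fragment(frag, target, sm, p)
      hit <- fwd
      retained <- fwd$identity >= p$min_identity && fwd$coverage >= p$min_aln_frac
      if (!retained) {
        rev <- .align_fragment(.revcomp_code(frag), target, sm, p)
        if (rev$score > fwd$score) hit <- rev
        retained <- hit$identity >= p$min_identity &&
          hit$coverage >= p$min_aln_frac
      }
      if (retained) ids <- c(ids, hit$identity)
    }
  }
  list(identities = ids, n_fragments = n_frag, n_used = length(ids))
}

#' Fragment-based average nucleotide identity (Goris method)
#'
#' Genome A is cut into consecutive non-overlapping fragments (trailing
#' remainders discarded); each fragment is aligned locally against genome B
#' (both strands, exact affine-gap alignment) and retained when it passes
#' the identity/coverage thresholds. `ani_ab` is 100 times the mean retained
#' identity; the reciprocal direction is computed the same way and
#' `ani_mean` averages the two. With no retained fragments the direction is
#' reported below detection (`NA`), never 0.
#'
#' @param a,b genomes: FASTA paths, `Biostrings::DNAStringSet`s, or
#'   character vectors of contig sequences.
#' @param params an [ani_params()].
#' @return an `ani_result`: list with `ani_ab`, `ani_ba`, `ani_mean`,
#'   `below_detection`, per-direction fragment tallies and identities.
#' @export
goris_ani <- function(a, b, params = ani_params()) {
  stopifnot(inherits(params, "ani_params"))
  ca <- .load_dna(a); cb <- .load_dna(b)
  if (sum(lengths(ca)) < 10000L || sum(lengths(cb)) < 10000L)
    g_abort("genomes must be >= 10 kb", "genome_too_short")
  sm <- .dna_score_matrix(params)
  # multi-contig targets are concatenated with an N spacer so no alignment
  # can bridge two contigs profitably
  glue <- function(ctgs) {
    if (length(ctgs) == 1L) return(ctgs[[1L]])
    spacer <- rep(4L, 50L)
    out <- ctgs[[1L]]
    for (i in 2L:length(ctgs)) out <- c(out, spacer, ctgs[[i]])
    out
  }
  ab <- .ani_one_direction(ca, glue(cb), sm, params)
  ba <- .ani_one_direction(cb, glue(ca), sm, params)
  ani_ab <- if (ab$n_used) 100 * mean(ab$identities) else NA_real_
  ani_ba <- if (ba$n_used) 100 * mean(ba$identities) else NA_real_
  structure(list(ani_ab = ani_ab, ani_ba = ani_ba,
                 ani_mean = mean(c(ani_ab, ani_ba)),
                 below_detection = ab$n_used == 0L && ba$n_used == 0L,
                 n_fragments_ab = ab$n_fragments, n_used_ab = ab$n_used,
                 n_fragments_ba = ba$n_fragments, n_used_ba = ba$n_used,
                 identities_ab = ab$identities, identities_ba = ba$identities,
                 params = params),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  if (x$below_detection) {
    cat("<ani_result> below detection (no fragment passed retention)\n")
  } else {
    cat(sprintf("<ani_result> ANI %.2f%% (A->B %.2f%% on %d/%d; B->A %.2f%% on %d/%d)\n",
                x$ani_mean, x$ani_ab, x$n_used_ab, x$n_fragments_ab,
                x$ani_ba, x$n_used_ba, x$n_fragments_ba))
  }
  invisible(x)
}

.load_protein <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readAAStringSet(x)
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet"))
    x <- stats::setNames(as.character(x), names(x))
  if (is.null(names(x))) names(x) <- sprintf("p%04d", seq_along(x))
  x
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = environment())
      cache <<- get("BLOSUM62", envir = environment())
    }
    cache
  }
})

#' Reciprocal best-hit average amino acid identity
#'
#' All-versus-all exact local alignment under BLOSUM62 (gap open -11,
#' extend -1); orthologs are reciprocal best hits passing the identity and
#' shorter-sequence coverage thresholds; AAI is the mean ortholog identity.
#' Each protein participates in at most one pair. With zero accepted RBHs
#' the AAI is reported below detection (`NA`).
#'
#' @param a,b proteomes: FASTA paths, `Biostrings::AAStringSet`s, or named
#'   character vectors (>= 10 proteins each).
#' @param min_identity,min_coverage acceptance thresholds.
#' @param gap_open,gap_extend affine gap scores.
#' @return an `aai_result`: list with `aai`, `n_rbh`, the ortholog-pair
#'   table and the thresholds used.
#' @export
rbh_aai <- function(a, b, min_identity = 0.30, min_coverage = 0.70,
                    gap_open = -11L, gap_extend = -1L) {
  pa <- .load_protein(a); pb <- .load_protein(b)
  if (length(pa) < 10L || length(pb) < 10L)
    g_abort("proteomes must have >= 10 proteins", "proteome_too_small")
  sm <- .blosum62()
  alpha <- colnames(sm)
  enc <- function(s) {
    v <- match(strsplit(s, "")[[1]], alpha) - 1L
    v[is.na(v)] <- match("*", alpha) - 1L
    v
  }
  ea <- lapply(pa, enc); eb <- lapply(pb, enc)
  storage.mode(sm) <- "integer"
  na <- length(ea); nb <- length(eb)
  score <- matrix(0L, na, nb); ident <- matrix(0, na, nb); cov <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    tb <- .sw_traceback(ea[[i]], eb[[j]], sm, gap_open, gap_extend)
    score[i, j] <- tb$score
    ident[i, j] <- if (tb$aln_len) tb$matches / tb$aln_len else 0
    shorter <- min(length(ea[[i]]), length(eb[[j]]))
    consumed <- min(tb$qend - tb$qstart + 1L, tb$tend - tb$tstart + 1L)
    cov[i, j] <- consumed / shorter
  }
  best_ab <- apply(score, 1L, which.max)
  best_ba <- apply(score, 2L, which.max)
  pairs <- list()
  for (i in seq_len(na)) {
    j <- best_ab[i]
    if (best_ba[j] == i && ident[i, j] >= min_identity && cov[i, j] >= min_coverage)
      pairs[[length(pairs) + 1L]] <- data.frame(
        protein_a = names(pa)[i], protein_b = names(pb)[j],
        identity = ident[i, j], coverage = cov[i, j], score = score[i, j],
        stringsAsFactors = FALSE)
  }
  rbh <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(protein_a = character(), protein_b = character(),
               identity = numeric(), coverage = numeric(), score = integer())
  structure(list(aai = if (nrow(rbh)) 100 * mean(rbh$identity) else NA_real_,
                 n_rbh = nrow(rbh), below_detection = nrow(rbh) == 0L,
                 pairs = rbh,
                 thresholds = list(min_identity = min_identity,
                                   min_coverage = min_coverage)),
            class = "aai_result")
}

#' Single-linkage partition of a pairwise percent matrix
#'
#' Clusters are the connected components of the graph whose edges join
#' genome pairs with similarity above (strictly, by default, matching the
#' "ANI > 95 %" species rule) the threshold.
#'
#' @param mat symmetric pairwise matrix (percent).
#' @param threshold linking threshold.
#' @param strict_greater use `>` (default) rather than `>=`.
#' @return a `cluster_partition`: list with `partition` (named genome ->
#'   cluster id), `n_clusters`, `threshold`.
#' @export
cluster_at_threshold <- function(mat, threshold, strict_greater = TRUE) {
  if (!isTRUE(nrow(mat) == ncol(mat)) ||
      max(abs(mat - t(mat)), na.rm = TRUE) > 1e-6)
    g_abort("matrix must be symmetric", "asymmetric_matrix")
  ids <- rownames(mat)
  adj <- if (strict_greater) mat > threshold else mat >= threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  structure(list(partition = stats::setNames(comp$membership, ids),
                 n_clusters = comp$no, threshold = threshold,
                 linkage = "single"),
            class = "cluster_partition")
}
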