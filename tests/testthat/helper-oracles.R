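# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, exhaustive enumeration and
# edge-marking, so agreement is evidence rather than tautology.

options(guildomics.verbose = FALSE)

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# IndVal by direct looping over families and groups
oracle_indval_stat <- function(m, f) {
  ks <- levels(f)
  stat <- numeric(nrow(m))
  for (j in seq_len(nrow(m))) {
    means <- occ <- numeric(length(ks))
    for (k in seq_along(ks)) {
      x <- m[j, f == ks[k]]
      means[k] <- mean(x)
      occ[k] <- mean(x > 0)
    }
    if (sum(means) == 0) { stat[j] <- 0; next }
    stat[j] <- max(100 * (means / sum(means)) * occ)
  }
  stat
}

# Exact permutation p for two groups: enumerate every distinct assignment of
# group-1 positions, p = proportion of assignments whose max-indval statistic
# reaches the observed one (the identity assignment is included, so p > 0).
oracle_exact_indval_p <- function(m, f) {
  n <- ncol(m)
  n1 <- sum(f == levels(f)[1L])
  obs <- oracle_indval_stat(m, f)
  sets <- utils::combn(n, n1)
  hits <- numeric(nrow(m))
  for (c in seq_len(ncol(sets))) {
    fp <- factor(ifelse(seq_len(n) %in% sets[, c], levels(f)[1L], levels(f)[2L]),
                 levels = levels(f))
    hits <- hits + (oracle_indval_stat(m, fp) >= obs - 1e-12)
  }
  hits / ncol(sets)
}

# Faith's PD by edge marking: an edge is on a tip-to-root path iff any target
# tip descends from it; without the root, it must also NOT subtend all of them.
oracle_faith_pd <- function(tree, tips, include_root = TRUE) {
  tip_idx <- match(tips, tree$tip.label)
  below <- function(node) {
    if (node <= length(tree$tip.label)) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  pd <- 0
  for (e in seq_len(nrow(tree$edge))) {
    sub <- below(tree$edge[e, 2])
    n_in <- length(intersect(sub, tip_idx))
    keep <- if (include_root) n_in >= 1 else (n_in >= 1 && n_in < length(tip_idx))
    if (keep) pd <- pd + tree$edge.length[e]
  }
  pd
}

# A toy annotation builder for hand-constructed neighbourhood tests
toy_annotation <- function(genome_id = "toy", contig_len = 50000L, genes,
                           hits = NULL) {
  genome_annotation(genome_id,
                    stats::setNames(rep(contig_len, length(unique(genes$contig_id))),
                                    unique(genes$contig_id)),
                    genes, hits)
}

# Annotations whose CAZy census reproduces a given count matrix exactly:
# one gene per count unit, genes spaced 1 kb apart on one contig.
annotations_from_counts <- function(m) {
  lapply(colnames(m), function(g) {
    n_genes <- sum(m[, g])
    n_genes <- max(n_genes, 1L)
    genes <- data.frame(contig_id = "c1",
                        gene_id = sprintf("%s_g%05d", g, seq_len(n_genes)),
                        start = seq_len(n_genes) * 1000L,
                        end = seq_len(n_genes) * 1000L + 800L,
                        strand = "+")
    fams <- rep(rownames(m), m[, g])
    hits <- if (length(fams))
      data.frame(gene_id = genes$gene_id[seq_along(fams)], accession = fams,
                 namespace = "CAZY") else NULL
    genome_annotation(g, c(c1 = n_genes * 1000L + 2000L), genes, hits)
  })
}
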