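# Trophic-guild inference: Bray-Curtis/average-linkage clustering of CAZy
# percent profiles, the Dufrene-Legendre indicator-value statistic with a
# permutation null, a negative-binomial Wald test for pairwise differential
# abundance, and the dual criterion that intersects the two.

.check_labels <- function(labels, genome_ids) {
  if (is.null(names(labels)) || !all(genome_ids %in% names(labels)))
    g_abort("labels must be a named vector covering every genome",
            "bad_labels", missing = setdiff(genome_ids, names(labels)))
  f <- factor(labels[genome_ids])
  if (any(table(f) == 0L)) f <- droplevels(f)
  if (nlevels(f) < 2L) g_abort("need at least two guilds", "bad_labels")
  f
}

#' Cluster genomes into candidate guilds
#'
#' Hierarchical clustering (average linkage) of dissimilarities between
#' genome percent profiles, cut into `K` groups. The default dissimilarity
#' is profile correlation distance (`1 - Pearson r`), which targets the
#' correlated multi-family enrichment pattern that defines a guild;
#' Bray-Curtis is available via `method = "bray"` but is dominated by
#' absolute differences in the most abundant families and recovers planted
#' guild structure less reliably (see the methods vignette). Deterministic
#' given the input column order; equal-dissimilarity merges follow the
#' clustering routine's input-order convention.
#'
#' @param profile percent matrix from [percent_of_cazy()] (families x genomes).
#' @param K number of guilds.
#' @param method `"correlation"` (default) or `"bray"`.
#' @return named character vector genome -> `"guild1" ... "guildK"`, with the
#'   `hclust` object in attribute `"hclust"`.
#' @export
cluster_guilds <- function(profile, K, method = c("correlation", "bray")) {
  method <- match.arg(method)
  if (K > ncol(profile)) g_abort("K exceeds the number of genomes", "bad_k")
  d <- switch(method,
              # zero-variance profiles yield NA correlations, caught below
              correlation = as.dist(1 - suppressWarnings(stats::cor(profile))),
              bray = vegan::vegdist(t(profile), method = "bray"))
  if (any(is.na(d)))
    g_abort("constant genome profiles have no defined correlation distance",
            "no_structure")
  if (all(d == 0))
    g_abort("all genome profiles identical: no structure to cluster",
            "no_structure")
  hc <- hclust(d, method = "average")
  cut <- cutree(hc, k = K)
  labels <- stats::setNames(paste0("guild", cut), names(cut))
  attr(labels, "hclust") <- hc
  labels
}

.group_means <- function(m, f) {
  # features x levels matrix of group means
  t(rowsum(t(m), f)) / matrix(as.numeric(table(f)), nrow(m), nlevels(f),
                              byrow = TRUE)
}

.indval_components <- function(m, f) {
  means <- .group_means(m, f)
  tot <- rowSums(means)
  A <- means / ifelse(tot == 0, 1, tot)
  A[tot == 0, ] <- 0
  B <- t(rowsum(0 + t(m > 0), f)) / matrix(as.numeric(table(f)), nrow(m),
                                       nlevels(f), byrow = TRUE)
  iv <- 100 * A * B
  colnames(iv) <- levels(f)
  list(A = A, B = B, indval = iv, stat = apply(iv, 1L, max),
       best = levels(f)[apply(iv, 1L, which.max)])  # ties -> lowest guild index
}

#' Indicator value analysis (IndVal)
#'
#' For family j and guild k, specificity `A = mean_jk / sum_k' mean_jk'`,
#' fidelity `B` = occupancy (fraction of guild-k genomes with a nonzero
#' count) and `indval = 100 A B`. The per-family statistic is the maximum
#' over guilds; its p-value comes from random relabelings preserving group
#' sizes, using the `(1 + b) / (1 + n_perm)` estimator, with BH adjustment
#' across families. All-zero families are reported with indval 0, p 1 and
#' `degenerate = TRUE`.
#'
#' @param m count matrix (families x genomes).
#' @param labels named genome -> guild vector.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation null.
#' @return an `indval_result`: list with matrices `A`, `B`, `indval` and a
#'   `summary` data.frame (family, best guild, stat, p, q, degenerate).
#' @export
indval <- function(m, labels, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) g_abort("n_perm must be >= 99", "bad_params")
  f <- .check_labels(labels, colnames(m))
  set.seed(seed)
  g_log("indval seed=", seed, " n_perm=", n_perm)
  obs <- .indval_components(m, f)
  degenerate <- rowSums(m) == 0L
  exceed <- integer(nrow(m))
  for (b in seq_len(n_perm)) {
    stat_b <- .indval_components(m, sample(f))$stat
    # tie-safe comparison: permuted statistics that are mathematically equal
    # to the observed one must count as exceedances regardless of
    # summation-order roundoff
    exceed <- exceed + (stat_b >= obs$stat - 1e-8)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[degenerate] <- 1
  structure(list(A = obs$A, B = obs$B, indval = obs$indval,
                 summary = data.frame(family = rownames(m),
                                      best_guild = obs$best,
                                      stat = obs$stat, p = p,
                                      q = p.adjust(p, "BH"),
                                      degenerate = degenerate,
                                      row.names = NULL),
                 n_perm = n_perm, seed = seed),
            class = "indval_result")
}

#' Negative-binomial Wald test for one guild pair
#'
#' Per family, a two-group negative-binomial model on size-factor-normalised
#' counts: method-of-moments dispersion (pooled within-group), shrunk 50/50
#' toward the across-family median and floored at 1e-8; log2 fold change
#' `log2((mu2 + 0.5) / (mu1 + 0.5))`; Wald standard error from the NB Fisher
#' information; two-sided normal p-values with BH adjustment within the
#' comparison. Families zero in both groups are excluded (logged).
#'
#' @param m count matrix (families x genomes).
#' @param labels named genome -> guild vector.
#' @param pair length-2 character vector `(k1, k2)`; positive fold changes
#'   mean enrichment in `k2`.
#' @param sf optional size factors for all genomes in `m`.
#' @return data.frame (family, base_mean1/2, lfc, se, z, p, q, direction)
#'   with attribute `"pair"`.
#' @export
nb_pairwise_da <- function(m, labels, pair, sf = NULL) {
  f <- .check_labels(labels, colnames(m))
  stopifnot(length(pair) == 2L, all(pair %in% levels(f)))
  if (is.null(sf)) sf <- size_factors(m, fallback = "positive")
  g1 <- colnames(m)[f == pair[1L]]
  g2 <- colnames(m)[f == pair[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    g_abort("both guilds need >= 2 genomes", "bad_labels", pair = pair)
  y1 <- sweep(m[, g1, drop = FALSE], 2, sf[g1], "/")
  y2 <- sweep(m[, g2, drop = FALSE], 2, sf[g2], "/")
  keep <- rowSums(m[, c(g1, g2)]) > 0
  if (any(!keep))
    g_log("nb_pairwise_da: dropping ", sum(!keep), " all-zero families")
  y1 <- y1[keep, , drop = FALSE]; y2 <- y2[keep, , drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  mu1 <- rowMeans(y1); mu2 <- rowMeans(y2)
  v1 <- apply(y1, 1L, var); v2 <- apply(y2, 1L, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mw <- ((n1 - 1) * mu1 + (n2 - 1) * mu2) / (n1 + n2 - 2)
  m2w <- ((n1 - 1) * mu1^2 + (n2 - 1) * mu2^2) / (n1 + n2 - 2)
  disp_mom <- pmax(0, (s2 - mw) / pmax(m2w, 1e-12))
  disp <- pmax(1e-8, 0.5 * disp_mom + 0.5 * median(disp_mom))
  mu1s <- mu1 + 0.5; mu2s <- mu2 + 0.5
  lfc <- log2(mu2s / mu1s)
  var_log <- (mu1s + disp * mu1s^2) / (n1 * mu1s^2) +
             (mu2s + disp * mu2s^2) / (n2 * mu2s^2)
  se <- sqrt(var_log) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(family = rownames(m)[keep],
                    base_mean1 = mu1, base_mean2 = mu2,
                    dispersion = disp, lfc = lfc, se = se, z = z, p = p,
                    q = p.adjust(p, "BH"),
                    direction = ifelse(lfc > 0, pair[2L],
                                       ifelse(lfc < 0, pair[1L], NA_character_)),
                    row.names = NULL)
  attr(out, "pair") <- pair
  out
}

#' All pairwise differential-abundance comparisons
#'
#' Runs [nb_pairwise_da()] on every unordered guild pair with shared size
#' factors.
#' @inheritParams nb_pairwise_da
#' @return named list of comparison data.frames (`"k1|k2"`).
#' @export
nb_all_pairs <- function(m, labels, sf = NULL) {
  f <- .check_labels(labels, colnames(m))
  if (is.null(sf)) sf <- size_factors(m, fallback = "positive")
  ks <- levels(f)
  out <- list()
  for (i in seq_along(ks)) for (j in seq_along(ks)) if (i < j) {
    out[[paste(ks[i], ks[j], sep = "|")]] <-
      nb_pairwise_da(m, labels, c(ks[i], ks[j]), sf = sf)
  }
  out
}

#' Guild-defining enzyme families by the dual criterion
#'
#' A family defines guild k iff (i) its IndVal best guild is k with
#' `q <= alpha`, and (ii) it is enriched in k versus *every* other guild at
#' `q <= alpha` with the fold change pointing toward k.
#'
#' @param iv an `indval_result` from [indval()].
#' @param da_pairs list from [nb_all_pairs()] covering every unordered pair.
#' @param labels named genome -> guild vector.
#' @param alpha BH-adjusted significance threshold.
#' @return a `guild_definition`: list with `labels`, `alpha` and `defining`,
#'   a guild -> character-vector map of defining families.
#' @export
define_guild_enzymes <- function(iv, da_pairs, labels, alpha = 0.05) {
  stopifnot(inherits(iv, "indval_result"))
  guilds <- sort(unique(as.character(labels)))
  need <- utils::combn(guilds, 2L, function(p) paste(p, collapse = "|"))
  if (!all(need %in% names(da_pairs)))
    g_abort("da_pairs must cover every unordered guild pair",
            "missing_pair", missing = setdiff(need, names(da_pairs)))
  sm <- iv$summary
  defining <- stats::setNames(vector("list", length(guilds)), guilds)
  for (k in guilds) {
    cand <- sm$family[sm$best_guild == k & sm$q <= alpha & !sm$degenerate]
    for (other in setdiff(guilds, k)) {
      key <- paste(sort(c(k, other)), collapse = "|")
      da <- da_pairs[[key]]
      pair <- attr(da, "pair")
      sign_needed <- if (pair[2L] == k) 1 else -1
      ok <- da$family[da$q <= alpha & sign(da$lfc) == sign_needed]
      cand <- intersect(cand, ok)
    }
    defining[[k]] <- sort(cand)
  }
  structure(list(labels = labels, alpha = alpha, defining = defining,
                 indval = iv, da_pairs = da_pairs),
            class = "guild_definition")
}

#' @export
print.guild_definition <- function(x, ...) {
  cat("<guild_definition> alpha =", x$alpha, "\n")
  for (k in names(x$defining))
    cat(sprintf("  %s (%d genomes): %s\n", k, sum(x$labels == k),
                paste(x$defining[[k]], collapse = ", ")))
  invisible(x)
}

#' Principal-component ordination of genome profiles
#'
#' Centred SVD of the genome-by-feature matrix (genomes as observations).
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param x numeric matrix, features x genomes (e.g. from [stabilize()]).
#' @param n_comp number of components returned.
#' @return list with `scores` (genomes x components), `loadings`,
#'   `explained` (variance fractions).
#' @export
ordinate <- function(x, n_comp = 2L) {
  if (ncol(x) < 3L) g_abort("need at least three genomes", "bad_params")
  X <- t(x)
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < 1e-12)) g_abort("constant matrix has no ordination", "no_structure")
  sv <- svd(X)
  n_comp <- min(n_comp, length(sv$d))
  for (i in seq_len(n_comp)) {
    j <- which.max(abs(sv$v[, i]))
    if (sv$v[j, i] < 0) { sv$v[, i] <- -sv$v[, i]; sv$u[, i] <- -sv$u[, i] }
  }
  scores <- sv$u[, seq_len(n_comp), drop = FALSE] %*%
    diag(sv$d[seq_len(n_comp)], n_comp)
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(n_comp))
  loadings <- sv$v[, seq_len(n_comp), drop = FALSE]
  rownames(loadings) <- rownames(x)
  list(scores = scores, loadings = loadings,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_comp)])
}
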