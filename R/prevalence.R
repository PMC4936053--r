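# Presence/absence and relative abundance of population genomes across
# metagenome samples, from read-mapping count tables.

.cutoff_ratio <- function(cutoff) {
  # exact rational representation of the cutoff so boundary comparisons
  # never hinge on floating-point rounding
  den <- 1e6
  num <- round(cutoff * den)
  if (abs(num / den - cutoff) > 1e-12)
    g_abort("cutoff must be representable at 1e-6 resolution", "bad_cutoff")
  g <- .gcd(num, den)
  c(num = num / g, den = den / g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Detect genome presence from mapped-read fractions
#'
#' A genome is present in a sample when `mapped / total >= cutoff`; the
#' boundary is inclusive and evaluated with integer arithmetic
#' (`mapped * den >= num * total`), so a sample at exactly the cutoff is
#' called present.
#'
#' @param cov a [coverage_table()].
#' @param cutoff minimum mapped-read fraction (default 0.005, i.e. 0.5 %).
#' @return logical sample x genome matrix with attribute `"cutoff"`.
#' @export
detect_presence <- function(cov, cutoff = 0.005) {
  stopifnot(inherits(cov, "coverage_table"))
  r <- .cutoff_ratio(cutoff)
  pres <- cov$mapped_reads * r["den"] >=
    outer(cov$total_reads * r["num"], rep(1, ncol(cov$mapped_reads)))
  dimnames(pres) <- dimnames(cov$mapped_reads)
  attr(pres, "cutoff") <- cutoff
  pres
}

#' Relative abundance of present genomes
#'
#' For present genomes, the percentage of total reads attributed to the
#' genome, rescaled for genome size: `100 * (mapped/total) * (Lbar / L_g)`
#' where `Lbar` is the mean length of the genome panel — so equal read
#' fractions imply higher abundance for the smaller genome. Absent genomes
#' are 0. `normalization = "raw_fraction"` skips the size rescaling.
#'
#' @param cov a [coverage_table()].
#' @param presence matrix from [detect_presence()].
#' @param normalization `"size_scaled"` (default) or `"raw_fraction"`.
#' @return sample x genome percent matrix; the normalisation record is kept
#'   in attribute `"normalization"`.
#' @export
relative_abundance <- function(cov, presence = detect_presence(cov),
                               normalization = c("size_scaled", "raw_fraction")) {
  normalization <- match.arg(normalization)
  frac <- sweep(cov$mapped_reads, 1, cov$total_reads, "/")
  a <- 100 * frac
  lbar <- mean(cov$genome_lengths)
  if (normalization == "size_scaled")
    a <- sweep(a, 2, lbar / cov$genome_lengths, "*")
  a[!presence] <- 0
  attr(a, "normalization") <- list(method = normalization,
                                   mean_genome_length = lbar,
                                   cutoff = attr(presence, "cutoff"))
  a
}

#' Prevalence and abundance summaries
#'
#' Per genome: the fraction of samples where it is present and its mean
#' abundance over positive samples only. Family-level prevalence is the
#' fraction of samples with at least one present genome. With `groups`
#' (named sample -> stratum), the same summaries are recomputed per stratum.
#'
#' @param presence logical matrix from [detect_presence()].
#' @param abundance percent matrix from [relative_abundance()].
#' @param groups optional named sample -> group vector.
#' @return list with `per_genome` (data.frame), `family_prevalence`,
#'   `mean_family_abundance` (mean per-sample summed abundance over
#'   family-positive samples), and `by_group` when requested.
#' @export
summarize_prevalence <- function(presence, abundance, groups = NULL) {
  one <- function(pres, ab) {
    npos <- colSums(pres)
    mean_ab <- ifelse(npos > 0, colSums(ab) / npos, NA_real_)
    fam_pos <- rowSums(pres) > 0
    list(per_genome = data.frame(genome_id = colnames(pres),
                                 prevalence = colMeans(pres),
                                 n_positive = npos,
                                 mean_abundance_positive = mean_ab,
                                 row.names = NULL),
         family_prevalence = mean(fam_pos),
         mean_family_abundance = if (any(fam_pos))
           mean(rowSums(ab)[fam_pos]) else NA_real_)
  }
  out <- one(presence, abundance)
  if (!is.null(groups)) {
    gs <- groups[rownames(presence)]
    out$by_group <- lapply(split(rownames(presence), gs), function(s)
      one(presence[s, , drop = FALSE], abundance[s, , drop = FALSE]))
  }
  out
}
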