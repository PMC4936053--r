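# Gene-neighbourhood analyses: susCD-anchored PUL detection with CAZyme
# association and regulator proximity, and a presence/absence census of
# named gene sets with contig-boundary flags.

#' PUL detection rules
#'
#' SusC/SusD are recognised by domain accessions (defaults target the
#' TonB-dependent transporter TIGRFAM and the SusD Pfam clan) rather than
#' sequence orthology; every clause is independently configurable so the
#' rules can match the user's annotator. Adjacency means: consecutive genes
#' on the same contig, intergenic gap at most `max_intergenic_bp`, same
#' strand, and susC upstream of susD in transcription direction.
#'
#' @param susC_accessions,susD_accessions accession sets identifying the
#'   two anchor genes.
#' @param max_intergenic_bp maximum intergenic gap within a pair.
#' @param require_same_strand,require_order_C_then_D clause switches.
#' @param cazyme_window_genes,cazyme_window_bp association window around the
#'   pair (both constraints apply).
#' @param regulator_accessions accessions of hybrid two-component system
#'   (HTCS) regulators.
#' @param regulator_window_bp "close proximity" distance for regulators.
#' @return a `pul_rules` list.
#' @export
pul_rules <- function(susC_accessions = "TIGR04056",
                      susD_accessions = c("PF07980", "PF12741", "PF12771",
                                          "PF14322"),
                      max_intergenic_bp = 500L,
                      require_same_strand = TRUE,
                      require_order_C_then_D = TRUE,
                      cazyme_window_genes = 10L,
                      cazyme_window_bp = 10000L,
                      regulator_accessions = "HTCS",
                      regulator_window_bp = 5000L) {
  if (any(c(max_intergenic_bp, cazyme_window_genes, cazyme_window_bp,
            regulator_window_bp) <= 0L))
    g_abort("windows must be positive", "bad_params")
  if (!length(susC_accessions) || !length(susD_accessions))
    g_abort("accession sets must be non-empty", "bad_params")
  structure(as.list(environment()), class = "pul_rules")
}

.genes_with_accession <- function(ann, accessions) {
  unique(ann$hits$gene_id[ann$hits$accession %in% accessions])
}

#' Find susCD gene pairs
#'
#' Scans each contig's genes in coordinate order and pairs consecutive
#' susC/susD genes satisfying the rules; pairing is greedy left-to-right and
#' each gene participates in at most one pair.
#'
#' @param ann a [genome_annotation()].
#' @param rules a [pul_rules()].
#' @return data.frame with one row per pair: contig, susC/susD gene ids,
#'   strand, coordinate span.
#' @export
find_suscd_pairs <- function(ann, rules = pul_rules()) {
  stopifnot(inherits(ann, "genome_annotation"), inherits(rules, "pul_rules"))
  g <- ann$genes  # already sorted by (contig, start)
  is_c <- g$gene_id %in% .genes_with_accession(ann, rules$susC_accessions)
  is_d <- g$gene_id %in% .genes_with_accession(ann, rules$susD_accessions)
  out <- list()
  used <- logical(nrow(g))
  for (i in seq_len(nrow(g) - 1L)) {
    j <- i + 1L
    if (used[i] || used[j]) next
    if (g$contig_id[i] != g$contig_id[j]) next
    ci <- is_c[i] && is_d[j]; cj <- is_c[j] && is_d[i]
    if (!ci && !cj) next
    if (rules$require_same_strand && g$strand[i] != g$strand[j]) next
    gap <- g$start[j] - g$end[i] - 1L
    if (gap > rules$max_intergenic_bp) next
    # transcription order: on '+' the upstream gene is the left one, on '-'
    # the right one
    if (rules$require_order_C_then_D) {
      strand <- g$strand[i]
      upstream_is_c <- if (strand == "+") is_c[i] else is_c[j]
      downstream_is_d <- if (strand == "+") is_d[j] else is_d[i]
      if (!(upstream_is_c && downstream_is_d)) next
      c_idx <- if (strand == "+") i else j
      d_idx <- if (strand == "+") j else i
    } else {
      c_idx <- if (ci) i else j
      d_idx <- if (ci) j else i
    }
    used[i] <- used[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      genome_id = ann$genome_id, contig_id = g$contig_id[i],
      susC_gene_id = g$gene_id[c_idx], susD_gene_id = g$gene_id[d_idx],
      strand = g$strand[i],
      span_start = min(g$start[c(i, j)]), span_end = max(g$end[c(i, j)]),
      span = max(g$end[c(i, j)]) - min(g$start[c(i, j)]) + 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(genome_id = character(), contig_id = character(),
                      susC_gene_id = character(), susD_gene_id = character(),
                      strand = character(), span_start = integer(),
                      span_end = integer(), span = integer()))
  do.call(rbind, out)
}

.interval_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s2 - e1, s1 - e2) - 1L)

#' Call polysaccharide utilisation loci
#'
#' Each susCD pair becomes a PUL call. Associated CAZymes are CAZy-annotated
#' genes (other than the pair itself) on the same contig within
#' `cazyme_window_genes` genes *and* `cazyme_window_bp` bp of the pair;
#' `regulator_nearby` is true when any regulator accession lies within
#' `regulator_window_bp`.
#'
#' @inheritParams find_suscd_pairs
#' @return data.frame of calls (one per pair) with `n_cazymes`,
#'   `regulator_nearby`, `regulator_gene_id`, and the per-call CAZyme gene
#'   tables in attribute `"cazymes"` (a named list).
#' @export
call_puls <- function(ann, rules = pul_rules()) {
  pairs <- find_suscd_pairs(ann, rules)
  g <- ann$genes
  caz_hits <- unique(ann$hits[ann$hits$namespace == "CAZY",
                              c("gene_id", "accession")])
  reg_genes <- .genes_with_accession(ann, rules$regulator_accessions)
  caz_list <- list()
  pairs$n_cazymes <- integer(nrow(pairs))
  pairs$regulator_nearby <- logical(nrow(pairs))
  pairs$regulator_gene_id <- rep(NA_character_, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    on_contig <- which(g$contig_id == pairs$contig_id[r])
    idx_c <- which(g$gene_id == pairs$susC_gene_id[r])
    idx_d <- which(g$gene_id == pairs$susD_gene_id[r])
    pos <- match(on_contig, on_contig)  # 1..n along contig
    pair_pos <- match(c(idx_c, idx_d), on_contig)
    gene_dist <- pmin(abs(pos - pair_pos[1L]), abs(pos - pair_pos[2L]))
    bp_dist <- .interval_gap(g$start[on_contig], g$end[on_contig],
                             pairs$span_start[r], pairs$span_end[r])
    near <- on_contig[gene_dist <= rules$cazyme_window_genes &
                        bp_dist <= rules$cazyme_window_bp]
    near <- setdiff(near, c(idx_c, idx_d))
    caz <- caz_hits[caz_hits$gene_id %in% g$gene_id[near], , drop = FALSE]
    key <- paste(pairs$susC_gene_id[r], pairs$susD_gene_id[r], sep = "|")
    caz_list[[key]] <- data.frame(gene_id = caz$gene_id, family = caz$accession,
                                  stringsAsFactors = FALSE)
    pairs$n_cazymes[r] <- length(unique(caz$gene_id))
    reg_idx <- on_contig[g$gene_id[on_contig] %in% reg_genes]
    if (length(reg_idx)) {
      rd <- .interval_gap(g$start[reg_idx], g$end[reg_idx],
                          pairs$span_start[r], pairs$span_end[r])
      if (any(rd <= rules$regulator_window_bp)) {
        pairs$regulator_nearby[r] <- TRUE
        pairs$regulator_gene_id[r] <- g$gene_id[reg_idx[which.min(rd)]]
      }
    }
  }
  attr(pairs, "cazymes") <- caz_list
  pairs
}

#' Per-guild PUL summary
#'
#' @param calls data.frame of PUL calls (rows from [call_puls()], possibly
#'   several genomes bound together).
#' @param labels named genome -> guild vector; genomes without calls count
#'   as zero.
#' @return data.frame per guild: mean susCD pairs per genome, mean
#'   CAZyme-associated pairs per genome, fraction of PULs with a nearby
#'   regulator.
#' @export
pul_summary <- function(calls, labels) {
  guilds <- sort(unique(as.character(labels)))
  out <- lapply(guilds, function(k) {
    gen <- names(labels)[labels == k]
    sub <- calls[calls$genome_id %in% gen, , drop = FALSE]
    data.frame(guild = k, n_genomes = length(gen),
               mean_pairs = nrow(sub) / length(gen),
               mean_cazyme_pairs = sum(sub$n_cazymes > 0) / length(gen),
               frac_regulator = if (nrow(sub)) mean(sub$regulator_nearby) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Load gene-set definitions from YAML
#'
#' Each entry: `name`, `required` (accessions or gene symbols), optional
#' `complete_rule` (`"all"`, the default, or an integer threshold) and
#' `namespace`.
#' @param path YAML file; defaults to the bundled gene sets (respiratory
#'   complexes, T9SS, cydAB, urease cluster, oxalate-degradation pair,
#'   oxidative-stress singletons).
#' @return list of feature-set definitions.
#' @export
load_feature_sets <- function(path = system.file("extdata", "featuresets.yaml",
                                                 package = "guildomics")) {
  .check_file(path)
  defs <- yaml::read_yaml(path)
  lapply(defs, function(d) {
    if (is.null(d$name) || !length(d$required))
      g_abort("feature set needs a name and a non-empty required list",
              "bad_feature_set")
    d$required <- as.character(d$required)
    d$complete_rule <- if (is.null(d$complete_rule)) "all" else d$complete_rule
    d
  })
}

#' Gene-set presence/absence census
#'
#' For each feature set: `complete` when the required members satisfy the
#' completeness rule, `partial` when at least one is found, else `absent`.
#' `boundary_flag` marks partial sets in which a found member lies within
#' `boundary_bp` of a contig end — the pattern expected when incomplete
#' assembly, not gene loss, explains the missing members.
#'
#' @param ann a [genome_annotation()].
#' @param defs list of feature-set definitions (see [load_feature_sets()]).
#' @param boundary_bp contig-boundary distance.
#' @return data.frame per feature set: status, found/missing members
#'   (comma-separated), boundary_flag.
#' @export
feature_census <- function(ann, defs = load_feature_sets(), boundary_bp = 5000L) {
  stopifnot(inherits(ann, "genome_annotation"))
  have_ns <- unique(ann$hits$namespace)
  out <- lapply(defs, function(d) {
    if (!is.null(d$namespace) && !d$namespace %in% have_ns)
      g_warn(paste0("annotation has no ", d$namespace,
                    " hits; feature set '", d$name, "' treated as missing"),
             "namespace_absent")
    found <- intersect(d$required, ann$hits$accession)
    missing <- setdiff(d$required, found)
    need <- if (identical(d$complete_rule, "all")) length(d$required)
            else as.integer(d$complete_rule)
    status <- if (length(found) >= need) "complete"
              else if (length(found) >= 1L) "partial" else "absent"
    boundary <- FALSE
    if (status == "partial") {
      genes_found <- unique(ann$hits$gene_id[ann$hits$accession %in% found])
      gi <- ann$genes[ann$genes$gene_id %in% genes_found, , drop = FALSE]
      clen <- ann$contig_lengths[gi$contig_id]
      boundary <- any(gi$start - 1L <= boundary_bp | clen - gi$end <= boundary_bp)
    }
    data.frame(genome_id = ann$genome_id, feature_set = d$name,
               status = status, n_found = length(found),
               n_required = length(d$required),
               found = paste(found, collapse = ","),
               missing = paste(missing, collapse = ","),
               boundary_flag = boundary, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
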