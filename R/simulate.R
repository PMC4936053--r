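# Synthetic-data generators. Each generator is a pure function of its
# parameter object (which includes the seed) and returns the planted ground
# truth alongside the data, so downstream recovery tests consume the truth
# rather than re-deriving it.

#' Parameters for the guild-structured CAZy count generator
#'
#' Defaults mirror the shape of the study family this workflow was built
#' around: three trophic guilds of 13, 12 and 5 genomes, a background
#' negative-binomial mean of 6 counts per family, and a 3-fold enrichment of
#' each guild's five defining enzyme families.
#'
#' @param n_genomes_per_guild named integer vector of guild sizes.
#' @param n_families number of enzyme families simulated.
#' @param baseline_mean background NB mean per family and genome.
#' @param enrichment_factor multiplicative enrichment (> 1) of a defining
#'   family within its own guild.
#' @param n_defining_per_guild defining families planted per guild.
#' @param nb_dispersion NB dispersion `alpha` in the `var = mu + alpha mu^2`
#'   parameterisation (0 gives Poisson counts).
#' @param seed integer seed.
#' @return a `guild_sim_params` list.
#' @export
guild_sim_params <- function(n_genomes_per_guild = c(alpha_glucan = 13L,
                                                     plant_glycan = 12L,
                                                     host_glycan = 5L),
                             n_families = 60L, baseline_mean = 6,
                             enrichment_factor = 3, n_defining_per_guild = 5L,
                             nb_dispersion = 0.3, seed = 1L) {
  if (any(n_genomes_per_guild < 1L))
    g_abort("every guild needs at least one genome", "bad_params")
  if (is.null(names(n_genomes_per_guild)))
    names(n_genomes_per_guild) <- paste0("guild", seq_along(n_genomes_per_guild))
  if (enrichment_factor < 1) g_abort("enrichment_factor must be >= 1", "bad_params")
  if (nb_dispersion < 0) g_abort("nb_dispersion must be >= 0", "bad_params")
  if (n_defining_per_guild * length(n_genomes_per_guild) > n_families)
    g_abort("not enough families for the requested defining sets", "bad_params")
  structure(list(n_genomes_per_guild = as.integer(n_genomes_per_guild),
                 guilds = names(n_genomes_per_guild),
                 n_families = as.integer(n_families),
                 baseline_mean = baseline_mean,
                 enrichment_factor = enrichment_factor,
                 n_defining_per_guild = as.integer(n_defining_per_guild),
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "guild_sim_params")
}

.rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a guild-structured CAZy family count matrix
#'
#' Counts are negative-binomial with mean `baseline_mean` for background
#' families and `baseline_mean * enrichment_factor` for a guild's defining
#' families in that guild's genomes. Defining sets are disjoint blocks of
#' the first families.
#'
#' @param params a [guild_sim_params()].
#' @return list with `counts` (family x genome integer matrix), `labels`
#'   (named genome -> guild vector) and `defining` (guild -> family sets).
#' @export
simulate_cazy_counts <- function(params = guild_sim_params()) {
  stopifnot(inherits(params, "guild_sim_params"))
  set.seed(params$seed)
  g_log("simulate_cazy_counts seed=", params$seed)
  guilds <- params$guilds
  sizes <- params$n_genomes_per_guild
  genome_ids <- unlist(lapply(seq_along(guilds), function(k)
    sprintf("%s_%02d", toupper(substr(guilds[k], 1, 1)), seq_len(sizes[k]))))
  labels <- stats::setNames(rep(guilds, sizes), genome_ids)
  fams <- sprintf("GH%03d", seq_len(params$n_families))
  defining <- stats::setNames(lapply(seq_along(guilds), function(k) {
    i <- (k - 1L) * params$n_defining_per_guild + seq_len(params$n_defining_per_guild)
    fams[i]
  }), guilds)
  mu <- matrix(params$baseline_mean, params$n_families, length(genome_ids),
               dimnames = list(fams, genome_ids))
  for (k in guilds)
    mu[defining[[k]], labels == k] <- params$baseline_mean * params$enrichment_factor
  counts <- matrix(.rnb(length(mu), as.vector(mu), params$nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  list(counts = validate_count_matrix(counts), labels = labels,
       defining = defining, params = params)
}

#' Parameters for the planted-PUL genome generator
#'
#' Planted loci satisfy the susCD detection rule exactly; each decoy
#' violates exactly one clause (`lone_susC`, `opposite_strand`,
#' `excess_gap`, `wrong_order`, `no_cazyme`). Units are laid out one per
#' contig so neighbourhood windows cannot leak between them.
#'
#' @param n_planted_puls number of rule-satisfying loci.
#' @param n_decoys number of decoy units (types cycle through the list above).
#' @param genes_per_contig genes per contig.
#' @param n_background_contigs contigs carrying only background genes.
#' @param gene_len_bp,intergenic_gap_bp gene length and intergenic gap.
#' @param susC_accession,susD_accession,htcs_accession accessions planted on
#'   the transporter, binding-protein and regulator genes.
#' @param feature_symbols optional character vector of gene symbols scattered
#'   (one per background gene) as GENE_SYMBOL hits, e.g. for census tests.
#' @param seed integer seed.
#' @return a `pul_sim_params` list.
#' @export
pul_sim_params <- function(n_planted_puls = 3L, n_decoys = 5L,
                           genes_per_contig = 12L, n_background_contigs = 2L,
                           gene_len_bp = 900L, intergenic_gap_bp = 100L,
                           susC_accession = "TIGR04056",
                           susD_accession = "PF07980",
                           htcs_accession = "HTCS",
                           feature_symbols = NULL, seed = 1L) {
  if (genes_per_contig < 8L) g_abort("need >= 8 genes per contig", "bad_params")
  if (intergenic_gap_bp > 500L)
    g_abort("intergenic gap must keep planted pairs adjacent (<= 500 bp)",
            "bad_params")
  structure(as.list(environment()), class = "pul_sim_params")
}

DECOY_TYPES <- c("lone_susC", "opposite_strand", "excess_gap", "wrong_order",
                 "no_cazyme")

#' Simulate one genome annotation with planted PULs and decoys
#'
#' @param params a [pul_sim_params()].
#' @param genome_id identifier for the simulated genome.
#' @return list with `annotation` (a [genome_annotation()]) and `truth`, a
#'   data.frame of planted units: type, violated clause, member gene ids,
#'   the expected pair/call outcome and expected associated CAZyme genes
#'   (comma-separated).
#' @export
simulate_genome_tables <- function(params = pul_sim_params(), genome_id = "sim") {
  stopifnot(inherits(params, "pul_sim_params"))
  set.seed(params$seed)
  g_log("simulate_genome_tables seed=", params$seed)
  n_units <- params$n_planted_puls + params$n_decoys
  unit_types <- c(rep("planted", params$n_planted_puls),
                  DECOY_TYPES[(seq_len(params$n_decoys) - 1L) %% length(DECOY_TYPES) + 1L])
  n_contigs <- n_units + params$n_background_contigs
  genes <- list(); hits <- list(); contig_lengths <- numeric(0)
  truth <- list()
  gid <- 0L
  for (ci in seq_len(n_contigs)) {
    contig <- sprintf("ctg%02d", ci)
    unit <- if (ci <= n_units) unit_types[ci] else "background"
    # slot -> extra gap inserted before that slot (decoy 'excess_gap')
    extra_gap <- rep(0L, params$genes_per_contig)
    if (unit == "excess_gap") extra_gap[6L] <- 2000L
    starts <- integer(params$genes_per_contig)
    pos <- 1L
    for (s in seq_len(params$genes_per_contig)) {
      pos <- pos + extra_gap[s]
      starts[s] <- pos
      pos <- pos + params$gene_len_bp + params$intergenic_gap_bp
    }
    ends <- starts + params$gene_len_bp - 1L
    ids <- sprintf("%s_g%04d", contig, gid + seq_len(params$genes_per_contig))
    gid <- gid + params$genes_per_contig
    strands <- rep("+", params$genes_per_contig)
    prods <- rep("hypothetical protein", params$genes_per_contig)
    h <- list()
    pair_strand <- "+"
    if (unit %in% c("planted", "opposite_strand", "excess_gap", "wrong_order",
                    "no_cazyme")) {
      # slots 5 and 6 hold the susC/susD pair (coordinate order depends on strand)
      pair_strand <- if (unit == "planted" && ci %% 2L == 0L) "-" else "+"
      c_slot <- if (pair_strand == "+") 5L else 6L
      d_slot <- if (pair_strand == "+") 6L else 5L
      if (unit == "wrong_order") { c_slot <- 6L; d_slot <- 5L; pair_strand <- "+" }
      strands[c(5L, 6L)] <- pair_strand
      if (unit == "opposite_strand") strands[6L] <- "-"
      h[[length(h) + 1L]] <- data.frame(gene_id = ids[c_slot],
                                        accession = params$susC_accession,
                                        namespace = "TIGRFAM")
      h[[length(h) + 1L]] <- data.frame(gene_id = ids[d_slot],
                                        accession = params$susD_accession,
                                        namespace = "PFAM")
      prods[c_slot] <- "SusC-like TonB-dependent transporter"
      prods[d_slot] <- "SusD-like glycan-binding lipoprotein"
    } else if (unit == "lone_susC") {
      strands[5L] <- "+"
      h[[length(h) + 1L]] <- data.frame(gene_id = ids[5L],
                                        accession = params$susC_accession,
                                        namespace = "TIGRFAM")
      prods[5L] <- "SusC-like TonB-dependent transporter"
    }
    caz_genes <- character(0)
    if (unit == "planted") {
      caz_slots <- c(4L, 7L)
      for (s in caz_slots)
        h[[length(h) + 1L]] <- data.frame(gene_id = ids[s], accession = "GH13",
                                          namespace = "CAZY")
      prods[caz_slots] <- "glycoside hydrolase"
      caz_genes <- ids[caz_slots]
      if (ci == 1L) {  # first planted locus carries a nearby HTCS regulator
        h[[length(h) + 1L]] <- data.frame(gene_id = ids[8L],
                                          accession = params$htcs_accession,
                                          namespace = "GENE_SYMBOL")
        prods[8L] <- "hybrid two-component system sensor-regulator"
      }
    }
    if (unit == "background") {
      h[[length(h) + 1L]] <- data.frame(gene_id = ids[2L], accession = "PF00005",
                                        namespace = "PFAM")
      if (!is.null(params$feature_symbols)) {
        free <- setdiff(seq_len(params$genes_per_contig), 2L)
        syms <- params$feature_symbols
        take <- utils::head(free, length(syms))
        if (length(take) < length(syms))
          g_abort("contig too short for requested feature symbols", "contig_too_short")
        h[[length(h) + 1L]] <- data.frame(gene_id = ids[take], accession = syms,
                                          namespace = "GENE_SYMBOL")
        params$feature_symbols <- NULL
      }
    }
    contig_lengths[contig] <- max(ends) + 200L
    genes[[ci]] <- data.frame(contig_id = contig, gene_id = ids, start = starts,
                              end = ends, strand = strands, product = prods,
                              stringsAsFactors = FALSE)
    if (length(h)) {
      hh <- do.call(rbind, h)
      hh$score <- NA_real_; hh$score_type <- NA_character_
      hits[[length(hits) + 1L]] <- hh
    }
    if (unit != "background") {
      c_id <- if (unit == "lone_susC") ids[5L] else ids[if (pair_strand == "+") 5L else 6L]
      d_id <- if (unit == "lone_susC") NA_character_ else ids[if (pair_strand == "+") 6L else 5L]
      if (unit == "wrong_order") { c_id <- ids[6L]; d_id <- ids[5L] }
      truth[[length(truth) + 1L]] <- data.frame(
        unit_id = sprintf("u%02d", ci), type = if (unit == "planted") "planted" else "decoy",
        subtype = unit, contig_id = contig, susC_gene_id = c_id,
        susD_gene_id = d_id, strand = pair_strand,
        expect_pair = unit %in% c("planted", "no_cazyme"),
        expect_cazymes = paste(caz_genes, collapse = ","),
        expect_regulator = unit == "planted" && ci == 1L,
        stringsAsFactors = FALSE)
    }
  }
  ann <- genome_annotation(genome_id, contig_lengths, do.call(rbind, genes),
                           do.call(rbind, hits))
  list(annotation = ann, truth = do.call(rbind, truth), params = params)
}

#' Parameters for the diverged-sequence-pair generator
#'
#' @param length_bp ancestral sequence length (>= 10,200 bp so that 1020-bp
#'   fragment statistics are meaningful).
#' @param substitution_prob per-site substitution probability in `[0, 1)`;
#'   substituted bases are drawn uniformly from the three alternatives.
#' @param indel_prob per-site probability of initiating an indel.
#' @param mean_indel_len mean geometric indel length.
#' @param seed integer seed.
#' @return a `divergence_sim_params` list.
#' @export
divergence_sim_params <- function(length_bp = 100000L, substitution_prob = 0,
                                  indel_prob = 0, mean_indel_len = 3,
                                  seed = 1L) {
  if (substitution_prob < 0 || substitution_prob >= 1)
    g_abort("substitution_prob must be in [0, 1)", "bad_params")
  if (indel_prob < 0 || indel_prob >= 1)
    g_abort("indel_prob must be in [0, 1)", "bad_params")
  if (length_bp < 10200L)
    g_abort("length_bp must be >= 10200 for fragment statistics", "bad_params")
  structure(list(length_bp = as.integer(length_bp),
                 substitution_prob = substitution_prob,
                 indel_prob = indel_prob, mean_indel_len = mean_indel_len,
                 seed = as.integer(seed)),
            class = "divergence_sim_params")
}

#' Simulate a nucleotide sequence pair at controlled divergence
#'
#' The second sequence derives from the first by i.i.d. substitutions and
#' geometric-length indels; `realized_identity = 1 - substitutions / length`
#' is recorded as ground truth for ANI validation.
#'
#' @param params a [divergence_sim_params()].
#' @return list with `a`, `b` (character sequences), `realized_identity`,
#'   `n_substitutions`, `n_indels`.
#' @export
simulate_sequence_pair <- function(params = divergence_sim_params()) {
  stopifnot(inherits(params, "divergence_sim_params"))
  set.seed(params$seed)
  g_log("simulate_sequence_pair seed=", params$seed)
  bases <- c("A", "C", "G", "T")
  n <- params$length_bp
  a <- sample(bases, n, replace = TRUE)
  b <- a
  sub <- which(runif(n) < params$substitution_prob)
  if (length(sub)) {
    shift <- sample(1:3, length(sub), replace = TRUE)
    b[sub] <- bases[(match(b[sub], bases) - 1L + shift) %% 4L + 1L]
  }
  n_indels <- 0L
  if (params$indel_prob > 0) {
    pos <- which(runif(n) < params$indel_prob)
    n_indels <- length(pos)
    if (n_indels) {
      lens <- rgeom(n_indels, 1 / params$mean_indel_len) + 1L
      ins <- runif(n_indels) < 0.5
      out <- character(0)
      prev <- 1L
      for (i in seq_len(n_indels)) {
        out <- c(out, b[prev:pos[i]])
        if (ins[i]) out <- c(out, sample(bases, lens[i], replace = TRUE))
        else out <- out[seq_len(max(0L, length(out) - lens[i]))]
        prev <- pos[i] + 1L
      }
      if (prev <= n) out <- c(out, b[prev:n])
      b <- out
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       realized_identity = 1 - length(sub) / n,
       n_substitutions = length(sub), n_indels = n_indels)
}

#' Simulate a diverged proteome pair
#'
#' Companion generator for AAI validation: `n_proteins` random amino-acid
#' sequences, each copied with a fixed per-residue substitution probability
#' (substituted residues drawn uniformly from the 19 alternatives).
#'
#' @param n_proteins,mean_len proteome size and mean protein length.
#' @param divergence per-residue substitution probability.
#' @param seed integer seed.
#' @return list with `a`, `b` (named character vectors) and
#'   `realized_identity` per protein.
#' @export
simulate_proteome_pair <- function(n_proteins = 30L, mean_len = 300L,
                                   divergence = 0.1, seed = 1L) {
  set.seed(seed)
  g_log("simulate_proteome_pair seed=", seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- pmax(50L, rpois(n_proteins, mean_len))
  a <- character(n_proteins); b <- character(n_proteins)
  rid <- numeric(n_proteins)
  for (i in seq_len(n_proteins)) {
    s <- sample(aa, lens[i], replace = TRUE)
    t <- s
    sub <- which(runif(lens[i]) < divergence)
    if (length(sub)) {
      shift <- sample(1:19, length(sub), replace = TRUE)
      t[sub] <- aa[(match(t[sub], aa) - 1L + shift) %% 20L + 1L]
    }
    a[i] <- paste(s, collapse = ""); b[i] <- paste(t, collapse = "")
    rid[i] <- 1 - length(sub) / lens[i]
  }
  names(a) <- sprintf("protA_%03d", seq_len(n_proteins))
  names(b) <- sprintf("protB_%03d", seq_len(n_proteins))
  list(a = a, b = b, realized_identity = rid)
}

#' Simulate a sample-by-genome coverage table with known presence
#'
#' Present genomes receive read fractions above the detection cutoff, absent
#' genomes background fractions strictly below it; the truth table is
#' returned alongside.
#'
#' @param n_samples number of samples.
#' @param genomes character vector of genome ids.
#' @param present_sets list (length `n_samples`) of genome-id vectors present
#'   in each sample.
#' @param seed integer seed.
#' @param cutoff detection cutoff as a fraction of total reads.
#' @param total_reads per-sample sequencing depth.
#' @param genome_lengths optional named lengths; simulated around 2.7 Mb
#'   when missing.
#' @return list with `coverage` (a [coverage_table()]) and `truth`
#'   (sample x genome logical matrix).
#' @export
simulate_coverage <- function(n_samples, genomes, present_sets, seed = 1L,
                              cutoff = 0.005, total_reads = 1e6,
                              genome_lengths = NULL) {
  stopifnot(length(present_sets) == n_samples)
  set.seed(seed)
  g_log("simulate_coverage seed=", seed)
  if (is.null(genome_lengths))
    genome_lengths <- stats::setNames(round(runif(length(genomes), 2.2e6, 3.2e6)),
                                      genomes)
  samples <- sprintf("s%03d", seq_len(n_samples))
  truth <- matrix(FALSE, n_samples, length(genomes),
                  dimnames = list(samples, genomes))
  for (i in seq_len(n_samples)) truth[i, present_sets[[i]]] <- TRUE
  frac <- matrix(runif(length(truth), 0, 0.5 * cutoff), n_samples, length(genomes))
  frac[truth] <- runif(sum(truth), 2 * cutoff, 8 * cutoff)
  if (any(rowSums(frac) > 1))
    g_abort("requested presence fractions are infeasible (sum > 1)",
            "infeasible_fractions")
  mapped <- round(frac * total_reads)
  # rounding guards: present strictly at/above cutoff, absent strictly below
  mapped[truth] <- pmax(mapped[truth], ceiling(cutoff * total_reads))
  mapped[!truth] <- pmin(mapped[!truth], ceiling(cutoff * total_reads) - 1)
  dimnames(mapped) <- dimnames(truth)
  cov <- coverage_table(mapped,
                        stats::setNames(rep(total_reads, n_samples), samples),
                        genome_lengths)
  list(coverage = cov, truth = truth)
}

#' Simulate a rooted gene tree
#'
#' Yule (pure-birth) topology with i.i.d. exponential branch lengths; tips
#' are labelled `t1..tn` (or `tip_labels` when given) for guild mapping.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param rate exponential rate for branch lengths.
#' @param tip_labels optional tip labels.
#' @return an `ape::phylo` tree.
#' @export
simulate_tree <- function(n_tips, seed = 1L, rate = 1, tip_labels = NULL) {
  if (n_tips < 2L) g_abort("need at least two tips", "bad_params")
  set.seed(seed)
  g_log("simulate_tree seed=", seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- rexp(nrow(tr$edge), rate)
  tr$tip.label <- if (is.null(tip_labels)) sprintf("t%d", seq_len(n_tips)) else tip_labels
  validate_tree(tr)
}
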