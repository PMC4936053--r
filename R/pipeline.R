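# End-to-end orchestration: one config drives simulate -> profile -> guilds
# -> PULs -> census -> relatedness -> PD -> prevalence and writes a
# reproduction-style report bundle (TSV tables + JSON provenance).

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate all inputs; `seed` mandatory) or
#'   `"user-data"` (paths below must exist).
#' @param out_dir report directory (created if missing).
#' @param seed master seed for synthetic mode.
#' @param K number of guilds.
#' @param alpha BH-adjusted significance threshold for the dual criterion.
#' @param n_perm IndVal permutations.
#' @param guild_params a [guild_sim_params()] (synthetic mode).
#' @param ani_divergences substitution probabilities for the ANI validation
#'   stage (synthetic mode).
#' @param ani_length_bp sequence length for the ANI stage.
#' @param species_threshold ANI percent threshold for species partitioning.
#' @param prevalence_cutoff presence cutoff as a read fraction.
#' @param counts_path,labels_path,gene_table_path,domain_table_path,tree_path,coverage_path
#'   inputs for user-data mode (only the stages whose inputs are supplied
#'   are run).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "user-data"),
                            out_dir = tempfile("guildomics_run_"),
                            seed = 1L, K = 3L, alpha = 0.05, n_perm = 999L,
                            guild_params = NULL,
                            ani_divergences = c(0.02, 0.05),
                            ani_length_bp = 20000L,
                            species_threshold = 95,
                            prevalence_cutoff = 0.005,
                            counts_path = NULL, labels_path = NULL,
                            gene_table_path = NULL, domain_table_path = NULL,
                            tree_path = NULL, coverage_path = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && (is.null(seed) || is.na(seed)))
    g_abort("synthetic mode requires a seed", "bad_config")
  if (mode == "user-data") {
    for (p in c(counts_path, labels_path, gene_table_path, domain_table_path,
                tree_path, coverage_path))
      if (!is.null(p) && !file.exists(p))
        g_abort("configured input file not found", "missing_file", path = p)
    if (is.null(counts_path))
      g_abort("user-data mode requires counts_path", "bad_config")
  }
  if (is.null(guild_params))
    guild_params <- guild_sim_params(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config and seeds. Stage outputs are written as
#' TSV under `out_dir`, and `report.json` records every result summary plus
#' a provenance block (package version, seeds, thresholds and defaults), so
#' decisions taken by default are visible in the output.
#'
#' @param cfg a [pipeline_config()].
#' @return the report, invisibly (a named list).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      g_abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
              "stage_failure", stage = name))
  }
  synth <- cfg$mode == "synthetic"

  # --- guild inference on CAZy counts -------------------------------------
  truth <- NULL
  if (synth) {
    sim <- stage("simulate", simulate_cazy_counts(cfg$guild_params))
    counts <- sim$counts; truth <- sim
    user_labels <- NULL
  } else {
    counts <- stage("read_counts", read_count_matrix(cfg$counts_path))
    user_labels <- if (!is.null(cfg$labels_path)) {
      lab <- read.delim(cfg$labels_path, stringsAsFactors = FALSE)
      stats::setNames(lab[[2L]], lab[[1L]])
    }
  }
  pct <- stage("profile", percent_of_cazy(counts))
  clustered <- stage("cluster", cluster_guilds(pct, cfg$K))
  # inferential stages run on the planted labels in synthetic mode (the
  # clustering result is reported next to them) and on user labels when given
  labels <- if (!is.null(user_labels)) user_labels
            else if (synth) truth$labels
            else clustered
  iv <- stage("indval", indval(counts, labels, n_perm = cfg$n_perm,
                               seed = cfg$seed))
  da <- stage("differential_abundance", nb_all_pairs(counts, labels))
  def <- stage("defining", define_guild_enzymes(iv, da, labels,
                                                alpha = cfg$alpha))
  write_count_matrix(counts, file.path(cfg$out_dir, "cazy_counts.tsv"))
  write.table(data.frame(genome_id = names(labels), guild = as.character(labels)),
              file.path(cfg$out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(iv$summary, file.path(cfg$out_dir, "indval.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, lapply(names(da), function(k)
    cbind(comparison = k, da[[k]]))), file.path(cfg$out_dir, "da_pairs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  def_df <- do.call(rbind, lapply(names(def$defining), function(k)
    if (length(def$defining[[k]]))
      data.frame(guild = k, family = def$defining[[k]]) else NULL))
  if (is.null(def_df)) def_df <- data.frame(guild = character(),
                                            family = character())
  write.table(def_df, file.path(cfg$out_dir, "defining.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$guilds <- list(labels = as.list(labels),
                        clustered = as.list(clustered),
                        defining = def$defining,
                        alpha = cfg$alpha)
  pca <- stage("ordination", ordinate(stabilize(counts,
                                                size_factors(counts, "positive"))))
  report$ordination <- list(explained = pca$explained)

  # --- PULs and census ----------------------------------------------------
  if (synth || !is.null(cfg$gene_table_path)) {
    if (synth) {
      gsim <- stage("simulate_genomes", simulate_genome_tables(
        pul_sim_params(seed = cfg$seed,
                       feature_symbols = load_feature_sets()[[1L]]$required)))
      ann <- gsim$annotation
    } else {
      ann <- stage("read_annotation",
                   read_annotation(cfg$gene_table_path, cfg$domain_table_path))
    }
    puls <- stage("puls", call_puls(ann))
    census <- stage("census", feature_census(ann))
    write.table(puls, file.path(cfg$out_dir, "puls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(census, file.path(cfg$out_dir, "census.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$puls <- list(n_pairs = nrow(puls),
                        n_with_cazymes = sum(puls$n_cazymes > 0))
    report$census <- stats::setNames(census$status, census$feature_set)
  }

  # --- relatedness --------------------------------------------------------
  if (synth) {
    ani_tab <- lapply(cfg$ani_divergences, function(p_sub) {
      sp <- simulate_sequence_pair(divergence_sim_params(
        length_bp = cfg$ani_length_bp, substitution_prob = p_sub,
        seed = cfg$seed))
      res <- goris_ani(sp$a, sp$b)
      data.frame(substitution_prob = p_sub,
                 realized_identity = sp$realized_identity,
                 ani_mean = res$ani_mean, n_used_ab = res$n_used_ab)
    })
    ani_tab <- do.call(rbind, ani_tab)
    write.table(ani_tab, file.path(cfg$out_dir, "ani.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$ani <- ani_tab
    pp <- simulate_proteome_pair(seed = cfg$seed)
    aai <- stage("aai", rbh_aai(pp$a, pp$b))
    report$aai <- list(aai = aai$aai, n_rbh = aai$n_rbh)
  }

  # --- phylogenetic diversity --------------------------------------------
  if (synth || !is.null(cfg$tree_path)) {
    if (synth) {
      tr <- simulate_tree(length(labels), seed = cfg$seed,
                          tip_labels = names(labels))
      map <- labels
    } else {
      tr <- stage("read_tree", read_tree(cfg$tree_path))
      map <- labels[intersect(names(labels), tr$tip.label)]
    }
    pd <- stage("pd", guild_pd(tr, map))
    write.table(pd$per_guild, file.path(cfg$out_dir, "pd.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$pd <- pd$per_guild
  }

  # --- prevalence ---------------------------------------------------------
  if (synth || !is.null(cfg$coverage_path)) {
    if (synth) {
      genomes <- names(labels)
      set.seed(cfg$seed + 7L)
      present <- lapply(seq_len(10L), function(i)
        sample(genomes, sample(0:4, 1L)))
      csim <- simulate_coverage(10L, genomes, present, seed = cfg$seed,
                                cutoff = cfg$prevalence_cutoff)
      cov <- csim$coverage
    } else {
      cov <- stage("read_coverage", read_coverage(cfg$coverage_path))
    }
    pres <- detect_presence(cov, cfg$prevalence_cutoff)
    ab <- relative_abundance(cov, pres)
    sm <- summarize_prevalence(pres, ab)
    write.table(sm$per_genome, file.path(cfg$out_dir, "prevalence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$prevalence <- list(family_prevalence = sm$family_prevalence,
                              mean_family_abundance = sm$mean_family_abundance)
  }

  report$provenance <- list(
    package = "guildomics",
    version = as.character(utils::packageVersion("guildomics")),
    r_version = R.version.string,
    mode = cfg$mode, seed = cfg$seed, K = cfg$K, alpha = cfg$alpha,
    n_perm = cfg$n_perm, species_threshold = cfg$species_threshold,
    prevalence_cutoff = cfg$prevalence_cutoff,
    pul_rules = unclass(pul_rules()))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
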