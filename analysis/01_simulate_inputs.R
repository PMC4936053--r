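#!/usr/bin/env Rscript
# Generate every input the downstream analyses consume, with known ground
# truth, mirroring the shape of the study family: three trophic guilds of
# 13, 12 and 5 genomes; one genome annotation with planted susCD loci and
# decoys; diverged sequence pairs for the ANI validation; gene trees; and a
# sample-by-genome read-mapping table.

suppressMessages(library(guildomics))
SEED <- 1L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## CAZy family counts with guild structure
sim <- simulate_cazy_counts(guild_sim_params(seed = SEED))
write_count_matrix(sim$counts, file.path(out, "cazy_counts.tsv"))
write.table(data.frame(genome_id = names(sim$labels), guild = sim$labels),
            file.path(out, "guild_labels_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(sim$defining, file.path(out, "defining_truth.json"),
                     pretty = TRUE)
cat(sprintf("counts: %d families x %d genomes (guilds: %s)\n",
            nrow(sim$counts), ncol(sim$counts),
            paste(table(sim$labels)[unique(sim$labels)], collapse = "/")))

## genome annotation with planted PULs, decoys and a complete complex I
fs <- load_feature_sets()
gsim <- simulate_genome_tables(
  pul_sim_params(seed = SEED, n_planted_puls = 4L, n_decoys = 5L,
                 feature_symbols = fs[[1]]$required))
write_annotation(gsim$annotation, file.path(out, "genome_genes.tsv"),
                 file.path(out, "genome_hits.tsv"))
write.table(gsim$truth, file.path(out, "pul_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("genome: %d contigs, %d genes, %d planted PULs + %d decoys\n",
            length(gsim$annotation$contig_lengths), nrow(gsim$annotation$genes),
            sum(gsim$truth$type == "planted"), sum(gsim$truth$type == "decoy")))

## sequence pairs at controlled divergence (ANI validation)
for (p_sub in c(0.02, 0.05)) {
  sp <- simulate_sequence_pair(divergence_sim_params(
    length_bp = 20400L, substitution_prob = p_sub, seed = SEED))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(ancestor = sp$a, derived = sp$b)),
    file.path(out, sprintf("seqpair_%02dpct.fasta", round(100 * p_sub))))
  cat(sprintf("sequence pair at %.0f%% divergence: realised identity %.4f\n",
              100 * p_sub, sp$realized_identity))
}

## gene trees (susC/susD stand-ins) tips named after the genomes
for (tree_name in c("susC", "susD")) {
  tr <- simulate_tree(length(sim$labels),
                      seed = SEED + (tree_name == "susD"),
                      tip_labels = names(sim$labels))
  ape::write.tree(tr, file.path(out, paste0(tree_name, "_genetree.nwk")))
}

## coverage table with planted presence/absence
set.seed(SEED)
genomes <- names(sim$labels)
sets <- lapply(1:20, function(i) sample(genomes, sample(0:6, 1)))
cs <- simulate_coverage(20, genomes, sets, seed = SEED)
write_coverage(cs$coverage, file.path(out, "coverage.tsv"))
write.table(data.frame(sample_id = rownames(cs$truth), cs$truth),
            file.path(out, "presence_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("coverage: %d samples x %d genomes\n", nrow(cs$truth), ncol(cs$truth)))
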