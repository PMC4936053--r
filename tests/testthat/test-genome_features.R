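mk_genes <- function(starts, ends, strands, ids = NULL) {
  data.frame(contig_id = "c1",
             gene_id = if (is.null(ids)) sprintf("g%d", seq_along(starts)) else ids,
             start = starts, end = ends, strand = strands)
}

sus_hits <- function(c_gene, d_gene) {
  data.frame(gene_id = c(c_gene, d_gene),
             accession = c("TIGR04056", "PF07980"),
             namespace = c("TIGRFAM", "PFAM"))
}

test_that("susCD pairing applies gap, strand and order clauses", {
  # adjacent same-strand C->D, gap 100 bp
  ann <- toy_annotation(genes = mk_genes(c(1000L, 2001L), c(1900L, 2900L),
                                         c("+", "+")),
                        hits = sus_hits("g1", "g2"))
  expect_equal(nrow(find_suscd_pairs(ann)), 1L)

  # opposite strands
  ann2 <- toy_annotation(genes = mk_genes(c(1000L, 2001L), c(1900L, 2900L),
                                          c("+", "-")),
                         hits = sus_hits("g1", "g2"))
  expect_equal(nrow(find_suscd_pairs(ann2)), 0L)

  # separated by 2 kb
  ann3 <- toy_annotation(genes = mk_genes(c(1000L, 4000L), c(1900L, 4900L),
                                          c("+", "+")),
                         hits = sus_hits("g1", "g2"))
  expect_equal(nrow(find_suscd_pairs(ann3)), 0L)

  # D before C on '+' violates transcription order; on '-' it is the valid order
  ann4 <- toy_annotation(genes = mk_genes(c(1000L, 2001L), c(1900L, 2900L),
                                          c("+", "+")),
                         hits = sus_hits("g2", "g1"))
  expect_equal(nrow(find_suscd_pairs(ann4)), 0L)
  ann5 <- toy_annotation(genes = mk_genes(c(1000L, 2001L), c(1900L, 2900L),
                                          c("-", "-")),
                         hits = sus_hits("g2", "g1"))
  expect_equal(nrow(find_suscd_pairs(ann5)), 1L)
})

test_that("planted loci are recovered exactly and decoys never called", {
  for (s in 1:5) {
    sim <- simulate_genome_tables(pul_sim_params(seed = s, n_planted_puls = 4,
                                                 n_decoys = 5))
    calls <- call_puls(sim$annotation)
    truth <- sim$truth
    expected <- truth[truth$expect_pair, ]
    expect_setequal(calls$susC_gene_id, expected$susC_gene_id)
    expect_setequal(calls$susD_gene_id, expected$susD_gene_id)
    caz <- attr(calls, "cazymes")
    for (i in seq_len(nrow(expected))) {
      key <- paste(expected$susC_gene_id[i], expected$susD_gene_id[i], sep = "|")
      want <- setdiff(strsplit(expected$expect_cazymes[i], ",")[[1]], "")
      expect_setequal(unique(caz[[key]]$gene_id), want)
    }
    got_reg <- calls$regulator_nearby[match(expected$susC_gene_id,
                                            calls$susC_gene_id)]
    expect_equal(got_reg, expected$expect_regulator)
  }
})

test_that("calls are invariant to gene input order", {
  sim <- simulate_genome_tables(pul_sim_params(seed = 8))
  ann <- sim$annotation
  set.seed(1)
  shuffled <- genome_annotation(ann$genome_id, ann$contig_lengths,
                                ann$genes[sample(nrow(ann$genes)), ],
                                ann$hits)
  c1 <- call_puls(ann); c2 <- call_puls(shuffled)
  expect_equal(c1[order(c1$susC_gene_id), ], c2[order(c2$susC_gene_id), ],
               ignore_attr = TRUE)
})

test_that("shrinking windows never adds calls or associations", {
  sim <- simulate_genome_tables(pul_sim_params(seed = 9, n_planted_puls = 4))
  wide <- call_puls(sim$annotation, pul_rules())
  narrow <- call_puls(sim$annotation,
                      pul_rules(max_intergenic_bp = 50L,
                                cazyme_window_genes = 1L,
                                cazyme_window_bp = 1200L,
                                regulator_window_bp = 500L))
  expect_lte(nrow(narrow), nrow(wide))
  for (k in intersect(paste(narrow$susC_gene_id, narrow$susD_gene_id, sep = "|"),
                      paste(wide$susC_gene_id, wide$susD_gene_id, sep = "|"))) {
    expect_lte(nrow(attr(narrow, "cazymes")[[k]]),
               nrow(attr(wide, "cazymes")[[k]]))
  }
  expect_lte(sum(narrow$regulator_nearby), sum(wide$regulator_nearby))
})

test_that("a CAZyme beyond the window leaves the pair with an empty set", {
  genes <- mk_genes(c(1000L, 2001L, 30000L), c(1900L, 2900L, 30900L),
                    c("+", "+", "+"))
  hits <- rbind(sus_hits("g1", "g2"),
                data.frame(gene_id = "g3", accession = "GH13",
                           namespace = "CAZY"))
  calls <- call_puls(toy_annotation(genes = genes, hits = hits))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_cazymes, 0L)
})

test_that("regulators within the window are flagged", {
  genes <- mk_genes(c(1000L, 2001L, 5500L), c(1900L, 2900L, 6400L),
                    c("+", "+", "+"))
  hits <- rbind(sus_hits("g1", "g2"),
                data.frame(gene_id = "g3", accession = "HTCS",
                           namespace = "GENE_SYMBOL"))
  calls <- call_puls(toy_annotation(genes = genes, hits = hits))
  expect_true(calls$regulator_nearby)
  expect_equal(calls$regulator_gene_id, "g3")
})

test_that("per-guild PUL summaries aggregate correctly", {
  sim1 <- simulate_genome_tables(pul_sim_params(seed = 2, n_planted_puls = 5),
                                 genome_id = "plantish")
  sim2 <- simulate_genome_tables(pul_sim_params(seed = 3, n_planted_puls = 1),
                                 genome_id = "starchy")
  calls <- rbind(call_puls(sim1$annotation), call_puls(sim2$annotation))
  labels <- c(plantish = "plant", starchy = "alpha")
  sm <- pul_summary(calls, labels)
  # single-genome guilds: means equal that genome's counts
  expect_equal(sm$mean_pairs[sm$guild == "plant"],
               sum(calls$genome_id == "plantish"))
  # guild planted with more PULs ranks first
  expect_gt(sm$mean_pairs[sm$guild == "plant"],
            sm$mean_pairs[sm$guild == "alpha"])
  empty <- pul_summary(calls[0, ], labels)
  expect_true(all(empty$mean_pairs == 0))
})

test_that("gene-set census distinguishes complete, partial and absent", {
  defs <- load_feature_sets()
  cI <- defs[[which(vapply(defs, `[[`, "", "name") == "complex_I")]]
  mk_ann <- function(symbols, near_end = FALSE) {
    n <- length(symbols)
    starts <- 10000L + seq_len(n) * 1000L  # interior, away from both ends
    ends <- starts + 800L
    if (near_end && n > 0) { starts[n] <- 48000L; ends[n] <- 48800L }
    genome_annotation("G", c(c1 = 50000L),
                      mk_genes(starts, ends, rep("+", n)),
                      if (n) data.frame(gene_id = sprintf("g%d", seq_len(n)),
                                        accession = symbols,
                                        namespace = "GENE_SYMBOL"))
  }
  full <- feature_census(mk_ann(cI$required), list(cI))
  expect_equal(full$status, "complete")
  expect_false(full$boundary_flag)

  part <- feature_census(mk_ann(cI$required[1:9], near_end = TRUE), list(cI))
  expect_equal(part$status, "partial")
  expect_true(part$boundary_flag)   # one member within 5 kb of the contig end

  part2 <- feature_census(mk_ann(cI$required[1:9]), list(cI))
  expect_false(part2$boundary_flag)

  none <- feature_census(mk_ann(c("xyzA")), list(cI))
  expect_equal(none$status, "absent")
})

test_that("bundled gene sets encode the family's shared-feature catalogue", {
  defs <- load_feature_sets()
  names(defs) <- vapply(defs, `[[`, "", "name")
  expect_equal(length(defs$complex_I$required), 11L)  # NuoEFG ancestrally absent
  expect_equal(length(defs$t9ss$required), 10L)
  expect_setequal(defs$cydAB$required, c("cydA", "cydB"))
  expect_true(all(c("frc", "oxc") %in% defs$oxalate_degradation$required))
})
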