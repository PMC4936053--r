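test_that("generators are pure functions of their seed", {
  p <- guild_sim_params(seed = 42)
  expect_identical(simulate_cazy_counts(p)$counts, simulate_cazy_counts(p)$counts)
  dp <- divergence_sim_params(length_bp = 12000, substitution_prob = 0.03,
                              indel_prob = 0.001, seed = 9)
  expect_identical(simulate_sequence_pair(dp), simulate_sequence_pair(dp))
  cs1 <- simulate_coverage(3, c("g1", "g2"), list("g1", "g2", character(0)),
                           seed = 5)
  cs2 <- simulate_coverage(3, c("g1", "g2"), list("g1", "g2", character(0)),
                           seed = 5)
  expect_identical(cs1, cs2)
  expect_identical(ape::write.tree(simulate_tree(10, seed = 3)),
                   ape::write.tree(simulate_tree(10, seed = 3)))
})

test_that("NB counts match their analytic moments", {
  p <- guild_sim_params(seed = 7)
  sim <- simulate_cazy_counts(p)
  mu_bg <- p$baseline_mean
  mu_hi <- p$baseline_mean * p$enrichment_factor
  for (k in names(sim$defining)) {
    in_guild <- names(sim$labels)[sim$labels == k]
    fams <- sim$defining[[k]]
    x <- sim$counts[fams, in_guild]
    se <- sqrt((mu_hi + p$nb_dispersion * mu_hi^2) / length(x))
    expect_lt(abs(mean(x) - mu_hi), 3 * se)
    # the same families outside the guild stay at baseline
    y <- sim$counts[fams, setdiff(names(sim$labels), in_guild)]
    se_bg <- sqrt((mu_bg + p$nb_dispersion * mu_bg^2) / length(y))
    expect_lt(abs(mean(y) - mu_bg), 3 * se_bg)
  }
})

test_that("null generator (dispersion 0, enrichment 1) is Poisson noise", {
  p <- guild_sim_params(enrichment_factor = 1, nb_dispersion = 0, seed = 21)
  sim <- simulate_cazy_counts(p)
  x <- as.vector(sim$counts)
  expect_lt(abs(mean(x) - p$baseline_mean), 3 * sqrt(p$baseline_mean / length(x)))
  # variance/mean ratio ~ 1 for Poisson
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
  # no family should clear the dual criterion at alpha = 0.05
  iv <- indval(sim$counts, sim$labels, n_perm = 199, seed = 1)
  da <- nb_all_pairs(sim$counts, sim$labels)
  def <- define_guild_enzymes(iv, da, sim$labels)
  expect_lte(length(unlist(def$defining)), 2L)
})

test_that("sequence pairs realise the requested divergence", {
  dp0 <- divergence_sim_params(length_bp = 12000, substitution_prob = 0, seed = 1)
  s0 <- simulate_sequence_pair(dp0)
  expect_identical(s0$a, s0$b)
  expect_equal(s0$realized_identity, 1)

  dp <- divergence_sim_params(length_bp = 1e5, substitution_prob = 0.05, seed = 2)
  s <- simulate_sequence_pair(dp)
  expect_lt(abs(s$realized_identity - 0.95), 3 * sqrt(0.05 * 0.95 / 1e5))
  expect_equal(nchar(s$a), nchar(s$b))  # substitutions only

  dpi <- divergence_sim_params(length_bp = 12000, substitution_prob = 0.01,
                               indel_prob = 0.002, seed = 3)
  si <- simulate_sequence_pair(dpi)
  expect_gt(si$n_indels, 0)
  expect_false(nchar(si$a) == nchar(si$b) && identical(si$a, si$b))

  expect_error(divergence_sim_params(length_bp = 5000),
               class = "guildomics_bad_params")
  expect_error(divergence_sim_params(substitution_prob = 1),
               class = "guildomics_bad_params")
})

test_that("coverage generator plants exact presence truth", {
  genomes <- sprintf("g%d", 1:5)
  sets <- list(c("g1", "g3"), character(0), genomes, "g5",
               c("g2", "g4"), "g1")
  cs <- simulate_coverage(6, genomes, sets, seed = 11)
  pres <- detect_presence(cs$coverage)
  expect_true(all(pres == cs$truth))
  expect_equal(sum(pres[2, ]), 0L)  # all-absent sample
  expect_error(simulate_coverage(1, genomes, list(genomes), seed = 1,
                                 cutoff = 0.2),
               class = "guildomics_infeasible_fractions")
})

test_that("simulated trees are valid rooted trees with usable tips", {
  tr <- simulate_tree(2, seed = 5)
  expect_equal(length(tr$tip.label), 2L)   # a single cherry
  expect_equal(nrow(tr$edge), 2L)
  tr2 <- simulate_tree(25, seed = 6)
  expect_true(all(tr2$edge.length >= 0))
  expect_true(ape::is.rooted(tr2))
})

test_that("planted PUL decoys each violate exactly their clause", {
  sim <- simulate_genome_tables(pul_sim_params(seed = 13, n_decoys = 5))
  tr <- sim$truth
  expect_setequal(tr$subtype[tr$type == "decoy"],
                  c("lone_susC", "opposite_strand", "excess_gap",
                    "wrong_order", "no_cazyme"))
  ann <- sim$annotation
  g <- ann$genes
  # excess_gap decoy: pair gap really exceeds the 500 bp rule
  row <- tr[tr$subtype == "excess_gap", ]
  gc <- g[g$gene_id == row$susC_gene_id, ]; gd <- g[g$gene_id == row$susD_gene_id, ]
  expect_gt(abs(gd$start - gc$end), 500L)
  # opposite_strand decoy: strands really differ
  row <- tr[tr$subtype == "opposite_strand", ]
  expect_false(g$strand[g$gene_id == row$susC_gene_id] ==
                 g$strand[g$gene_id == row$susD_gene_id])
})
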