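test_that("annotation constructor validates coordinates, strands and hits", {
  genes <- data.frame(contig_id = "c1", gene_id = c("g1", "g2"),
                      start = c(10L, 500L), end = c(300L, 900L),
                      strand = c("+", "-"))
  ann <- genome_annotation("G", c(c1 = 1200L), genes,
                           data.frame(gene_id = "g1", accession = "GH13",
                                      namespace = "CAZY"))
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(ann$genome_length, 1200L)

  expect_error(genome_annotation("G", c(c1 = 1200L), genes,
                                 data.frame(gene_id = "gX", accession = "GH13",
                                            namespace = "CAZY")),
               class = "guildomics_unknown_gene")
  bad <- genes; bad$end[2] <- 1500L
  expect_error(genome_annotation("G", c(c1 = 1200L), bad),
               class = "guildomics_coordinate_overflow")
  expect_error(genome_annotation("G", c(c1 = 1200L), genes,
                                 data.frame(gene_id = "g1", accession = "X1",
                                            namespace = "FOO")),
               class = "guildomics_unknown_namespace")
  bad <- genes; bad$strand[1] <- "."
  expect_error(genome_annotation("G", c(c1 = 1200L), bad),
               class = "guildomics_bad_strand")
})

test_that("genes are canonically sorted regardless of input order", {
  genes <- data.frame(contig_id = c("c2", "c1", "c1"),
                      gene_id = c("g3", "g2", "g1"),
                      start = c(10L, 900L, 10L), end = c(200L, 1000L, 200L),
                      strand = "+")
  ann <- genome_annotation("G", c(c1 = 2000L, c2 = 2000L), genes)
  expect_equal(ann$genes$gene_id, c("g1", "g2", "g3"))
})

test_that("annotation TSV dialect round-trips", {
  sim <- simulate_genome_tables(pul_sim_params(seed = 3))
  gp <- tempfile(fileext = ".tsv"); hp <- tempfile(fileext = ".tsv")
  write_annotation(sim$annotation, gp, hp)
  back <- read_annotation(gp, hp, genome_id = sim$annotation$genome_id)
  expect_equal(back, sim$annotation)
})

test_that("GFF3 gene tables are read with contig lengths from pragmas", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region c1 1 5000",
               "c1\tsim\tgene\t100\t400\t.\t+\t.\tID=g1;product=amylase",
               "c1\tsim\tgene\t600\t900\t.\t-\t.\tID=g2"), gff)
  hits <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = "g1", accession = "GH13", namespace = "CAZY"),
              hits, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotation(gff, hits, genome_id = "G")
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(nrow(ann$hits), 1L)
  expect_equal(unname(ann$contig_lengths["c1"]), 5000L)
  expect_equal(ann$genes$strand, c("+", "-"))
})

test_that("missing files raise a typed error", {
  expect_error(read_annotation("/nonexistent/x.tsv"),
               class = "guildomics_missing_file")
  expect_error(read_coverage("/nonexistent/x.tsv"),
               class = "guildomics_missing_file")
  expect_error(read_tree("/nonexistent/x.nwk"),
               class = "guildomics_missing_file")
})

test_that("coverage tables validate and round-trip", {
  m <- matrix(c(100L, 200L, 300L, 400L, 500L, 600L), 2, 3,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  cov <- coverage_table(m, c(s1 = 1000L, s2 = 2000L),
                        c(g1 = 2e6, g2 = 3e6, g3 = 2.5e6))
  p <- tempfile(fileext = ".tsv")
  write_coverage(cov, p)
  expect_equal(read_coverage(p), cov)

  expect_error(coverage_table(matrix(1100L, 1, 1, dimnames = list("s1", "g1")),
                              c(s1 = 1000L), c(g1 = 2e6)),
               class = "guildomics_mapped_exceeds_total")
  expect_error(coverage_table(m[, 0, drop = FALSE], c(s1 = 1000L, s2 = 2000L),
                              numeric(0)),
               class = "guildomics_no_genomes")
  expect_error(coverage_table(matrix(1.5, 1, 1, dimnames = list("s1", "g1")),
                              c(s1 = 1000L), c(g1 = 2e6)),
               class = "guildomics_non_integer_counts")
})

test_that("count matrices round-trip and validate", {
  m <- simulate_cazy_counts(guild_sim_params(seed = 2))$counts
  p <- tempfile(fileext = ".tsv")
  write_count_matrix(m, p)
  expect_identical(read_count_matrix(p), m)
  bad <- m; bad[1, 1] <- -1L
  expect_error(validate_count_matrix(bad), class = "guildomics_negative_counts")
})

test_that("newick reading enforces tip uniqueness and parseability", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):0.5,C:1);", p)
  tr <- read_tree(p)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))

  writeLines("((A:1,A:2):0.5,C:1);", p)
  expect_error(read_tree(p), class = "guildomics_duplicate_tips")

  writeLines("(A:1,B:2", p)
  expect_error(read_tree(p), class = "guildomics_tree_parse")

  writeLines("((A,B),C);", p)
  expect_warning(tr <- read_tree(p), class = "guildomics_no_branch_lengths")
  expect_true(all(tr$edge.length == 0))
})
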