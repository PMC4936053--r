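# Validated in-memory model for one genome's annotation: contigs, gene
# coordinates (1-based, inclusive, GFF3 convention) and per-gene domain hits
# under a single namespaced accession vocabulary.

DOMAIN_NAMESPACES <- c("CAZY", "PFAM", "TIGRFAM", "COG", "KO", "GENE_SYMBOL")

#' Construct a validated genome annotation
#'
#' The central container consumed by CAZy profiling, PUL calling and the
#' gene-set census. Coordinates are 1-based and inclusive on both ends;
#' strand must be `"+"` or `"-"` (strandless features are rejected because
#' the PUL rules are strand-aware). Genes are stored sorted by
#' (contig, start).
#'
#' @param genome_id single genome identifier.
#' @param contig_lengths named integer vector, contig id -> length in bp.
#' @param genes data.frame with columns `contig_id`, `gene_id`, `start`,
#'   `end`, `strand` and optionally `product`.
#' @param hits data.frame with columns `gene_id`, `accession`, `namespace`
#'   (one of `r paste(DOMAIN_NAMESPACES, collapse = ", ")`) and optionally
#'   `score`, `score_type`.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, contig_lengths, genes, hits = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (is.null(names(contig_lengths)) || anyDuplicated(names(contig_lengths)))
    g_abort("contig lengths must be uniquely named", "bad_contigs", genome_id = genome_id)
  contig_lengths <- stats::setNames(as.integer(contig_lengths),
                                    names(contig_lengths))
  if (any(contig_lengths <= 0L))
    g_abort("contig lengths must be positive", "bad_contigs", genome_id = genome_id)

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("contig_id", "gene_id", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    g_abort("gene table must have columns contig_id, gene_id, start, end, strand",
            "bad_gene_table", missing = setdiff(req, names(genes)))
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes$product <- as.character(genes$product)
  genes$strand <- as.character(genes$strand)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    g_abort("gene ids must be unique within a genome", "duplicate_gene",
            gene_id = genes$gene_id[duplicated(genes$gene_id)])
  if (any(bad <- !genes$strand %in% c("+", "-")))
    g_abort("strand must be '+' or '-'", "bad_strand", gene_id = genes$gene_id[bad])
  if (any(bad <- genes$start < 1L | genes$end < genes$start))
    g_abort("need 1 <= start <= end", "bad_coordinates", gene_id = genes$gene_id[bad])
  if (any(bad <- !genes$contig_id %in% names(contig_lengths)))
    g_abort("gene on unknown contig", "unknown_contig",
            gene_id = genes$gene_id[bad], contig_id = genes$contig_id[bad])
  over <- genes$end > contig_lengths[genes$contig_id]
  if (any(over))
    g_abort("gene coordinates exceed contig length", "coordinate_overflow",
            gene_id = genes$gene_id[over], contig_id = genes$contig_id[over])
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  if (is.null(hits))
    hits <- data.frame(gene_id = character(), accession = character(),
                       namespace = character(), score = numeric(),
                       score_type = character(), stringsAsFactors = FALSE)
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "accession", "namespace") %in% names(hits)))
    g_abort("domain table must have columns gene_id, accession, namespace",
            "bad_domain_table")
  if (!"score" %in% names(hits)) hits$score <- NA_real_
  if (!"score_type" %in% names(hits)) hits$score_type <- NA_character_
  hits$score <- as.numeric(hits$score)
  hits$score_type <- as.character(hits$score_type)
  if (any(bad <- !hits$namespace %in% DOMAIN_NAMESPACES))
    g_abort("unknown accession namespace", "unknown_namespace",
            namespace = unique(hits$namespace[bad]))
  if (any(bad <- is.na(hits$accession) | !nzchar(hits$accession)))
    g_abort("empty accession", "empty_accession", gene_id = hits$gene_id[bad])
  if (any(bad <- !hits$gene_id %in% genes$gene_id))
    g_abort("domain hit references unknown gene", "unknown_gene",
            gene_id = unique(hits$gene_id[bad]))
  rownames(hits) <- NULL

  structure(list(genome_id = genome_id,
                 contig_lengths = contig_lengths,
                 genes = genes, hits = hits,
                 genome_length = sum(contig_lengths)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d contigs (%.2f Mb), %d genes, %d domain hits\n",
              x$genome_id, length(x$contig_lengths), x$genome_length / 1e6,
              nrow(x$genes), nrow(x$hits)))
  invisible(x)
}

.check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    g_abort("input file not found", "missing_file", path = path)
  path
}

#' Read a genome annotation from a gene table and a domain-hit table
#'
#' The gene table is either GFF3 (`.gff`/`.gff3`, read with rtracklayer;
#' contig lengths taken from `##sequence-region` pragmas) or this package's
#' TSV dialect as written by [write_annotation()]: `##contig <id> <length>`
#' header lines followed by a tab-separated table with columns `contig_id`,
#' `gene_id`, `start`, `end`, `strand`, `product`. The domain table is TSV
#' with columns `gene_id`, `accession`, `namespace` and optional `score`,
#' `score_type`.
#'
#' @param gene_table_path,domain_table_path input paths.
#' @param genome_id genome identifier; defaults to the gene-table basename.
#' @return a validated [genome_annotation()].
#' @export
read_annotation <- function(gene_table_path, domain_table_path = NULL,
                            genome_id = NULL) {
  .check_file(gene_table_path)
  if (is.null(genome_id))
    genome_id <- sub("\\.(gff3?|tsv|txt)$", "", basename(gene_table_path))
  if (grepl("\\.gff3?$", gene_table_path)) {
    parsed <- .read_genes_gff3(gene_table_path)
  } else {
    parsed <- .read_genes_tsv(gene_table_path)
  }
  hits <- NULL
  if (!is.null(domain_table_path)) {
    .check_file(domain_table_path)
    hits <- read.delim(domain_table_path, stringsAsFactors = FALSE)
  }
  genome_annotation(genome_id, parsed$contig_lengths, parsed$genes, hits)
}

.read_genes_tsv <- function(path) {
  lines <- readLines(path)
  pragma <- grep("^##contig\t", lines, value = TRUE)
  if (!length(pragma))
    g_abort("TSV gene table lacks '##contig' header lines", "bad_gene_table",
            path = path)
  parts <- strsplit(pragma, "\t", fixed = TRUE)
  contig_lengths <- stats::setNames(
    as.integer(vapply(parts, `[`, "", 3L)),
    vapply(parts, `[`, "", 2L))
  body <- lines[!startsWith(lines, "##")]
  genes <- read.delim(text = paste(body, collapse = "\n"),
                      stringsAsFactors = FALSE)
  list(contig_lengths = contig_lengths, genes = genes)
}

.read_genes_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    g_abort("rtracklayer is required to read GFF3", "missing_dependency")
  gr <- rtracklayer::import(path, format = "gff3",
                            sequenceRegionsAsSeqinfo = TRUE)
  lens <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(lens)))
    g_abort("GFF3 lacks ##sequence-region pragmas for some contigs",
            "bad_contigs", contig_id = names(lens)[is.na(lens)])
  df <- as.data.frame(gr)
  ids <- if (!is.null(df$ID)) as.character(df$ID) else as.character(df$Name)
  prod <- if (!is.null(df$product)) as.character(df$product) else NA_character_
  genes <- data.frame(contig_id = as.character(df$seqnames),
                      gene_id = ids,
                      start = df$start,
                      end = df$end,
                      strand = as.character(df$strand),
                      product = prod, stringsAsFactors = FALSE)
  if (any(genes$strand == "*"))
    g_abort("strandless GFF3 features are not supported", "bad_strand",
            gene_id = genes$gene_id[genes$strand == "*"])
  list(contig_lengths = lens, genes = genes)
}

#' Write a genome annotation in the package TSV dialect
#'
#' @param ann a [genome_annotation()].
#' @param gene_table_path,domain_table_path output paths.
#' @return `ann`, invisibly.
#' @export
write_annotation <- function(ann, gene_table_path, domain_table_path) {
  stopifnot(inherits(ann, "genome_annotation"))
  con <- file(gene_table_path, "w")
  on.exit(close(con))
  writeLines(sprintf("##contig\t%s\t%d", names(ann$contig_lengths),
                     ann$contig_lengths), con)
  write.table(ann$genes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ann$hits, domain_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ann)
}
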