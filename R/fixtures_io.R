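# Plain-text fixture I/O: GFF3 gene coordinates (1-based inclusive on disk,
# 0-based half-open in memory), FASTA sequence sets, TSV tables and the
# JSON truth record.

#' Write simulator outputs as standard plain-text fixtures
#'
#' Writes whichever components are present in `x`: genomes as GFF3
#' (`genes_<id>.gff3`), CDS sets as FASTA (`cds_<id>.fasta`), the homology
#' pair table, count/length/sample/metabolite tables as TSV, and the
#' scenario/truth record as JSON. GFF3 coordinates are 1-based inclusive
#' (internal representation is 0-based half-open, so starts shift by +1 on
#' write).
#'
#' @param x Named list; recognised components: `genome_a`, `genome_b`
#'   (`sim_genome`), `cds_a`, `cds_b` (named character/`DNAStringSet`),
#'   `homology` (data frame), `counts`, `lengths`, `samples`,
#'   `metabolites`, `truth` (any JSON-serialisable list).
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of written paths.
#' @export
write_fixtures <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(path) {
    written <<- c(written, path)
    path
  }
  wgff <- function(genome, path) {
    g <- genome$genes
    gr <- GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- g$gene_id
    S4Vectors::mcols(gr)$ancestral_id <- g$ancestral_id
    S4Vectors::mcols(gr)$copy_label <- g$copy_label
    rtracklayer::export(gr, emit(path), format = "gff3")
  }
  wfa <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, emit(path))
  }
  wtsv <- function(df, path, rows = FALSE) {
    write.table(df, emit(path), sep = "\t", quote = FALSE,
                row.names = rows, col.names = TRUE)
  }
  if (!is.null(x$genome_a)) wgff(x$genome_a, file.path(dir, "genes_A.gff3"))
  if (!is.null(x$genome_b)) wgff(x$genome_b, file.path(dir, "genes_B.gff3"))
  if (!is.null(x$cds_a)) wfa(x$cds_a, file.path(dir, "cds_A.fasta"))
  if (!is.null(x$cds_b)) wfa(x$cds_b, file.path(dir, "cds_B.fasta"))
  if (!is.null(x$homology)) wtsv(x$homology, file.path(dir, "homology.tsv"))
  if (!is.null(x$counts)) wtsv(as.data.frame(x$counts),
                               file.path(dir, "counts.tsv"), rows = TRUE)
  if (!is.null(x$lengths))
    wtsv(data.frame(gene = names(x$lengths), length = unname(x$lengths)),
         file.path(dir, "lengths.tsv"))
  if (!is.null(x$samples)) wtsv(x$samples, file.path(dir, "samples.tsv"))
  if (!is.null(x$metabolites))
    wtsv(as.data.frame(x$metabolites), file.path(dir, "metabolites.tsv"),
         rows = TRUE)
  if (!is.null(x$truth))
    jsonlite::write_json(x$truth, emit(file.path(dir, "truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(written)
}

#' Read a genome written by [write_fixtures()] back from GFF3
#'
#' @param path GFF3 file path.
#' @param genome_id Genome id to stamp on the result.
#' @return A `sim_genome` with 0-based half-open coordinates and dense ranks.
#' @export
read_genome_gff3 <- function(path, genome_id = "genome") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  genes <- data.frame(
    gene_id = S4Vectors::mcols(gr)$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ancestral_id = S4Vectors::mcols(gr)$ancestral_id,
    copy_label = S4Vectors::mcols(gr)$copy_label,
    rank = 0L, stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  g <- structure(list(genome_id = genome_id, genes = genes,
                      chrom_order = unique(genes$chrom)),
                 class = "sim_genome")
  relayout <- relayout_genome(g)
  # keep the imported coordinates (relayout only refreshes ranks here)
  relayout$genes$start <- genes$start[match(relayout$genes$gene_id,
                                            genes$gene_id)]
  relayout$genes$end <- genes$end[match(relayout$genes$gene_id,
                                        genes$gene_id)]
  relayout
}

#' Read a homology pair table
#' @param path TSV with columns `gene_a`, `gene_b`.
#' @return Data frame.
#' @export
read_homology_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
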