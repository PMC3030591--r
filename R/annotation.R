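#' Gene annotation container
#'
#' A lightweight container for gene models: a \code{genes} table (gene_id,
#' chrom, strand, biotype) and an \code{exons} table (gene_id, chrom, strand,
#' start, end, exon_number). All in-memory coordinates are 0-based half-open;
#' exons are non-overlapping within a gene and sorted by genomic start
#' (\code{exon_number} follows genomic order, not transcription order).
#'
#' @param genes data.frame with columns gene_id, chrom, strand, biotype.
#' @param exons data.frame with columns gene_id, chrom, strand, start, end.
#' @return A \code{gene_annotation} object.
#' @export
gene_annotation <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "biotype") %in% names(genes)),
            all(c("gene_id", "chrom", "strand", "start", "end") %in% names(exons)))
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  exons$exon_number <- stats::ave(exons$start, exons$gene_id,
                                  FUN = seq_along)
  bad <- exons$end <= exons$start
  if (any(bad)) stop("empty exon interval for gene ", exons$gene_id[bad][1L])
  by_gene <- split(exons, exons$gene_id)
  for (g in by_gene) {
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
      stop("overlapping exons in gene ", g$gene_id[1L])
  }
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "rRNA"), "rRNA ),",
      nrow(x$exons), "exons\n")
  invisible(x)
}

# Gene spans (0-based half-open) as a data.frame aligned with ann$genes.
gene_spans <- function(ann) {
  s <- tapply(ann$exons$start, ann$exons$gene_id, min)
  e <- tapply(ann$exons$end, ann$exons$gene_id, max)
  idx <- match(ann$genes$gene_id, names(s))
  data.frame(gene_id = ann$genes$gene_id, chrom = ann$genes$chrom,
             strand = ann$genes$strand, start = as.integer(s[idx]),
             end = as.integer(e[idx]), stringsAsFactors = FALSE)
}

# Merged exon-model length (bases) per gene; exons within a gene are already
# non-overlapping so this is a plain sum.
exon_model_lengths <- function(ann) {
  len <- tapply(ann$exons$end - ann$exons$start, ann$exons$gene_id, sum)
  out <- as.integer(len[match(ann$genes$gene_id, names(len))])
  names(out) <- ann$genes$gene_id
  out
}

# Spliced (mature) transcript sequence of one gene, in transcription order.
spliced_sequence <- function(genome, ann, gene_id) {
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown gene ", gene_id)
  chrom_seq <- genome[[ex$chrom[1L]]]
  parts <- as.character(Biostrings::extractAt(
    chrom_seq, IRanges::IRanges(ex$start + 1L, ex$end)))
  s <- paste(parts, collapse = "")
  if (ex$strand[1L] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Write an annotation as GTF
#'
#' Emits one \code{exon} feature per exon with \code{gene_id} and
#' \code{biotype} attributes. On-disk coordinates are 1-based inclusive, per
#' the GTF convention; in-memory coordinates are 0-based half-open.
#'
#' @param ann A [gene_annotation()] object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gtf <- function(ann, path) {
  ex <- ann$exons
  bt <- ann$genes$biotype[match(ex$gene_id, ann$genes$gene_id)]
  lines <- sprintf(
    "%s\tsolidtags\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; biotype \"%s\";",
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, bt)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF into a gene annotation
#'
#' Imports \code{exon} features (via \pkg{rtracklayer}) and reassembles gene
#' models keyed on the \code{gene_id} attribute; a \code{biotype} attribute is
#' honoured when present, otherwise genes default to \code{protein_coding}.
#'
#' @param path GTF path.
#' @return A [gene_annotation()] object (0-based half-open in memory).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  bt <- if (!is.null(gr$biotype)) gr$biotype else rep("protein_coding", length(gr))
  exons <- data.frame(
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  first <- !duplicated(exons$gene_id)
  genes <- data.frame(gene_id = exons$gene_id[first],
                      chrom = exons$chrom[first],
                      strand = exons$strand[first],
                      biotype = bt[first],
                      stringsAsFactors = FALSE)
  gene_annotation(genes, exons[, c("gene_id", "chrom", "strand", "start", "end")])
}
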