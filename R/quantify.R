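#' Assign uniquely mapped tags to gene features
#'
#' Rules, applied in order per tag (any >= 1-base overlap counts):
#' \enumerate{
#'   \item same-strand overlap with an exon of exactly one gene -> exon tag
#'     of that gene (junction blocks count as exonic); exons of more than one
#'     gene -> ambiguous, excluded from counts;
#'   \item otherwise same-strand overlap with a gene body -> intron tag
#'     (more than one gene -> ambiguous);
#'   \item otherwise opposite-strand overlap with a gene body -> antisense
#'     tag (more than one gene -> ambiguous);
#'   \item otherwise intergenic (counted, unassigned).
#' }
#'
#' @param outcomes Mapping outcomes (only \code{status == "unique"} rows are
#'   used) carrying \code{chrom}, \code{blocks}, \code{strand}.
#' @param ann A [gene_annotation()].
#' @param chrom_lengths Named vector of chromosome lengths; blocks beyond a
#'   chromosome end raise an error when supplied.
#' @return list with \code{counts} (per gene: exon, intron, antisense),
#'   \code{labels} (per unique tag: feature class and gene) and
#'   \code{class_totals} (exon, intron, antisense, intergenic, ambiguous).
#' @export
assign_tags <- function(outcomes, ann, chrom_lengths = NULL) {
  uo <- outcomes[outcomes$status == "unique", , drop = FALSE]
  n <- nrow(uo)
  gene_tab <- gene_spans(ann)
  empty_counts <- data.frame(gene_id = ann$genes$gene_id, exon = 0L,
                             intron = 0L, antisense = 0L,
                             stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(counts = empty_counts,
                labels = data.frame(id = character(0), feature = character(0),
                                    gene_id = character(0)),
                class_totals = c(exon = 0L, intron = 0L, antisense = 0L,
                                 intergenic = 0L, ambiguous = 0L)))
  bl <- strsplit(uo$blocks, ",", fixed = TRUE)
  nb <- lengths(bl)
  flat <- unlist(bl, use.names = FALSE)
  se <- matrix(as.integer(unlist(strsplit(flat, "-", fixed = TRUE),
                                 use.names = FALSE)), ncol = 2L, byrow = TRUE)
  tag_of_block <- rep.int(seq_len(n), nb)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[uo$chrom[tag_of_block]]
    if (any(is.na(lim)) || any(se[, 2L] > lim))
      stop("mapped block beyond chromosome bounds")
  }
  gr_blocks <- GenomicRanges::GRanges(
    uo$chrom[tag_of_block],
    IRanges::IRanges(start = se[, 1L] + 1L, end = se[, 2L]),
    strand = uo$strand[tag_of_block])
  gr_exons <- GenomicRanges::GRanges(
    ann$exons$chrom,
    IRanges::IRanges(ann$exons$start + 1L, ann$exons$end),
    strand = ann$exons$strand)
  gr_genes <- GenomicRanges::GRanges(
    gene_tab$chrom, IRanges::IRanges(gene_tab$start + 1L, gene_tab$end),
    strand = gene_tab$strand)

  genes_hit <- function(query, subject, subject_gene) {
    ov <- GenomicRanges::findOverlaps(query, subject, ignore.strand = FALSE)
    tg <- tag_of_block[S4Vectors::queryHits(ov)]
    gid <- subject_gene[S4Vectors::subjectHits(ov)]
    u <- !duplicated(paste(tg, gid, sep = "\r"))
    list(tag = tg[u], gene = gid[u])
  }

  feature <- rep("intergenic", n)
  gene_assigned <- rep(NA_character_, n)

  hit_ex <- genes_hit(gr_blocks, gr_exons, ann$exons$gene_id)
  ngene_ex <- tabulate(hit_ex$tag, nbins = n)
  first_ex <- hit_ex$gene[match(seq_len(n), hit_ex$tag)]
  feature[ngene_ex == 1L] <- "exon"
  gene_assigned[ngene_ex == 1L] <- first_ex[ngene_ex == 1L]
  feature[ngene_ex > 1L] <- "ambiguous"

  rest <- feature == "intergenic"
  hit_gb <- genes_hit(gr_blocks, gr_genes, gene_tab$gene_id)
  ngene_gb <- tabulate(hit_gb$tag, nbins = n)
  first_gb <- hit_gb$gene[match(seq_len(n), hit_gb$tag)]
  sel <- rest & ngene_gb == 1L
  feature[sel] <- "intron"
  gene_assigned[sel] <- first_gb[sel]
  feature[rest & ngene_gb > 1L] <- "ambiguous"

  rest <- feature == "intergenic"
  gr_flip <- gr_blocks
  GenomicRanges::strand(gr_flip) <- ifelse(
    as.character(GenomicRanges::strand(gr_blocks)) == "+", "-", "+")
  hit_as <- genes_hit(gr_flip, gr_genes, gene_tab$gene_id)
  ngene_as <- tabulate(hit_as$tag, nbins = n)
  first_as <- hit_as$gene[match(seq_len(n), hit_as$tag)]
  sel <- rest & ngene_as == 1L
  feature[sel] <- "antisense"
  gene_assigned[sel] <- first_as[sel]
  feature[rest & ngene_as > 1L] <- "ambiguous"

  counts <- empty_counts
  for (cl in c("exon", "intron", "antisense")) {
    t <- table(gene_assigned[feature == cl])
    idx <- match(names(t), counts$gene_id)
    counts[[cl]][idx] <- as.integer(t)
  }
  class_totals <- c(exon = sum(feature == "exon"),
                    intron = sum(feature == "intron"),
                    antisense = sum(feature == "antisense"),
                    intergenic = sum(feature == "intergenic"),
                    ambiguous = sum(feature == "ambiguous"))
  list(counts = counts,
       labels = data.frame(id = uo$id, feature = feature,
                           gene_id = gene_assigned, stringsAsFactors = FALSE),
       class_totals = class_totals)
}

#' Call expressed genes
#'
#' A gene is expressed when more than one tag (by default, at least 2)
#' matches its exon regions.
#'
#' @param counts Gene counts from [assign_tags()].
#' @param min_exon_tags Threshold; \code{expressed <=> exon >= min_exon_tags}.
#' @return Logical vector named by gene.
#' @export
call_expressed <- function(counts, min_exon_tags = 2L) {
  stats::setNames(counts$exon >= min_exon_tags, counts$gene_id)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' \code{RPKM = 1e9 * C / (N * L)} with C the gene's exon tag count, N the
#' library's uniquely mapped tag total and L the merged exon-model length in
#' bases.
#'
#' @param C Exon tag count(s).
#' @param N Library unique mapped total (> 0).
#' @param L Exon model length(s) in bases (> 0).
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("library size N must be positive")
  if (any(L <= 0)) stop("exon model length L must be positive")
  1e9 * C / (N * L)
}

#' Per-gene expression table for one library
#'
#' @param counts Gene counts from [assign_tags()].
#' @param ann A [gene_annotation()].
#' @param N Library unique mapped tag total; defaults to the sum of all
#'   feature-class totals being unavailable here, so pass the mapper's
#'   \code{unique} count.
#' @param min_exon_tags Expressed-gene threshold (see [call_expressed()]).
#' @return data.frame: gene_id, exon tags, exon model length, RPKM,
#'   expressed flag.
#' @export
expression_table <- function(counts, ann, N, min_exon_tags = 2L) {
  L <- exon_model_lengths(ann)[counts$gene_id]
  data.frame(gene_id = counts$gene_id,
             exon_tags = counts$exon,
             exon_model_length = as.integer(L),
             rpkm = rpkm(counts$exon, N, L),
             expressed = counts$exon >= min_exon_tags,
             stringsAsFactors = FALSE)
}
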