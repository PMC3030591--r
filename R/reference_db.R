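#' Reference sequence set
#'
#' A set of named nucleotide sequences with their color-space encodings, used
#' as an alignment target. Categories: \code{genome} (the chromosomes),
#' \code{junction} (exon-junction sequences, with a record table for lifting
#' hits back to genomic coordinates) and \code{rRNA}. Color encodings use an
#' assumed preceding anchor 'T'; the first color of every reference sequence
#' depends on that convention and is never compared by the aligner, which
#' matches patterns at color offsets >= 1 only.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param category One of \code{"genome"}, \code{"junction"}, \code{"rRNA"}.
#' @param records For junction sets, the JunctionRecord data.frame.
#' @return A \code{reference_set} object.
#' @export
reference_set <- function(seqs, category = c("genome", "junction", "rRNA"),
                          records = NULL) {
  category <- match.arg(category)
  if (anyDuplicated(names(seqs))) stop("reference names must be unique")
  colors <- vapply(seqs, encode_colors, character(1), anchor = "T",
                   USE.NAMES = FALSE)
  structure(list(names = names(seqs), seqs = unname(seqs), colors = colors,
                 category = category, records = records),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set [", x$category, "]: ", length(x$names), " sequences\n",
      sep = "")
  invisible(x)
}

#' Build the genome reference set
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return A genome-category [reference_set()].
#' @export
build_genome_db <- function(genome) {
  seqs <- as.character(genome)
  reference_set(seqs, "genome")
}

#' Build the ribosomal RNA reference set
#'
#' One sequence per rRNA-biotype gene (spliced if multi-exon), on the gene's
#' strand, used to remove rRNA remnants before genome alignment. An
#' annotation without rRNA genes yields an empty set with a warning (the
#' filter stage then becomes a no-op).
#'
#' @param ann A [gene_annotation()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return An rRNA-category [reference_set()].
#' @export
build_rrna_db <- function(ann, genome) {
  ids <- ann$genes$gene_id[ann$genes$biotype == "rRNA"]
  if (length(ids) == 0L) {
    warning("annotation contains no rRNA genes; rRNA filter will be a no-op")
    return(reference_set(stats::setNames(character(0), character(0)), "rRNA"))
  }
  seqs <- vapply(ids, spliced_sequence, character(1), genome = genome,
                 ann = ann)
  reference_set(stats::setNames(seqs, ids), "rRNA")
}

#' Build the exon-junction reference database
#'
#' For every multi-exon gene, exon flanks around splice points are
#' concatenated into artificial junction sequences so that tags spanning a
#' junction align contiguously. Each junction takes the last
#' \code{min(J, exon length)} bases of the upstream exon (in transcription
#' order) followed by the first \code{min(J, exon length)} bases of the
#' downstream exon, on the gene's strand. \code{mode = "all_pairs"} pairs
#' every ordered exon pair within a gene (capturing combinatorial exon usage
#' from alternative splicing); \code{mode = "adjacent"} keeps only
#' consecutive pairs. Duplicate sequences are deduplicated, retaining the
#' first record's provenance.
#'
#' @param ann A [gene_annotation()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param J Flank length in bases; defaults to 34, one less than the tag
#'   length, the minimal flank that guarantees a 35-nt junction-spanning tag
#'   fits entirely inside the junction sequence.
#' @param mode \code{"all_pairs"} (default) or \code{"adjacent"}.
#' @return A junction-category [reference_set()] whose \code{records} table
#'   holds, per junction: gene, chromosome, strand, the genomic intervals of
#'   both flanks (0-based half-open) and the breakpoint offset within the
#'   junction sequence.
#' @export
build_junction_db <- function(ann, genome, J = 34L,
                              mode = c("all_pairs", "adjacent")) {
  mode <- match.arg(mode)
  if (J < 1L) stop("flank length J must be at least 1")
  recs <- list()
  seqs <- character(0)
  for (g in unique(ann$exons$gene_id)) {
    ex <- ann$exons[ann$exons$gene_id == g, , drop = FALSE]
    k <- nrow(ex)
    if (k < 2L) next
    strand <- ex$strand[1L]
    chrom <- ex$chrom[1L]
    # exon indices in transcription order
    ord <- if (strand == "+") seq_len(k) else rev(seq_len(k))
    pairs <- if (mode == "adjacent") {
      cbind(ord[-k], ord[-1L])
    } else {
      idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      cbind(ord[idx[, "row"]], ord[idx[, "col"]])
    }
    chrom_seq <- genome[[chrom]]
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      li <- ex$end[i] - ex$start[i]
      lj <- ex$end[j] - ex$start[j]
      fu <- min(J, li)
      fd <- min(J, lj)
      if (strand == "+") {
        up <- c(ex$end[i] - fu, ex$end[i])
        dn <- c(ex$start[j], ex$start[j] + fd)
        sq <- paste0(
          as.character(Biostrings::subseq(chrom_seq, up[1L] + 1L, up[2L])),
          as.character(Biostrings::subseq(chrom_seq, dn[1L] + 1L, dn[2L])))
      } else {
        up <- c(ex$start[i], ex$start[i] + fu)
        dn <- c(ex$end[j] - fd, ex$end[j])
        sq <- paste0(
          as.character(Biostrings::reverseComplement(
            Biostrings::subseq(chrom_seq, up[1L] + 1L, up[2L]))),
          as.character(Biostrings::reverseComplement(
            Biostrings::subseq(chrom_seq, dn[1L] + 1L, dn[2L]))))
      }
      id <- sprintf("%s|exon%d|exon%d|%s:%d-%d,%d-%d", g,
                    which(ord == i), which(ord == j), chrom,
                    up[1L], up[2L], dn[1L], dn[2L])
      recs[[length(recs) + 1L]] <- data.frame(
        id = id, gene_id = g, chrom = chrom, strand = strand,
        up_start = up[1L], up_end = up[2L],
        down_start = dn[1L], down_end = dn[2L],
        breakpoint = fu, stringsAsFactors = FALSE)
      seqs[[id]] <- sq
    }
  }
  if (length(recs) == 0L)
    return(reference_set(stats::setNames(character(0), character(0)),
                         "junction",
                         records = data.frame(id = character(0))))
  records <- do.call(rbind, recs)
  dup <- duplicated(unname(seqs))
  reference_set(seqs[!dup], "junction", records = records[!dup, , drop = FALSE])
}

#' Lift a junction-sequence hit to genomic blocks
#'
#' A hit covering junction-sequence bases \code{[offset, offset + len)} is
#' lifted to genomic coordinates. Hits spanning the breakpoint by at least
#' one base on each side yield two forward-strand genomic intervals, ordered
#' by transcription; hits confined to one flank are flagged non-spanning
#' (they are redundant with genomic alignment and callers discard them).
#'
#' @param offset 0-based start of the hit within the junction sequence.
#' @param len Hit length in bases.
#' @param record One row of a junction [reference_set()] \code{records} table.
#' @return list(spanning = logical, blocks = list of c(start, end) or NULL).
#' @export
liftover_junction_hit <- function(offset, len, record) {
  fu <- record$up_end - record$up_start
  fd <- record$down_end - record$down_start
  if (offset < 0 || offset + len > fu + fd)
    stop("hit interval outside the junction sequence")
  b <- record$breakpoint
  if (!(offset < b && offset + len > b))
    return(list(spanning = FALSE, blocks = NULL))
  up_len <- b - offset
  dn_len <- offset + len - b
  if (record$strand == "+") {
    blocks <- list(c(record$up_end - up_len, record$up_end),
                   c(record$down_start, record$down_start + dn_len))
  } else {
    blocks <- list(c(record$up_start, record$up_start + up_len),
                   c(record$down_end - dn_len, record$down_end))
  }
  list(spanning = TRUE, blocks = blocks)
}

#' Write a junction reference set as FASTA plus a record sidecar
#'
#' @param db A junction [reference_set()].
#' @param fasta Output FASTA path (structured headers
#'   \code{gene|exonI|exonJ|coords}).
#' @param tsv Output TSV path for the JunctionRecord table.
#' @return Invisibly the paths.
#' @export
write_junction_db <- function(db, fasta, tsv) {
  x <- Biostrings::DNAStringSet(stats::setNames(db$seqs, db$names))
  Biostrings::writeXStringSet(x, fasta)
  utils::write.table(db$records, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta, tsv))
}
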