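#' Generate a random genome
#'
#' Draws i.i.d. bases with a specified GC content. Chromosomes are named
#' \code{chr1}, \code{chr2}, ...
#'
#' @param lengths Integer vector of chromosome lengths (bases), all positive.
#' @param gc Target GC fraction in (0, 1).
#' @param seed Optional integer seed; identical seeds give identical genomes.
#' @return A named [Biostrings::DNAStringSet].
#' @export
generate_genome <- function(lengths, gc = 0.45, seed = NULL) {
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  base_ints <- utf8ToInt("ACGT")
  seqs <- vapply(lengths, function(n) {
    intToUtf8(base_ints[sample.int(4L, n, replace = TRUE, prob = prob)])
  }, character(1))
  names(seqs) <- paste0("chr", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

#' Generate a random gene annotation
#'
#' Places non-overlapping gene models along the genome, separated by random
#' intergenic gaps, with random strands. Protein-coding genes draw an exon
#' count, exon lengths and intron lengths uniformly from the given ranges;
#' rRNA genes are single-exon. Fails with a capacity error when the requested
#' genes do not fit.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param n_genes Number of protein-coding genes.
#' @param n_rrna Number of rRNA genes.
#' @param exon_count_range,exon_len_range,intron_len_range,rrna_len_range
#'   Inclusive integer ranges sampled uniformly.
#' @param gap_range Intergenic gap range (bases).
#' @param seed Optional integer seed.
#' @return A [gene_annotation()] object.
#' @export
generate_annotation <- function(genome, n_genes, n_rrna = 0L,
                                exon_count_range = c(1L, 4L),
                                exon_len_range = c(100L, 300L),
                                intron_len_range = c(100L, 400L),
                                rrna_len_range = c(500L, 1500L),
                                gap_range = c(50L, 300L),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runif_int <- function(r) sample(seq.int(r[1L], r[2L]), 1L)
  total <- n_genes + n_rrna
  biotypes <- sample(c(rep("protein_coding", n_genes), rep("rRNA", n_rrna)))
  chrom_names <- names(genome)
  chrom_lens <- Biostrings::width(genome)
  ci <- 1L
  cursor <- 0L
  genes <- vector("list", total)
  exons <- vector("list", total)
  n_pc <- 0L
  n_rr <- 0L
  for (i in seq_len(total)) {
    bt <- biotypes[i]
    if (bt == "rRNA") {
      n_rr <- n_rr + 1L
      gid <- sprintf("rrna%02d", n_rr)
      ex_lens <- runif_int(rrna_len_range)
      in_lens <- integer(0)
    } else {
      n_pc <- n_pc + 1L
      gid <- sprintf("gene%04d", n_pc)
      k <- runif_int(exon_count_range)
      ex_lens <- vapply(seq_len(k), function(.) runif_int(exon_len_range),
                        integer(1))
      in_lens <- if (k > 1L)
        vapply(seq_len(k - 1L), function(.) runif_int(intron_len_range),
               integer(1)) else integer(0)
    }
    span <- sum(ex_lens) + sum(in_lens)
    gap <- runif_int(gap_range)
    while (cursor + gap + span > chrom_lens[ci]) {
      ci <- ci + 1L
      cursor <- 0L
      if (ci > length(chrom_names))
        stop("insufficient genome space: placed ", i - 1L, " of ", total,
             " genes")
    }
    gstart <- cursor + gap
    starts <- gstart + cumsum(c(0L, ex_lens[-length(ex_lens)] +
                                  if (length(in_lens)) in_lens else integer(0)))
    strand <- sample(c("+", "-"), 1L)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom_names[ci],
                             strand = strand, biotype = bt,
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, chrom = chrom_names[ci],
                             strand = strand, start = starts,
                             end = starts + ex_lens, stringsAsFactors = FALSE)
    cursor <- gstart + span
  }
  gene_annotation(do.call(rbind, genes), do.call(rbind, exons))
}

#' Generate ground-truth expression for two conditions
#'
#' Baseline transcript abundances are drawn log-normal (heavy-tailed, as in
#' real RNA-seq libraries). A chosen set of protein-coding genes is flagged
#' differentially expressed: their condition-1 abundance is multiplied by the
#' fold change (up) or its reciprocal (down) relative to condition 2.
#' Abundances are molar fractions, normalized to sum to 1 per condition over
#' protein-coding genes; rRNA gene abundance is governed separately by the
#' simulator's rRNA contamination fraction.
#'
#' @param ann A [gene_annotation()] object.
#' @param n_de Number of DE genes (must not exceed the protein-coding count).
#' @param fold_change True fold change applied to DE genes (condition 1 vs 2).
#' @param up_frac Fraction of DE genes that are up-regulated in condition 1.
#' @param meanlog,sdlog Log-normal baseline parameters.
#' @param seed Optional integer seed.
#' @return data.frame with gene_id, is_de, direction (\code{up}/\code{down}/
#'   \code{ns}), true_fc (condition1/condition2; 1 for non-DE genes) and
#'   normalized abundance_1, abundance_2.
#' @export
generate_expression <- function(ann, n_de, fold_change = 4, up_frac = 0.5,
                                meanlog = 0, sdlog = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pc <- ann$genes$gene_id[ann$genes$biotype == "protein_coding"]
  if (n_de > length(pc))
    stop("n_de exceeds the number of protein-coding genes")
  base <- stats::rlnorm(length(pc), meanlog, sdlog)
  de_idx <- sample(seq_along(pc), n_de)
  n_up <- round(n_de * up_frac)
  dir <- rep("ns", length(pc))
  dir[de_idx[seq_len(n_up)]] <- "up"
  if (n_de > n_up) dir[de_idx[seq.int(n_up + 1L, n_de)]] <- "down"
  fc <- rep(1, length(pc))
  fc[dir == "up"] <- fold_change
  fc[dir == "down"] <- 1 / fold_change
  a1 <- base * fc
  a2 <- base
  data.frame(gene_id = pc,
             is_de = dir != "ns",
             direction = dir,
             true_fc = fc,
             abundance_1 = a1 / sum(a1),
             abundance_2 = a2 / sum(a2),
             stringsAsFactors = FALSE)
}

# Map a spliced-coordinate interval [t, t + len) of a gene to genomic blocks
# (0-based half-open, forward-strand coordinates, ordered by transcription).
# ex: the gene's exons in genomic order; strand: gene strand.
spliced_to_blocks <- function(ex, strand, t, len) {
  ex_ord <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  lens <- (ex$end - ex$start)[ex_ord]
  cum <- cumsum(c(0L, lens))
  t2 <- t + len
  blocks <- list()
  for (j in seq_along(ex_ord)) {
    lo <- max(t, cum[j])
    hi <- min(t2, cum[j + 1L])
    if (lo >= hi) next
    k <- ex_ord[j]
    if (strand == "+") {
      gs <- ex$start[k] + (lo - cum[j])
      ge <- ex$start[k] + (hi - cum[j])
    } else {
      ge <- ex$end[k] - (lo - cum[j])
      gs <- ex$end[k] - (hi - cum[j])
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  blocks
}

blocks_to_string <- function(blocks) {
  paste(vapply(blocks, function(b) paste0(b[1L], "-", b[2L]), character(1)),
        collapse = ",")
}

# Fast vectorised reverse complement on plain character vectors.
revcomp_chr <- function(s) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", s))
}

#' Simulate a stranded color-space tag library
#'
#' Emits \code{n_tags} 35-nt tags (anchor base + 35 color calls + 35 quality
#' values) from a synthetic genome with ground truth. Tag classes:
#' \describe{
#'   \item{mature}{sampled uniformly along spliced transcripts, genes weighted
#'     by abundance x spliced length; a tag crossing an exon boundary is
#'     recorded as \code{junction_spanning}, otherwise \code{mature_exonic}.}
#'   \item{antisense}{sampled like mature tags but emitted from the opposite
#'     strand (fraction \code{antisense_frac}).}
#'   \item{pre-mRNA}{fraction \code{intron_frac}, drawn wholly within introns
#'     of unspliced transcripts, genes weighted by abundance x eligible
#'     intronic positions.}
#'   \item{rRNA}{fraction \code{rrna_frac}, drawn from rRNA genes.}
#' }
#' Color-call errors are i.i.d. per color at \code{color_error_rate},
#' replacing the true color with a uniformly chosen different color. A
#' fraction \code{lowq_frac} of tags receives per-color quality values
#' uniform on 2..7 (mean below the QV-8 filter threshold); all others uniform
#' on 15..30. Transcripts shorter than the tag are excluded with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param ann A [gene_annotation()].
#' @param truth Expression truth from [generate_expression()]; the
#'   \code{condition} argument selects which abundance column drives sampling.
#' @param n_tags Number of tags to emit.
#' @param condition 1 or 2.
#' @param tag_len Tag length in colors (and decoded bases); default 35.
#' @param color_error_rate Per-color error probability.
#' @param antisense_frac,intron_frac,rrna_frac,lowq_frac Class fractions; the
#'   contamination fractions must sum to less than 1.
#' @param seed Optional integer seed.
#' @param id_prefix Prefix for tag ids.
#' @return list with \code{reads} (a \code{color_reads} data.frame with
#'   quals) and \code{truth} (per-tag TagTruth data.frame: origin gene, class,
#'   antisense flag, chrom, genomic blocks, genomic strand, injected error
#'   positions, low-quality flag).
#' @export
simulate_tags <- function(genome, ann, truth, n_tags, condition = 1L,
                          tag_len = 35L, color_error_rate = 0.02,
                          antisense_frac = 0.06, intron_frac = 0.15,
                          rrna_frac = 0.10, lowq_frac = 0.10,
                          seed = NULL, id_prefix = "tag") {
  fracs <- c(rrna_frac, intron_frac, antisense_frac, lowq_frac,
             color_error_rate)
  if (any(fracs < 0) || any(fracs[1:4] > 1))
    stop("fractions must lie in [0, 1]")
  if (rrna_frac + intron_frac + antisense_frac >= 1)
    stop("contamination fractions must sum to less than 1")
  if (!is.null(seed)) set.seed(seed)

  abcol <- if (condition == 1L) "abundance_1" else "abundance_2"
  ab <- stats::setNames(truth[[abcol]], truth$gene_id)

  pc_ids <- truth$gene_id
  exons_by_gene <- split(ann$exons, ann$exons$gene_id)
  gene_tbl <- ann$genes
  strand_of <- stats::setNames(gene_tbl$strand, gene_tbl$gene_id)
  chrom_of <- stats::setNames(gene_tbl$chrom, gene_tbl$gene_id)

  # Spliced sequences and weights for mature sampling
  spl_len <- vapply(pc_ids, function(g) {
    ex <- exons_by_gene[[g]]
    sum(ex$end - ex$start)
  }, numeric(1))
  eligible <- spl_len >= tag_len
  if (!all(eligible))
    warning(sum(!eligible), " transcript(s) shorter than the tag length ",
            "excluded from sampling")
  mature_w <- ab[pc_ids] * spl_len
  mature_w[!eligible] <- 0
  if (sum(mature_w) <= 0) stop("no transcript is long enough to sample from")

  spl_seq <- new.env(parent = emptyenv())
  get_spliced <- function(g) {
    if (is.null(spl_seq[[g]])) spl_seq[[g]] <- spliced_sequence(genome, ann, g)
    spl_seq[[g]]
  }

  # Intron catalogue: per gene, intron intervals with >= tag_len positions
  intron_tbl <- do.call(rbind, lapply(pc_ids, function(g) {
    ex <- exons_by_gene[[g]]
    if (nrow(ex) < 2L) return(NULL)
    is_ <- ex$end[-nrow(ex)]
    ie_ <- ex$start[-1L]
    keep <- (ie_ - is_) >= tag_len
    if (!any(keep)) return(NULL)
    data.frame(gene_id = g, start = is_[keep], end = ie_[keep],
               stringsAsFactors = FALSE)
  }))
  has_introns <- !is.null(intron_tbl) && nrow(intron_tbl) > 0L
  if (intron_frac > 0 && !has_introns)
    stop("intron_frac > 0 but no intron can hold a full tag")
  if (has_introns) {
    intron_tbl$npos <- intron_tbl$end - intron_tbl$start - tag_len + 1L
    intron_tbl$w <- ab[intron_tbl$gene_id] * intron_tbl$npos
  }

  rr_ids <- gene_tbl$gene_id[gene_tbl$biotype == "rRNA"]
  if (rrna_frac > 0 && length(rr_ids) == 0L)
    stop("rrna_frac > 0 but the annotation has no rRNA genes")
  rr_ex <- if (length(rr_ids))
    ann$exons[ann$exons$gene_id %in% rr_ids, , drop = FALSE] else NULL
  if (!is.null(rr_ex)) {
    rr_ex$npos <- rr_ex$end - rr_ex$start - tag_len + 1L
    rr_ex <- rr_ex[rr_ex$npos > 0L, , drop = FALSE]
    if (rrna_frac > 0 && nrow(rr_ex) == 0L)
      stop("rRNA genes shorter than the tag length")
  }

  cls <- sample(c("rrna", "intron", "antisense", "mature"), n_tags,
                replace = TRUE,
                prob = c(rrna_frac, intron_frac, antisense_frac,
                         1 - rrna_frac - intron_frac - antisense_frac))

  seqs <- character(n_tags)        # sense-of-read (as sequenced) base sequence
  gene_v <- character(n_tags)
  class_v <- character(n_tags)
  anti_v <- logical(n_tags)
  chrom_v <- character(n_tags)
  blocks_v <- character(n_tags)
  strand_v <- character(n_tags)

  chrom_str <- stats::setNames(as.character(genome), names(genome))

  # mature + antisense tags
  mi <- which(cls %in% c("mature", "antisense"))
  if (length(mi)) {
    gsel <- sample(pc_ids, length(mi), replace = TRUE,
                   prob = mature_w / sum(mature_w))
    for (g in unique(gsel)) {
      rows <- mi[gsel == g]
      s <- get_spliced(g)
      L <- nchar(s)
      starts <- sample.int(L - tag_len + 1L, length(rows), replace = TRUE) - 1L
      frag <- substring(s, starts + 1L, starts + tag_len)
      gstrand <- strand_of[[g]]
      ex <- exons_by_gene[[g]]
      k <- nrow(ex)
      ord <- if (gstrand == "+") seq_len(k) else rev(seq_len(k))
      bnd <- cumsum(c(0L, (ex$end - ex$start)[ord]))
      e1 <- findInterval(starts, bnd)
      e2 <- findInterval(starts + tag_len - 1L, bnd)
      single <- e1 == e2
      blk <- character(length(rows))
      if (any(single)) {
        kx <- ord[e1[single]]
        if (gstrand == "+") {
          gs <- ex$start[kx] + (starts[single] - bnd[e1[single]])
          blk[single] <- paste0(gs, "-", gs + tag_len)
        } else {
          ge <- ex$end[kx] - (starts[single] - bnd[e1[single]])
          blk[single] <- paste0(ge - tag_len, "-", ge)
        }
      }
      for (k2 in which(!single))
        blk[k2] <- blocks_to_string(
          spliced_to_blocks(ex, gstrand, starts[k2], tag_len))
      gene_v[rows] <- g
      class_v[rows] <- ifelse(single, "mature_exonic", "junction_spanning")
      chrom_v[rows] <- chrom_of[[g]]
      blocks_v[rows] <- blk
      anti <- cls[rows] == "antisense"
      anti_v[rows] <- anti
      seqs[rows] <- ifelse(anti, revcomp_chr(frag), frag)
      strand_v[rows] <- ifelse(anti, if (gstrand == "+") "-" else "+", gstrand)
    }
  }

  # pre-mRNA intronic tags
  ii <- which(cls == "intron")
  if (length(ii)) {
    isel <- sample.int(nrow(intron_tbl), length(ii), replace = TRUE,
                       prob = intron_tbl$w / sum(intron_tbl$w))
    offs <- as.integer((stats::runif(length(ii)) * intron_tbl$npos[isel]) %/% 1)
    gstart <- intron_tbl$start[isel] + offs
    g <- intron_tbl$gene_id[isel]
    ch <- unname(chrom_of[g])
    gstrand <- unname(strand_of[g])
    sq <- substring(chrom_str[ch], gstart + 1L, gstart + tag_len)
    neg <- gstrand == "-"
    sq[neg] <- revcomp_chr(sq[neg])
    seqs[ii] <- sq
    gene_v[ii] <- g
    class_v[ii] <- "pre_mRNA_intronic"
    chrom_v[ii] <- ch
    blocks_v[ii] <- paste0(gstart, "-", gstart + tag_len)
    strand_v[ii] <- gstrand
  }

  # rRNA tags
  ri <- which(cls == "rrna")
  if (length(ri)) {
    rsel <- sample.int(nrow(rr_ex), length(ri), replace = TRUE,
                       prob = rr_ex$npos / sum(rr_ex$npos))
    offs <- as.integer((stats::runif(length(ri)) * rr_ex$npos[rsel]) %/% 1)
    gstart <- rr_ex$start[rsel] + offs
    ch <- rr_ex$chrom[rsel]
    gstrand <- rr_ex$strand[rsel]
    sq <- substring(chrom_str[ch], gstart + 1L, gstart + tag_len)
    neg <- gstrand == "-"
    sq[neg] <- revcomp_chr(sq[neg])
    seqs[ri] <- sq
    gene_v[ri] <- rr_ex$gene_id[rsel]
    class_v[ri] <- "rRNA"
    chrom_v[ri] <- ch
    blocks_v[ri] <- paste0(gstart, "-", gstart + tag_len)
    strand_v[ri] <- gstrand
  }

  # encode, inject color errors
  cols_mat <- {
    m <- matrix(.base_code[vapply(seqs, utf8ToInt, integer(tag_len),
                                  USE.NAMES = FALSE)], nrow = tag_len)
    prev <- rbind(rep.int(3L, ncol(m)), m[-tag_len, , drop = FALSE]) # anchor T
    matrix(bitwXor(prev, m), nrow = tag_len)
  }
  err_mask <- matrix(stats::runif(tag_len * n_tags) < color_error_rate,
                     nrow = tag_len)
  n_err <- sum(err_mask)
  if (n_err > 0L) {
    shift <- sample.int(3L, n_err, replace = TRUE)
    cols_mat[err_mask] <- (cols_mat[err_mask] + shift) %% 4L
  }
  chr_mat <- cols_mat + .ZERO_INT
  colors <- vapply(seq_len(n_tags), function(j) intToUtf8(chr_mat[, j]),
                   character(1))
  err_pos <- vapply(seq_len(n_tags), function(j) {
    p <- which(err_mask[, j])
    if (length(p)) paste(p, collapse = ",") else ""
  }, character(1))

  # qualities
  lowq <- stats::runif(n_tags) < lowq_frac
  qv <- matrix(0L, nrow = tag_len, ncol = n_tags)
  n_low <- sum(lowq)
  if (n_low > 0L)
    qv[, lowq] <- sample(2:7, tag_len * n_low, replace = TRUE)
  if (n_low < n_tags)
    qv[, !lowq] <- sample(15:30, tag_len * (n_tags - n_low), replace = TRUE)
  quals <- vapply(seq_len(n_tags), function(j) paste(qv[, j], collapse = " "),
                  character(1))

  ids <- sprintf("%s_%d", id_prefix, seq_len(n_tags))
  reads <- data.frame(id = ids, anchor = "T", colors = colors, quals = quals,
                      stringsAsFactors = FALSE)
  class(reads) <- c("color_reads", "data.frame")
  tag_truth <- data.frame(id = ids, gene_id = gene_v, class = class_v,
                          antisense = anti_v, chrom = chrom_v,
                          blocks = blocks_v, strand = strand_v,
                          n_errors = colSums(err_mask),
                          error_pos = err_pos, lowq = lowq,
                          stringsAsFactors = FALSE)
  list(reads = reads, truth = tag_truth)
}

#' Simulate a complete two-library study
#'
#' Convenience wrapper: genome, annotation, expression truth and two tag
#' libraries (condition 1 = tumor analog, condition 2 = normal analog), all
#' from one master seed. Defaults follow the package's reference study
#' conditions: a 500-kb genome, 300 protein-coding genes plus 2 rRNA genes,
#' 50 DE genes at fold change 4, 200,000 tags per library, 2% color error,
#' 10% rRNA, 15% intronic and 6% antisense tags.
#'
#' @param genome_length Total genome size in bases (single chromosome).
#' @param n_genes,n_rrna,n_de,fold_change See the component generators.
#' @param n_tags Tags per library.
#' @param seed Master seed; component seeds are derived from it.
#' @param ... Passed to [simulate_tags()].
#' @return list(genome, annotation, expression, lib1, lib2).
#' @export
simulate_study <- function(genome_length = 500000L, n_genes = 300L,
                           n_rrna = 2L, n_de = 50L, fold_change = 4,
                           n_tags = 200000L, seed = 1L, ...) {
  genome <- generate_genome(genome_length, gc = 0.45, seed = seed)
  ann <- generate_annotation(genome, n_genes, n_rrna,
                             exon_count_range = c(2L, 4L),
                             seed = seed + 101L)
  expr <- generate_expression(ann, n_de, fold_change = fold_change,
                              seed = seed + 202L)
  lib1 <- simulate_tags(genome, ann, expr, n_tags, condition = 1L,
                        seed = seed + 303L, id_prefix = "lib1", ...)
  lib2 <- simulate_tags(genome, ann, expr, n_tags, condition = 2L,
                        seed = seed + 404L, id_prefix = "lib2", ...)
  list(genome = genome, annotation = ann, expression = expr,
       lib1 = lib1, lib2 = lib2)
}

#' Write a simulated library and its truth to disk
#'
#' @param lib A list from [simulate_tags()].
#' @param outdir Output directory (created if needed).
#' @param name Basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_library <- function(lib, outdir, name) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cs <- file.path(outdir, paste0(name, ".csfasta"))
  qu <- file.path(outdir, paste0(name, ".qual"))
  tr <- file.path(outdir, paste0(name, "_truth.tsv"))
  write_csfasta(lib$reads, cs, qu)
  utils::write.table(lib$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cs, qu, tr))
}
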