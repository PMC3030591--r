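#' Mapper configuration
#'
#' The hierarchical cascade: full-length alignment first, then iterative
#' 5-color trims from the 3' end for reads that remain unmapped. Defaults:
#' 35 colors at up to 3 mismatches, then 30 and 25 colors at up to 2. The
#' 25-color allowance is chosen by analogy with the 30-color stage and is
#' configurable. Stage lengths must decrease by the trim step.
#'
#' @param cascade list of c(length_in_colors, max_mismatches) pairs.
#' @param min_avg_qv Quality filter threshold (reads with mean QV strictly
#'   below this are discarded).
#' @param trim_step Colors removed from the 3' end between stages.
#' @param rrna_max_mm Mismatch allowance of the rRNA removal step (defaults
#'   to the stage-1 allowance).
#' @return A \code{mapper_config} list.
#' @export
mapper_config <- function(cascade = list(c(35L, 3L), c(30L, 2L), c(25L, 2L)),
                          min_avg_qv = 8, trim_step = 5L, rrna_max_mm = NULL) {
  if (length(cascade) == 0L) stop("empty cascade")
  lens <- vapply(cascade, `[`, numeric(1), 1L)
  mms <- vapply(cascade, `[`, numeric(1), 2L)
  if (any(mms < 0)) stop("mismatch allowances must be non-negative")
  if (length(lens) > 1L && any(diff(lens) != -trim_step))
    stop("stage lengths must decrease by trim_step")
  if (is.null(rrna_max_mm)) rrna_max_mm <- mms[1L]
  structure(list(cascade = cascade, min_avg_qv = min_avg_qv,
                 trim_step = trim_step, rrna_max_mm = rrna_max_mm),
            class = "mapper_config")
}

#' Filter low-quality reads
#'
#' Removes reads whose arithmetic mean quality value is strictly below the
#' threshold ("below 8" is read strictly: a mean of exactly 8 is kept).
#'
#' @param reads A \code{color_reads} data.frame with a \code{quals} column.
#' @param min_avg_qv Threshold (default 8).
#' @return list(kept, removed) of \code{color_reads}.
#' @export
filter_low_quality <- function(reads, min_avg_qv = 8) {
  if (is.null(reads$quals) || anyNA(reads$quals))
    stop("missing QUAL record for read ",
         reads$id[which(is.na(reads$quals))[1L]])
  keep <- qual_means(reads$quals) >= min_avg_qv
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Align reads at one cascade stage
#'
#' Finds, for each read, every placement of its first \code{L} colors on both
#' strands of every reference sequence with at most \code{M} color
#' mismatches. The search is complete: the pattern (the read's internal
#' colors 2..L) is partitioned into M+1 contiguous seed blocks, each looked
#' up exactly in a k-mer index, so any window with <= M mismatches has at
#' least one clean seed and is found (pigeonhole). Missing calls '.' are
#' permanent mismatches. Minus-strand search exploits the strand symmetry of
#' di-base colors: the color string of the reverse complement is the reversed
#' color string.
#'
#' @param reads \code{color_reads} data.frame.
#' @param refsets list of [reference_set()] objects.
#' @param L Stage length in colors; every read must be at least this long.
#' @param M Maximum color mismatches.
#' @return data.frame of hits: \code{read_idx}, \code{id}, \code{category},
#'   \code{ref}, \code{start} (0-based base offset within the reference),
#'   \code{strand} (of the read relative to the stored reference sequence),
#'   \code{L}, \code{mm}.
#' @export
align_stage <- function(reads, refsets, L, M) {
  if (inherits(refsets, "reference_set")) refsets <- list(refsets)
  if (any(nchar(reads$colors) < L))
    stop("stage length ", L, " exceeds a read's color count")
  ref_names <- unlist(lapply(refsets, `[[`, "names"), use.names = FALSE)
  ref_cat <- unlist(lapply(refsets, function(s)
    rep(s$category, length(s$names))), use.names = FALSE)
  ref_cols <- unlist(lapply(refsets, `[[`, "colors"), use.names = FALSE)
  n <- nrow(reads)
  if (n == 0L || length(ref_cols) == 0L)
    return(data.frame(read_idx = integer(0), id = character(0),
                      category = character(0), ref = character(0),
                      start = integer(0), strand = character(0),
                      L = integer(0), mm = integer(0)))
  fwd <- substr(reads$colors, 2L, L)
  rev_ <- stringi::stri_reverse(fwd)
  h <- .cs_seed_align(ref_cols, c(fwd, rev_), as.integer(M), 1L)
  if (nrow(h) == 0L)
    return(data.frame(read_idx = integer(0), id = character(0),
                      category = character(0), ref = character(0),
                      start = integer(0), strand = character(0),
                      L = integer(0), mm = integer(0)))
  is_rev <- h$pat > n
  read_idx <- ifelse(is_rev, h$pat - n, h$pat)
  data.frame(read_idx = read_idx,
             id = reads$id[read_idx],
             category = ref_cat[h$ref],
             ref = ref_names[h$ref],
             start = h$offset - 1L,  # window at color offset w covers bases [w-1, w-1+L)
             strand = ifelse(is_rev, "-", "+"),
             L = L,
             mm = h$mm,
             stringsAsFactors = FALSE)
}

#' Remove rRNA reads
#'
#' A read aligning anywhere on the rRNA reference set (full current length,
#' both strands, at most \code{max_mm} color mismatches) is removed.
#'
#' @param reads \code{color_reads}.
#' @param rrna_db rRNA [reference_set()].
#' @param max_mm Mismatch allowance (default 3, the stage-1 value).
#' @return list(kept, removed).
#' @export
filter_rrna <- function(reads, rrna_db, max_mm = 3L) {
  if (length(rrna_db$names) == 0L || nrow(reads) == 0L)
    return(list(kept = reads, removed = reads[0, , drop = FALSE]))
  L <- min(nchar(reads$colors))
  hits <- align_stage(reads, list(rrna_db), L, max_mm)
  bad <- unique(hits$read_idx)
  keep <- !(seq_len(nrow(reads)) %in% bad)
  list(kept = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

# Lift junction hits (vectorised) and normalise genome hits into genomic
# locations: chrom, blocks string "s-e[,s-e]" (0-based half-open, ordered by
# transcription), genomic strand. Non-spanning junction hits are dropped:
# they are redundant with genomic alignment.
hits_to_locations <- function(hits, junction_db) {
  gen <- hits[hits$category == "genome", , drop = FALSE]
  out <- list()
  if (nrow(gen)) {
    out[[1L]] <- data.frame(
      read_idx = gen$read_idx, id = gen$id, chrom = gen$ref,
      blocks = paste0(gen$start, "-", gen$start + gen$L),
      strand = gen$strand, mm = gen$mm, stage = gen$L,
      category = "genome", stringsAsFactors = FALSE)
  }
  jun <- hits[hits$category == "junction", , drop = FALSE]
  if (nrow(jun)) {
    rec <- junction_db$records[match(jun$ref, junction_db$records$id), ,
                               drop = FALSE]
    b <- rec$breakpoint
    len <- jun$L
    off <- jun$start
    span <- off < b & off + len > b
    if (any(span)) {
      jun <- jun[span, , drop = FALSE]
      rec <- rec[span, , drop = FALSE]
      b <- b[span]; off <- off[span]; len <- len[span]
      up_len <- b - off
      dn_len <- off + len - b
      plus <- rec$strand == "+"
      b1s <- ifelse(plus, rec$up_end - up_len, rec$up_start)
      b1e <- ifelse(plus, rec$up_end, rec$up_start + up_len)
      b2s <- ifelse(plus, rec$down_start, rec$down_end - dn_len)
      b2e <- ifelse(plus, rec$down_start + dn_len, rec$down_end)
      gstrand <- ifelse(jun$strand == "+", rec$strand,
                        ifelse(rec$strand == "+", "-", "+"))
      out[[length(out) + 1L]] <- data.frame(
        read_idx = jun$read_idx, id = jun$id, chrom = rec$chrom,
        blocks = paste0(b1s, "-", b1e, ",", b2s, "-", b2e),
        strand = gstrand, mm = jun$mm, stage = jun$L,
        category = "junction", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_idx = integer(0), id = character(0),
                      chrom = character(0), blocks = character(0),
                      strand = character(0), mm = integer(0),
                      stage = integer(0), category = character(0)))
  do.call(rbind, out)
}

#' Run the trim-and-remap cascade
#'
#' Stage 1 aligns the full 35 colors against the genome and junction
#' databases with up to 3 mismatches; reads without any hit are trimmed by 5
#' colors from the 3' end and realigned (30 colors, <= 2 mismatches), then
#' again (25 colors, <= 2). A read stops at the first stage with at least one
#' hit. Junction hits are lifted to genomic blocks (non-spanning ones
#' dropped as redundant), hits at identical genomic locations are
#' deduplicated, and a read is \code{unique} iff exactly one location attains
#' the minimal mismatch count (worse-scoring locations do not demote a
#' read); otherwise \code{multiple}. Reads exhausting the cascade are
#' \code{unmapped}.
#'
#' @param reads \code{color_reads} (already quality- and rRNA-filtered).
#' @param genome_db,junction_db [reference_set()] objects.
#' @param config A [mapper_config()].
#' @return list with \code{outcomes} (per read: id, status, stage, mm,
#'   chrom, blocks, strand of the best location for unique reads, n_best)
#'   and \code{stage_mapped} (reads mapped per stage).
#' @export
run_cascade <- function(reads, genome_db, junction_db,
                        config = mapper_config()) {
  if (!inherits(config, "mapper_config")) stop("config must be a mapper_config")
  n <- nrow(reads)
  status <- rep("unmapped", n)
  stage_of <- rep(NA_integer_, n)
  mm_best <- rep(NA_integer_, n)
  chrom <- rep(NA_character_, n)
  blocks <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  n_best <- rep(0L, n)
  active <- seq_len(n)
  stage_mapped <- integer(length(config$cascade))
  names(stage_mapped) <- vapply(config$cascade, function(s)
    paste0(s[1L], "bp"), character(1))
  for (si in seq_along(config$cascade)) {
    if (length(active) == 0L) break
    L <- as.integer(config$cascade[[si]][1L])
    M <- as.integer(config$cascade[[si]][2L])
    hits <- align_stage(reads[active, , drop = FALSE],
                        list(genome_db, junction_db), L, M)
    locs <- hits_to_locations(hits, junction_db)
    if (nrow(locs) == 0L) next
    # deduplicate identical genomic locations, keep min mismatch per location
    key <- paste(locs$read_idx, locs$chrom, locs$blocks, locs$strand,
                 sep = "\r")
    o <- order(key, locs$mm)
    locs <- locs[o[!duplicated(key[o])], , drop = FALSE]
    # best score per read, count of best-scoring locations
    best <- tapply(locs$mm, locs$read_idx, min)
    ridx <- as.integer(names(best))
    locs$is_best <- locs$mm == best[as.character(locs$read_idx)]
    nb <- tapply(locs$is_best, locs$read_idx, sum)
    gidx <- active[ridx]  # global read indices
    stage_mapped[si] <- length(gidx)
    status[gidx] <- ifelse(nb == 1L, "unique", "multiple")
    stage_of[gidx] <- L
    mm_best[gidx] <- as.integer(best)
    n_best[gidx] <- as.integer(nb)
    bl <- locs[locs$is_best, , drop = FALSE]
    bl <- bl[!duplicated(bl$read_idx), , drop = FALSE]  # unique reads: the one best
    uni <- ridx[nb == 1L]
    bsel <- bl[match(uni, bl$read_idx), , drop = FALSE]
    chrom[active[uni]] <- bsel$chrom
    blocks[active[uni]] <- bsel$blocks
    strand[active[uni]] <- bsel$strand
    active <- active[-ridx]
  }
  outcomes <- data.frame(id = reads$id, status = status, stage = stage_of,
                         mm = mm_best, chrom = chrom, blocks = blocks,
                         strand = strand, n_best = n_best,
                         stringsAsFactors = FALSE)
  list(outcomes = outcomes, stage_mapped = stage_mapped)
}

#' Map one library end to end
#'
#' Quality filter, rRNA removal, then the trim-and-remap cascade; assembles
#' the mapping summary counts (raw, high-quality, per-stage mapped, unique,
#' multiple, annotated and the annotation rate with the high-quality count as
#' denominator).
#'
#' @param reads \code{color_reads} with qualities (the raw library).
#' @param genome_db,junction_db,rrna_db [reference_set()] objects.
#' @param config A [mapper_config()].
#' @return list(outcomes, summary); \code{outcomes} covers every read
#'   (statuses \code{filtered_low_quality}, \code{rrna}, \code{unique},
#'   \code{multiple}, \code{unmapped}), \code{summary} is a named list of
#'   counts.
#' @export
map_library <- function(reads, genome_db, junction_db, rrna_db,
                        config = mapper_config()) {
  fq <- filter_low_quality(reads, config$min_avg_qv)
  fr <- filter_rrna(fq$kept, rrna_db, config$rrna_max_mm)
  casc <- run_cascade(fr$kept, genome_db, junction_db, config)
  all_out <- rbind(
    data.frame(id = fq$removed$id, status = "filtered_low_quality",
               stage = NA_integer_, mm = NA_integer_, chrom = NA_character_,
               blocks = NA_character_, strand = NA_character_, n_best = 0L,
               stringsAsFactors = FALSE),
    data.frame(id = fr$removed$id, status = "rrna", stage = NA_integer_,
               mm = NA_integer_, chrom = NA_character_,
               blocks = NA_character_, strand = NA_character_, n_best = 0L,
               stringsAsFactors = FALSE),
    casc$outcomes)
  all_out <- all_out[match(reads$id, all_out$id), , drop = FALSE]
  n_unique <- sum(casc$outcomes$status == "unique")
  n_multiple <- sum(casc$outcomes$status == "multiple")
  summary <- c(list(raw = nrow(reads),
                    high_quality = nrow(fq$kept),
                    rrna_removed = nrow(fr$removed)),
               as.list(casc$stage_mapped),
               list(unique = n_unique,
                    multiple = n_multiple,
                    annotated = n_unique + n_multiple,
                    unmapped = sum(casc$outcomes$status == "unmapped")))
  list(outcomes = all_out, summary = summary)
}
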