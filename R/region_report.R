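# Round half away from zero to `digits` decimals (table formatting: 44.885
# prints as 44.89, never banker's rounding).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a per-base expression coverage track
#'
#' Every base covered by at least one uniquely mapped tag block receives the
#' value depth x 1e6 / N (tag depth per million uniquely mapped tags).
#' Junction tags contribute to both of their genomic blocks.
#'
#' @param outcomes Mapping outcomes (unique-status rows are used).
#' @param N Library unique mapped total (> 0).
#' @return A \code{coverage_track}: list with \code{cov} (an
#'   [IRanges::RleList] of per-base values) and \code{N}.
#' @export
build_track <- function(outcomes, N) {
  if (N <= 0) stop("N must be positive")
  uo <- outcomes[outcomes$status == "unique", , drop = FALSE]
  if (nrow(uo) == 0L) {
    return(structure(list(cov = IRanges::RleList(), N = N),
                     class = "coverage_track"))
  }
  bl <- strsplit(uo$blocks, ",", fixed = TRUE)
  nb <- lengths(bl)
  flat <- unlist(bl, use.names = FALSE)
  se <- matrix(as.integer(unlist(strsplit(flat, "-", fixed = TRUE),
                                 use.names = FALSE)), ncol = 2L, byrow = TRUE)
  gr <- GenomicRanges::GRanges(
    rep.int(uo$chrom, nb),
    IRanges::IRanges(start = se[, 1L] + 1L, end = se[, 2L]))
  cov <- GenomicRanges::coverage(gr)
  structure(list(cov = cov * (1e6 / N), N = N), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track over", length(x$cov), "chromosome(s), N =", x$N, "\n")
  invisible(x)
}

#' Summarize one chromosome of a coverage track
#'
#' Statistics are computed over covered bases only (value > 0): first and
#' last covered base (0-based), the expression-value sum, bases covered
#' (count and percent of chromosome length, 2 decimals), minimum, maximum,
#' range (max - min), mean, variance (unbiased, n - 1 denominator) and
#' standard deviation. An empty or absent chromosome yields covered = 0 and
#' NA statistics rather than an error.
#'
#' @param track A [build_track()] result.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bases (for the covered percent).
#' @return Named list of summary statistics.
#' @export
summarize_chromosome <- function(track, chrom, chrom_length) {
  empty <- list(chrom = chrom, start = NA_integer_, end = NA_integer_,
                expression_sum = NA_real_, bases_covered = 0L,
                bases_covered_pct = 0, min = NA_real_, max = NA_real_,
                range = NA_real_, mean = NA_real_, variance = NA_real_,
                sd = NA_real_)
  if (!chrom %in% names(track$cov)) return(empty)
  r <- track$cov[[chrom]]
  v <- S4Vectors::runValue(r)
  l <- S4Vectors::runLength(r)
  keep <- v > 0
  if (!any(keep)) return(empty)
  ends <- cumsum(l)
  starts1 <- ends - l + 1L   # 1-based run starts
  v2 <- v[keep]
  l2 <- l[keep]
  ncov <- sum(l2)
  mu <- sum(v2 * l2) / ncov
  varc <- if (ncov > 1L) sum(l2 * (v2 - mu)^2) / (ncov - 1L) else 0
  list(chrom = chrom,
       start = min(starts1[keep]) - 1L,            # 0-based first covered base
       end = max(ends[keep]) - 1L,                 # 0-based last covered base
       expression_sum = sum(v2 * l2),
       bases_covered = as.integer(ncov),
       bases_covered_pct = round_half_up(100 * ncov / chrom_length, 2L),
       min = min(v2), max = max(v2), range = max(v2) - min(v2),
       mean = mu, variance = varc, sd = sqrt(varc))
}

#' Mapping summary report (Table-1 style)
#'
#' Takes per-library mapping counts and emits the standard summary rows:
#' raw and high-quality tag numbers, per-stage mapped counts, unique and
#' multiple locus counts, the annotated total (unique + multiple), the
#' annotation rate (annotated / high-quality x 100, 2 decimals, half-up) and
#' the exon / intron / antisense fractions of unique reads as percents.
#'
#' @param counts A named list (or list of named lists, one per library) with
#'   entries raw, high_quality, \code{35bp}, \code{30bp}, \code{25bp},
#'   unique, multiple and optionally unique_exon, unique_intron,
#'   unique_antisense. \code{annotated} defaults to unique + multiple.
#' @param libraries Column names (library labels).
#' @return data.frame with a \code{row} name column and one column per
#'   library; rates are numeric percents rounded to 2 decimals, NA when the
#'   denominator is zero.
#' @export
mapping_summary_report <- function(counts, libraries = NULL) {
  if (!is.null(counts$high_quality)) counts <- list(counts)
  nlib <- length(counts)
  if (is.null(libraries)) libraries <- paste0("lib", seq_len(nlib))
  rows <- c("Raw tag number", "High-quality reads", "35 bp mapped reads",
            "30 bp mapped reads", "25 bp mapped reads",
            "Reads Mapped to unique locus", "Reads Mapped to multiple loci",
            "Annotated tag number", "Annotation rate",
            "Unique reads mapped to exon", "Unique reads mapped to intron",
            "Exon fraction of unique reads",
            "Intron fraction of unique reads")
  out <- data.frame(row = rows, stringsAsFactors = FALSE)
  for (i in seq_len(nlib)) {
    x <- counts[[i]]
    annotated <- if (!is.null(x$annotated)) x$annotated else
      (x$unique %||% 0) + (x$multiple %||% 0)
    rate <- if (!is.null(x$high_quality) && x$high_quality > 0)
      round_half_up(100 * annotated / x$high_quality, 2L) else NA_real_
    exon_frac <- if (!is.null(x$unique_exon) && x$unique > 0)
      round_half_up(100 * x$unique_exon / x$unique, 2L) else NA_real_
    intron_frac <- if (!is.null(x$unique_intron) && x$unique > 0)
      round_half_up(100 * x$unique_intron / x$unique, 2L) else NA_real_
    out[[libraries[i]]] <- c(x$raw %||% NA, x$high_quality %||% NA,
                             x[["35bp"]] %||% NA, x[["30bp"]] %||% NA,
                             x[["25bp"]] %||% NA, x$unique %||% NA,
                             x$multiple %||% NA, annotated, rate,
                             x$unique_exon %||% NA, x$unique_intron %||% NA,
                             exon_frac, intron_frac)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Category summary of differential-expression calls
#'
#' Per functional category: the number of up- and down-regulated genes, the
#' percent of expressed genes falling in the category, and a major-category
#' flag when that percent exceeds 10. Genes may carry several categories and
#' increment each of them (documented double-counting); genes absent from
#' the mapping fall into an \code{unmapped} category.
#'
#' @param de_table The table from [call_de()].
#' @param gene2cat data.frame with columns gene_id, category (one row per
#'   gene-category pair).
#' @param expressed_ids Character vector of expressed gene ids.
#' @return data.frame: category, n_up, n_down, n_expressed, percent, major.
#' @export
category_summary <- function(de_table, gene2cat, expressed_ids) {
  cat_of <- function(ids) {
    m <- gene2cat[gene2cat$gene_id %in% ids, , drop = FALSE]
    unmapped <- setdiff(ids, gene2cat$gene_id)
    if (length(unmapped))
      m <- rbind(m, data.frame(gene_id = unmapped, category = "unmapped",
                               stringsAsFactors = FALSE))
    m
  }
  all_cats <- sort(unique(c(gene2cat$category,
                            if (length(setdiff(expressed_ids,
                                               gene2cat$gene_id))) "unmapped")))
  up_ids <- de_table$gene_id[de_table$call == "up"]
  down_ids <- de_table$gene_id[de_table$call == "down"]
  cnt <- function(ids) {
    t <- table(cat_of(ids)$category)
    out <- stats::setNames(integer(length(all_cats)), all_cats)
    out[names(t)] <- as.integer(t)
    out
  }
  n_up <- cnt(up_ids)
  n_down <- cnt(down_ids)
  n_expr <- cnt(expressed_ids)
  pct <- round_half_up(100 * n_expr / max(1L, length(expressed_ids)), 2L)
  data.frame(category = all_cats, n_up = n_up, n_down = n_down,
             n_expressed = n_expr, percent = pct, major = pct > 10,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' List genes in a genomic region
#'
#' Returns every gene whose body intersects the query region (>= 1 base;
#' genes straddling a boundary are included), with expression and
#' differential-expression columns when supplied. Region coordinates are
#' 0-based half-open (BED convention).
#'
#' @param region list or data.frame row with chrom, start, end.
#' @param ann A [gene_annotation()].
#' @param expr1,expr2 Optional [expression_table()] results per library.
#' @param de_table Optional [call_de()] table.
#' @return data.frame of genes in the region.
#' @export
region_genes <- function(region, ann, expr1 = NULL, expr2 = NULL,
                         de_table = NULL) {
  spans <- gene_spans(ann)
  if (!region$chrom %in% spans$chrom && !region$chrom %in% unique(ann$exons$chrom))
    stop("unknown chromosome: ", region$chrom)
  sel <- spans$chrom == region$chrom & spans$start < region$end &
    spans$end > region$start
  out <- spans[sel, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(expr1)) {
    out$rpkm_1 <- expr1$rpkm[match(out$gene_id, expr1$gene_id)]
    out$expressed_1 <- expr1$expressed[match(out$gene_id, expr1$gene_id)]
  }
  if (!is.null(expr2)) {
    out$rpkm_2 <- expr2$rpkm[match(out$gene_id, expr2$gene_id)]
    out$expressed_2 <- expr2$expressed[match(out$gene_id, expr2$gene_id)]
  }
  if (!is.null(de_table)) {
    m <- match(out$gene_id, de_table$gene_id)
    out$fold_change <- de_table$fold_change[m]
    out$p_value <- de_table$p_value[m]
    out$call <- de_table$call[m]
  }
  out
}

#' Write a report table as TSV with a JSON mirror
#'
#' @param x data.frame.
#' @param tsv,json Output paths (either may be NULL to skip).
#' @return Invisibly, \code{x}.
#' @export
write_report <- function(x, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(x, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(x, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(x)
}
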