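# Small deterministic study shared by mapper/quantify tests. Built once per
# test file; cheap (~1 s).
small_study <- function(n_tags = 3000L, color_error_rate = 0,
                        seed = 11L, ...) {
  genome <- generate_genome(100000L, gc = 0.5, seed = seed)
  ann <- generate_annotation(genome, 30L, 2L, exon_count_range = c(2L, 4L),
                             seed = seed + 1L)
  expr <- generate_expression(ann, 5L, seed = seed + 2L)
  lib <- simulate_tags(genome, ann, expr, n_tags,
                       color_error_rate = color_error_rate,
                       seed = seed + 3L, ...)
  list(genome = genome, ann = ann, expr = expr, lib = lib)
}

# A hand-laid two-gene annotation on a fixed genome, for feature-assignment
# rules: gpos (+ strand, exons [100,200) and [300,400)) and gneg (- strand,
# single exon [600,700)).
toy_annotation <- function() {
  genes <- data.frame(gene_id = c("gpos", "gneg"), chrom = "chr1",
                      strand = c("+", "-"),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gpos", "gpos", "gneg"), chrom = "chr1",
                      strand = c("+", "+", "-"),
                      start = c(100L, 300L, 600L),
                      end = c(200L, 400L, 700L), stringsAsFactors = FALSE)
  gene_annotation(genes, exons)
}

# Minimal unique-status outcome rows.
toy_outcome <- function(chrom, blocks, strand, id = NULL) {
  n <- length(blocks)
  data.frame(id = id %||% paste0("r", seq_len(n)), status = "unique",
             stage = 35L, mm = 0L, chrom = chrom, blocks = blocks,
             strand = strand, n_best = 1L, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
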