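test_that("genome generation is reproducible with correct composition", {
  g <- generate_genome(10000L, gc = 0.5, seed = 1)
  expect_equal(as.integer(Biostrings::width(g)), 10000L)
  g2 <- generate_genome(10000L, gc = 0.5, seed = 1)
  expect_identical(as.character(g), as.character(g2))
  # realized GC within 3 binomial SD of the target
  g3 <- generate_genome(100000L, gc = 0.6, seed = 2)
  f <- Biostrings::letterFrequency(g3[[1]], c("G", "C"))
  gc_obs <- sum(f) / 100000
  expect_lt(abs(gc_obs - 0.6), 3 * sqrt(0.6 * 0.4 / 100000))
  expect_error(generate_genome(c(100, -5)), "positive")
  expect_error(generate_genome(100, gc = 1.2), "between 0 and 1")
})

test_that("annotation generation yields valid, in-bounds gene models", {
  g <- generate_genome(200000L, gc = 0.45, seed = 3)
  ann <- generate_annotation(g, 50L, 2L, seed = 4)
  expect_equal(nrow(ann$genes), 52L)
  expect_equal(sum(ann$genes$biotype == "rRNA"), 2L)
  rr <- ann$genes$gene_id[ann$genes$biotype == "rRNA"]
  expect_true(all(table(ann$exons$gene_id)[rr] == 1L))
  # exon invariants: half-open, sorted, non-overlapping, within bounds
  for (gid in unique(ann$exons$gene_id)) {
    ex <- ann$exons[ann$exons$gene_id == gid, ]
    expect_true(all(ex$end > ex$start))
    expect_true(!is.unsorted(ex$start, strictly = TRUE))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
    expect_true(all(ex$end <= Biostrings::width(g)[1]))
  }
  expect_error(generate_annotation(g, 5000L, seed = 5),
               "insufficient genome space")
})

test_that("GTF writing and re-reading round-trips the gene models", {
  g <- generate_genome(200000L, gc = 0.45, seed = 6)
  ann <- generate_annotation(g, 20L, 2L, seed = 7)
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  back <- read_gtf(path)
  expect_equal(back$genes[order(back$genes$gene_id), ],
               ann$genes[order(ann$genes$gene_id), ],
               ignore_attr = TRUE)
  cols <- c("gene_id", "chrom", "strand", "start", "end")
  expect_equal(back$exons[order(back$exons$gene_id, back$exons$start), cols],
               ann$exons[order(ann$exons$gene_id, ann$exons$start), cols],
               ignore_attr = TRUE)
})

test_that("expression truth is normalized with the requested DE structure", {
  g <- generate_genome(300000L, gc = 0.45, seed = 8)
  ann <- generate_annotation(g, 60L, 2L, seed = 9)
  expr <- generate_expression(ann, 10L, fold_change = 4, seed = 10)
  expect_equal(sum(expr$is_de), 10L)
  expect_true(all(expr$true_fc[!expr$is_de] == 1))
  expect_true(all(expr$true_fc[expr$direction == "up"] == 4))
  expect_true(all(expr$true_fc[expr$direction == "down"] == 0.25))
  expect_lt(abs(sum(expr$abundance_1) - 1), 1e-9)
  expect_lt(abs(sum(expr$abundance_2) - 1), 1e-9)
  expect_false(any(expr$abundance_1 < 0))
  expect_error(generate_expression(ann, 1000L), "exceeds")
})

test_that("error-free tags decode exactly to their recorded origin blocks", {
  st <- small_study(n_tags = 800L, color_error_rate = 0)
  gs <- as.character(st$genome)
  lib <- st$lib
  strand_of <- setNames(st$ann$genes$strand, st$ann$genes$gene_id)
  for (i in seq_len(nrow(lib$reads))) {
    dec <- decode_colors(lib$reads$anchor[i], lib$reads$colors[i])
    tr <- lib$truth[i, ]
    parts <- vapply(strsplit(tr$blocks, ",")[[1]], function(bs) {
      b <- as.integer(strsplit(bs, "-")[[1]])
      s <- substring(gs[tr$chrom], b[1] + 1, b[2])
      if (strand_of[tr$gene_id] == "-") revcomp_str(s) else s
    }, character(1))
    sense <- paste(parts, collapse = "")
    expected <- if (tr$antisense) revcomp_str(sense) else sense
    expect_identical(dec, expected)
  }
})

test_that("junction-spanning tags cover both sides of the breakpoint", {
  st <- small_study(n_tags = 2000L, color_error_rate = 0)
  js <- st$lib$truth[st$lib$truth$class == "junction_spanning", ]
  expect_gt(nrow(js), 0)
  for (b in strsplit(js$blocks, ",")) {
    expect_gte(length(b), 2L)
    for (bs in b) {
      be <- as.integer(strsplit(bs, "-")[[1]])
      expect_gte(be[2] - be[1], 1L)
    }
  }
})

test_that("tag class composition tracks the requested fractions", {
  st <- small_study(n_tags = 20000L, color_error_rate = 0.02)
  tr <- st$lib$truth
  n <- nrow(tr)
  sd3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(tr$class == "rRNA") - 0.10), sd3(0.10))
  expect_lt(abs(mean(tr$class == "pre_mRNA_intronic") - 0.15), sd3(0.15))
  expect_lt(abs(mean(tr$antisense) - 0.06), sd3(0.06))
  expect_lt(abs(mean(tr$lowq) - 0.10), sd3(0.10))
  # low-quality tags always average below the QV-8 filter threshold
  qm <- vapply(strsplit(st$lib$reads$quals[tr$lowq], " "),
               function(q) mean(as.numeric(q)), numeric(1))
  expect_true(all(qm < 8))
})

test_that("simulation is reproducible for a fixed seed", {
  a <- small_study(n_tags = 500L, seed = 33L)
  b <- small_study(n_tags = 500L, seed = 33L)
  expect_identical(a$lib$reads, b$lib$reads)
  expect_identical(a$lib$truth, b$lib$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_library(a$lib, dirname(f1), basename(f1))
  write_library(b$lib, dirname(f2), basename(f2))
  expect_identical(readLines(paste0(f1, ".csfasta")),
                   readLines(paste0(f2, ".csfasta")))
})

test_that("transcripts shorter than the tag are excluded with a warning", {
  genes <- data.frame(gene_id = c("big", "tiny"), chrom = "chr1",
                      strand = "+", biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("big", "tiny"), chrom = "chr1",
                      strand = "+", start = c(0L, 300L),
                      end = c(200L, 310L), stringsAsFactors = FALSE)
  ann <- gene_annotation(genes, exons)
  g <- generate_genome(1000L, gc = 0.5, seed = 12)
  expr <- data.frame(gene_id = c("big", "tiny"), is_de = FALSE,
                     direction = "ns", true_fc = 1,
                     abundance_1 = c(0.5, 0.5), abundance_2 = c(0.5, 0.5),
                     stringsAsFactors = FALSE)
  expect_warning(
    lib <- simulate_tags(g, ann, expr, 200L, intron_frac = 0, rrna_frac = 0,
                         seed = 13),
    "shorter than the tag")
  expect_true(all(lib$truth$gene_id == "big"))
})
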