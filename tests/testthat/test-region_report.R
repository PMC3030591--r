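make_track <- function(values_by_chrom, N = 1e6) {
  structure(list(cov = do.call(IRanges::RleList,
                               lapply(values_by_chrom, S4Vectors::Rle)),
                 N = N),
            class = "coverage_track")
}

test_that("coverage track values are depth per million unique tags", {
  out <- toy_outcome("chr1", "100-135", "+")
  tr <- build_track(out, 1e6)
  r <- tr$cov[["chr1"]]
  expect_equal(sum(S4Vectors::runLength(r)[S4Vectors::runValue(r) > 0]), 35L)
  expect_equal(max(S4Vectors::runValue(r)), 1.0)
  # additivity: two identical tags double the per-base value
  out2 <- rbind(out, toy_outcome("chr1", "100-135", "+", "r2"))
  tr2 <- build_track(out2, 5e5)
  expect_equal(max(S4Vectors::runValue(tr2$cov[["chr1"]])), 2 * 1e6 / 5e5)
  # junction tags cover both blocks
  trj <- build_track(toy_outcome("chr1", "10-20,50-75", "+"), 1e6)
  rj <- trj$cov[["chr1"]]
  expect_equal(sum(S4Vectors::runLength(rj)[S4Vectors::runValue(rj) > 0]), 35L)
})

test_that("random hit sets match a brute-force depth recomputation", {
  set.seed(51)
  n <- 300L
  starts <- sample(0:2000, n, replace = TRUE)
  out <- toy_outcome("chr1", paste0(starts, "-", starts + 35L), "+",
                     paste0("r", seq_len(n)))
  N <- 123456
  tr <- build_track(out, N)
  depth <- integer(3000)
  for (s in starts) depth[(s + 1):(s + 35)] <- depth[(s + 1):(s + 35)] + 1L
  vals <- as.numeric(tr$cov[["chr1"]])  # runs stop at the last covered base
  expect_equal(vals, (depth * 1e6 / N)[seq_along(vals)], tolerance = 1e-12)
  expect_true(all(depth[-seq_along(vals)] == 0))
})

test_that("chromosome summaries compute covered-base statistics", {
  # single covered base
  tr <- make_track(list(chr1 = c(0, 0, 7.5, 0)))
  s <- summarize_chromosome(tr, "chr1", 4)
  expect_equal(s$start, 2L)
  expect_equal(s$end, 2L)
  expect_equal(s$bases_covered, 1L)
  expect_equal(s$min, 7.5)
  expect_equal(s$max, 7.5)
  expect_equal(s$range, 0)
  expect_equal(s$variance, 0)
  # range = max - min on a min/max pair like a published chromosome table
  tr2 <- make_track(list(chr1 = c(0.21, rep(0, 5), 157)))
  s2 <- summarize_chromosome(tr2, "chr1", 7)
  expect_equal(round(s2$range, 2), 156.79)
  # absent or empty chromosome: covered 0, NA statistics, no error
  s3 <- summarize_chromosome(tr2, "chrX", 100)
  expect_equal(s3$bases_covered, 0L)
  expect_true(is.na(s3$mean))
})

test_that("summary statistics match a two-pass oracle on random tracks", {
  set.seed(52)
  v <- round(rexp(10000, 1 / 3), 3)
  v[sample(10000, 2000)] <- 0
  tr <- make_track(list(chr1 = v))
  s <- summarize_chromosome(tr, "chr1", 10000)
  cov <- v[v > 0]
  mu <- sum(cov) / length(cov)
  va <- sum((cov - mu)^2) / (length(cov) - 1)
  expect_equal(s$mean, mu, tolerance = 1e-9)
  expect_equal(s$variance, va, tolerance = 1e-9)
  expect_equal(s$sd, sqrt(va), tolerance = 1e-9)
  expect_equal(s$bases_covered, length(cov))
  expect_equal(s$expression_sum, sum(cov), tolerance = 1e-9)
  expect_equal(s$start, min(which(v > 0)) - 1L)
  expect_equal(s$end, max(which(v > 0)) - 1L)
  # invariance to chunked computation: splitting the run-length encoding
  # differently cannot change the statistics (values are identical)
  tr2 <- make_track(list(chr1 = c(v[1:5000], v[5001:10000])))
  expect_equal(summarize_chromosome(tr2, "chr1", 10000), s)
})

test_that("mapping summary report computes rates from counts", {
  counts <- list(raw = 5000, high_quality = 4489, `35bp` = 4022,
                 `30bp` = 4, `25bp` = 5, unique = 4024, multiple = 7,
                 unique_exon = 3106, unique_intron = 671)
  rep <- mapping_summary_report(counts)
  get <- function(row) rep$lib1[rep$row == row]
  expect_equal(get("Annotated tag number"), 4031)
  expect_equal(get("Annotation rate"), round(100 * 4031 / 4489, 2))
  expect_equal(get("Exon fraction of unique reads"),
               round(100 * 3106 / 4024, 2))
  # degenerate inputs
  z <- mapping_summary_report(list(raw = 10, high_quality = 10, unique = 0,
                                   multiple = 0))
  expect_equal(z$lib1[z$row == "Annotation rate"], 0)
  z2 <- mapping_summary_report(list(raw = 0, high_quality = 0))
  expect_true(is.na(z2$lib1[z2$row == "Annotation rate"]))
})

test_that("percent rounding is half-up to two decimals", {
  expect_equal(solidtags:::round_half_up(44.875, 2), 44.88)
  expect_equal(solidtags:::round_half_up(0.005, 2), 0.01)
  expect_equal(solidtags:::round_half_up(2.675, 2), 2.68)
})

test_that("category summary counts calls and flags major categories", {
  de <- data.frame(gene_id = paste0("g", 1:6),
                   call = c("up", "up", "down", "ns", "ns", "up"),
                   stringsAsFactors = FALSE)
  g2c <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g1"),
                    category = c("A", "A", "B", "B", "C"),
                    stringsAsFactors = FALSE)
  expressed <- paste0("g", 1:10)
  cs <- category_summary(de, g2c, expressed)
  a <- cs[cs$category == "A", ]
  expect_equal(a$n_up, 2L)
  expect_equal(a$n_down, 0L)
  expect_equal(a$percent, 20)
  expect_true(a$major)
  # a gene in two categories increments both
  expect_equal(cs$n_up[cs$category == "C"], 1L)
  # genes without a category land in "unmapped"
  expect_equal(cs$n_expressed[cs$category == "unmapped"], 6L)
  expect_equal(cs$n_up[cs$category == "B"], 0L)
  expect_equal(cs$n_down[cs$category == "B"], 1L)
})

test_that("region gene listings use the intersection rule", {
  ann <- toy_annotation()
  r <- region_genes(list(chrom = "chr1", start = 0L, end = 1000L), ann)
  expect_equal(nrow(r), 2L)
  # straddling gene included, empty region empty, unknown chromosome errors
  r2 <- region_genes(list(chrom = "chr1", start = 350L, end = 500L), ann)
  expect_equal(r2$gene_id, "gpos")
  r3 <- region_genes(list(chrom = "chr1", start = 450L, end = 500L), ann)
  expect_equal(nrow(r3), 0L)
  expect_error(region_genes(list(chrom = "chr9", start = 0, end = 10), ann),
               "unknown chromosome")
  # with expression and DE columns attached
  expr <- data.frame(gene_id = c("gpos", "gneg"), exon_tags = c(5L, 2L),
                     exon_model_length = c(200L, 100L),
                     rpkm = c(2.5, 2.0), expressed = TRUE,
                     stringsAsFactors = FALSE)
  de <- data.frame(gene_id = "gpos", k1 = 5L, k2 = 1L, fold_change = 3.7,
                   p_value = 0.004, call = "up", stringsAsFactors = FALSE)
  r4 <- region_genes(list(chrom = "chr1", start = 0L, end = 1000L), ann,
                     expr1 = expr, de_table = de)
  expect_equal(r4$call[r4$gene_id == "gpos"], "up")
  expect_equal(r4$rpkm_1[r4$gene_id == "gneg"], 2.0)
})
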