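test_that("quality filter applies the strict below-8 rule", {
  reads <- data.frame(
    id = c("mean8", "mean7", "mean797"),
    anchor = "T",
    colors = strrep("0", 35),
    quals = c(paste(rep(8L, 35), collapse = " "),
              paste(rep(7L, 35), collapse = " "),
              # 34 values of 8 plus one 7: mean 279/35 = 7.971..., removed
              paste(c(rep(8L, 34), 7L), collapse = " ")),
    stringsAsFactors = FALSE)
  f <- filter_low_quality(reads)
  expect_identical(f$kept$id, "mean8")
  expect_setequal(f$removed$id, c("mean7", "mean797"))
  reads$quals <- NULL
  expect_error(filter_low_quality(reads), "QUAL")
})

test_that("an exact unique substring read yields one zero-mismatch hit", {
  set.seed(31)
  ref <- random_dna(2000)
  gdb <- reference_set(c(chr1 = ref), "genome")
  p <- 400L
  read_seq <- substring(ref, p + 1, p + 35)
  reads <- data.frame(id = "r1", anchor = "T",
                      colors = encode_colors(read_seq, "T"),
                      stringsAsFactors = FALSE)
  hits <- align_stage(reads, gdb, 35L, 0L)
  hits <- hits[hits$strand == "+", ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, p)
  expect_equal(hits$mm, 0L)
})

test_that("seeded search equals brute-force scan at every cascade stage", {
  set.seed(32)
  ref <- random_dna(2000)
  gdb <- reference_set(c(chr1 = ref), "genome")
  # half sampled from the reference with injected color errors, half random
  n <- 60L
  colors <- character(n)
  for (i in seq_len(n)) {
    if (i %% 2 == 0) {
      p <- sample(1900, 1)
      cv <- utf8ToInt(encode_colors(substring(ref, p, p + 34), "T")) - 48L
      ne <- sample(0:4, 1)
      if (ne > 0) {
        at <- sample(35, ne)
        cv[at] <- (cv[at] + sample(1:3, ne, replace = TRUE)) %% 4
      }
      colors[i] <- paste(cv, collapse = "")
    } else {
      colors[i] <- paste(sample(0:3, 35, replace = TRUE), collapse = "")
    }
  }
  reads <- data.frame(id = paste0("r", 1:n), anchor = "T", colors = colors,
                      stringsAsFactors = FALSE)
  for (stage in list(c(35L, 3L), c(30L, 2L), c(25L, 2L))) {
    got <- align_stage(reads, gdb, stage[1], stage[2])
    want <- brute_align_stage(reads, gdb, stage[1], stage[2])
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("lowering the mismatch allowance never adds hits", {
  set.seed(33)
  ref <- random_dna(3000)
  gdb <- reference_set(c(chr1 = ref), "genome")
  reads <- data.frame(id = paste0("r", 1:20), anchor = "T",
                      colors = replicate(20, paste(sample(0:3, 35, TRUE),
                                                   collapse = "")),
                      stringsAsFactors = FALSE)
  prev <- NULL
  for (M in 3:0) {
    h <- align_stage(reads, gdb, 35L, M)
    if (!is.null(prev)) expect_true(all(hit_key(h) %in% prev))
    prev <- hit_key(h)
  }
})

test_that("errors that defeat every seed of one partition are still found", {
  # pigeonhole: with M = 3 the 34 internal colors split into 4 blocks;
  # placing exactly 3 errors in 3 different blocks leaves one clean block,
  # so the true placement must be recovered.
  set.seed(34)
  ref <- random_dna(5000)
  gdb <- reference_set(c(chr1 = ref), "genome")
  p <- 1234L
  cv <- utf8ToInt(encode_colors(substring(ref, p + 1, p + 35), "T")) - 48L
  # internal colors are pattern positions 2..35; blocks start at 2, 11, 20, 28
  for (at in list(c(3L, 13L, 22L), c(10L, 19L, 27L), c(2L, 20L, 35L))) {
    cv2 <- cv
    cv2[at] <- (cv[at] + 1L) %% 4L
    reads <- data.frame(id = "adv", anchor = "T",
                        colors = paste(cv2, collapse = ""),
                        stringsAsFactors = FALSE)
    hits <- align_stage(reads, gdb, 35L, 3L)
    expect_true(any(hits$start == p & hits$strand == "+" & hits$mm == 3L))
    # and the hit set still equals brute force
    expect_identical(hit_key(hits),
                     hit_key(brute_align_stage(reads, gdb, 35L, 3L)))
  }
})

test_that("reads trimmed of 3'-end errors map at the 30-color stage", {
  set.seed(35)
  ref <- random_dna(5000)
  gdb <- reference_set(c(chr1 = ref), "genome")
  jdb <- build_junction_db(gene_annotation(
    data.frame(gene_id = "x", chrom = "chr1", strand = "+",
               biotype = "protein_coding", stringsAsFactors = FALSE),
    data.frame(gene_id = "x", chrom = "chr1", strand = "+", start = 0L,
               end = 40L, stringsAsFactors = FALSE)),
    Biostrings::DNAStringSet(c(chr1 = ref)))
  p <- 2000L
  cv <- utf8ToInt(encode_colors(substring(ref, p + 1, p + 35), "T")) - 48L
  cv[c(10L, 20L, 31L, 33L, 35L)] <- (cv[c(10L, 20L, 31L, 33L, 35L)] + 2L) %% 4L
  reads <- data.frame(id = "trimme", anchor = "T",
                      colors = paste(cv, collapse = ""),
                      quals = paste(rep(20L, 35), collapse = " "),
                      stringsAsFactors = FALSE)
  res <- run_cascade(reads, gdb, jdb)
  expect_equal(res$outcomes$status, "unique")
  expect_equal(res$outcomes$stage, 30L)
  expect_equal(res$outcomes$blocks, paste0(p, "-", p + 30L))
})

test_that("cascade statuses partition the library and recover the truth", {
  st <- small_study(n_tags = 3000L, color_error_rate = 0)
  gdb <- build_genome_db(st$genome)
  jdb <- build_junction_db(st$ann, st$genome)
  rdb <- build_rrna_db(st$ann, st$genome)
  res <- map_library(st$lib$reads, gdb, jdb, rdb)
  out <- res$outcomes
  s <- res$summary
  # conservation
  expect_equal(nrow(out), 3000L)
  expect_equal(sum(out$status == "filtered_low_quality") +
                 sum(out$status == "rrna") + s$unique + s$multiple +
                 s$unmapped, 3000L)
  expect_equal(s$annotated, s$unique + s$multiple)
  expect_equal(s$annotated, sum(s[["35bp"]], s[["30bp"]], s[["25bp"]]))
  # error-free rRNA tags are always removed by the rRNA filter
  tr <- st$lib$truth
  hq <- !tr$lowq
  expect_equal(mean(out$status[tr$class == "rRNA" & hq] == "rrna"), 1.0)
  # >= 99% of high-quality mature tags map uniquely at stage 35, at truth
  m <- tr$class == "mature_exonic" & hq
  expect_gte(mean(out$status[m] == "unique"), 0.99)
  u <- m & out$status == "unique"
  expect_gte(mean(out$blocks[u] == tr$blocks[u] &
                    out$strand[u] == tr$strand[u]), 0.999)
  expect_true(all(out$stage[u] == 35L))
})

test_that("junction hits merge with genomic hits into unique calls", {
  st <- small_study(n_tags = 2000L, color_error_rate = 0)
  gdb <- build_genome_db(st$genome)
  jdb <- build_junction_db(st$ann, st$genome)
  res <- run_cascade(st$lib$reads, gdb, jdb)
  tr <- st$lib$truth
  js <- tr$class == "junction_spanning"
  out <- res$outcomes
  # junction-spanning tags with >= 5 bases on each side are unambiguous
  side_ok <- vapply(strsplit(tr$blocks, ","), function(b) {
    lens <- vapply(strsplit(b, "-"), function(x)
      diff(as.integer(x)), numeric(1))
    length(lens) == 2 && all(lens >= 5)
  }, logical(1))
  sel <- js & side_ok
  expect_gte(mean(out$status[sel] == "unique"), 0.99)
  u <- sel & out$status == "unique"
  expect_gte(mean(out$blocks[u] == tr$blocks[u]), 0.999)
})

test_that("empty cascade and short reads are rejected", {
  expect_error(mapper_config(cascade = list()), "empty")
  expect_error(mapper_config(cascade = list(c(35L, 3L), c(28L, 2L))),
               "trim_step")
  gdb <- reference_set(c(chr1 = random_dna(100)), "genome")
  reads <- data.frame(id = "r", anchor = "T", colors = "0123",
                      stringsAsFactors = FALSE)
  expect_error(align_stage(reads, gdb, 35L, 3L), "exceeds")
})
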