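# Independent oracles, deliberately naive: direct window-by-window scans and
# two-pass statistics, sharing no code with the package's seeded paths.

# All <= max_mm windows of `pat` against one reference color string, by full
# scan. Window starts are 0-based color offsets; offset 0 is excluded, the
# same first-color convention the mapper states. '.' mismatches everything.
brute_windows <- function(ref_colors, pat, max_mm, min_offset = 1L) {
  rv <- utf8ToInt(ref_colors)
  pv <- utf8ToInt(pat)
  Lp <- length(pv)
  n <- length(rv)
  dot <- utf8ToInt(".")
  if (n - Lp < min_offset)
    return(data.frame(offset = integer(0), mm = integer(0)))
  ws <- seq.int(min_offset, n - Lp)
  mm <- integer(length(ws))
  for (i in seq_len(Lp)) {
    ri <- rv[ws + i]
    mm <- mm + (ri != pv[i] | ri == dot | pv[i] == dot)
  }
  keep <- mm <= max_mm
  data.frame(offset = ws[keep], mm = mm[keep])
}

# Full-scan equivalent of align_stage for a set of reads against a list of
# reference sets: both strands, first L colors, internal-color comparison.
brute_align_stage <- function(reads, refsets, L, M) {
  if (inherits(refsets, "reference_set")) refsets <- list(refsets)
  out <- list()
  for (rs in refsets) {
    for (ri in seq_along(rs$names)) {
      rc <- rs$colors[ri]
      for (i in seq_len(nrow(reads))) {
        pat <- substr(reads$colors[i], 2L, L)
        for (strand in c("+", "-")) {
          p <- if (strand == "+") pat else
            paste(rev(strsplit(pat, "")[[1]]), collapse = "")
          h <- brute_windows(rc, p, M)
          if (nrow(h))
            out[[length(out) + 1L]] <- data.frame(
              read_idx = i, id = reads$id[i], category = rs$category,
              ref = rs$names[ri], start = h$offset - 1L, strand = strand,
              L = L, mm = h$mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_idx = integer(0), id = character(0),
                      category = character(0), ref = character(0),
                      start = integer(0), strand = character(0),
                      L = integer(0), mm = integer(0)))
  do.call(rbind, out)
}

hit_key <- function(h) {
  sort(paste(h$read_idx, h$category, h$ref, h$start, h$strand, h$mm,
             sep = "|"))
}

# Exact two-sided conditional binomial p-value by explicit enumeration with
# choose(); minimum-likelihood rule.
enum_binom_p <- function(k1, k2, N1, N2) {
  n <- k1 + k2
  if (n == 0) return(1)
  p0 <- N1 / (N1 + N2)
  pr <- vapply(0:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
               numeric(1))
  obs <- pr[k1 + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", s))
}
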