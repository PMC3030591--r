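#' @useDynLib solidtags, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Two-bit base codes: A=0, C=1, G=2, T=3. The SOLiD di-base color of a base
# pair (x, y) is xor(code(x), code(y)), which reproduces the standard scheme
# {AA,CC,GG,TT}=0, {AC,CA,GT,TG}=1, {AG,GA,CT,TC}=2, {AT,TA,CG,GC}=3.
.base_code <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 0L
  v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L
  v[utf8ToInt("T")] <- 3L
  v
})
.code_base <- c("A", "C", "G", "T")
.DOT_INT <- utf8ToInt(".")
.ZERO_INT <- utf8ToInt("0")

#' Di-base transition table
#'
#' The 4x4 SOLiD color table: entry \code{[x, y]} is the color (0-3) emitted
#' for the adjacent base pair x, y. The table is symmetric and every diagonal
#' entry is 0.
#'
#' @return An integer matrix with dimnames over A, C, G, T.
#' @export
dibase_table <- function() {
  m <- outer(0:3, 0:3, bitwXor)
  dimnames(m) <- list(.code_base, .code_base)
  m
}

#' Encode a nucleotide sequence in color space
#'
#' Translates a base sequence into SOLiD di-base colors. Color i is the
#' transition between base i-1 and base i, with the anchor (primer) base
#' standing in for base 0; the output therefore has the same length as the
#' input.
#'
#' @param seq Nucleotide string over A, C, G, T.
#' @param anchor Single anchor base preceding the sequence (default "T",
#'   the SOLiD primer convention).
#' @param ambiguous How to treat non-ACGT characters: \code{"error"} (default)
#'   or \code{"dot"} to emit a missing call \code{"."} for the two transitions
#'   touching the ambiguous base.
#' @return A color string over \code{0123} (and \code{.} if
#'   \code{ambiguous = "dot"}).
#' @examples
#' encode_colors("TT")        # "00"
#' encode_colors("ACGT", "T") # "3131"
#' @export
encode_colors <- function(seq, anchor = "T", ambiguous = c("error", "dot")) {
  ambiguous <- match.arg(ambiguous)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a non-empty string")
  a <- .base_code[utf8ToInt(anchor)]
  if (length(a) != 1L || is.na(a)) stop("invalid anchor base: ", anchor)
  codes <- .base_code[utf8ToInt(seq)]
  if (anyNA(codes)) {
    if (ambiguous == "error")
      stop("ambiguous base at position ", which(is.na(codes))[1L])
  }
  prev <- c(a, codes[-length(codes)])
  cols <- bitwXor(prev, codes)
  out <- cols + .ZERO_INT
  out[is.na(out)] <- .DOT_INT
  intToUtf8(out)
}

#' Decode a color string into nucleotides
#'
#' Inverse of [encode_colors()]: base i is fully determined by base i-1 and
#' color i, starting from the anchor base. Because each base depends on every
#' color before it, a single color error corrupts all downstream bases; this
#' propagation is why alignment is done in color space rather than after
#' decoding.
#'
#' @param anchor Anchor base.
#' @param colors Color string over \code{0123}; a missing call \code{.} is not
#'   decodable and raises an error naming its position. The empty string
#'   decodes to the empty sequence.
#' @return Nucleotide string, same length as \code{colors}.
#' @export
decode_colors <- function(anchor, colors) {
  a <- .base_code[utf8ToInt(anchor)]
  if (length(a) != 1L || is.na(a)) stop("invalid anchor base: ", anchor)
  if (!nzchar(colors)) return("")
  ints <- utf8ToInt(colors) - .ZERO_INT
  bad <- ints < 0L | ints > 3L
  if (any(bad)) {
    pos <- which(bad)[1L]
    if (utf8ToInt(substr(colors, pos, pos)) == .DOT_INT)
      stop("missing color call '.' at position ", pos, " cannot be decoded")
    stop("invalid color character at position ", pos)
  }
  # xor is bitwise, so decode each bit by a cumulative parity
  b0 <- (a %% 2L + cumsum(ints %% 2L)) %% 2L
  b1 <- (a %/% 2L + cumsum(ints %/% 2L)) %% 2L
  paste(.code_base[b0 + 2L * b1 + 1L], collapse = "")
}

#' Count color-space mismatches
#'
#' Hamming distance between two equal-length color strings. A missing call
#' \code{.} never matches anything (including another \code{.}).
#'
#' @param a,b Color strings of equal length.
#' @return Integer mismatch count.
#' @export
color_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("color strings differ in length")
  if (!nzchar(a)) return(0L)
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  sum(x != y | x == .DOT_INT | y == .DOT_INT)
}

#' Reverse-complement in color space
#'
#' The color sequence of the reverse complement of a DNA sequence is the
#' reversed color sequence (di-base colors are strand-symmetric). This helper
#' reverses a color string; it is what the mapper uses to search the minus
#' strand without re-encoding the reference.
#'
#' @param colors Color string.
#' @return Reversed color string.
#' @export
reverse_colors <- function(colors) {
  stringi::stri_reverse(colors)
}

# Vectorised encoder for equal-length sequences; returns a character vector of
# color strings. Used by the simulator, where hundreds of thousands of
# tag-length sequences are encoded at once.
encode_colors_many <- function(seqs, anchor = "T") {
  if (length(seqs) == 0L) return(character(0))
  a <- .base_code[utf8ToInt(anchor)]
  n <- nchar(seqs[1L])
  m <- matrix(.base_code[vapply(seqs, utf8ToInt, integer(n), USE.NAMES = FALSE)],
              nrow = n)
  if (anyNA(m)) stop("ambiguous base in sequence batch")
  prev <- rbind(rep.int(a, ncol(m)), m[-n, , drop = FALSE])
  cols <- matrix(bitwXor(prev, m) + .ZERO_INT, nrow = n)
  vapply(seq_len(ncol(cols)), function(j) intToUtf8(cols[, j]), character(1))
}
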