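#' Read a color-space FASTA (csfasta) file with its QUAL companion
#'
#' The csfasta dialect stores one record per tag: a \code{>} header carrying
#' the tag id, then a line consisting of a single anchor base (A/C/G/T)
#' followed by the color calls (characters \code{0123} or \code{.} for a
#' missing call). The QUAL file repeats the ids and holds one space-separated
#' integer quality value per color. Lines starting with \code{#} are comments.
#'
#' @param csfasta Path to the csfasta file.
#' @param qual Optional path to the matching QUAL file.
#' @return A \code{color_reads} data.frame with columns \code{id},
#'   \code{anchor}, \code{colors} and, when \code{qual} is given, \code{quals}
#'   (space-separated integers, one per color).
#' @export
read_csfasta <- function(csfasta, qual = NULL) {
  lines <- readLines(csfasta)
  lines <- lines[!startsWith(lines, "#")]
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) {
    reads <- data.frame(id = character(0), anchor = character(0),
                        colors = character(0), stringsAsFactors = FALSE)
  } else {
    ids <- sub("^>", "", lines[hdr])
    rec <- lines[!hdr]
    if (length(rec) != length(ids))
      stop("malformed csfasta: ", length(ids), " headers but ",
           length(rec), " record lines")
    reads <- data.frame(id = ids,
                        anchor = substr(rec, 1L, 1L),
                        colors = substr(rec, 2L, nchar(rec)),
                        stringsAsFactors = FALSE)
  }
  if (!is.null(qual)) {
    q <- read_qual(qual)
    idx <- match(reads$id, q$id)
    if (anyNA(idx))
      stop("missing QUAL record for read ", reads$id[which(is.na(idx))[1L]])
    reads$quals <- q$quals[idx]
  }
  class(reads) <- c("color_reads", "data.frame")
  reads
}

#' Read a QUAL file
#'
#' @param path Path to the QUAL file.
#' @return data.frame with columns \code{id} and \code{quals} (space-separated
#'   integer string per read).
#' @export
read_qual <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  hdr <- startsWith(lines, ">")
  ids <- sub("^>", "", lines[hdr])
  rec <- trimws(lines[!hdr])
  if (length(rec) != length(ids)) stop("malformed QUAL file: ", path)
  data.frame(id = ids, quals = rec, stringsAsFactors = FALSE)
}

#' Write color reads as csfasta + QUAL
#'
#' @param reads A \code{color_reads} data.frame (see [read_csfasta()]).
#' @param csfasta Output csfasta path.
#' @param qual Optional output QUAL path (requires a \code{quals} column).
#' @return Invisibly, \code{reads}.
#' @export
write_csfasta <- function(reads, csfasta, qual = NULL) {
  out <- character(2L * nrow(reads))
  out[c(TRUE, FALSE)] <- paste0(">", reads$id)
  out[c(FALSE, TRUE)] <- paste0(reads$anchor, reads$colors)
  writeLines(out, csfasta)
  if (!is.null(qual)) {
    if (is.null(reads$quals)) stop("reads carry no quality values")
    outq <- character(2L * nrow(reads))
    outq[c(TRUE, FALSE)] <- paste0(">", reads$id)
    outq[c(FALSE, TRUE)] <- reads$quals
    writeLines(outq, qual)
  }
  invisible(reads)
}

# Mean quality value per read from the space-separated representation.
qual_means <- function(quals) {
  vapply(strsplit(quals, " ", fixed = TRUE),
         function(q) mean(as.numeric(q)), numeric(1))
}
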