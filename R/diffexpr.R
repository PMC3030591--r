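#' Exact conditional test under the random-sampling model
#'
#' Under the random-sampling model, a gene's tag count in each library is a
#' binomial draw from the library total. Under the null of equal expression,
#' conditional on the combined count \code{n = k1 + k2}, \code{k1} is
#' Binomial(n, N1 / (N1 + N2)). The two-sided p-value uses the
#' minimum-likelihood rule: the sum of the probabilities of all outcomes no
#' more probable than the observed one, capped at 1. This is the exact
#' conditional form of the model behind two-library count comparisons; it
#' depends on the library sizes only through the proportion N1 / (N1 + N2).
#'
#' @param k1,k2 Tag counts in libraries 1 and 2 (non-negative).
#' @param N1,N2 Library totals (positive); recycled.
#' @return p-value(s) in (0, 1].
#' @export
de_test <- function(k1, N1, k2, N2) {
  if (any(c(k1, k2) < 0)) stop("counts must be non-negative")
  if (any(c(N1, N2) <= 0)) stop("library totals must be positive")
  df <- data.frame(k1 = k1, N1 = N1, k2 = k2, N2 = N2)
  mapply(function(k1, N1, k2, N2) {
    n <- k1 + k2
    if (n == 0) return(1)
    p0 <- N1 / (N1 + N2)
    d <- stats::dbinom(0:n, n, p0)
    min(1, sum(d[d <= d[k1 + 1] * (1 + 1e-7)]))
  }, df$k1, df$N1, df$k2, df$N2)
}

#' Differential-expression configuration
#'
#' @param alpha p-value threshold (default 0.01).
#' @param fc_threshold Fold-change gate (default 2; a call requires the
#'   normalized fold change to exceed it, or fall below its reciprocal).
#' @param pseudocount Added to both counts before forming the normalized
#'   ratio, avoiding division by zero (default 0.5).
#' @return A \code{de_config} list.
#' @export
de_config <- function(alpha = 0.01, fc_threshold = 2, pseudocount = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 pseudocount = pseudocount), class = "de_config")
}

#' Call differentially expressed genes between two libraries
#'
#' Genes expressed in at least one library are tested with [de_test()]; the
#' fold change is the pseudocounted normalized ratio
#' \code{((k1 + c) / N1) / ((k2 + c) / N2)} (gene length cancels within a
#' gene, so counts and RPKM give the same ratio up to the pseudocount). A
#' gene is called \code{up} when p < alpha and FC > fc_threshold, \code{down}
#' when p < alpha and FC < 1 / fc_threshold, otherwise \code{ns}. No
#' multiple-testing correction is applied; calls are on raw p-values.
#'
#' @param counts1,counts2 Gene counts from [assign_tags()] for each library.
#' @param N1,N2 Library unique mapped totals.
#' @param config A [de_config()].
#' @param min_exon_tags Expressed-gene threshold used for the testing gate.
#' @param fc_on \code{"counts"} (default) or \code{"rpkm"}; with
#'   \code{"rpkm"}, supply \code{ann} so exon-model lengths are available
#'   (the two differ only through the pseudocount).
#' @param ann Annotation, required for \code{fc_on = "rpkm"}.
#' @return list with \code{table} (gene_id, k1, k2, fold_change, p_value,
#'   call for every tested gene) and \code{summary}
#'   (n_tested, n_signif, n_up, n_down, n_total_de).
#' @export
call_de <- function(counts1, counts2, N1, N2, config = de_config(),
                    min_exon_tags = 2L, fc_on = c("counts", "rpkm"),
                    ann = NULL) {
  fc_on <- match.arg(fc_on)
  all_ids <- union(counts1$gene_id, counts2$gene_id)
  k1 <- counts1$exon[match(all_ids, counts1$gene_id)]
  k2 <- counts2$exon[match(all_ids, counts2$gene_id)]
  if (anyNA(k1) || anyNA(k2)) {
    warning("genes missing from one library treated as zero counts")
    k1[is.na(k1)] <- 0L
    k2[is.na(k2)] <- 0L
  }
  tested <- k1 >= min_exon_tags | k2 >= min_exon_tags
  ids <- all_ids[tested]
  k1 <- k1[tested]
  k2 <- k2[tested]
  p <- de_test(k1, N1, k2, N2)
  cc <- config$pseudocount
  if (fc_on == "rpkm") {
    if (is.null(ann)) stop("fc_on = 'rpkm' requires the annotation")
    L <- exon_model_lengths(ann)[ids]
    fc <- (1e9 * (k1 + cc) / (N1 * L)) / (1e9 * (k2 + cc) / (N2 * L))
  } else {
    fc <- ((k1 + cc) / N1) / ((k2 + cc) / N2)
  }
  call <- rep("ns", length(ids))
  call[p < config$alpha & fc > config$fc_threshold] <- "up"
  call[p < config$alpha & fc < 1 / config$fc_threshold] <- "down"
  tab <- data.frame(gene_id = ids, k1 = k1, k2 = k2, fold_change = fc,
                    p_value = p, call = call, stringsAsFactors = FALSE)
  list(table = tab,
       summary = list(n_tested = length(ids),
                      n_signif = sum(p < config$alpha),
                      n_up = sum(call == "up"),
                      n_down = sum(call == "down"),
                      n_total_de = sum(call != "ns")))
}
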