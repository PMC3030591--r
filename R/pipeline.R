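#' Run the full two-library analysis on a simulated study
#'
#' Builds the reference databases, maps both libraries through the filter and
#' trim-and-remap cascade, assigns unique tags to features, quantifies RPKM
#' and calls differential expression.
#'
#' @param study A [simulate_study()] result.
#' @param config A [mapper_config()].
#' @param de_cfg A [de_config()].
#' @param min_exon_tags Expressed-gene threshold.
#' @return list: per-library mapping results (\code{map1}, \code{map2}),
#'   feature assignments (\code{assign1}, \code{assign2}), expression tables
#'   (\code{expr1}, \code{expr2}), \code{de} (from [call_de()]) and the
#'   two-column mapping summary report.
#' @export
run_study_pipeline <- function(study, config = mapper_config(),
                               de_cfg = de_config(), min_exon_tags = 2L) {
  gdb <- build_genome_db(study$genome)
  jdb <- build_junction_db(study$annotation, study$genome)
  rdb <- build_rrna_db(study$annotation, study$genome)
  m1 <- map_library(study$lib1$reads, gdb, jdb, rdb, config)
  m2 <- map_library(study$lib2$reads, gdb, jdb, rdb, config)
  a1 <- assign_tags(m1$outcomes, study$annotation)
  a2 <- assign_tags(m2$outcomes, study$annotation)
  N1 <- m1$summary$unique
  N2 <- m2$summary$unique
  e1 <- expression_table(a1$counts, study$annotation, N1, min_exon_tags)
  e2 <- expression_table(a2$counts, study$annotation, N2, min_exon_tags)
  de <- call_de(a1$counts, a2$counts, N1, N2, de_cfg, min_exon_tags)
  counts <- lapply(list(list(m1, a1), list(m2, a2)), function(x) {
    c(x[[1]]$summary,
      list(unique_exon = unname(x[[2]]$class_totals[["exon"]]),
           unique_intron = unname(x[[2]]$class_totals[["intron"]])))
  })
  report <- mapping_summary_report(counts, c("lib1", "lib2"))
  list(map1 = m1, map2 = m2, assign1 = a1, assign2 = a2,
       expr1 = e1, expr2 = e2, de = de, report = report)
}

#' Compare pipeline results against the simulation ground truth
#'
#' Computes the truth-recovery metrics the package's validation rests on:
#' rRNA-filter recall on error-free rRNA tags, the observed intronic tag
#' fraction against the truth classes of the same reads, differential-
#' expression direction accuracy on adequately covered DE genes, and the
#' Spearman correlation between true abundances and RPKM.
#'
#' @param study A [simulate_study()] result.
#' @param res A [run_study_pipeline()] result.
#' @param min_expected Coverage gate: a DE gene counts as adequately covered
#'   when its realized sense mature-tag count is at least this in both
#'   libraries (default 20).
#' @return Named list of metrics.
#' @export
truth_recovery_metrics <- function(study, res, min_expected = 20L) {
  tr1 <- study$lib1$truth
  tr2 <- study$lib2$truth
  out1 <- res$map1$outcomes
  out2 <- res$map2$outcomes

  clean_rrna <- tr1$class == "rRNA" & !tr1$lowq & tr1$n_errors == 0
  rrna_recall <- mean(out1$status[clean_rrna] == "rrna")

  uniq1 <- out1$status == "unique"
  obs_intron <- unname(res$assign1$class_totals[["intron"]]) / sum(uniq1)
  tr_u <- tr1[match(out1$id[uniq1], tr1$id), ]
  truth_intron <- mean(tr_u$class == "pre_mRNA_intronic" & !tr_u$antisense)
  gen_intron <- mean(tr1$class == "pre_mRNA_intronic")

  mature_counts <- function(tr) {
    sel <- tr$class %in% c("mature_exonic", "junction_spanning") &
      !tr$antisense & !tr$lowq
    table(factor(tr$gene_id[sel], levels = study$expression$gene_id))
  }
  n1 <- mature_counts(tr1)
  n2 <- mature_counts(tr2)
  covered <- pmin(as.integer(n1), as.integer(n2)) >= min_expected
  de_truth <- study$expression
  de_tab <- res$de$table
  call_of <- stats::setNames(de_tab$call, de_tab$gene_id)
  sel <- de_truth$is_de & covered
  correct <- call_of[de_truth$gene_id[sel]] == de_truth$direction[sel]
  correct[is.na(correct)] <- FALSE
  de_accuracy <- if (any(sel)) mean(correct) else NA_real_

  m <- match(de_truth$gene_id, res$expr1$gene_id)
  spear <- stats::cor(de_truth$abundance_1, res$expr1$rpkm[m],
                      method = "spearman")

  is_de_of <- de_truth$is_de[match(de_tab$gene_id, de_truth$gene_id)]
  false_pos_rate <- mean(de_tab$p_value[!is_de_of & !is.na(is_de_of)] < 0.01)

  list(rrna_recall = rrna_recall,
       observed_intron_fraction = obs_intron,
       truth_intron_fraction = truth_intron,
       generated_intron_fraction = gen_intron,
       n_unique_lib1 = sum(uniq1),
       n_covered_de = sum(sel),
       de_direction_accuracy = de_accuracy,
       spearman_rpkm_truth = spear,
       nonde_fraction_below_alpha = false_pos_rate)
}
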