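# Two-group differential expression: Welch t-test on log2 values with
# Benjamini-Hochberg adjustment, and the fold-change / adjusted-p status
# thresholds applied downstream.

#' Two-group differential expression (subtype vs control)
#'
#' Per-gene Welch two-sample t statistic on log2 expression, two-sided
#' p-value, Benjamini-Hochberg adjustment across all tested genes.  Genes
#' with zero variance in both groups get p = 1.  Status is set with
#' [apply_de_thresholds()] at its defaults.
#'
#' @param cohort an `ExpressionCohort` (log2 scale).
#' @param subtype tumor subtype label to compare against controls.
#' @param control_label annotation label of the control group.
#' @param lfc_cut,adjp_cut thresholds forwarded to [apply_de_thresholds()].
#' @return data.frame with columns `gene`, `log2FC` (subtype mean minus
#'   control mean), `t`, `pvalue`, `adj_pvalue`, `status`.
#' @export
two_group_de <- function(cohort, subtype, control_label = "Control",
                         lfc_cut = 1, adjp_cut = 0.001) {
  ann <- cohort$annotation
  if (!subtype %in% ann$subtype) {
    stop(sprintf("subtype '%s' not present in annotation", subtype), call. = FALSE)
  }
  g1 <- ann$sample_id[ann$subtype == subtype]
  g2 <- ann$sample_id[ann$subtype == control_label]
  if (length(g1) < 3 || length(g2) < 3) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  x1 <- cohort$matrix[, g1, drop = FALSE]
  x2 <- cohort$matrix[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_sds(x1)^2; v2 <- row_sds(x2)^2
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2

  zero_var <- se2 < .Machine$double.eps
  tstat <- ifelse(zero_var, 0, lfc / sqrt(pmax(se2, .Machine$double.eps)))
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), df))
  res <- data.frame(
    gene = rownames(cohort$matrix),
    log2FC = lfc, t = tstat, pvalue = p,
    adj_pvalue = stats::p.adjust(p, method = "BH"),
    status = "not_significant",
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  apply_de_thresholds(res, lfc_cut = lfc_cut, adjp_cut = adjp_cut)
}

#' Set differential-expression status by fold-change and adjusted-p cuts
#'
#' A gene is `up` when `log2FC > lfc_cut` and `adj_pvalue < adjp_cut`,
#' `down` when `log2FC < -lfc_cut` and `adj_pvalue < adjp_cut`, otherwise
#' `not_significant`.  The adjusted-p bound is the binding one: BH-adjusted
#' p below 0.001 already implies FDR control far below 0.1.
#'
#' @param results data.frame from [two_group_de()] (needs `log2FC`,
#'   `adj_pvalue`).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @param adjp_cut adjusted p-value threshold (default 0.001).
#' @return the input with `status` recomputed.
#' @export
apply_de_thresholds <- function(results, lfc_cut = 1, adjp_cut = 0.001) {
  stopifnot(all(c("log2FC", "adj_pvalue") %in% names(results)))
  status <- rep("not_significant", nrow(results))
  sig <- results$adj_pvalue < adjp_cut
  status[sig & results$log2FC > lfc_cut] <- "up"
  status[sig & results$log2FC < -lfc_cut] <- "down"
  results$status <- status
  results
}
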