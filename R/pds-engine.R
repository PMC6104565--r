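# Pathway Deregulation Score (PDS): control-anchored principal-curve scoring.
#
# For each pathway: restrict the cohort to the pathway's genes, standardise
# each gene to the control distribution, reduce samples to the leading
# principal components, fit a principal curve through all samples, orient it
# so controls sit at the low end, and min-max normalise the arc-length
# position to [0, 1].  A sample's PDS is its normalised displacement along
# the curve away from the controls.

#' PDS engine parameters
#'
#' @param var_expl minimum fraction of variance the retained principal
#'   components must explain.
#' @param max_components cap on retained components.
#' @param max_iter,tol,span principal-curve fitting controls (see
#'   [fit_principal_curve()]).
#' @param sd_tol genes whose control SD falls below this are dropped.
#' @return list of parameters.
#' @export
pds_params <- function(var_expl = 0.85, max_components = 10,
                       max_iter = 50, tol = 1e-4, span = 0.3,
                       sd_tol = 1e-8) {
  list(
    var_expl = var_expl, max_components = as.integer(max_components),
    max_iter = max_iter, tol = tol, span = span, sd_tol = sd_tol
  )
}

#' Standardise a pathway's genes against the control group
#'
#' Centers each retained gene by its control mean and scales by its control
#' SD.  Genes absent from the matrix or with control SD below `sd_tol` are
#' dropped and reported.
#'
#' @param cohort an `ExpressionCohort` with at least 3 control samples.
#' @param genes member gene ids of the pathway.
#' @param sd_tol minimum control SD for a gene to be kept.
#' @return list with `z` (standardised gene-by-sample matrix), `dropped`
#'   (gene ids removed), `ok = TRUE`; or, when fewer than 3 usable genes
#'   remain, a `degenerate_pathway` record (`ok = FALSE`, `reason`).
#' @export
standardize_to_controls <- function(cohort, genes, sd_tol = 1e-8) {
  ann <- cohort$annotation
  ctrl_ids <- ann$sample_id[ann$subtype == "Control"]
  if (length(ctrl_ids) < 3) {
    stop("need at least 3 control samples to anchor standardisation", call. = FALSE)
  }
  present <- intersect(genes, rownames(cohort$matrix))
  missing <- setdiff(genes, present)
  sub <- cohort$matrix[present, , drop = FALSE]
  if (length(present) >= 1) {
    mu <- rowMeans(sub[, ctrl_ids, drop = FALSE])
    sd <- row_sds(sub[, ctrl_ids, drop = FALSE])
  } else {
    mu <- sd <- numeric(0)
  }
  keep <- sd > sd_tol
  dropped <- c(missing, present[!keep])
  if (sum(keep) < 3) {
    return(structure(
      list(
        ok = FALSE, reason = "fewer than 3 usable genes after filtering",
        dropped = dropped, n_usable = sum(keep)
      ),
      class = "degenerate_pathway"
    ))
  }
  z <- (sub[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  list(z = z, dropped = dropped, ok = TRUE)
}

#' Score one pathway's deregulation per sample
#'
#' @param cohort an `ExpressionCohort` (one subtype's tumors plus controls).
#' @param genes the pathway's member gene ids.
#' @param params a [pds_params()] list.
#' @return list with `pds` (named per-sample scores in `[0, 1]`) and `meta`
#'   (genes used/dropped, components kept, convergence, degeneracy flag); or
#'   a `degenerate_pathway` record if standardisation failed.
#' @export
pathway_pds <- function(cohort, genes, params = pds_params()) {
  std <- standardize_to_controls(cohort, genes, params$sd_tol)
  if (!isTRUE(std$ok)) return(std)
  z <- std$z
  samples <- colnames(z)
  ann <- cohort$annotation
  is_ctrl <- ann$subtype[match(samples, ann$sample_id)] == "Control"

  degenerate <- function(reason) {
    list(
      pds = stats::setNames(rep(0, length(samples)), samples),
      meta = list(
        genes_used = rownames(z), dropped = std$dropped,
        n_components = 0L, converged = NA, iterations = 0L,
        degenerate = TRUE, reason = reason
      )
    )
  }

  pts <- t(z) # samples as points in gene space
  if (all(abs(sweep(pts, 2, pts[1, ], `-`)) < 1e-12)) {
    return(degenerate("all samples identical after standardisation"))
  }

  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  var_frac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- min(
    which(var_frac >= params$var_expl)[1],
    params$max_components,
    ncol(pc$x)
  )
  red <- pc$x[, seq_len(ncomp), drop = FALSE]

  fit <- fit_principal_curve(red,
    max_iter = params$max_iter,
    tol = params$tol, span = params$span
  )
  lambda <- fit$lambda
  # anchor: controls define the low-deregulation end of the curve
  if (stats::median(lambda[is_ctrl]) > stats::median(lambda[!is_ctrl])) {
    lambda <- max(lambda) - lambda
  }
  rng <- max(lambda) - min(lambda)
  if (rng < 1e-12) return(degenerate("zero arc-length spread"))
  list(
    pds = stats::setNames((lambda - min(lambda)) / rng, samples),
    meta = list(
      genes_used = rownames(z), dropped = std$dropped,
      n_components = ncomp, converged = fit$converged,
      iterations = fit$iterations, degenerate = FALSE, reason = NA_character_
    )
  )
}

#' Compute the pathway-by-sample PDS matrix
#'
#' Applies [pathway_pds()] to every entry of a gene-set collection,
#' preserving pathway order.  Pathways that cannot be scored (too few usable
#' genes) are skipped and recorded.
#'
#' @param cohort an `ExpressionCohort`.
#' @param collection a `GeneSetCollection`.
#' @param params a [pds_params()] list.
#' @return object of class `PDSMatrix`: list with `scores`
#'   (pathway-by-sample matrix), `meta` (per-pathway data.frame), `skipped`
#'   (named list of `degenerate_pathway` records).
#' @export
compute_pds_matrix <- function(cohort, collection, params = pds_params()) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (length(collection$ids) == 0) stop("empty gene-set collection", call. = FALSE)
  samples <- colnames(cohort$matrix)
  rows <- list()
  meta <- list()
  skipped <- list()
  for (id in collection$ids) {
    res <- pathway_pds(cohort, collection$members[[id]], params)
    if (inherits(res, "degenerate_pathway")) {
      skipped[[id]] <- res
      next
    }
    rows[[id]] <- res$pds[samples]
    m <- res$meta
    meta[[id]] <- data.frame(
      pathway = id,
      n_genes_used = length(m$genes_used), n_dropped = length(m$dropped),
      n_components = m$n_components, converged = isTRUE(m$converged),
      iterations = m$iterations, degenerate = m$degenerate,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no pathway could be scored", call. = FALSE)
  scores <- do.call(rbind, rows)
  colnames(scores) <- samples
  structure(
    list(
      scores = scores,
      meta = do.call(rbind, meta),
      skipped = skipped
    ),
    class = "PDSMatrix"
  )
}

#' @export
print.PDSMatrix <- function(x, ...) {
  cat(sprintf(
    "PDSMatrix: %d pathways x %d samples (%d degenerate, %d skipped)\n",
    nrow(x$scores), ncol(x$scores), sum(x$meta$degenerate), length(x$skipped)
  ))
  invisible(x)
}
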