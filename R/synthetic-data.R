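# Synthetic dual-platform expression cohorts with planted pathway deregulation.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: two platforms measuring the same cohort-level signal (a microarray
# style log2 Gaussian platform and a sequencing style negative-binomial count
# platform with upper-quartile normalization), control vs tumor groups split
# into intrinsic subtypes, a minority of pathways carrying coordinated
# expression shifts, and a sparse drug-target table.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator.  Defaults follow a
#' scaled-down breast-cancer cohort composition (Basal 12, Her2 8, LumA 40,
#' LumB 20 tumors plus 14 controls) and disjoint gene-set blocks.
#'
#' @param n_genes total number of genes in the universe.
#' @param n_pathways number of gene sets.
#' @param genes_per_pathway members per gene set.
#' @param subtypes character vector of tumor subtype labels (controls are
#'   always labelled `"Control"` and configured via `n_control`).
#' @param n_tumor tumors per subtype; a scalar is recycled, or a named vector
#'   over `subtypes`.
#' @param n_control number of control samples.
#' @param planted `data.frame` with columns `subtype`, `pathway`, `effect`
#'   declaring which pathways are deregulated in which subtype and by how
#'   many control standard deviations (log2 scale).  `NULL` plants nothing.
#' @param platform `"microarray"` (Gaussian on log2 scale) or `"counts"`
#'   (negative-binomial counts, upper-quartile scaled, then `log2(x + 1)`).
#' @param noise_sd residual SD of the microarray platform on log2 scale.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression.
#' @param frac_up fraction of a planted pathway's genes shifted up (the rest
#'   shift down); deregulation scoring is direction-agnostic, differential
#'   expression is not, hence the knob.
#' @param overlap_frac fraction of each gene set (after the first) whose
#'   members are resampled from earlier sets, emulating overlapping pathway
#'   catalogs; `0` keeps sets disjoint.
#' @param nb_size negative-binomial size (inverse dispersion) of the count
#'   platform.
#' @param uq_target fixed upper quartile that every count sample is scaled to
#'   before the log transform.
#' @param seed master seed; every random stream derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000,
                       n_pathways = 20,
                       genes_per_pathway = 50,
                       subtypes = c("Basal", "Her2", "LumA", "LumB"),
                       n_tumor = c(Basal = 12, Her2 = 8, LumA = 40, LumB = 20),
                       n_control = 14,
                       planted = NULL,
                       platform = c("microarray", "counts"),
                       noise_sd = 1,
                       baseline_mean = 7,
                       baseline_sd = 1,
                       frac_up = 0.5,
                       overlap_frac = 0,
                       nb_size = 10,
                       uq_target = 1000,
                       seed = 1) {
  platform <- match.arg(platform)
  if (length(n_tumor) == 1L) n_tumor <- stats::setNames(rep(n_tumor, length(subtypes)), subtypes)
  if (is.null(names(n_tumor))) names(n_tumor) <- subtypes
  cfg <- list(
    n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
    genes_per_pathway = as.integer(genes_per_pathway),
    subtypes = as.character(subtypes), n_tumor = n_tumor,
    n_control = as.integer(n_control), planted = planted,
    platform = platform, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    frac_up = frac_up, overlap_frac = overlap_frac,
    nb_size = nb_size, uq_target = uq_target, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop_validation("n_genes", "must be positive")
  if (cfg$n_pathways < 1) stop_validation("n_pathways", "must be positive")
  if (cfg$genes_per_pathway < 1) stop_validation("genes_per_pathway", "must be positive")
  if (cfg$genes_per_pathway * cfg$n_pathways > cfg$n_genes) {
    stop_validation("genes_per_pathway", sprintf(
      "x n_pathways (%d) exceeds n_genes (%d)",
      cfg$genes_per_pathway * cfg$n_pathways, cfg$n_genes
    ))
  }
  if (length(cfg$subtypes) < 1) stop_validation("subtypes", "must be non-empty")
  if ("Control" %in% cfg$subtypes) stop_validation("subtypes", "must not contain 'Control'")
  if (!setequal(names(cfg$n_tumor), cfg$subtypes)) {
    stop_validation("n_tumor", "names must match subtypes")
  }
  if (any(cfg$n_tumor < 1)) stop_validation("n_tumor", "must be positive")
  if (cfg$n_control < 1) stop_validation("n_control", "must be positive")
  if (cfg$noise_sd <= 0) stop_validation("noise_sd", "must be positive")
  if (cfg$frac_up < 0 || cfg$frac_up > 1) stop_validation("frac_up", "must lie in [0, 1]")
  if (cfg$overlap_frac < 0 || cfg$overlap_frac >= 1) stop_validation("overlap_frac", "must lie in [0, 1)")
  if (!is.null(cfg$planted)) {
    pl <- cfg$planted
    if (!is.data.frame(pl) || !all(c("subtype", "pathway", "effect") %in% names(pl))) {
      stop_validation("planted", "must be a data.frame with columns subtype, pathway, effect")
    }
    if (!all(pl$subtype %in% cfg$subtypes)) stop_validation("planted", "has subtypes outside 'subtypes'")
    if (any(pl$effect < 0)) stop_validation("planted", "effect sizes must be >= 0")
    pw_ids <- sprintf("pw%02d", seq_len(cfg$n_pathways))
    if (!all(pl$pathway %in% pw_ids)) {
      stop_validation("planted", sprintf(
        "pathway ids must be among %s..%s", pw_ids[1], pw_ids[length(pw_ids)]
      ))
    }
  }
  invisible(cfg)
}

#' Expression cohort container
#'
#' @param matrix numeric gene-by-sample matrix (log2 scale).
#' @param annotation `data.frame` with columns `sample_id`, `subtype`,
#'   `dataset`.
#' @param platform platform tag.
#' @return object of class `ExpressionCohort`.
#' @export
expression_cohort <- function(matrix, annotation, platform = "microarray") {
  stopifnot(is.matrix(matrix), is.data.frame(annotation))
  if (anyNA(matrix)) stop("expression matrix contains missing values", call. = FALSE)
  if (anyDuplicated(annotation$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (!all(annotation$sample_id %in% colnames(matrix))) {
    stop("annotated samples missing from the matrix", call. = FALSE)
  }
  structure(
    list(matrix = matrix, annotation = annotation, platform = platform),
    class = "ExpressionCohort"
  )
}

#' @export
print.ExpressionCohort <- function(x, ...) {
  cat(sprintf(
    "ExpressionCohort: %d genes x %d samples (%s), %d control / %d tumor\n",
    nrow(x$matrix), ncol(x$matrix), x$platform,
    sum(x$annotation$subtype == "Control"),
    sum(x$annotation$subtype != "Control")
  ))
  invisible(x)
}

#' Restrict a cohort to one subtype plus its controls
#'
#' Deregulation is scored for each tumor subgroup against the control group,
#' with other subtypes excluded from the run.
#'
#' @param cohort an `ExpressionCohort`.
#' @param subtype subtype label to keep (controls are always kept).
#' @return an `ExpressionCohort` with only that subtype's tumors and controls.
#' @export
subset_cohort <- function(cohort, subtype) {
  ann <- cohort$annotation
  if (!subtype %in% ann$subtype) {
    stop(sprintf("subtype '%s' not present in annotation", subtype), call. = FALSE)
  }
  keep <- ann$subtype %in% c(subtype, "Control")
  expression_cohort(
    cohort$matrix[, ann$sample_id[keep], drop = FALSE],
    ann[keep, , drop = FALSE],
    cohort$platform
  )
}

# Shared simulation structure (baselines, gene sets, shift signs) drawn from
# dedicated seed streams so both platforms see the same ground truth.
sim_structure <- function(cfg) {
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  pw_ids <- sprintf("pw%02d", seq_len(cfg$n_pathways))

  baseline <- with_seed(
    derive_seed(cfg$seed, 1L),
    stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  )
  names(baseline) <- gene_ids

  members <- with_seed(derive_seed(cfg$seed, 2L), {
    blocks <- split(
      gene_ids[seq_len(cfg$n_pathways * cfg$genes_per_pathway)],
      rep(seq_len(cfg$n_pathways), each = cfg$genes_per_pathway)
    )
    names(blocks) <- pw_ids
    if (cfg$overlap_frac > 0 && cfg$n_pathways > 1) {
      n_swap <- floor(cfg$overlap_frac * cfg$genes_per_pathway)
      for (i in seq(2L, cfg$n_pathways)) {
        pool <- unlist(blocks[seq_len(i - 1L)], use.names = FALSE)
        swap <- sample(cfg$genes_per_pathway, n_swap)
        blocks[[i]][swap] <- sample(pool, n_swap)
        blocks[[i]] <- unique(blocks[[i]])
      }
    }
    blocks
  })
  collection <- gene_set_collection(
    ids = pw_ids,
    names = sprintf("Pathway %02d", seq_len(cfg$n_pathways)),
    members = members
  )

  # Per (subtype, gene) log2 shifts implied by the planted pathways.  Signs
  # are balanced within each pathway (frac_up up, rest down) and shared
  # across platforms: they are part of the ground truth, not of the noise.
  shifts <- list()
  if (!is.null(cfg$planted) && nrow(cfg$planted) > 0) {
    shifts <- with_seed(derive_seed(cfg$seed, 3L), {
      out <- list()
      for (st in unique(cfg$planted$subtype)) {
        delta <- stats::setNames(numeric(cfg$n_genes), gene_ids)
        rows <- cfg$planted[cfg$planted$subtype == st, , drop = FALSE]
        for (r in seq_len(nrow(rows))) {
          gs <- members[[rows$pathway[r]]]
          m <- length(gs)
          n_up <- round(cfg$frac_up * m)
          signs <- sample(c(rep(1, n_up), rep(-1, m - n_up)))
          delta[gs] <- delta[gs] + rows$effect[r] * signs
        }
        out[[st]] <- delta
      }
      out
    })
  }

  list(
    gene_ids = gene_ids, pathway_ids = pw_ids, baseline = baseline,
    collection = collection, shifts = shifts
  )
}

# Draw one cohort's samples given the shared structure.  `shift_scale` maps
# effect sizes (in control SD units on log2 scale) to log2 shifts per gene.
draw_cohort <- function(cfg, struct, platform, dataset, stream) {
  labels <- c(
    rep(cfg$subtypes, times = cfg$n_tumor[cfg$subtypes]),
    rep("Control", cfg$n_control)
  )
  sample_ids <- paste0(
    dataset, "_", labels, "_",
    unlist(lapply(
      c(cfg$n_tumor[cfg$subtypes], Control = cfg$n_control),
      function(n) sprintf("%03d", seq_len(n))
    ), use.names = FALSE)
  )
  n_samp <- length(labels)
  G <- cfg$n_genes

  mat <- with_seed(derive_seed(cfg$seed, stream), {
    if (platform == "microarray") {
      # effect sizes are in units of the control SD, which is noise_sd here
      delta <- matrix(0, G, n_samp)
      for (st in names(struct$shifts)) {
        idx <- which(labels == st)
        if (length(idx)) delta[, idx] <- struct$shifts[[st]] * cfg$noise_sd
      }
      struct$baseline + delta +
        matrix(stats::rnorm(G * n_samp, 0, cfg$noise_sd), G, n_samp)
    } else {
      mu0 <- 2^struct$baseline
      # approximate control SD on the log2(x+1) scale for a NB gene; used to
      # express planted effects in control-SD units on the count platform
      sd_log2 <- sqrt(1 / mu0 + 1 / cfg$nb_size) / log(2)
      lmu <- matrix(log2(mu0), G, n_samp)
      for (st in names(struct$shifts)) {
        idx <- which(labels == st)
        if (length(idx)) lmu[, idx] <- lmu[, idx] + struct$shifts[[st]] * sd_log2
      }
      counts <- matrix(
        stats::rnbinom(G * n_samp, mu = 2^lmu, size = cfg$nb_size),
        G, n_samp
      )
      # fixed-upper-quartile scaling within each sample, then log2(x + 1)
      q75 <- apply(counts, 2, stats::quantile, probs = 0.75)
      if (any(q75 <= 0)) stop("degenerate count sample: zero upper quartile", call. = FALSE)
      log2(sweep(counts, 2, cfg$uq_target / q75, `*`) + 1)
    }
  })
  dimnames(mat) <- list(struct$gene_ids, sample_ids)
  expression_cohort(
    mat,
    data.frame(
      sample_id = sample_ids, subtype = labels, dataset = dataset,
      stringsAsFactors = FALSE
    ),
    platform
  )
}

#' Generate one synthetic expression cohort with planted ground truth
#'
#' @param config a [sim_config()].
#' @param dataset dataset id recorded in the annotation.
#' @return list with elements `cohort` (an `ExpressionCohort`), `collection`
#'   (a `GeneSetCollection`), and `truth` (planted pathway ids per subtype,
#'   per-gene true log2 shifts per subtype, and the planted table).
#' @examples
#' sim <- generate_cohort(sim_config(
#'   n_genes = 200, n_pathways = 5, genes_per_pathway = 20,
#'   subtypes = "Basal", n_tumor = 10, n_control = 6,
#'   planted = data.frame(subtype = "Basal", pathway = "pw01", effect = 2),
#'   seed = 1
#' ))
#' dim(sim$cohort$matrix)
#' @export
generate_cohort <- function(config, dataset = "dsA") {
  validate_sim_config(config)
  struct <- sim_structure(config)
  cohort <- draw_cohort(config, struct, config$platform, dataset, stream = 10L)
  list(
    cohort = cohort,
    collection = struct$collection,
    truth = ground_truth(config, struct)
  )
}

ground_truth <- function(cfg, struct) {
  planted_ids <- list()
  if (!is.null(cfg$planted) && nrow(cfg$planted) > 0) {
    planted_ids <- split(cfg$planted$pathway, cfg$planted$subtype)
  }
  structure(
    list(
      planted = planted_ids,
      planted_table = cfg$planted,
      gene_shifts = struct$shifts,
      drug_effects = NULL
    ),
    class = "GroundTruth"
  )
}

#' Generate paired cohorts on two platforms sharing one ground truth
#'
#' Both cohorts share the gene universe, gene sets, and planted per-gene
#' shifts, but have independent samples and platform-specific noise: the
#' first is microarray-like (Gaussian on log2 scale), the second
#' sequencing-like (negative-binomial counts, scaled within samples to a
#' fixed upper quartile, then `log2(x + 1)`).
#'
#' @param config a [sim_config()] (its `platform` field is ignored).
#' @return list with `cohort_a`, `cohort_b`, `collection`, `truth`.
#' @export
generate_two_platform_cohorts <- function(config) {
  validate_sim_config(config)
  struct <- sim_structure(config)
  list(
    cohort_a = draw_cohort(config, struct, "microarray", "dsA", stream = 10L),
    cohort_b = draw_cohort(config, struct, "counts", "dsB", stream = 20L),
    collection = struct$collection,
    truth = ground_truth(config, struct)
  )
}

#' Generate a sparse synthetic drug-gene interaction table
#'
#' Emulates the shape of a drug-gene interaction database export: rows of
#' (drug, gene, interaction type, source), plus a symmetric drug-drug
#' conflict list.  A configurable fraction of genes has no drug at all.
#'
#' Draw order under the derived seed is documented and stable: (1) one
#' Bernoulli(fraction_druggable) draw per gene, in input order; (2) for each
#' druggable gene, a uniform draw of its number of drugs in
#' `drugs_per_gene`; (3) drug identities; (4) interaction types; (5)
#' drug-drug conflict pairs.
#'
#' @param genes character vector of gene ids.
#' @param fraction_druggable probability a gene has at least one drug.
#' @param drugs_per_gene integer range `c(min, max)` of drugs per druggable
#'   gene.
#' @param interaction_types vocabulary to sample types from.
#' @param n_drug_pool size of the synthetic drug name pool (drugs can hit
#'   several genes).
#' @param ddi_frac fraction of the drug pool engaged in pairwise conflicts.
#' @param seed integer seed.
#' @param ground_truth optional `GroundTruth`; when given, per-(drug, gene)
#'   expected effects are derived from the planted shift signs and returned.
#' @return list with `interactions` (data.frame `drug`, `gene`,
#'   `interaction_type`, `source`), `ddi` (data.frame `drug_a`, `drug_b`,
#'   `note`; unordered pairs stored once), and `truth_effects` (or `NULL`).
#' @export
generate_drug_table <- function(genes,
                                fraction_druggable = 0.3,
                                drugs_per_gene = c(1L, 3L),
                                interaction_types = c(
                                  "inhibitor", "antagonist", "blocker",
                                  "inducer", "activator", "agonist",
                                  "binder", "other"
                                ),
                                n_drug_pool = NULL,
                                ddi_frac = 0.05,
                                seed = 1,
                                ground_truth = NULL) {
  if (length(genes) == 0) stop_validation("genes", "must be non-empty")
  if (fraction_druggable < 0 || fraction_druggable > 1) {
    stop_validation("fraction_druggable", "must lie in [0, 1]")
  }
  n_pool <- n_drug_pool %||% max(10L, ceiling(length(genes) * fraction_druggable))
  pool <- sprintf("DRUG_%04d", seq_len(n_pool))

  res <- with_seed(derive_seed(seed, 31L), {
    druggable <- stats::rbinom(length(genes), 1L, fraction_druggable) == 1L
    gsel <- genes[druggable]
    n_drugs <- if (length(gsel)) {
      sample(seq(drugs_per_gene[1], drugs_per_gene[2]),
        length(gsel),
        replace = TRUE
      )
    } else {
      integer(0)
    }
    rows <- lapply(seq_along(gsel), function(i) {
      # without replacement within a gene: no duplicated (drug, gene) rows
      dr <- sample(pool, n_drugs[i])
      data.frame(
        drug = dr, gene = gsel[i],
        interaction_type = sample(interaction_types, n_drugs[i], replace = TRUE),
        source = "SynthDB", stringsAsFactors = FALSE
      )
    })
    interactions <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(
        drug = character(0), gene = character(0),
        interaction_type = character(0), source = character(0)
      )
    }
    n_pairs <- round(ddi_frac * n_pool)
    ddi <- if (n_pairs > 0 && n_pool >= 2) {
      pairs <- t(replicate(n_pairs, sort(sample(pool, 2L))))
      pairs <- unique(pairs)
      data.frame(
        drug_a = pairs[, 1], drug_b = pairs[, 2],
        note = "synthetic interaction", stringsAsFactors = FALSE
      )
    } else {
      data.frame(drug_a = character(0), drug_b = character(0), note = character(0))
    }
    list(interactions = interactions, ddi = ddi)
  })

  truth_effects <- NULL
  if (!is.null(ground_truth) && length(ground_truth$gene_shifts) &&
    nrow(res$interactions) > 0) {
    truth_effects <- do.call(rbind, lapply(names(ground_truth$gene_shifts), function(st) {
      delta <- ground_truth$gene_shifts[[st]]
      tb <- res$interactions
      sh <- delta[tb$gene]
      keep <- !is.na(sh) & sh != 0
      if (!any(keep)) return(NULL)
      tb <- tb[keep, , drop = FALSE]
      status <- ifelse(sh[keep] > 0, "up", "down")
      dir <- classify_interaction_direction(tb$interaction_type)
      data.frame(
        subtype = st, drug = tb$drug, gene = tb$gene,
        effect = classify_effect(status, dir), stringsAsFactors = FALSE
      )
    }))
  }
  list(interactions = res$interactions, ddi = res$ddi, truth_effects = truth_effects)
}
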