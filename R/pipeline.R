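# End-to-end pipeline: simulate (or ingest) two cohorts, score pathway
# deregulation per subtype on each platform, rank and intersect, test
# differential expression, prioritise drugs, and optionally recommend
# per-patient therapies.  Writes all stage outputs plus a run manifest.

#' Pipeline configuration
#'
#' Validated container of every tunable parameter of [run_pipeline()].
#' Unknown keys are rejected.
#'
#' @param sim a [sim_config()] describing the synthetic cohorts (simulate
#'   mode), or `NULL` when file inputs are given.
#' @param paths named list of input file paths (`expression_a`,
#'   `annotation_a`, `expression_b`, `annotation_b`, `gmt`, `drugs`, `ddi`)
#'   for ingest mode; ignored when `sim` is given.
#' @param pds a [pds_params()] list.
#' @param top_k top-k cut for the per-dataset rankings (default 30).
#' @param lfc_cut,adjp_cut differential-expression thresholds.
#' @param pds_threshold per-patient pathway selection threshold.
#' @param drug_fraction,drug_seed drug-table generation knobs (simulate
#'   mode).
#' @param seed master seed for the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, pds = pds_params(),
                            top_k = 30, lfc_cut = 1, adjp_cut = 0.001,
                            pds_threshold = 0.45, drug_fraction = 0.3,
                            drug_seed = NULL, seed = 1) {
  if (is.null(sim) && is.null(paths)) {
    stop("pipeline_config needs either 'sim' or 'paths'", call. = FALSE)
  }
  if (!is.null(paths)) {
    known <- c(
      "expression_a", "annotation_a", "expression_b", "annotation_b",
      "gmt", "drugs", "ddi"
    )
    extra <- setdiff(names(paths), known)
    if (length(extra)) {
      stop(sprintf("unknown path keys: %s", paste(extra, collapse = ", ")),
        call. = FALSE
      )
    }
  }
  if (top_k < 1) stop_validation("top_k", "must be >= 1")
  if (lfc_cut < 0) stop_validation("lfc_cut", "must be >= 0")
  if (adjp_cut <= 0 || adjp_cut > 1) stop_validation("adjp_cut", "must lie in (0, 1]")
  if (pds_threshold < 0 || pds_threshold > 1) {
    stop_validation("pds_threshold", "must lie in [0, 1]")
  }
  structure(
    list(
      sim = sim, paths = paths, pds = pds, top_k = top_k,
      lfc_cut = lfc_cut, adjp_cut = adjp_cut,
      pds_threshold = pds_threshold, drug_fraction = drug_fraction,
      drug_seed = drug_seed, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full deregulation-to-repurposing pipeline
#'
#' Stages: simulate or ingest two cohorts -> per-subtype PDS on each
#' platform -> PDSz, median aggregation, top-k, cross-dataset consensus ->
#' differential expression per subtype -> drug prioritization and effect
#' classification -> target counts and homeostasis network.  When
#' `out_dir` is given, every stage output is written as TSV/GMT/JSON plus a
#' manifest with parameter values and md5 hashes of all outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (`NULL` skips writing).
#' @return list with `cohorts`, `collection`, `truth`, `pds` (nested
#'   `[dataset][subtype]` `PDSMatrix`), `rankings`, `top`, `consensus`
#'   (per subtype), `de` (per dataset x subtype), `prioritization`
#'   (combined table), `target_counts`, `network`, `drugs`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  if (!is.null(config$sim)) {
    sim <- generate_two_platform_cohorts(config$sim)
    cohorts <- list(dsA = sim$cohort_a, dsB = sim$cohort_b)
    collection <- sim$collection
    truth <- sim$truth
    drug_tab <- generate_drug_table(
      rownames(sim$cohort_a$matrix),
      fraction_druggable = config$drug_fraction,
      seed = config$drug_seed %||% config$seed,
      ground_truth = truth
    )
  } else {
    p <- config$paths
    cohorts <- list(
      dsA = read_expression_tsv(p$expression_a, p$annotation_a, "microarray"),
      dsB = read_expression_tsv(p$expression_b, p$annotation_b, "counts")
    )
    collection <- read_gmt(p$gmt)
    truth <- NULL
    drug_tab <- list(
      interactions = if (!is.null(p$drugs)) read_drug_table(p$drugs) else NULL,
      ddi = if (!is.null(p$ddi)) read_ddi_table(p$ddi) else NULL
    )
  }

  subtypes <- setdiff(unique(cohorts$dsA$annotation$subtype), "Control")

  pds <- list()
  rankings <- list()
  top <- list()
  for (ds in names(cohorts)) {
    pds[[ds]] <- list()
    rankings[[ds]] <- list()
    top[[ds]] <- list()
    for (st in subtypes) {
      run_cohort <- subset_cohort(cohorts[[ds]], st)
      pm <- compute_pds_matrix(run_cohort, collection, config$pds)
      pz <- suppressWarnings(pdsz_transform(pm))
      med <- median_pdsz_by_subtype(pz, run_cohort$annotation, st)
      pds[[ds]][[st]] <- pm
      rankings[[ds]][[st]] <- med
      top[[ds]][[st]] <- suppressWarnings(top_k_pathways(med, config$top_k))
    }
  }

  consensus <- lapply(stats::setNames(subtypes, subtypes), function(st) {
    cross_dataset_intersection(top$dsA[[st]], top$dsB[[st]])
  })

  de <- list()
  for (ds in names(cohorts)) {
    de[[ds]] <- lapply(stats::setNames(subtypes, subtypes), function(st) {
      two_group_de(cohorts[[ds]], st,
        lfc_cut = config$lfc_cut, adjp_cut = config$adjp_cut
      )
    })
  }

  prioritization <- do.call(rbind, lapply(subtypes, function(st) {
    # a target must be differentially expressed consistently; dsA's DE call
    # is used for logFC reporting, dsB's must agree in direction
    de_a <- de$dsA[[st]]
    de_b <- de$dsB[[st]]
    agree <- de_a$status %in% c("up", "down") &
      de_a$status == de_b$status[match(de_a$gene, de_b$gene)]
    de_use <- de_a
    de_use$status[!agree] <- "not_significant"
    build_prioritization_table(
      consensus[[st]], de_use, drug_tab$interactions, collection,
      subtype = st
    )
  }))

  target_counts <- count_targets_by_subtype(prioritization)
  network <- build_multipartite_network(prioritization)

  result <- list(
    cohorts = cohorts, collection = collection, truth = truth,
    pds = pds, rankings = rankings, top = top, consensus = consensus,
    de = de, prioritization = prioritization,
    target_counts = target_counts, network = network, drugs = drug_tab,
    manifest = NULL
  )

  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config, out_dir, t0)
  }
  result
}

write_pipeline_outputs <- function(result, config, out_dir, t0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    file
  }
  files <- character(0)

  for (ds in names(result$cohorts)) {
    files <- c(files, wt(
      data.frame(
        gene = rownames(result$cohorts[[ds]]$matrix),
        result$cohorts[[ds]]$matrix, check.names = FALSE
      ),
      sprintf("expression_%s.tsv", ds)
    ))
    files <- c(files, wt(result$cohorts[[ds]]$annotation, sprintf("annotation_%s.tsv", ds)))
    for (st in names(result$pds[[ds]])) {
      f <- sprintf("pds_%s_%s.tsv", ds, st)
      write_pds_matrix(result$pds[[ds]][[st]], file.path(out_dir, f))
      files <- c(files, f, paste0(f, ".meta.json"))
    }
  }
  write_gmt(result$collection, file.path(out_dir, "gene_sets.gmt"))
  files <- c(files, "gene_sets.gmt")

  rank_rows <- do.call(rbind, lapply(names(result$rankings), function(ds) {
    do.call(rbind, lapply(names(result$rankings[[ds]]), function(st) {
      med <- sort(result$rankings[[ds]][[st]], decreasing = TRUE)
      data.frame(
        subtype = st, dataset = ds, pathway = names(med),
        median_pdsz = unname(med), rank = seq_along(med),
        stringsAsFactors = FALSE
      )
    }))
  }))
  files <- c(files, wt(rank_rows, "ranking.tsv"))

  cons_rows <- do.call(rbind, lapply(names(result$consensus), function(st) {
    cbind(subtype = st, result$consensus[[st]])
  }))
  files <- c(files, wt(cons_rows, "consensus.tsv"))

  for (ds in names(result$de)) {
    for (st in names(result$de[[ds]])) {
      files <- c(files, wt(result$de[[ds]][[st]], sprintf("de_%s_%s.tsv", ds, st)))
    }
  }
  files <- c(files, wt(result$prioritization, "prioritization.tsv"))
  files <- c(files, wt(result$target_counts, "target_counts.tsv"))

  if (igraph::vcount(result$network) > 0) {
    igraph::write_graph(result$network,
      file.path(out_dir, "network.graphml"),
      format = "graphml"
    )
    files <- c(files, "network.graphml")
    el <- igraph::as_data_frame(result$network, what = "edges")
    files <- c(files, wt(el, "network_edges.tsv"))
  }

  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    params = list(
      top_k = config$top_k, lfc_cut = config$lfc_cut,
      adjp_cut = config$adjp_cut, pds_threshold = config$pds_threshold,
      var_expl = config$pds$var_expl, max_components = config$pds$max_components,
      curve_tol = config$pds$tol, curve_max_iter = config$pds$max_iter,
      curve_span = config$pds$span
    ),
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(files))))
  )
  names(manifest$outputs) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}
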