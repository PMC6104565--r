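# Per-patient drug recommendation: select the patient's deregulated
# pathways by PDS threshold, map them to homeostasis drugs, and screen
# drug-drug conflicts.

#' Patient deregulation profile
#'
#' @param patient_id sample/patient identifier.
#' @param pathways character vector of pathway ids or names.
#' @param pds numeric PDS values in `[0, 1]`, same length as `pathways`.
#' @param subtype the patient's tumor subtype label.
#' @return object of class `PatientProfile`.
#' @export
patient_profile <- function(patient_id, pathways, pds, subtype = NA_character_) {
  stopifnot(length(pathways) == length(pds))
  if (any(pds < 0 | pds > 1)) stop("PDS values must lie in [0, 1]", call. = FALSE)
  structure(
    list(
      patient_id = patient_id,
      profile = data.frame(
        pathway = as.character(pathways), pds = as.numeric(pds),
        stringsAsFactors = FALSE
      ),
      subtype = subtype
    ),
    class = "PatientProfile"
  )
}

#' Extract a patient profile from a PDS matrix
#'
#' @param pds a `PDSMatrix`.
#' @param sample_id column to extract.
#' @param subtype subtype label to record.
#' @return a `PatientProfile` over the matrix's pathways.
#' @export
profile_from_pds <- function(pds, sample_id, subtype = NA_character_) {
  stopifnot(inherits(pds, "PDSMatrix"))
  if (!sample_id %in% colnames(pds$scores)) {
    stop(sprintf("sample '%s' not in PDS matrix", sample_id), call. = FALSE)
  }
  patient_profile(sample_id, rownames(pds$scores), pds$scores[, sample_id], subtype)
}

#' Select a patient's deregulated pathways by PDS threshold
#'
#' @param profile a `PatientProfile`.
#' @param candidates pathway ids to consider (default: all in the profile).
#' @param pds_threshold inclusive selection threshold in `[0, 1]`.
#' @return list with `selected` (data.frame `pathway`, `pds`) and `excluded`
#'   (data.frame `pathway`, `pds`, `reason = "below_threshold"`).
#' @export
select_patient_pathways <- function(profile, candidates = NULL,
                                    pds_threshold = 0.45) {
  if (pds_threshold < 0 || pds_threshold > 1) {
    stop("pds_threshold must lie in [0, 1]", call. = FALSE)
  }
  p <- profile$profile
  if (!is.null(candidates)) p <- p[p$pathway %in% candidates, , drop = FALSE]
  sel <- p$pds >= pds_threshold
  excluded <- p[!sel, , drop = FALSE]
  excluded$reason <- if (nrow(excluded)) "below_threshold" else character(0)
  list(
    selected = p[sel, , drop = FALSE],
    excluded = excluded
  )
}

#' Recommend drugs for one patient
#'
#' Takes the union of Homeostasis drugs over the patient's selected
#' pathways; selected pathways with no druggable target are annotated
#' `no_druggable_target`; the resulting drug set is screened for known
#' drug-drug conflicts.
#'
#' @param profile a `PatientProfile`.
#' @param prioritization prioritization table restricted to the patient's
#'   subtype (from [build_prioritization_table()]); pathways are matched on
#'   the `pathway` column, falling back to `pathway_name`.
#' @param ddi drug-drug interaction data.frame (`drug_a`, `drug_b`) or
#'   `NULL`.
#' @param pds_threshold inclusive pathway selection threshold.
#' @return object of class `TherapyRecommendation`: list with `patient_id`,
#'   `selected` (pathways with PDS), `records` (pathway, pds, gene, drug,
#'   interaction_type rows behind each recommendation), `drugs` (retained,
#'   conflict-free, sorted), `excluded` (pathway, pds, reason), `conflicts`
#'   (dropped drugs and the pair that triggered each drop).
#' @export
recommend_drugs <- function(profile, prioritization, ddi = NULL,
                            pds_threshold = 0.45) {
  sel <- select_patient_pathways(profile, pds_threshold = pds_threshold)
  selected <- sel$selected
  excluded <- sel$excluded

  # match on pathway id, or on pathway name when profiles use display names
  match_col <- if (nrow(prioritization) > 0 &&
    any(selected$pathway %in% prioritization$pathway)) {
    "pathway"
  } else {
    "pathway_name"
  }
  hom <- prioritization[prioritization$effect == "Homeostasis", , drop = FALSE]

  records <- list()
  no_target <- character(0)
  for (i in seq_len(nrow(selected))) {
    pw <- selected$pathway[i]
    hit <- hom[!is.na(hom[[match_col]]) & hom[[match_col]] == pw, , drop = FALSE]
    if (nrow(hit) == 0) {
      no_target <- c(no_target, pw)
      next
    }
    records[[pw]] <- data.frame(
      pathway = pw, pds = selected$pds[i],
      gene = hit$gene, drug = hit$drug,
      interaction_type = hit$interaction_type,
      stringsAsFactors = FALSE
    )
  }
  records <- if (length(records)) do.call(rbind, records) else {
    data.frame(
      pathway = character(0), pds = numeric(0), gene = character(0),
      drug = character(0), interaction_type = character(0)
    )
  }
  rownames(records) <- NULL
  records <- records[order(-records$pds, records$pathway, records$gene, records$drug), ,
    drop = FALSE
  ]

  if (length(no_target)) {
    excluded <- rbind(excluded, data.frame(
      pathway = no_target,
      pds = selected$pds[match(no_target, selected$pathway)],
      reason = "no_druggable_target", stringsAsFactors = FALSE
    ))
  }
  selected <- selected[!selected$pathway %in% no_target, , drop = FALSE]

  # best supporting PDS per drug drives conflict resolution
  support <- if (nrow(records)) {
    tapply(records$pds, records$drug, max)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  screened <- check_drug_pair_interactions(
    sort(unique(records$drug)), ddi, support
  )

  structure(
    list(
      patient_id = profile$patient_id,
      selected = selected,
      records = records[records$drug %in% screened$retained, , drop = FALSE],
      drugs = screened$retained,
      excluded = excluded[order(excluded$pathway), , drop = FALSE],
      conflicts = screened$report
    ),
    class = "TherapyRecommendation"
  )
}

#' Screen a drug set for pairwise interactions
#'
#' Tests every unordered pair against the interaction table; on a conflict
#' the drug whose best supporting pathway has the lower PDS is dropped
#' (ties drop the lexicographically later name), greedily until the
#' retained set is conflict-free.  Idempotent.
#'
#' @param drugs character vector of candidate drugs.
#' @param ddi data.frame with `drug_a`, `drug_b` (unordered pairs) or
#'   `NULL`.
#' @param support named numeric vector, drug -> best supporting PDS
#'   (missing drugs default to 0).
#' @return list with `retained` (sorted character vector) and `report`
#'   (data.frame `dropped`, `kept`, `drug_a`, `drug_b`).
#' @export
check_drug_pair_interactions <- function(drugs, ddi, support = NULL) {
  report <- data.frame(
    dropped = character(0), kept = character(0),
    drug_a = character(0), drug_b = character(0), stringsAsFactors = FALSE
  )
  drugs <- sort(unique(drugs))
  if (is.null(ddi) || nrow(ddi) == 0 || length(drugs) < 2) {
    return(list(retained = drugs, report = report))
  }
  pair_key <- function(a, b) {
    paste(pmin(toupper(trimws(a)), toupper(trimws(b))),
      pmax(toupper(trimws(a)), toupper(trimws(b))),
      sep = "\r"
    )
  }
  bad <- pair_key(ddi$drug_a, ddi$drug_b)
  supp <- function(d) if (!is.null(support) && d %in% names(support)) support[[d]] else 0

  retained <- drugs
  repeat {
    if (length(retained) < 2) break
    pairs <- utils::combn(retained, 2)
    conflict <- which(pair_key(pairs[1, ], pairs[2, ]) %in% bad)
    if (length(conflict) == 0) break
    a <- pairs[1, conflict[1]]
    b <- pairs[2, conflict[1]]
    sa <- supp(a); sb <- supp(b)
    drop_drug <- if (sa < sb) a else if (sb < sa) b else max(a, b)
    keep_drug <- setdiff(c(a, b), drop_drug)
    retained <- setdiff(retained, drop_drug)
    report <- rbind(report, data.frame(
      dropped = drop_drug, kept = keep_drug, drug_a = a, drug_b = b,
      stringsAsFactors = FALSE
    ))
  }
  list(retained = retained, report = report)
}

#' @export
print.TherapyRecommendation <- function(x, ...) {
  cat(sprintf("Therapy recommendation for %s\n", x$patient_id))
  if (nrow(x$selected)) {
    cat("Selected pathways:\n")
    for (i in seq_len(nrow(x$selected))) {
      cat(sprintf("  %-40s PDS %.3f\n", x$selected$pathway[i], x$selected$pds[i]))
    }
  }
  cat(sprintf(
    "Recommended drugs: %s\n",
    if (length(x$drugs)) paste(x$drugs, collapse = ", ") else "(none)"
  ))
  if (nrow(x$excluded)) {
    cat("Excluded pathways:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf(
        "  %-40s PDS %.3f (%s)\n",
        x$excluded$pathway[i], x$excluded$pds[i], x$excluded$reason[i]
      ))
    }
  }
  if (nrow(x$conflicts)) {
    cat("Conflicts resolved:\n")
    for (i in seq_len(nrow(x$conflicts))) {
      cat(sprintf(
        "  dropped %s (conflicts with %s)\n",
        x$conflicts$dropped[i], x$conflicts$kept[i]
      ))
    }
  }
  invisible(x)
}
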