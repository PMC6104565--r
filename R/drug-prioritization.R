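# Joining consensus deregulated pathways with druggable differentially
# expressed targets; classifying each drug's expected effect on its target;
# counting targets; building the pathway-target-drug network.

INHIBITORY_TYPES <- c(
  "inhibitor", "antagonist", "blocker", "suppressor", "negative modulator"
)
ACTIVATING_TYPES <- c(
  "inducer", "activator", "agonist", "positive modulator", "stimulator"
)

#' Classify a drug-target interaction type as inhibitory or activating
#'
#' Case-insensitive vocabulary lookup after whitespace trimming; interaction
#' types outside both vocabularies (e.g. "binder") map to `other`.
#'
#' @param interaction_type character vector of interaction type strings.
#' @return character vector over `{inhibitory, activating, other}`.
#' @export
classify_interaction_direction <- function(interaction_type) {
  x <- tolower(trimws(as.character(interaction_type)))
  out <- rep("other", length(x))
  out[x %in% INHIBITORY_TYPES] <- "inhibitory"
  out[x %in% ACTIVATING_TYPES] <- "activating"
  out
}

#' Classify a drug's expected effect on a deregulated target
#'
#' A drug pushing a differentially expressed target back toward its control
#' level (inhibiting an overexpressed gene, activating an underexpressed
#' one) is `Homeostasis`; pushing it further away is `Anti-homeostasis`;
#' directionless interaction types are `Undetermined`.
#'
#' @param de_status `up` or `down` (non-significant genes never reach this
#'   call).
#' @param direction `inhibitory`, `activating`, or `other` (from
#'   [classify_interaction_direction()]).
#' @return character vector over
#'   `{Homeostasis, Anti-homeostasis, Undetermined}`.
#' @export
classify_effect <- function(de_status, direction) {
  if (!all(de_status %in% c("up", "down"))) {
    stop("de_status must be 'up' or 'down'", call. = FALSE)
  }
  ifelse(direction == "other", "Undetermined",
    ifelse(
      (de_status == "up") == (direction == "inhibitory"),
      "Homeostasis", "Anti-homeostasis"
    )
  )
}

#' Build the prioritization table (pathway x target x drug)
#'
#' One record per (pathway, gene, drug) triple where the pathway is in the
#' consensus set, the gene is a differentially expressed member of that
#' pathway, and the drug interacts with the gene.  Drug/gene name matching
#' is exact, case-insensitive, after whitespace trimming.
#'
#' @param consensus character vector of consensus pathway ids for one
#'   subtype (or the data.frame returned by
#'   [cross_dataset_intersection()]).
#' @param de DE results data.frame (from [two_group_de()]); only genes with
#'   status `up`/`down` are joined.
#' @param drugs drug-gene interaction data.frame (`drug`, `gene`,
#'   `interaction_type`, `source`).
#' @param collection a `GeneSetCollection`.
#' @param subtype subtype label stamped on the records.
#' @return data.frame with columns `subtype`, `pathway`, `pathway_name`,
#'   `gene`, `drug`, `interaction_type`, `source`, `log2FC`, `status`,
#'   `effect`, ordered by (pathway, gene, drug).
#' @export
build_prioritization_table <- function(consensus, de, drugs, collection,
                                       subtype = NA_character_) {
  if (is.data.frame(consensus)) consensus <- consensus$pathway
  empty <- data.frame(
    subtype = character(0), pathway = character(0), pathway_name = character(0),
    gene = character(0), drug = character(0), interaction_type = character(0),
    source = character(0), log2FC = numeric(0), status = character(0),
    effect = character(0), stringsAsFactors = FALSE
  )
  sig <- de[de$status %in% c("up", "down"), , drop = FALSE]
  if (length(consensus) == 0 || nrow(sig) == 0 || nrow(drugs) == 0) return(empty)

  key <- function(x) toupper(trimws(x))
  sig_key <- key(sig$gene)
  drug_gene_key <- key(drugs$gene)

  rows <- list()
  for (pw in consensus) {
    members <- collection$members[[pw]]
    if (is.null(members)) next
    hit <- sig[sig_key %in% key(members), , drop = FALSE]
    if (nrow(hit) == 0) next
    for (i in seq_len(nrow(hit))) {
      dr <- drugs[drug_gene_key == key(hit$gene[i]), , drop = FALSE]
      if (nrow(dr) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = subtype, pathway = pw,
        pathway_name = collection$names[match(pw, collection$ids)],
        gene = hit$gene[i], drug = dr$drug,
        interaction_type = dr$interaction_type, source = dr$source,
        log2FC = hit$log2FC[i], status = hit$status[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab[c("pathway", "gene", "drug", "interaction_type")]), ]
  tab$effect <- classify_effect(
    tab$status, classify_interaction_direction(tab$interaction_type)
  )
  tab <- tab[order(tab$pathway, tab$gene, tab$drug), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Count druggable differentially expressed targets per (subtype, pathway)
#'
#' @param table a prioritization table from [build_prioritization_table()].
#' @return data.frame with `subtype`, `pathway`, `n_targets` (distinct
#'   genes), `n_drugs` (distinct drugs).
#' @export
count_targets_by_subtype <- function(table) {
  if (nrow(table) == 0) {
    return(data.frame(
      subtype = character(0), pathway = character(0),
      n_targets = integer(0), n_drugs = integer(0), stringsAsFactors = FALSE
    ))
  }
  grp <- paste(table$subtype, table$pathway, sep = "\r")
  keys <- unique(table[c("subtype", "pathway")])
  keys <- keys[order(keys$subtype, keys$pathway), , drop = FALSE]
  key_id <- paste(keys$subtype, keys$pathway, sep = "\r")
  keys$n_targets <- vapply(
    key_id, function(k) length(unique(table$gene[grp == k])), integer(1)
  )
  keys$n_drugs <- vapply(
    key_id, function(k) length(unique(table$drug[grp == k])), integer(1)
  )
  rownames(keys) <- NULL
  keys
}

#' Build the tripartite pathway-target-drug network
#'
#' Nodes are typed by layer (`pathway`, `gene`, `drug`); edges connect
#' pathways to their member targets and targets to their drugs, never
#' pathways to drugs.  By default only records with the `Homeostasis`
#' effect are kept.
#'
#' @param table a prioritization table.
#' @param effect_filter keep only records with this effect (`NULL` keeps
#'   all).
#' @return an [igraph::graph] with vertex attribute `type` and edge
#'   attributes `interaction_type` and `effect` on gene-drug edges.
#' @export
build_multipartite_network <- function(table, effect_filter = "Homeostasis") {
  if (!is.null(effect_filter)) {
    table <- table[table$effect %in% effect_filter, , drop = FALSE]
  }
  if (nrow(table) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  pg <- unique(table[c("pathway", "gene")])
  gd <- unique(table[c("gene", "drug", "interaction_type", "effect")])
  edges <- rbind(
    data.frame(
      from = pg$pathway, to = pg$gene,
      interaction_type = NA_character_, effect = NA_character_,
      stringsAsFactors = FALSE
    ),
    data.frame(
      from = gd$gene, to = gd$drug,
      interaction_type = gd$interaction_type, effect = gd$effect,
      stringsAsFactors = FALSE
    )
  )
  vertices <- rbind(
    data.frame(name = unique(table$pathway), type = "pathway"),
    data.frame(name = unique(table$gene), type = "gene"),
    data.frame(name = unique(table$drug), type = "drug")
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}
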