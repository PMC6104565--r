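# Drug-target direction and effect classification, the prioritization
# join, target counting, and the tripartite network.

test_that("interaction vocabularies classify case-insensitively", {
  expect_equal(classify_interaction_direction("Inhibitor"), "inhibitory")
  expect_equal(classify_interaction_direction("Inducer"), "activating")
  expect_equal(classify_interaction_direction("binder"), "other")
  expect_equal(
    classify_interaction_direction(c(" ANTAGONIST ", "agonist", "mystery")),
    c("inhibitory", "activating", "other")
  )
})

test_that("effect classification follows the homeostasis truth table", {
  expect_equal(classify_effect("up", "inhibitory"), "Homeostasis")
  expect_equal(classify_effect("down", "activating"), "Homeostasis")
  expect_equal(classify_effect("up", "activating"), "Anti-homeostasis")
  expect_equal(classify_effect("down", "inhibitory"), "Anti-homeostasis")
  expect_equal(classify_effect("up", "other"), "Undetermined")
  expect_equal(classify_effect("down", "other"), "Undetermined")
  expect_error(classify_effect("not_significant", "inhibitory"), "up")

  # flipping both status and direction preserves the effect label
  for (st in c("up", "down")) {
    for (dir in c("inhibitory", "activating")) {
      flip_st <- if (st == "up") "down" else "up"
      flip_dir <- if (dir == "inhibitory") "activating" else "inhibitory"
      expect_equal(classify_effect(st, dir), classify_effect(flip_st, flip_dir))
    }
  }
})

test_that("the published nine-row example classifies 9/9", {
  rows <- drug_effect_example_rows()
  got <- classify_effect(
    ifelse(rows$logFC > 0, "up", "down"),
    classify_interaction_direction(rows$interaction_type)
  )
  expect_identical(got, rows$expected_effect)
})

example_join_inputs <- function() {
  rows <- drug_effect_example_rows()
  members <- split(rows$gene, rows$pathway)
  members <- lapply(members, unique)
  collection <- gene_set_collection(
    names(members),
    c("Purine metabolism", "Steroid biosynthesis", "Lysine degradation")[
      match(names(members), c("hsa00230", "hsa00100", "hsa00310"))
    ],
    members
  )
  de <- data.frame(
    gene = unique(rows$gene),
    log2FC = rows$logFC[match(unique(rows$gene), rows$gene)],
    adj_pvalue = 1e-6
  )
  de$status <- ifelse(de$log2FC > 0, "up", "down")
  drugs <- rows[c("drug", "gene", "interaction_type", "source")]
  list(collection = collection, de = de, drugs = drugs, rows = rows)
}

test_that("the prioritization join reproduces the example effect column", {
  inp <- example_join_inputs()
  tab <- build_prioritization_table(
    consensus = inp$collection$ids, de = inp$de, drugs = inp$drugs,
    collection = inp$collection, subtype = "Basal"
  )
  expect_equal(nrow(tab), 9L)
  key <- paste(tab$gene, tab$drug)
  want <- inp$rows$expected_effect[match(key, paste(inp$rows$gene, inp$rows$drug))]
  expect_identical(tab$effect, want)
  # every homeostasis record pairs (+, inhibitory) or (-, activating)
  hom <- tab[tab$effect == "Homeostasis", ]
  dir <- classify_interaction_direction(hom$interaction_type)
  expect_true(all(
    (hom$log2FC > 0 & dir == "inhibitory") |
      (hom$log2FC < 0 & dir == "activating")
  ))
})

test_that("the join is empty without significant genes or consensus", {
  inp <- example_join_inputs()
  de_ns <- inp$de
  de_ns$status <- "not_significant"
  expect_equal(nrow(build_prioritization_table(
    inp$collection$ids, de_ns, inp$drugs, inp$collection
  )), 0L)
  expect_equal(nrow(build_prioritization_table(
    character(0), inp$de, inp$drugs, inp$collection
  )), 0L)
})

test_that("the join matches a brute-force triple loop on random instances", {
  set.seed(16)
  genes <- sprintf("g%02d", 1:30)
  members <- list(
    pA = genes[1:10], pB = genes[8:20], pC = genes[15:30]
  )
  collection <- gene_set_collection(names(members), names(members), members)
  de <- data.frame(
    gene = genes, log2FC = rnorm(30, 0, 2), adj_pvalue = runif(30)
  )
  de <- apply_de_thresholds(de, lfc_cut = 1, adjp_cut = 0.5)
  drugs <- generate_drug_table(genes, fraction_druggable = 0.6, seed = 3)$interactions
  consensus <- c("pA", "pC")
  tab <- build_prioritization_table(consensus, de, drugs, collection)

  count <- 0
  for (pw in consensus) {
    for (g in members[[pw]]) {
      st <- de$status[de$gene == g]
      if (!st %in% c("up", "down")) next
      count <- count + sum(drugs$gene == g)
    }
  }
  expect_equal(nrow(tab), count)
  # shrinking the consensus never adds records
  tab_small <- build_prioritization_table("pA", de, drugs, collection)
  expect_true(nrow(tab_small) <= nrow(tab))
  expect_true(all(
    paste(tab_small$pathway, tab_small$gene, tab_small$drug) %in%
      paste(tab$pathway, tab$gene, tab$drug)
  ))
})

test_that("target counts are distinct-gene counts, drugs counted apart", {
  empty <- count_targets_by_subtype(
    build_prioritization_table(character(0), data.frame(
      gene = character(0), log2FC = numeric(0), adj_pvalue = numeric(0),
      status = character(0)
    ), data.frame(), gene_set_collection("p", "p", list(p = "g")))
  )
  expect_equal(nrow(empty), 0L)

  tab <- data.frame(
    subtype = "Basal", pathway = "pA", pathway_name = "pA",
    gene = "g1", drug = c("d1", "d2", "d3"),
    interaction_type = "inhibitor", source = "x",
    log2FC = 2, status = "up", effect = "Homeostasis"
  )
  cnt <- count_targets_by_subtype(tab)
  expect_equal(cnt$n_targets, 1L)
  expect_equal(cnt$n_drugs, 3L)

  # brute-force distinct counting on a random table
  set.seed(17)
  tab2 <- data.frame(
    subtype = sample(c("Basal", "Her2"), 60, TRUE),
    pathway = sample(c("pA", "pB"), 60, TRUE),
    gene = sample(sprintf("g%d", 1:8), 60, TRUE),
    drug = sample(sprintf("d%d", 1:10), 60, TRUE)
  )
  cnt2 <- count_targets_by_subtype(tab2)
  for (i in seq_len(nrow(cnt2))) {
    sel <- tab2$subtype == cnt2$subtype[i] & tab2$pathway == cnt2$pathway[i]
    expect_equal(cnt2$n_targets[i], length(unique(tab2$gene[sel])))
    expect_equal(cnt2$n_drugs[i], length(unique(tab2$drug[sel])))
  }
})

test_that("the tripartite network has typed layers and no pathway-drug edges", {
  inp <- example_join_inputs()
  tab <- build_prioritization_table(
    inp$collection$ids, inp$de, inp$drugs, inp$collection,
    subtype = "Basal"
  )
  g <- build_multipartite_network(tab, effect_filter = "Homeostasis")
  # steroid-biosynthesis block: 1 pathway + SQLE + 4 drugs; purine block:
  # 1 pathway + HPRT1 + AZATHIOPRINE
  sub <- igraph::induced_subgraph(
    g, igraph::V(g)[igraph::components(g)$membership ==
      igraph::components(g)$membership[["hsa00100"]]]
  )
  types <- igraph::V(sub)$type
  expect_equal(sum(types == "pathway"), 1L)
  expect_equal(sum(types == "gene"), 1L)
  expect_equal(sum(types == "drug"), 4L)
  expect_equal(igraph::ecount(sub), 5L)

  el <- igraph::as_data_frame(g, what = "edges")
  vt <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_false(any(vt[el$from] == "pathway" & vt[el$to] == "drug"))
  expect_false(any(vt[el$from] == "drug" & vt[el$to] == "pathway"))

  expect_equal(igraph::vcount(build_multipartite_network(tab[0, ])), 0L)
})
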