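# Fixtures built in code: small simulation configs, the published worked
# examples (drug-effect table and two basal patient profiles), and a helper
# that runs the PDS -> PDSz -> median -> top-k chain for one cohort.

# One-subtype planted configuration used across recovery tests.
planted_config <- function(seed, n_tumor = 60, n_control = 30,
                           effect = 1.5, n_genes = 1000, n_pathways = 20,
                           genes_per_pathway = 50,
                           planted_ids = c("pw01", "pw02", "pw03")) {
  sim_config(
    n_genes = n_genes, n_pathways = n_pathways,
    genes_per_pathway = genes_per_pathway,
    subtypes = "Basal", n_tumor = n_tumor, n_control = n_control,
    planted = if (length(planted_ids)) {
      data.frame(subtype = "Basal", pathway = planted_ids, effect = effect)
    } else {
      NULL
    },
    seed = seed
  )
}

# Four-subtype configuration with distinct planted pathways per subtype,
# used for profile-clustering checks.
four_subtype_config <- function(seed, effect = 2, n_per_subtype = 15,
                                n_control = 15) {
  planted <- data.frame(
    subtype = rep(c("Basal", "Her2", "LumA", "LumB"), times = c(3, 3, 2, 2)),
    pathway = sprintf("pw%02d", 1:10),
    effect = effect
  )
  sim_config(
    n_genes = 400, n_pathways = 20, genes_per_pathway = 20,
    subtypes = c("Basal", "Her2", "LumA", "LumB"),
    n_tumor = n_per_subtype, n_control = n_control,
    planted = planted, seed = seed
  )
}

# PDS -> PDSz -> median over tumors -> top-k, for one cohort and subtype.
rank_cohort <- function(cohort, collection, subtype, k,
                        params = pds_params()) {
  run <- subset_cohort(cohort, subtype)
  pm <- compute_pds_matrix(run, collection, params)
  pz <- suppressWarnings(pdsz_transform(pm))
  med <- median_pdsz_by_subtype(pz, run$annotation, subtype)
  list(
    pds = pm, median = med,
    top = suppressWarnings(top_k_pathways(med, k))
  )
}

# Published worked example: nine drug-target rows with known logFC sign,
# interaction type, and expected effect label.
drug_effect_example_rows <- function() {
  data.frame(
    pathway = c(rep("hsa00230", 4), "hsa00310", rep("hsa00100", 4)),
    pathway_name = c(
      rep("Purine metabolism", 4), "Lysine degradation",
      rep("Steroid biosynthesis", 4)
    ),
    gene = c("HPRT1", "PNP", "PDE2A", "PDE8B", "ALDH2", rep("SQLE", 4)),
    drug = c(
      "AZATHIOPRINE", "CLADRINE", "TOFISPAM", "KETOTIFEN", "DISULFIRAM",
      "NAFTIFINE", "TERBINAFINE", "BUTENAFINE", "ELLAGIC ACID"
    ),
    interaction_type = c("Inhibitor", "Inducer", rep("Inhibitor", 7)),
    source = "DrugBank",
    logFC = c(1.623, 1.628, -3.962, -2.509, -2.363, rep(2.703, 4)),
    expected_effect = c(
      "Homeostasis", "Anti-homeostasis", "Anti-homeostasis",
      "Anti-homeostasis", "Anti-homeostasis",
      rep("Homeostasis", 4)
    ),
    stringsAsFactors = FALSE
  )
}

# Published basal patient profiles (pathway PDS tables).
patient_example_profile <- function(id = c("MB.3058", "MB.5387")) {
  id <- match.arg(id)
  pathways <- c(
    "Steroid biosynthesis", "Pyrimidine metabolism",
    "Sphingolipid metabolism", "Olfactory transduction", "Apoptosis",
    "Oocyte meiosis", "Cell cycle", "Neurotrophin signaling pathway",
    "ErbB signaling pathway", "Drug metabolism - other enzymes"
  )
  pds <- if (id == "MB.3058") {
    c(0.937, 0.466, 0.628, 0.736, 0.398, 0.406, 0.328, 0.765, 0.783, 0.712)
  } else {
    c(0.597, 0.605, 0.590, 0.500, 0.712, 1.000, 0.718, 0.839, 0.616, 0.846)
  }
  patient_profile(id, pathways, pds, subtype = "Basal")
}

# Homeostasis prioritization records matching the patient profiles' targets.
patient_example_prioritization <- function() {
  data.frame(
    subtype = "Basal",
    pathway = c(
      "Steroid biosynthesis", "Pyrimidine metabolism", "Pyrimidine metabolism",
      "Sphingolipid metabolism", "Apoptosis", "Apoptosis",
      "Oocyte meiosis", "Oocyte meiosis", "Cell cycle"
    ),
    pathway_name = c(
      "Steroid biosynthesis", "Pyrimidine metabolism", "Pyrimidine metabolism",
      "Sphingolipid metabolism", "Apoptosis", "Apoptosis",
      "Oocyte meiosis", "Oocyte meiosis", "Cell cycle"
    ),
    gene = c(
      "SQLE", "TYMS", "TYMS", "SPHK1", "BIRC5", "BIRC5",
      "AURKA", "CDK1", "CDK1"
    ),
    drug = c(
      "TERBINAFINE", "PEMETREXED", "CAPECITABINE", "SK1-I",
      "ALVOCIDIB", "PACLITAXEL", "ALISERTIB", "DINACICLIB", "DINACICLIB"
    ),
    interaction_type = "inhibitor",
    source = "DrugBank",
    log2FC = 2, status = "up", effect = "Homeostasis",
    stringsAsFactors = FALSE
  )
}
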