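# PDS engine: control anchoring, normalisation contract, degeneracy
# handling, orientation invariance, and planted-signal response.

make_tiny_cohort <- function(mat, subtypes) {
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  expression_cohort(
    mat,
    data.frame(
      sample_id = colnames(mat), subtype = subtypes, dataset = "ds",
      stringsAsFactors = FALSE
    )
  )
}

test_that("standardisation centers and scales genes by the control group", {
  set.seed(1)
  mat <- matrix(rnorm(10 * 20, 5, 2), 10, 20)
  co <- make_tiny_cohort(mat, rep(c("Basal", "Control"), each = 10))
  std <- standardize_to_controls(co, rownames(co$matrix))
  expect_true(std$ok)
  ctrl <- co$annotation$sample_id[co$annotation$subtype == "Control"]
  expect_lt(max(abs(rowMeans(std$z[, ctrl]))), 1e-12)
  expect_lt(max(abs(apply(std$z[, ctrl], 1, sd) - 1)), 1e-12)
})

test_that("constant-in-controls genes are dropped, tiny sets degenerate", {
  set.seed(2)
  mat <- matrix(rnorm(5 * 12), 5, 12)
  mat[2, 7:12] <- 3 # constant across controls
  co <- make_tiny_cohort(mat, rep(c("Basal", "Control"), each = 6))
  std <- standardize_to_controls(co, rownames(co$matrix))
  expect_true(std$ok)
  expect_true("g02" %in% std$dropped)
  expect_false("g02" %in% rownames(std$z))

  deg <- standardize_to_controls(co, c("g01", "g02", "g99"))
  expect_s3_class(deg, "degenerate_pathway")
  expect_false(deg$ok)
  expect_match(deg$reason, "fewer than 3")

  expect_error(
    standardize_to_controls(make_tiny_cohort(mat, c(rep("Basal", 10), "Control", "Control")), rownames(mat)),
    "control"
  )
})

test_that("a pathway with identical samples is reported degenerate", {
  mat <- matrix(5, 6, 12) + rep(rnorm(6), 12) # genes differ, samples equal
  co <- make_tiny_cohort(mat, rep(c("Basal", "Control"), each = 6))
  res <- pathway_pds(co, rownames(co$matrix))
  expect_s3_class(res, "degenerate_pathway") # zero control SD drops all genes
  expect_false(res$ok)
})

test_that("PDS lies in [0, 1] with the extremes attained", {
  sim <- generate_cohort(planted_config(
    seed = 9, n_tumor = 20, n_control = 10,
    n_genes = 100, n_pathways = 4, genes_per_pathway = 25,
    planted_ids = "pw01", effect = 1.5
  ))
  pm <- compute_pds_matrix(sim$cohort, sim$collection)
  expect_true(all(pm$scores >= 0 & pm$scores <= 1))
  expect_true(all(abs(apply(pm$scores, 1, max) - 1) < 1e-12))
  expect_true(all(abs(apply(pm$scores, 1, min)) < 1e-12))
  expect_false(any(pm$meta$degenerate))
})

test_that("PDS is invariant to negating the standardised data", {
  sim <- generate_cohort(planted_config(
    seed = 10, n_tumor = 15, n_control = 10,
    n_genes = 60, n_pathways = 2, genes_per_pathway = 30,
    planted_ids = "pw01", effect = 1.5
  ))
  genes <- sim$collection$members$pw01
  res <- pathway_pds(sim$cohort, genes)

  flipped <- sim$cohort
  ctrl <- flipped$annotation$sample_id[flipped$annotation$subtype == "Control"]
  m <- flipped$matrix[genes, ]
  mu <- rowMeans(m[, ctrl])
  flipped$matrix[genes, ] <- 2 * mu - m # reflect around the control mean
  res_f <- pathway_pds(flipped, genes)

  expect_equal(unname(sort(res$pds)), unname(sort(res_f$pds)), tolerance = 1e-6)
})

test_that("collinear standardised data give min-max normalised positions", {
  # samples strung exactly along one direction in gene space: PDS must equal
  # the normalised coordinate along that line
  n <- 30
  pos <- seq(0, 3, length.out = n)
  dir <- c(1, 2, -1, 0.5) / sqrt(sum(c(1, 2, -1, 0.5)^2))
  mat <- t(outer(pos, dir)) # 4 genes x 30 samples
  # controls occupy the low end with spread so control SD > 0
  subtypes <- c(rep("Control", 10), rep("Basal", 20))
  co <- make_tiny_cohort(mat, subtypes)
  res <- pathway_pds(co, rownames(co$matrix), pds_params(span = 0.5))
  expect_false(res$meta$degenerate)
  expected <- (pos - min(pos)) / (max(pos) - min(pos))
  expect_lt(max(abs(res$pds - expected)), 1e-6)
})

test_that("tumors score above controls on planted pathways", {
  gaps <- vapply(1:10, function(s) {
    sim <- generate_cohort(planted_config(
      seed = s, n_tumor = 60, n_control = 30,
      n_genes = 100, n_pathways = 2, genes_per_pathway = 50,
      planted_ids = "pw01", effect = 1.5
    ))
    res <- pathway_pds(sim$cohort, sim$collection$members$pw01)
    ann <- sim$cohort$annotation
    mean(res$pds[ann$sample_id[ann$subtype == "Basal"]]) -
      mean(res$pds[ann$sample_id[ann$subtype == "Control"]])
  }, numeric(1))
  expect_gte(sum(gaps > 0), 10 * 19 / 20)
})

test_that("tumor-control PDS gap responds monotonically to effect size", {
  mean_gap <- function(effect) {
    mean(vapply(1:5, function(s) {
      sim <- generate_cohort(planted_config(
        seed = s, n_tumor = 30, n_control = 15,
        n_genes = 100, n_pathways = 2, genes_per_pathway = 50,
        planted_ids = "pw01", effect = effect
      ))
      res <- pathway_pds(sim$cohort, sim$collection$members$pw01)
      ann <- sim$cohort$annotation
      mean(res$pds[ann$sample_id[ann$subtype == "Basal"]]) -
        mean(res$pds[ann$sample_id[ann$subtype == "Control"]])
    }, numeric(1)))
  }
  gaps <- vapply(c(0, 0.5, 1.5, 3), mean_gap, numeric(1))
  expect_true(all(diff(gaps) > -0.02)) # non-decreasing up to seed noise
})

test_that("the PDS matrix preserves pathway order and independence", {
  sim <- generate_cohort(planted_config(
    seed = 21, n_tumor = 15, n_control = 10,
    n_genes = 120, n_pathways = 4, genes_per_pathway = 30,
    planted_ids = "pw01", effect = 1.5
  ))
  pm <- compute_pds_matrix(sim$cohort, sim$collection)
  expect_identical(rownames(pm$scores), sim$collection$ids)

  single <- gene_set_collection(
    "pw02", "Pathway 02",
    sim$collection$members["pw02"]
  )
  pm1 <- compute_pds_matrix(sim$cohort, single)
  expect_equal(nrow(pm1$scores), 1L)
  expect_equal(pm1$scores["pw02", ], pm$scores["pw02", ])

  shuffled <- gene_set_collection(
    rev(sim$collection$ids), rev(sim$collection$names),
    sim$collection$members[rev(sim$collection$ids)]
  )
  pm2 <- compute_pds_matrix(sim$cohort, shuffled)
  expect_equal(pm2$scores[sim$collection$ids, ], pm$scores)
  expect_error(
    compute_pds_matrix(sim$cohort, gene_set_collection(character(0), character(0), list())),
    "empty"
  )
})

test_that("planted pathways carry the largest tumor-control PDS gaps", {
  wins <- vapply(1:6, function(s) {
    sim <- generate_cohort(planted_config(
      seed = s + 100, n_tumor = 30, n_control = 15,
      n_genes = 500, n_pathways = 10, genes_per_pathway = 50,
      planted_ids = c("pw01", "pw02", "pw03"), effect = 1.5
    ))
    pm <- compute_pds_matrix(sim$cohort, sim$collection)
    ann <- sim$cohort$annotation
    gap <- rowMeans(pm$scores[, ann$sample_id[ann$subtype == "Basal"]]) -
      rowMeans(pm$scores[, ann$sample_id[ann$subtype == "Control"]])
    all(c("pw01", "pw02", "pw03") %in%
      names(sort(gap, decreasing = TRUE))[1:3])
  }, logical(1))
  expect_gte(sum(wins), 4) # majority of seeds
})
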