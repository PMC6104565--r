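# Readers/writers for the pipeline's file formats: GMT gene sets,
# tab-separated expression/annotation/drug tables, PDS matrices with JSON
# metadata sidecars.

#' Gene-set collection container
#'
#' @param ids unique pathway ids.
#' @param names display names (defaults to ids).
#' @param members named list (by id) of member gene id vectors, non-empty.
#' @return object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(ids, names = ids, members) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("pathway ids must be unique", call. = FALSE)
  if (!all(ids %in% base::names(members))) {
    stop("every id needs a member list", call. = FALSE)
  }
  members <- members[ids]
  if (any(lengths(members) == 0)) stop("member lists must be non-empty", call. = FALSE)
  structure(
    list(ids = ids, names = as.character(names), members = members),
    class = "GeneSetCollection"
  )
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf(
    "GeneSetCollection: %d gene sets, %d-%d members\n",
    length(x$ids), min(lengths(x$members)), max(lengths(x$members))
  ))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a line are collapsed with a warning.
#'
#' @param path file path.
#' @return a `GeneSetCollection` (GMT name as id, description as display
#'   name).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file", call. = FALSE)
  ids <- character(length(lines))
  nms <- character(length(lines))
  members <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i), call. = FALSE)
    }
    ids[i] <- f[1]
    nms[i] <- f[2]
    mem <- f[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members collapsed", i, f[1]),
        call. = FALSE
      )
      mem <- unique(mem)
    }
    members[[i]] <- mem
  }
  names(members) <- ids
  gene_set_collection(ids, nms, members)
}

#' Write a `GeneSetCollection` to GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$ids), function(i) {
    paste(c(
      collection$ids[i], collection$names[i],
      collection$members[[collection$ids[i]]]
    ), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression cohort as TSV (matrix + annotation)
#'
#' @param cohort an `ExpressionCohort`.
#' @param matrix_path,annotation_path output paths.
#' @export
write_expression_tsv <- function(cohort, matrix_path, annotation_path) {
  df <- data.frame(gene = rownames(cohort$matrix), cohort$matrix,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, matrix_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(cohort$annotation, annotation_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(matrix_path)
}

#' Read an expression cohort from TSV
#'
#' @param matrix_path genes-by-samples TSV; first column gene ids, header
#'   row sample ids.
#' @param annotation_path sample annotation TSV (`sample_id`, `subtype`,
#'   `dataset`).
#' @param platform platform tag to record.
#' @return an `ExpressionCohort`.
#' @export
read_expression_tsv <- function(matrix_path, annotation_path,
                                platform = "microarray") {
  df <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  expression_cohort(m, ann, platform)
}

#' Read a drug-gene interaction TSV
#'
#' Expected header: `drug`, `gene`, `interaction_type`, `source`.
#'
#' @param path file path.
#' @return data.frame with those columns, fully duplicated rows removed.
#' @export
read_drug_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "gene", "interaction_type", "source")
  if (!all(need %in% names(tb))) {
    stop(sprintf(
      "drug table must have columns: %s", paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  tb$interaction_type[is.na(tb$interaction_type) | tb$interaction_type == ""] <- "n/a"
  unique(tb[need])
}

#' Read a drug-drug interaction TSV
#'
#' Expected columns `drug_a`, `drug_b` (a `note` column is kept when
#' present); self-pairs are dropped.
#'
#' @param path file path.
#' @return data.frame of unordered pairs.
#' @export
read_ddi_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug_a", "drug_b") %in% names(tb))) {
    stop("ddi table must have columns drug_a, drug_b", call. = FALSE)
  }
  if (!"note" %in% names(tb)) tb$note <- NA_character_
  tb <- tb[tb$drug_a != tb$drug_b, c("drug_a", "drug_b", "note"), drop = FALSE]
  unique(tb)
}

#' Write a PDS matrix as TSV with a JSON metadata sidecar
#'
#' @param pds a `PDSMatrix`.
#' @param path output TSV path; the sidecar is written to
#'   `paste0(path, ".meta.json")`.
#' @export
write_pds_matrix <- function(pds, path) {
  df <- data.frame(pathway = rownames(pds$scores), pds$scores,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(
      meta = pds$meta,
      skipped = lapply(pds$skipped, function(s) {
        list(reason = s$reason, dropped = s$dropped)
      })
    ),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
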