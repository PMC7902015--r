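#' Construct and validate an expression matrix
#'
#' An expression matrix is an ordinary numeric matrix of log2 intensities
#' with genes in rows and samples in columns. The constructor enforces the
#' container invariants (finite values, unique non-empty row and column
#' identifiers) and returns a plain matrix so that downstream code composes
#' with base R; all package entry points re-validate with
#' `validate_expression_matrix()`.
#'
#' @param values numeric matrix (genes x samples) of log2 intensities.
#' @param gene_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return a validated numeric matrix with gene ids as rownames and sample
#'   ids as colnames.
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    validation_error("`values` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    validation_error("expression matrix needs gene and sample identifiers")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    validation_error("identifier lengths do not match matrix dimensions")
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
}

#' @rdname expression_matrix
#' @param x object to validate as an expression matrix.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    validation_error("expression matrix must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    validation_error("expression matrix is empty")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    validation_error("expression matrix must carry gene and sample ids")
  if (anyDuplicated(rownames(x)))
    format_error(sprintf("duplicate gene ids: %s",
      paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  if (anyDuplicated(colnames(x)))
    format_error(sprintf("duplicate sample ids: %s",
      paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  if (!all(is.finite(x)))
    validation_error("expression matrix contains non-finite values")
  x
}

#' Construct sample annotations for a subset study
#'
#' One record per array: which donor it came from, the clinical group
#' (`HC` healthy control or `SLE` lupus patient) and the sorted B cell
#' subset (`naive`, `memory`, `plasmablast`).
#'
#' @param sample_id,donor_id,group,subset character vectors of equal length,
#'   or a single data.frame with these columns passed as `sample_id`.
#' @return a `data.frame` with validated columns.
#' @export
sample_annotation <- function(sample_id, donor_id = NULL, group = NULL,
                              subset = NULL) {
  if (is.data.frame(sample_id)) {
    df <- sample_id
    need <- c("sample_id", "donor_id", "group", "subset")
    miss <- setdiff(need, names(df))
    if (length(miss))
      format_error(sprintf("metadata missing column(s): %s",
                           paste(miss, collapse = ", ")))
    df <- df[, need]
  } else {
    df <- data.frame(sample_id = as.character(sample_id),
                     donor_id = as.character(donor_id),
                     group = as.character(group),
                     subset = as.character(subset),
                     stringsAsFactors = FALSE)
  }
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id))
    consistency_error("duplicate sample_id in annotation")
  bad_g <- setdiff(unique(df$group), c("HC", "SLE"))
  if (length(bad_g))
    validation_error(sprintf("unknown group(s): %s",
                             paste(bad_g, collapse = ", ")))
  bad_s <- setdiff(unique(df$subset), c("naive", "memory", "plasmablast"))
  if (length(bad_s))
    validation_error(sprintf("unknown subset(s): %s",
                             paste(bad_s, collapse = ", ")))
  key <- paste(df$donor_id, df$subset)
  if (anyDuplicated(key))
    consistency_error("duplicate (donor_id, subset) pair in annotation")
  rownames(df) <- NULL
  df
}

# Every matrix sample must have exactly one annotation record.
check_annotation <- function(matrix, annotation) {
  missing <- setdiff(colnames(matrix), annotation$sample_id)
  if (length(missing))
    consistency_error(sprintf(
      "sample(s) in matrix but not in metadata: %s",
      paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' Construct a gene set
#'
#' A named collection of gene identifiers (one GMT line). Duplicate members
#' are collapsed with a warning; an empty member list is an error.
#'
#' @param name,description set name and free-text description.
#' @param members character vector of gene identifiers (opaque,
#'   case-sensitive strings; no identifier mapping is attempted).
#' @return an object of class `gene_set` (a list with `name`,
#'   `description`, `members`).
#' @export
gene_set <- function(name, description = "", members) {
  members <- as.character(members)
  if (length(members) == 0L)
    validation_error(sprintf("gene set '%s' has no members", name))
  if (anyDuplicated(members)) {
    warning(sprintf("gene set '%s': %d duplicate member(s) collapsed",
                    name, sum(duplicated(members))), call. = FALSE)
    members <- unique(members)
  }
  structure(list(name = as.character(name),
                 description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes): %s%s\n", x$name, length(x$members),
              paste(head(x$members, 5L), collapse = ", "),
              if (length(x$members) > 5L) ", ..." else ""))
  invisible(x)
}

#' Construct a flow-cytometry event table
#'
#' Per-cell records with a dye-dilution channel (`dye_intensity`, linear
#' fluorescence, strictly positive) and apoptosis channels (`annexin`,
#' `viability`, linear). Simulated tables may carry `true_generation`.
#'
#' @param events data.frame with columns `cell_id`, `dye_intensity`,
#'   `annexin`, `viability` and optionally `true_generation`.
#' @return the validated data.frame.
#' @export
flow_event_table <- function(events) {
  need <- c("cell_id", "dye_intensity", "annexin", "viability")
  miss <- setdiff(need, names(events))
  if (length(miss))
    format_error(sprintf("flow event table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  for (col in c("dye_intensity", "annexin", "viability")) {
    v <- events[[col]]
    if (!is.numeric(v) || !all(is.finite(v)))
      validation_error(sprintf("channel '%s' must be finite numeric", col))
  }
  if (any(events$dye_intensity <= 0))
    validation_error("dye_intensity must be strictly positive")
  if ("true_generation" %in% names(events)) {
    tg <- events$true_generation
    if (any(tg < 0) || any(tg != round(tg)))
      validation_error("true_generation must be integers >= 0")
  }
  events
}
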