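# Readers/writers. One tabular dialect throughout: TSV, UTF-8, '.' decimal,
# no quoting -- values round-trip bit-exactly and files diff cleanly.
# Flow event tables are CSV to match cytometry-export convention.

#' Read an expression matrix and its sample metadata
#'
#' The matrix file is a TSV whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns are samples, in file order.
#' The metadata TSV must contain columns `sample_id`, `donor_id`, `group`,
#' `subset` and must cover every sample present in the matrix.
#'
#' @param path path to the expression TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @return a list with elements `matrix` (see [expression_matrix()]) and
#'   `annotation` (see [sample_annotation()]).
#' @export
read_expression <- function(path, metadata_path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  if (!file.exists(metadata_path))
    io_error(sprintf("no such file: %s", metadata_path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    format_error("expression file must have a gene_id column plus samples")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    format_error(sprintf("duplicate sample ids in header: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    quote = "", comment.char = "", colClasses = "character",
                    stringsAsFactors = FALSE)
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    format_error(sprintf("duplicate gene ids: %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad))
      parse_error(sprintf(
        "non-numeric value '%s' at row %d (gene %s), column '%s'",
        col[bad[1]], bad[1], gene_ids[bad[1]], sample_ids[j]))
    vals[, j] <- num
  }
  mat <- expression_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids)
  meta <- read.table(metadata_path, sep = "\t", header = TRUE,
                     check.names = FALSE, quote = "", comment.char = "",
                     colClasses = "character", stringsAsFactors = FALSE)
  ann <- sample_annotation(meta)
  check_annotation(mat, ann)
  list(matrix = mat, annotation = ann)
}

#' Write an expression matrix (and optionally metadata) to TSV
#'
#' Values are written with 17 significant digits so that
#' `read_expression()` recovers them bit-for-bit.
#'
#' @param matrix validated expression matrix.
#' @param path output TSV path.
#' @param annotation optional sample annotation data.frame.
#' @param metadata_path output path for the annotation (required when
#'   `annotation` is given).
#' @return invisibly, `path`.
#' @export
write_expression <- function(matrix, path, annotation = NULL,
                             metadata_path = NULL) {
  matrix <- validate_expression_matrix(matrix)
  lines <- c(
    paste(c("gene_id", colnames(matrix)), collapse = "\t"),
    vapply(seq_len(nrow(matrix)), function(i) {
      paste(c(rownames(matrix)[i], sprintf("%.17g", matrix[i, ])),
            collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  if (!is.null(annotation)) {
    if (is.null(metadata_path))
      validation_error("metadata_path required when annotation is given")
    write_table(annotation, metadata_path)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name`, `description`, then members. Duplicate members within a line are
#' collapsed with a warning; a line with fewer than three fields is a
#' format error; empty lines are skipped.
#'
#' @param path path to the GMT file.
#' @return a named list of [gene_set()] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      format_error(sprintf(
        "GMT line %d has %d field(s); need name, description, >=1 member",
        i, length(fields)))
    gene_set(fields[1], fields[2], fields[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a list of [gene_set()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Numeric columns are written with 9 significant digits. Because the
#' dialect forbids quoting, a character value containing a tab (or newline)
#' is an error rather than being silently mangled.
#'
#' @param records data.frame with a fixed schema.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) validation_error("`records` must be a data.frame")
  out <- records
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.numeric(col) && !is.integer(col)) {
      out[[nm]] <- sprintf("%.9g", col)
    } else {
      col <- as.character(col)
      if (any(grepl("[\t\n]", col)))
        format_error(sprintf(
          "column '%s' contains a tab or newline; unquoted TSV cannot hold it",
          nm))
      out[[nm]] <- col
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) io_error(sprintf("cannot write '%s': %s",
                                    path, conditionMessage(ok)))
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path TSV path.
#' @return a data.frame with columns typed by [read.table()]'s conversion.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             quote = "", comment.char = "", stringsAsFactors = FALSE)
}

#' Read or write a flow event table (CSV)
#'
#' Columns: `cell_id`, `dye_intensity`, `annexin`, `viability` and, for
#' simulated data, `true_generation`.
#'
#' @param path CSV path.
#' @return [read_flow_events()]: a validated event data.frame.
#' @export
read_flow_events <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  flow_event_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_flow_events
#' @param events event data.frame (see [flow_event_table()]).
#' @export
write_flow_events <- function(events, path) {
  events <- flow_event_table(events)
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
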