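# Gene-set signature score: each gene row is scaled so its maximum across
# samples is exactly 1, then per-sample values are summed. Scores are
# computed on linear-scale intensities (2^log2) by default: a ratio-to-max
# is only meaningful on a nonnegative scale, and log2 values would make
# the score offset-sensitive. The maximum is taken across ALL samples
# jointly so every subset/group cell is scored on one comparable axis.

#' Row-max normalization of a gene set's expression
#'
#' @param matrix expression matrix.
#' @param gene_set a [gene_set()]; members absent from the matrix are
#'   dropped (reported in attribute `missing_members`), never imputed.
#' @param scale `"linear"` (default): treat the matrix as log2 and map to
#'   linear via `2^x` before normalizing; `"asis"`: use values unchanged
#'   (they must then be positive where it matters).
#' @return matrix restricted to the usable set members, each row divided
#'   by its maximum across all samples (so every row max is exactly 1).
#' @export
max_normalize_rows <- function(matrix, gene_set, scale = c("linear", "asis")) {
  matrix <- validate_expression_matrix(matrix)
  scale <- match.arg(scale)
  if (!inherits(gene_set, "gene_set"))
    validation_error("`gene_set` must be a gene_set object")
  present <- intersect(gene_set$members, rownames(matrix))
  if (length(present) == 0L)
    validation_error(sprintf("no member of set '%s' is present in the matrix",
                             gene_set$name))
  x <- matrix[present, , drop = FALSE]
  if (scale == "linear") x <- 2^x
  row_max <- apply(x, 1L, max)
  if (any(row_max <= 0))
    validation_error(sprintf(
      "gene row maximum <= 0 for: %s (cannot ratio-to-max)",
      paste(present[row_max <= 0], collapse = ", ")))
  out <- x / row_max
  attr(out, "missing_members") <- setdiff(gene_set$members, present)
  out
}

#' Gene-set signature score
#'
#' Per sample, the sum over the set's usable genes of the row-max
#' normalized value; each gene contributes at most 1, so
#' `0 <= score <= n_genes_used`.
#'
#' @inheritParams max_normalize_rows
#' @param annotation optional sample annotation to join onto the result.
#' @return data.frame with columns `set_name`, `sample_id`, `score`,
#'   `n_genes_used` (plus annotation columns when given); missing members
#'   are carried in attribute `missing_members`, the scale choice in
#'   attribute `scale`.
#' @export
signature_score <- function(matrix, gene_set, annotation = NULL,
                            scale = c("linear", "asis")) {
  scale <- match.arg(scale)
  norm <- max_normalize_rows(matrix, gene_set, scale = scale)
  scores <- colSums(norm)
  out <- data.frame(set_name = gene_set$name,
                    sample_id = names(scores),
                    score = as.numeric(scores),
                    n_genes_used = nrow(norm),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotation)) {
    check_annotation(matrix, annotation)
    out <- merge(out, annotation, by = "sample_id", sort = FALSE)
    out <- out[match(colnames(matrix), out$sample_id), ]
    rownames(out) <- NULL
  }
  attr(out, "missing_members") <- attr(norm, "missing_members")
  attr(out, "scale") <- scale
  out
}

#' Min-normalized display values for a single gene
#'
#' Divides each sample's (linear-scale) value by the minimum across all
#' samples, so the minimum maps to exactly 1 — the display convention for
#' single-gene panels.
#'
#' @param matrix expression matrix.
#' @param gene_id gene to normalize.
#' @param scale as in [max_normalize_rows()].
#' @return named numeric vector of normalized values (minimum exactly 1).
#' @export
min_normalize_gene <- function(matrix, gene_id, scale = c("linear", "asis")) {
  matrix <- validate_expression_matrix(matrix)
  scale <- match.arg(scale)
  if (!gene_id %in% rownames(matrix))
    validation_error(sprintf("gene '%s' absent from matrix", gene_id))
  v <- matrix[gene_id, ]
  if (scale == "linear") v <- 2^v
  m <- min(v)
  if (m <= 0)
    validation_error(sprintf("gene '%s' has minimum <= 0; cannot ratio-to-min",
                             gene_id))
  v / m
}

#' Compare signature scores across the subset-by-group design
#'
#' One-way ANOVA across the six (subset, group) cells followed by Tukey
#' HSD adjusted pairwise p-values, plus per-subset two-sample (pooled
#' variance) t contrasts of SLE vs HC — the standard battery for a scored
#' signature panel.
#'
#' @param scores output of [signature_score()] (one set).
#' @param annotation sample annotation (ignored if `scores` already
#'   carries `subset`/`group` columns).
#' @return list with `anova` (data.frame: `F`, `p`), `tukey` (data.frame:
#'   `comparison`, `diff`, `p_adj`), and `subset_contrasts` (data.frame:
#'   `subset`, `mean_HC`, `mean_SLE`, `t`, `p`).
#' @export
compare_scores <- function(scores, annotation = NULL) {
  if (!all(c("subset", "group") %in% names(scores))) {
    if (is.null(annotation))
      validation_error("scores lack subset/group; supply `annotation`")
    scores <- merge(scores, annotation, by = "sample_id", sort = FALSE)
  }
  cell <- interaction(scores$subset, scores$group, drop = TRUE)
  expected <- as.vector(outer(unique(scores$subset), unique(scores$group),
                              paste, sep = "."))
  counts <- table(factor(as.character(cell), levels = expected))
  if (any(counts < 2L))
    validation_error(sprintf("design cell(s) with < 2 samples: %s",
      paste(names(counts)[counts < 2L], collapse = ", ")))
  if (var(scores$score) == 0) {
    anova_row <- data.frame(F = 0, p = 1)
    tk <- data.frame(comparison = character(0), diff = numeric(0),
                     p_adj = numeric(0))
  } else {
    fit <- aov(score ~ cell, data = data.frame(score = scores$score,
                                               cell = cell))
    tab <- summary(fit)[[1]]
    anova_row <- data.frame(F = tab[1, "F value"], p = tab[1, "Pr(>F)"])
    th <- TukeyHSD(fit)$cell
    tk <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                     p_adj = th[, "p adj"], stringsAsFactors = FALSE,
                     row.names = NULL)
  }
  contrasts <- do.call(rbind, lapply(unique(scores$subset), function(sb) {
    hc <- scores$score[scores$subset == sb & scores$group == "HC"]
    sle <- scores$score[scores$subset == sb & scores$group == "SLE"]
    if (sd(c(hc, sle)) == 0) {
      t_stat <- 0; p <- 1
    } else {
      tt <- t.test(sle, hc, var.equal = TRUE)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(subset = sb, mean_HC = mean(hc), mean_SLE = mean(sle),
               t = t_stat, p = p, stringsAsFactors = FALSE)
  }))
  list(anova = anova_row, tukey = tk, subset_contrasts = contrasts)
}
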