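# "Similar entities" screen: correlation of candidate genes' expression
# profiles to an anchor gene (FOXM1 in the motivating study), selected
# within a closed correlation band.

#' Correlation of candidate profiles to an anchor gene
#'
#' Pearson (default) or Spearman correlation between the anchor's
#' per-sample expression vector and each candidate's, across all samples.
#' A zero-variance anchor or candidate has no defined correlation; such
#' candidates are returned as `NA` with a warning.
#'
#' @param matrix expression matrix.
#' @param anchor_gene anchor gene id (must be present).
#' @param candidates candidate gene ids (must be present).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return named numeric vector of correlations (possibly `NA`).
#' @export
profile_correlation <- function(matrix, anchor_gene, candidates,
                                method = c("pearson", "spearman")) {
  matrix <- validate_expression_matrix(matrix)
  method <- match.arg(method)
  if (!anchor_gene %in% rownames(matrix))
    validation_error(sprintf("anchor gene '%s' absent from matrix",
                             anchor_gene))
  absent <- setdiff(candidates, rownames(matrix))
  if (length(absent))
    validation_error(sprintf("candidate(s) absent from matrix: %s",
                             paste(head(absent, 5L), collapse = ", ")))
  if (ncol(matrix) < 3L)
    validation_error("need >= 3 samples to correlate profiles")
  anchor_vec <- matrix[anchor_gene, ]
  cand <- matrix[candidates, , drop = FALSE]
  undef <- apply(cand, 1L, sd) == 0
  if (sd(anchor_vec) == 0) {
    warning(sprintf("anchor '%s' has zero variance; all correlations undefined",
                    anchor_gene), call. = FALSE)
    return(setNames(rep(NA_real_, length(candidates)), candidates))
  }
  r <- setNames(rep(NA_real_, length(candidates)), candidates)
  if (any(!undef))
    r[!undef] <- as.vector(cor(anchor_vec, t(cand[!undef, , drop = FALSE]),
                               method = method))
  if (any(undef))
    warning(sprintf("zero-variance candidate(s), correlation undefined: %s",
                    paste(candidates[undef], collapse = ", ")), call. = FALSE)
  r
}

#' Find genes with expression profiles similar to an anchor
#'
#' Selects candidates whose correlation with the anchor lies in the
#' closed band `[r_min, r_max]` (the band is closed at both ends, so a
#' candidate at exactly `r_min` is selected). Candidates with undefined
#' correlation are excluded. The anchor itself, if among the candidates,
#' is always selected (its correlation is 1).
#'
#' @inheritParams profile_correlation
#' @param r_min,r_max selection band (defaults 0.6 and 1.0).
#' @return an object of class `similarity_result`: list with
#'   `anchor_gene`, `r` (sorted by descending correlation), `selected`,
#'   `r_min`, `r_max`, `method`.
#' @export
find_similar_entities <- function(matrix, anchor_gene, candidates,
                                  r_min = 0.6, r_max = 1.0,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(candidates) == 0L)
    validation_error("`candidates` must be non-empty")
  if (!is.numeric(r_min) || !is.numeric(r_max) || r_min > r_max ||
      r_min < -1 || r_max > 1)
    validation_error("need -1 <= r_min <= r_max <= 1")
  r <- profile_correlation(matrix, anchor_gene, candidates, method = method)
  r <- r[order(-r, names(r), na.last = TRUE)]
  defined <- !is.na(r)
  selected <- names(r)[defined & r >= r_min & r <= r_max]
  structure(list(anchor_gene = anchor_gene, r = r, selected = selected,
                 r_min = r_min, r_max = r_max, method = method),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result> anchor %s: %d/%d candidates in [%g, %g] (%s)\n",
    x$anchor_gene, length(x$selected), length(x$r), x$r_min, x$r_max,
    x$method))
  invisible(x)
}
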