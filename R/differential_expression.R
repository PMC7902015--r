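# Empirical-Bayes moderated t-test and DEG calling.
#
# The per-gene variance model is the classical hierarchical one:
#   s_g^2 | sigma_g^2 ~ sigma_g^2 * chisq(df_g) / df_g
#   1 / sigma_g^2     ~ chisq(d0) / (d0 * s0^2)
# so the posterior variance is the precision-weighted mean
#   s~_g^2 = (d0 s0^2 + df_g s_g^2) / (d0 + df_g)
# and the moderated t statistic follows Student-t with df_g + d0 degrees
# of freedom. (d0, s0^2) are estimated by moment matching on log s_g^2.

#' Percentile-shift normalization
#'
#' Per sample, subtracts that sample's given percentile of log2 values so
#' the percentile becomes 0 — the standard per-array location shift for
#' one-color data. The percentile uses linear interpolation between order
#' statistics (`stats::quantile()` type 7).
#'
#' @param matrix expression matrix (log2).
#' @param percentile percentile in (0, 100], default 75.
#' @return the shifted matrix; gene order unchanged.
#' @export
normalize_percentile <- function(matrix, percentile = 75) {
  matrix <- validate_expression_matrix(matrix)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 100)
    validation_error("percentile must be a single value in (0, 100]")
  shifts <- apply(matrix, 2L, quantile, probs = percentile / 100,
                  names = FALSE, type = 7)
  sweep(matrix, 2L, shifts, `-`)
}

#' Signed linear fold change between groups within a subset
#'
#' The linear ratio `r = 2^(mean_b - mean_a)` is reported with the signed
#' convention used by array software: `r` itself when `r >= 1`, and
#' `-1/r` when `r < 1`, so down-regulation appears as a negative magnitude
#' (e.g. a halving is -2, never 0.5) and `|fc| >= 1` always.
#'
#' @param matrix expression matrix (log2).
#' @param annotation sample annotation.
#' @param subset which B cell subset to compare within.
#' @param group_a,group_b reference and test group labels.
#' @return named numeric vector of signed fold changes per gene.
#' @export
fold_change <- function(matrix, annotation, subset,
                        group_a = "HC", group_b = "SLE") {
  st <- group_stats(matrix, annotation, subset, group_a, group_b,
                    min_n = 1L)
  signed_fc(st$mean_b - st$mean_a)
}

signed_fc <- function(log2_diff) {
  r <- 2^log2_diff
  ifelse(r >= 1, r, -1 / r)
}

# Column selection + per-gene first/second moments for a two-group
# comparison within one subset.
group_stats <- function(matrix, annotation, subset, group_a, group_b,
                        min_n = 2L) {
  matrix <- validate_expression_matrix(matrix)
  check_annotation(matrix, annotation)
  if (!subset %in% annotation$subset)
    validation_error(sprintf("subset '%s' absent from annotation", subset))
  ann <- annotation[annotation$sample_id %in% colnames(matrix), ]
  sel_a <- ann$sample_id[ann$subset == subset & ann$group == group_a]
  sel_b <- ann$sample_id[ann$subset == subset & ann$group == group_b]
  if (length(sel_a) < min_n || length(sel_b) < min_n)
    validation_error(sprintf(
      "need >= %d samples per group in subset '%s' (found %d %s, %d %s)",
      min_n, subset, length(sel_a), group_a, length(sel_b), group_b))
  xa <- matrix[, sel_a, drop = FALSE]
  xb <- matrix[, sel_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  list(mean_a = ma, mean_b = mb, n_a = length(sel_a), n_b = length(sel_b),
       ss_a = rowSums((xa - ma)^2), ss_b = rowSums((xb - mb)^2))
}

#' Variance prior for the moderated t-test
#'
#' @param d0 prior degrees of freedom (> 0, or `Inf` for full shrinkage to
#'   `s0_sq`; 0 is admitted as the degenerate no-moderation limit in which
#'   the test reduces to the classical pooled t-test).
#' @param s0_sq prior variance scale (> 0).
#' @return an object of class `variance_prior`.
#' @export
variance_prior <- function(d0, s0_sq) {
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0)
    validation_error("d0 must be a single value >= 0 (possibly Inf)")
  if (!is.numeric(s0_sq) || length(s0_sq) != 1L || !is.finite(s0_sq) ||
      s0_sq <= 0)
    validation_error("s0_sq must be a single finite value > 0")
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("<variance_prior> d0 = %g, s0_sq = %g\n", x$d0, x$s0_sq))
  invisible(x)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by monotone Newton iteration on
#' `1/trigamma` (which is nearly linear in `x`), to relative tolerance
#' 1e-8.
#'
#' @param y positive value(s).
#' @return `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0)
      validation_error("trigamma_inverse needs y > 0")
    if (yi > 1e7) return(1 / sqrt(yi))        # trigamma(x) ~ 1/x^2 as x -> 0
    if (yi < 1e-6) return(1 / yi)             # trigamma(x) ~ 1/x as x -> Inf
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Fit the empirical-Bayes variance prior
#'
#' Matches the mean and variance of `log(s_sq)` to their theoretical
#' digamma/trigamma expressions under the scaled-inverse-chi-square prior:
#' with `z_g = log(s_g^2)` and `e_g = z_g - digamma(df_g/2) + log(df_g/2)`,
#' `E[e] = log(s0^2) - digamma(d0/2) + log(d0/2)` and
#' `Var[z] = trigamma(df_g/2) + trigamma(d0/2)`. The trigamma term in
#' `d0` is recovered by [trigamma_inverse()]. If the empirical excess
#' variance of `log(s_sq)` is <= 0 the prior is degenerate:
#' `d0 = Inf` with a geometric-mean-based scale.
#'
#' @param s_sq per-gene residual variances.
#' @param df_resid per-gene residual degrees of freedom (recycled).
#' @return a [variance_prior()].
#' @export
fit_variance_prior <- function(s_sq, df_resid) {
  df_resid <- rep_len(df_resid, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & df_resid >= 1
  if (sum(ok) < 10L)
    validation_error(paste("fewer than 10 genes with positive variance and",
      "df >= 1; too few to fit a prior - use an ordinary t-test"))
  s_sq <- s_sq[ok]; df <- df_resid[ok]
  z <- log(s_sq)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  excess <- var(z) - mean(trigamma(df / 2))
  if (excess <= 0)   # no excess dispersion: full shrinkage to the
    return(variance_prior(Inf, exp(mean(z))))  # geometric-mean scale
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  variance_prior(d0, s0_sq)
}

#' Empirical-Bayes moderated t-test for one subset contrast
#'
#' Per gene: pooled two-sample variance `s_g^2` with
#' `df_g = n_a + n_b - 2`; posterior variance
#' `s~^2 = (d0 s0^2 + df_g s_g^2) / (d0 + df_g)`;
#' `t = (mean_b - mean_a) / (s~ sqrt(1/n_a + 1/n_b))`; two-sided p from
#' Student-t with `df_g + d0` degrees of freedom (Normal reference when
#' `d0 = Inf`).
#'
#' @param matrix expression matrix (log2, normalized).
#' @param annotation sample annotation.
#' @param subset B cell subset to test within.
#' @param prior `"fit"` (default) to estimate the prior from this
#'   contrast's variances via [fit_variance_prior()], or a
#'   [variance_prior()] (use `variance_prior(0, 1)` for the classical
#'   pooled t-test).
#' @param group_a,group_b reference and test group labels.
#' @return a data.frame (one row per gene) with columns `gene_id`,
#'   `mean_a`, `mean_b`, `s_sq`, `df_resid`, `fc_signed`, `t_mod`,
#'   `df_total`, `p`; the fitted prior and group labels are attached as
#'   attributes `prior`, `group_a`, `group_b`.
#' @export
moderated_t_test <- function(matrix, annotation, subset, prior = "fit",
                             group_a = "HC", group_b = "SLE") {
  st <- group_stats(matrix, annotation, subset, group_a, group_b,
                    min_n = 2L)
  df_resid <- st$n_a + st$n_b - 2
  s_sq <- (st$ss_a + st$ss_b) / df_resid
  if (identical(prior, "fit"))
    prior <- fit_variance_prior(s_sq, df_resid)
  if (!inherits(prior, "variance_prior"))
    validation_error("`prior` must be \"fit\" or a variance_prior object")
  if (is.infinite(prior$d0)) {
    s_post <- rep_len(prior$s0_sq, length(s_sq))
    df_total <- Inf
  } else {
    s_post <- (prior$d0 * prior$s0_sq + df_resid * s_sq) /
      (prior$d0 + df_resid)
    df_total <- df_resid + prior$d0
  }
  diff <- st$mean_b - st$mean_a
  se <- sqrt(s_post * (1 / st$n_a + 1 / st$n_b))
  t_mod <- ifelse(se > 0, diff / se,
                  ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * pt(-abs(t_mod), df = df_total)
  res <- data.frame(gene_id = rownames(matrix),
                    mean_a = st$mean_a, mean_b = st$mean_b,
                    s_sq = s_sq, df_resid = df_resid,
                    fc_signed = signed_fc(diff),
                    t_mod = t_mod, df_total = df_total, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "prior") <- prior
  attr(res, "group_a") <- group_a
  attr(res, "group_b") <- group_b
  res
}

#' Call differentially expressed genes
#'
#' A gene is `up` when `p < p_thresh` and its signed fold change is
#' `>= fc_thresh` (more than `fc_thresh`-fold up-regulated), `down` when
#' `p < p_thresh` and the signed fold change is `<= -fc_thresh`
#' (less than `1/fc_thresh`-fold, i.e. halved at the default), `ns`
#' otherwise. No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param stats output of [moderated_t_test()].
#' @param p_thresh p-value threshold (default 0.05).
#' @param fc_thresh fold-change magnitude threshold (default 2).
#' @param adjust p-value adjustment method (see [stats::p.adjust()];
#'   default `"none"`).
#' @return an object of class `deg_result`: list with `stats` (the input
#'   plus a `call` column), `up_genes`, `down_genes`, and the thresholds.
#' @export
call_degs <- function(stats, p_thresh = 0.05, fc_thresh = 2,
                      adjust = "none") {
  if (!is.data.frame(stats) || nrow(stats) == 0L)
    validation_error("`stats` must be a non-empty GeneStat data.frame")
  if (p_thresh <= 0 || p_thresh > 1)
    validation_error("p_thresh must be in (0, 1]")
  if (fc_thresh < 1) validation_error("fc_thresh must be >= 1")
  p_use <- p.adjust(stats$p, method = adjust)
  up <- p_use < p_thresh & stats$fc_signed >= fc_thresh
  down <- p_use < p_thresh & stats$fc_signed <= -fc_thresh
  stats$call <- ifelse(up, "up", ifelse(down, "down", "ns"))
  structure(list(stats = stats,
                 up_genes = stats$gene_id[up],
                 down_genes = stats$gene_id[down],
                 p_thresh = p_thresh, fc_thresh = fc_thresh,
                 adjust = adjust),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf(
    "<deg_result> %d genes tested: %d up, %d down (p < %g, |fc| >= %g%s)\n",
    nrow(x$stats), length(x$up_genes), length(x$down_genes),
    x$p_thresh, x$fc_thresh,
    if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted") else ""))
  invisible(x)
}

#' One-sided Fisher's exact over-representation test
#'
#' For each gene set, tests whether `deg_genes` over-represents the set
#' within `background` using a one-sided (enrichment) Fisher's exact test
#' on the 2x2 table (in-DEG & in-set, in-DEG & not-set, set-only,
#' remainder). Sets with no member in the background are skipped with a
#' warning.
#'
#' @param deg_genes character vector of differentially expressed genes;
#'   must be a subset of `background`.
#' @param background character vector of all tested genes.
#' @param sets list of [gene_set()] objects.
#' @param p_thresh significance threshold (default 0.01).
#' @return data.frame with columns `set_name`, `set_size_bg`, `n_deg`,
#'   `overlap`, `p`, `neg_log10_p`, `significant`; the test direction is
#'   recorded in attribute `alternative`.
#' @export
ora_fisher <- function(deg_genes, background, sets, p_thresh = 0.01) {
  deg_genes <- unique(as.character(deg_genes))
  background <- unique(as.character(background))
  extra <- setdiff(deg_genes, background)
  if (length(extra))
    validation_error(sprintf(
      "deg_genes not contained in background (e.g. %s)",
      paste(head(extra, 3L), collapse = ", ")))
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, background)
    if (length(members) == 0L) {
      warning(sprintf("set '%s' has no member in the background; skipped",
                      s$name), call. = FALSE)
      return(NULL)
    }
    a <- length(intersect(deg_genes, members))
    b <- length(deg_genes) - a
    c_ <- length(members) - a
    d <- length(background) - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(set_name = s$name, set_size_bg = length(members),
               n_deg = length(deg_genes), overlap = a, p = p,
               neg_log10_p = -log10(p), significant = p < p_thresh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(0), set_size_bg = integer(0),
                      n_deg = integer(0), overlap = integer(0),
                      p = numeric(0), neg_log10_p = numeric(0),
                      significant = logical(0))
  rownames(out) <- NULL
  attr(out, "alternative") <- "greater"
  attr(out, "p_thresh") <- p_thresh
  out
}
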