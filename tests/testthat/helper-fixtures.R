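# Fixtures are built in code at test time; nothing is read from disk
# except files the tests themselves write to tempdir().

# A tiny fully-crossed study: n_per_group donors x 2 groups x subsets,
# gene values drawn N(0, 1) under the given seed.
make_toy_study <- function(n_genes = 20, n_per_group = 4,
                           subsets = c("naive", "memory", "plasmablast"),
                           seed = 42) {
  donors <- c(paste0("HC", seq_len(n_per_group)),
              paste0("SLE", seq_len(n_per_group)))
  groups <- rep(c("HC", "SLE"), each = n_per_group)
  ann <- expand.grid(donor_id = donors, subset = subsets,
                     stringsAsFactors = FALSE)
  ann$group <- groups[match(ann$donor_id, donors)]
  ann$sample_id <- paste(ann$donor_id, ann$subset, sep = "_")
  ann <- sample_annotation(ann[, c("sample_id", "donor_id", "group",
                                   "subset")])
  set.seed(seed)
  m <- matrix(rnorm(n_genes * nrow(ann)), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              ann$sample_id))
  list(matrix = expression_matrix(m), annotation = ann)
}

# Annotation for a single-subset two-group comparison; sample ids are
# s1..s(n_a+n_b) with the first n_a samples in HC.
make_two_group_annotation <- function(n_a, n_b, subset = "naive") {
  n <- n_a + n_b
  sample_annotation(data.frame(
    sample_id = paste0("s", seq_len(n)),
    donor_id = paste0("d", seq_len(n)),
    group = rep(c("HC", "SLE"), c(n_a, n_b)),
    subset = subset, stringsAsFactors = FALSE))
}

# Independent series oracle for trigamma: sum_{k>=0} 1/(x+k)^2, truncated
# with an Euler-Maclaurin tail so the value is good to ~1e-13.
trigamma_series <- function(x, K = 20000L) {
  k <- 0:(K - 1L)
  tail_x <- x + K
  sum(1 / (x + k)^2) + 1 / tail_x + 1 / (2 * tail_x^2) + 1 / (6 * tail_x^3)
}

# Brute-force one-sided enrichment p-value by exhaustive enumeration of
# all possible DEG draws of the observed size from the background.
enumerate_enrichment_p <- function(bg_size, set_size, deg_size, overlap) {
  draws <- utils::combn(bg_size, deg_size)
  in_set <- seq_len(set_size)   # wlog the first set_size elements
  hits <- colSums(matrix(draws %in% in_set, nrow = deg_size))
  mean(hits >= overlap)
}
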