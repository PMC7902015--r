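test_that("row-max normalization makes every gene's maximum exactly 1", {
  m <- expression_matrix(matrix(c(2, 4,     # -> 0.5, 1
                                  3, 3),    # constant -> 1, 1
                                nrow = 2, byrow = TRUE,
                                dimnames = list(c("gA", "gB"),
                                                c("s1", "s2"))))
  gs <- gene_set("demo", "", c("gA", "gB"))
  norm <- max_normalize_rows(m, gs, scale = "asis")
  expect_equal(unname(norm["gA", ]), c(0.5, 1), tolerance = 1e-12)
  expect_equal(unname(norm["gB", ]), c(1, 1), tolerance = 1e-12)

  # scale invariance: multiplying a row by c > 0 changes nothing
  m2 <- m; m2["gA", ] <- m2["gA", ] * 7.3
  expect_equal(max_normalize_rows(m2, gs, scale = "asis"), norm,
               ignore_attr = TRUE, tolerance = 1e-12)

  # on the default linear scale the same holds after 2^x mapping
  norm_lin <- max_normalize_rows(m, gs, scale = "linear")
  expect_equal(unname(apply(norm_lin, 1, max)), c(1, 1), tolerance = 1e-12)
})

test_that("signature scores match the hand-summed oracle", {
  # gene1 (1,2,4) -> (0.25, 0.5, 1); gene2 (3,3,1) -> (1, 1, 1/3)
  m <- expression_matrix(matrix(c(1, 2, 4, 3, 3, 1), nrow = 2, byrow = TRUE,
                                dimnames = list(c("g1", "g2"),
                                                c("s1", "s2", "s3"))))
  gs <- gene_set("demo", "", c("g1", "g2"))
  sc <- signature_score(m, gs, scale = "asis")
  expect_equal(sc$score, c(0.25 + 1, 0.5 + 1, 1 + 1 / 3),
               tolerance = 1e-12)
  expect_true(all(sc$n_genes_used == 2))
})

test_that("score bounds and degenerate patterns hold", {
  study <- make_toy_study(n_genes = 30, n_per_group = 2)
  gs <- gene_set("s", "", rownames(study$matrix)[1:10])
  sc <- signature_score(study$matrix, gs)
  expect_true(all(sc$score >= 0 & sc$score <= 10))

  # all samples identical on the set: every score equals the set size
  m <- study$matrix
  m[1:10, ] <- m[1:10, 1]
  expect_equal(signature_score(m, gs)$score, rep(10, ncol(m)),
               tolerance = 1e-12)

  # a sample attaining every row maximum scores the full set size and
  # strictly dominates the rest
  m2 <- study$matrix
  m2[1:10, 1] <- apply(m2[1:10, ], 1, max) + 0.5
  sc2 <- signature_score(m2, gs)
  expect_equal(sc2$score[1], 10, tolerance = 1e-12)
  expect_true(all(sc2$score[-1] < 10))
})

test_that("absent set members are dropped and never change scores", {
  study <- make_toy_study(n_genes = 15, n_per_group = 2)
  gs <- gene_set("s", "", rownames(study$matrix)[1:5])
  gs_extra <- gene_set("s", "", c(gs$members, "NOT_A_GENE"))
  sc <- signature_score(study$matrix, gs)
  sc_extra <- signature_score(study$matrix, gs_extra)
  expect_equal(sc_extra$score, sc$score, tolerance = 1e-15)
  expect_identical(sc_extra$n_genes_used, sc$n_genes_used)
  expect_identical(attr(sc_extra, "missing_members"), "NOT_A_GENE")

  gs_none <- gene_set("s", "", c("NOPE1", "NOPE2"))
  expect_error(signature_score(study$matrix, gs_none),
               class = "bsig_validation_error")
})

test_that("min normalization maps the minimum to exactly 1", {
  m <- expression_matrix(matrix(c(2, 4, 8), 1,
                                dimnames = list("g1", paste0("s", 1:3))))
  expect_equal(unname(min_normalize_gene(m, "g1", scale = "asis")),
               c(1, 2, 4), tolerance = 1e-12)
  # property: the output minimum is exactly 1 for any positive row
  set.seed(3)
  m2 <- expression_matrix(matrix(rnorm(8), 1,
                                 dimnames = list("g", paste0("s", 1:8))))
  expect_equal(min(min_normalize_gene(m2, "g")), 1, tolerance = 1e-15)
  expect_error(min_normalize_gene(m, "absent"),
               class = "bsig_validation_error")
})

test_that("score comparisons run ANOVA, Tukey and subset contrasts", {
  study <- make_toy_study(n_genes = 40, n_per_group = 4, seed = 10)
  gs <- gene_set("s", "", rownames(study$matrix)[1:12])
  sc <- signature_score(study$matrix, gs, annotation = study$annotation)
  cmp <- compare_scores(sc)
  expect_named(cmp, c("anova", "tukey", "subset_contrasts"))
  expect_identical(nrow(cmp$tukey), 15L)
  expect_identical(sort(cmp$subset_contrasts$subset),
                   sort(unique(study$annotation$subset)))
  expect_true(all(cmp$subset_contrasts$p >= 0 &
                    cmp$subset_contrasts$p <= 1))

  # all scores equal -> F = 0, p = 1
  sc0 <- sc; sc0$score <- 5
  cmp0 <- compare_scores(sc0)
  expect_identical(cmp0$anova$F, 0)
  expect_identical(cmp0$anova$p, 1)

  # two cells 10 SDs apart (n = 4) -> Tukey adjusted p < 0.001
  sc1 <- sc
  sc1$score <- rnorm(nrow(sc1), sd = 0.5)
  bump <- sc1$subset == "plasmablast" & sc1$group == "SLE"
  sc1$score[bump] <- sc1$score[bump] + 5
  cmp1 <- compare_scores(sc1)
  pair <- grepl("plasmablast.SLE", cmp1$tukey$comparison)
  expect_true(any(pair))
  expect_true(all(cmp1$tukey$p_adj[pair] < 0.001))

  # permuting samples within a cell leaves every statistic unchanged
  perm <- sc
  i <- which(perm$subset == "naive" & perm$group == "HC")
  perm[i, ] <- perm[rev(i), ]
  cmp_p <- compare_scores(perm)
  expect_equal(cmp_p$anova, cmp$anova, tolerance = 1e-12)
  expect_equal(cmp_p$subset_contrasts, cmp$subset_contrasts,
               tolerance = 1e-12)

  # an empty design cell is refused with its name
  sc_missing <- sc[!(sc$subset == "memory" & sc$group == "SLE"), ]
  err <- expect_error(compare_scores(sc_missing),
                      class = "bsig_validation_error")
  expect_match(conditionMessage(err), "memory")
})

test_that("planted signatures reproduce the subset-restricted pattern", {
  # IFN score up in SLE for all subsets; cell-cycle score up only in
  # plasmablasts — the expected readout of the generator's design
  hits_ifn <- 0; hits_cc <- 0; n_rep <- 10
  for (seed in 1:n_rep) {
    s <- simulate_expression_study(simulation_config(n_genes = 1200,
                                                     seed = seed))
    sets <- truth_gene_sets(s$truth)
    ci <- compare_scores(signature_score(s$matrix, sets$IFN_SIGNATURE,
                                         s$annotation))$subset_contrasts
    cc <- compare_scores(signature_score(s$matrix, sets$CELL_CYCLE,
                                         s$annotation))$subset_contrasts
    hits_ifn <- hits_ifn + all(ci$p < 0.05 & ci$mean_SLE > ci$mean_HC)
    pb <- cc$subset == "plasmablast"
    hits_cc <- hits_cc + (all(cc$p[pb] < 0.05 & cc$mean_SLE[pb] >
                                cc$mean_HC[pb]) && all(cc$p[!pb] >= 0.05))
  }
  expect_gte(hits_ifn / n_rep, 0.9)
  expect_gte(hits_cc / n_rep, 0.8)
})
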