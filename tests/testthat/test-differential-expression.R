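test_that("percentile normalization shifts each sample's percentile to 0", {
  study <- make_toy_study(n_genes = 50, n_per_group = 2)
  norm <- normalize_percentile(study$matrix, 75)
  q <- apply(norm, 2, quantile, probs = 0.75, names = FALSE)
  expect_equal(unname(q), rep(0, ncol(norm)), tolerance = 1e-12)

  # a column whose 75th percentile is already 0 is unchanged
  m2 <- study$matrix
  m2[, 1] <- m2[, 1] - quantile(m2[, 1], 0.75, names = FALSE)
  expect_equal(normalize_percentile(m2, 75)[, 1], m2[, 1],
               tolerance = 1e-12)

  # shift invariance: adding a constant to a column changes nothing
  m3 <- study$matrix
  m3[, 2] <- m3[, 2] + 3.7
  expect_equal(normalize_percentile(m3, 75), norm, tolerance = 1e-12)
})

test_that("the percentile matches a sort-and-interpolate oracle", {
  # 4 values {1,2,3,4}: order statistic position 1 + 0.75*(4-1) = 3.25,
  # so the 75th percentile is x_(3) + 0.25*(x_(4) - x_(3)) = 3.25
  m <- expression_matrix(matrix(c(4, 1, 3, 2), 4, 1,
                                dimnames = list(paste0("g", 1:4), "s1")))
  norm <- normalize_percentile(m, 75)
  expect_equal(unname(norm[, 1]), c(4, 1, 3, 2) - 3.25, tolerance = 1e-12)
})

test_that("signed fold change follows the array-software convention", {
  m <- expression_matrix(matrix(
    c(5, 5, 5, 5, 5, 5,      # equal means -> fc 1
      5, 5, 5, 6, 6, 6,      # +1 log2 -> fc 2
      5, 5, 5, 5 - log2(1.164), 5 - log2(1.164), 5 - log2(1.164)),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("flat", "up2", "dn"), paste0("s", 1:6))))
  ann <- make_two_group_annotation(3, 3)
  fc <- fold_change(m, ann, "naive")
  expect_equal(unname(fc["flat"]), 1, tolerance = 1e-12)
  expect_equal(unname(fc["up2"]), 2, tolerance = 1e-12)
  # r = 1/1.164 maps to -1.164: down-regulation as negative magnitude
  expect_equal(unname(fc["dn"]), -1.164, tolerance = 1e-9)
  expect_error(fold_change(m, ann, "plasmablast"),
               class = "bsig_validation_error")
})

test_that("signed fold change is a magnitude-preserving odd convention", {
  set.seed(7)
  d <- rnorm(200, sd = 2)
  fc <- bsig:::signed_fc(d)
  expect_true(all(abs(fc) >= 1))
  expect_equal(sign(fc[d != 0]), sign(d[d != 0]))
  expect_equal(bsig:::signed_fc(-d), ifelse(fc == 1, 1, -fc),
               tolerance = 1e-12)
})

test_that("trigamma_inverse inverts a series-evaluated trigamma", {
  for (x in c(0.7, 2, 5, 17)) {
    y <- trigamma_series(x)
    expect_equal(trigamma_inverse(y), x, tolerance = 1e-8)
  }
  expect_error(trigamma_inverse(-1), class = "bsig_validation_error")
})

test_that("identical variances collapse the prior to full shrinkage", {
  pr <- fit_variance_prior(rep(0.3, 50), 6)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.3, tolerance = 1e-12)
  expect_error(fit_variance_prior(rep(0.3, 5), 6),
               class = "bsig_validation_error")
})

test_that("the fitted prior recovers simulated hyperparameters", {
  # variances drawn from the stated prior (d0 = 4, s0_sq = 0.05, df = 6);
  # estimates should be within 15% of truth in >= 90% of replicates
  set.seed(123)
  ok <- replicate(30, {
    sigma_sq <- 4 * 0.05 / rchisq(5000, df = 4)
    s_sq <- sigma_sq * rchisq(5000, df = 6) / 6
    pr <- fit_variance_prior(s_sq, 6)
    abs(pr$d0 - 4) / 4 < 0.15 && abs(pr$s0_sq - 0.05) / 0.05 < 0.15
  })
  expect_gte(mean(ok), 0.9)
})

test_that("d0 = 0 reduces the moderated t to the classical pooled t-test", {
  for (i in 1:25) {
    set.seed(i)
    m <- expression_matrix(matrix(rnorm(40 * 8), 40, 8,
      dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:8))))
    ann <- make_two_group_annotation(4, 4)
    st <- moderated_t_test(m, ann, "naive", prior = variance_prior(0, 1))
    ref <- apply(m, 1, function(x) {
      tt <- t.test(x[5:8], x[1:4], var.equal = TRUE)
      c(unname(tt$statistic), tt$p.value)
    })
    expect_equal(st$t_mod, unname(ref[1, ]), tolerance = 1e-10)
    expect_equal(st$p, unname(ref[2, ]), tolerance = 1e-10)
    expect_true(all(st$df_total == 6))
  }
})

test_that("a 2-gene 3v3 instance matches step-by-step arithmetic", {
  vals <- matrix(c(1.0, 1.2, 0.8, 2.1, 2.3, 1.9,
                   5.0, 5.5, 4.5, 5.2, 5.1, 5.3),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
  m <- expression_matrix(vals)
  ann <- make_two_group_annotation(3, 3)
  pr <- variance_prior(d0 = 3, s0_sq = 0.04)
  st <- moderated_t_test(m, ann, "naive", prior = pr)
  # independent arithmetic oracle, spelt out term by term
  for (g in 1:2) {
    xa <- vals[g, 1:3]; xb <- vals[g, 4:6]
    ma <- (xa[1] + xa[2] + xa[3]) / 3
    mb <- (xb[1] + xb[2] + xb[3]) / 3
    ss <- sum((xa - ma)^2) + sum((xb - mb)^2)
    s2 <- ss / 4                               # df = 3 + 3 - 2
    s2_post <- (3 * 0.04 + 4 * s2) / (3 + 4)   # shrinkage
    t_oracle <- (mb - ma) / sqrt(s2_post * (1 / 3 + 1 / 3))
    p_oracle <- 2 * pt(-abs(t_oracle), df = 7)
    expect_equal(st$t_mod[g], unname(t_oracle), tolerance = 1e-12)
    expect_equal(st$p[g], unname(p_oracle), tolerance = 1e-12)
  }
})

test_that("posterior variances always lie between s_sq and s0_sq", {
  # heteroscedastic genes so the fitted prior has finite d0
  s <- simulate_expression_study(simulation_config(
    n_genes = 300, ifn_log2fc = 0, cc_log2fc = 0, foxm1_module_size = 0,
    seed = 8))
  st <- moderated_t_test(s$matrix, s$annotation, "memory")
  pr <- attr(st, "prior")
  expect_true(is.finite(pr$d0))
  s_post <- (pr$d0 * pr$s0_sq + st$df_resid * st$s_sq) /
    (pr$d0 + st$df_resid)
  expect_true(all(s_post >= pmin(st$s_sq, pr$s0_sq) - 1e-12))
  expect_true(all(s_post <= pmax(st$s_sq, pr$s0_sq) + 1e-12))
})

test_that("fitting agrees with an established moderated-t implementation", {
  skip_if_not_installed("limma")
  study <- make_toy_study(n_genes = 500, n_per_group = 4, seed = 21)
  sel <- study$annotation$subset == "plasmablast"
  ann <- study$annotation[sel, ]
  m <- study$matrix[, ann$sample_id]
  st <- moderated_t_test(study$matrix, study$annotation, "plasmablast")
  design <- cbind(1, as.numeric(ann$group == "SLE"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(st, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(st, "prior")$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(st$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(st$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("groups with fewer than 2 samples are refused", {
  set.seed(1)
  ann <- make_two_group_annotation(1, 3)
  m <- expression_matrix(matrix(rnorm(20), 5, 4,
    dimnames = list(paste0("g", 1:5), ann$sample_id)))
  expect_error(moderated_t_test(m, ann, "naive"),
               class = "bsig_validation_error")
})

test_that("DEG calls apply both thresholds and stay monotone", {
  stats <- data.frame(
    gene_id = c("up_hit", "weak_fc", "down_hit", "big_ns"),
    fc_signed = c(4.139, 1.5, -2.5, 8),
    p = c(0.04, 0.04, 0.001, 0.2))
  d <- call_degs(stats, p_thresh = 0.05, fc_thresh = 2)
  expect_identical(d$up_genes, "up_hit")
  expect_identical(d$down_genes, "down_hit")
  expect_identical(d$stats$call, c("up", "ns", "down", "ns"))

  # enumeration over random instances: tightening p never grows a list,
  # up/down lists are disjoint and exactly reproducible from the stats
  set.seed(5)
  for (i in 1:20) {
    stats <- data.frame(gene_id = sprintf("g%03d", 1:80),
                        fc_signed = bsig:::signed_fc(rnorm(80, sd = 1.5)),
                        p = runif(80))
    loose <- call_degs(stats, p_thresh = 0.1)
    tight <- call_degs(stats, p_thresh = 0.05)
    expect_true(all(tight$up_genes %in% loose$up_genes))
    expect_true(all(tight$down_genes %in% loose$down_genes))
    expect_length(intersect(loose$up_genes, loose$down_genes), 0)
    expect_setequal(loose$up_genes,
                    stats$gene_id[stats$p < 0.1 & stats$fc_signed >= 2])
    expect_setequal(loose$down_genes,
                    stats$gene_id[stats$p < 0.1 & stats$fc_signed <= -2])
  }
})

test_that("Fisher ORA matches exhaustive enumeration on small tables", {
  # the worked closed form: bg 20, set 5, deg 5, overlap 5
  sets <- list(gene_set("s", "", sprintf("g%02d", 1:5)))
  bg <- sprintf("g%02d", 1:20)
  res <- ora_fisher(sprintf("g%02d", 1:5), bg, sets)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$significant)

  # random small tables vs brute-force enumeration of all DEG draws
  set.seed(9)
  for (i in 1:10) {
    bg_size <- sample(10:20, 1)
    set_size <- sample(2:6, 1)
    deg_size <- sample(2:6, 1)
    bg <- sprintf("g%02d", 1:bg_size)
    deg <- sample(bg, deg_size)
    sets <- list(gene_set("s", "", bg[1:set_size]))
    res <- ora_fisher(deg, bg, sets, p_thresh = 0.01)
    overlap <- length(intersect(deg, bg[1:set_size]))
    expect_equal(res$p,
                 enumerate_enrichment_p(bg_size, set_size, deg_size,
                                        overlap),
                 tolerance = 1e-10)
  }
})

test_that("ORA degenerate inputs follow the contract", {
  sets <- list(gene_set("a", "", c("g1", "g2")),
               gene_set("faroff", "", c("zz1", "zz2")))
  bg <- paste0("g", 1:10)
  expect_warning(res <- ora_fisher(character(0), bg, sets), "no member")
  expect_equal(res$p, 1)                      # empty DEG list -> p = 1
  expect_identical(res$set_name, "a")         # disjoint set skipped
  expect_error(ora_fisher("not_in_bg", bg, sets),
               class = "bsig_validation_error")
})

test_that("null simulations are calibrated at the nominal level", {
  # planted-effect-free studies: the moderated-t p < 0.05 rate averaged
  # over seeds stays within 3 binomial SEs of 0.05
  rates <- sapply(1:8, function(seed) {
    s <- simulate_expression_study(simulation_config(
      n_genes = 2000, ifn_log2fc = 0, cc_log2fc = 0,
      foxm1_module_size = 0, seed = seed))
    st <- moderated_t_test(normalize_percentile(s$matrix), s$annotation,
                           "plasmablast")
    mean(st$p < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("stronger planted effects never reduce recall", {
  for (seed in 1:3) {
    recalls <- sapply(c(0.5, 1), function(eff) {
      s <- simulate_expression_study(simulation_config(
        n_genes = 600, ifn_log2fc = eff, cc_log2fc = eff,
        foxm1_module_size = 0, seed = seed))
      st <- moderated_t_test(normalize_percentile(s$matrix),
                             s$annotation, "naive")
      hits <- st$gene_id[st$p < 0.05 & st$fc_signed >= 1]
      mean(s$truth$ifn_genes %in% hits)
    })
    expect_gte(recalls[2], recalls[1])
  }
})
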