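#' Configuration for a synthetic B-cell subset expression study
#'
#' The generator emulates a 3-subset x 2-group x `n_donors_per_group`
#' design: an interferon-stimulated gene (ISG) set elevated in the SLE
#' samples of every subset, a cell-cycle set elevated only in SLE
#' plasmablasts, and a coexpression module of genes sharing a latent
#' donor-level factor with a FOXM1-like anchor that is active only in SLE
#' plasmablast samples. Defaults mirror the study design the package
#' targets: 4 donors per group, a 23-gene IFN signature, a 231-gene
#' cell-cycle signature, both planted at 1 log2 unit, residual noise scale
#' 0.5 log2 units.
#'
#' @param n_genes total number of genes.
#' @param n_donors_per_group donors per clinical group.
#' @param subsets character vector of B cell subsets.
#' @param baseline_mean_range range (log2) from which per-gene baseline
#'   levels are drawn uniformly.
#' @param noise_sd scale `s0` of the residual noise: per-gene variances are
#'   drawn from a scaled-inverse-chi-square prior with scale `noise_sd^2`
#'   and `var_prior_df` degrees of freedom, so the moderated-t variance
#'   prior is well-specified.
#' @param var_prior_df prior degrees of freedom `d0` of the variance draw.
#' @param subset_sd SD of per-gene subset offsets (log2).
#' @param donor_sd SD of the optional per-(gene, donor) random effect
#'   (log2); 0 disables it.
#' @param ifn_set_size,ifn_log2fc size of the planted IFN set and its log2
#'   effect, added to SLE samples of ALL subsets.
#' @param cc_set_size,cc_log2fc size of the planted cell-cycle set and its
#'   log2 effect, added to SLE plasmablast samples ONLY.
#' @param foxm1_module_size number of genes (anchor included) co-driven by
#'   the latent module factor.
#' @param foxm1_module_loading target correlation of each module gene to
#'   the latent factor, in (0, 1].
#' @param foxm1_factor_mean,foxm1_factor_sd mean and SD (log2-equivalent
#'   units) of the latent factor in SLE plasmablast samples; the factor is
#'   0 elsewhere.
#' @param anchor_loading target correlation of the anchor gene itself to
#'   the latent factor; the default 1 makes the anchor a noiseless
#'   readout of the factor, modelling a transcription factor that IS the
#'   module's driver.
#' @param seed integer RNG seed.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000L,
                              n_donors_per_group = 4L,
                              subsets = c("naive", "memory", "plasmablast"),
                              baseline_mean_range = c(4, 12),
                              noise_sd = 0.5,
                              var_prior_df = 4,
                              subset_sd = 0.5,
                              donor_sd = 0,
                              ifn_set_size = 23L,
                              ifn_log2fc = 1,
                              cc_set_size = 231L,
                              cc_log2fc = 1,
                              foxm1_module_size = 100L,
                              foxm1_module_loading = 0.8,
                              foxm1_factor_mean = 2,
                              foxm1_factor_sd = 1,
                              anchor_loading = 1,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_donors_per_group = as.integer(n_donors_per_group),
              subsets = as.character(subsets),
              baseline_mean_range = as.numeric(baseline_mean_range),
              noise_sd = noise_sd, var_prior_df = var_prior_df,
              subset_sd = subset_sd, donor_sd = donor_sd,
              ifn_set_size = as.integer(ifn_set_size),
              ifn_log2fc = ifn_log2fc,
              cc_set_size = as.integer(cc_set_size),
              cc_log2fc = cc_log2fc,
              foxm1_module_size = as.integer(foxm1_module_size),
              foxm1_module_loading = foxm1_module_loading,
              foxm1_factor_mean = foxm1_factor_mean,
              foxm1_factor_sd = foxm1_factor_sd,
              anchor_loading = anchor_loading,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) config_error("n_genes must be >= 1")
  if (cfg$n_donors_per_group < 1L)
    config_error("n_donors_per_group must be >= 1")
  if (cfg$ifn_set_size + cfg$cc_set_size + cfg$foxm1_module_size > cfg$n_genes)
    config_error("planted set sizes plus module size exceed n_genes")
  if (cfg$noise_sd <= 0) config_error("noise_sd must be > 0")
  if (cfg$var_prior_df <= 2)
    config_error("var_prior_df must be > 2 (finite prior mean)")
  if (cfg$foxm1_module_loading <= 0 || cfg$foxm1_module_loading > 1)
    config_error("foxm1_module_loading must be in (0, 1]")
  if (length(cfg$baseline_mean_range) != 2L ||
      diff(cfg$baseline_mean_range) < 0)
    config_error("baseline_mean_range must be an increasing interval")
  if (!"plasmablast" %in% cfg$subsets && cfg$foxm1_module_size > 0L)
    config_error("the module factor requires a plasmablast subset")
  structure(cfg, class = "simulation_config")
}

#' Simulate a B-cell subset expression study with ground truth
#'
#' Each observation is gene baseline + per-(gene, subset) offset +
#' planted effect + optional donor effect + module-factor contribution +
#' Gaussian noise with gene-specific SD (drawn from a scaled-inverse-
#' chi-square prior), all on the log2 scale. Identical `(config, seed)`
#' reproduces the matrix bit-for-bit.
#'
#' @param config a [simulation_config()].
#' @return a list with `matrix` (expression matrix), `annotation`
#'   (sample annotation) and `truth`: a list with `ifn_genes`, `cc_genes`,
#'   `foxm1_anchor`, `foxm1_module_genes`, `gene_sd` (per-gene noise SD)
#'   and `effects`, a genes x subsets matrix of true SLE-vs-HC log2
#'   effects (0 for HC everywhere).
#' @export
simulate_expression_study <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
    ifn_genes <- character(0); cc_genes <- character(0)
    module_genes <- character(0); anchor <- NA_character_
    pos <- 0L
    if (cfg$ifn_set_size > 0L) {
      ifn_genes <- gene_ids[pos + seq_len(cfg$ifn_set_size)]
      pos <- pos + cfg$ifn_set_size
    }
    if (cfg$cc_set_size > 0L) {
      cc_genes <- gene_ids[pos + seq_len(cfg$cc_set_size)]
      pos <- pos + cfg$cc_set_size
    }
    if (cfg$foxm1_module_size > 0L) {
      idx <- pos + seq_len(cfg$foxm1_module_size)
      gene_ids[idx[1]] <- "FOXM1"   # the anchor, named after its role
      module_genes <- gene_ids[idx]
      anchor <- "FOXM1"
    }

    donors <- c(paste0("HC", seq_len(cfg$n_donors_per_group)),
                paste0("SLE", seq_len(cfg$n_donors_per_group)))
    groups <- rep(c("HC", "SLE"), each = cfg$n_donors_per_group)
    ann <- expand.grid(donor_id = donors, subset = cfg$subsets,
                       stringsAsFactors = FALSE)
    ann$group <- groups[match(ann$donor_id, donors)]
    ann$sample_id <- paste(ann$donor_id, ann$subset, sep = "_")
    ann <- sample_annotation(ann[, c("sample_id", "donor_id",
                                     "group", "subset")])
    n_samp <- nrow(ann)

    baseline <- runif(cfg$n_genes, cfg$baseline_mean_range[1],
                      cfg$baseline_mean_range[2])
    subset_off <- matrix(rnorm(cfg$n_genes * length(cfg$subsets),
                               sd = cfg$subset_sd),
                         nrow = cfg$n_genes,
                         dimnames = list(gene_ids, cfg$subsets))
    # gene variances from the scaled-inverse-chi-square prior:
    # s_g^2 = d0 * s0^2 / chisq_{d0}
    gene_sd <- sqrt(cfg$var_prior_df * cfg$noise_sd^2 /
                      rchisq(cfg$n_genes, df = cfg$var_prior_df))
    names(gene_sd) <- gene_ids

    effects <- matrix(0, nrow = cfg$n_genes, ncol = length(cfg$subsets),
                      dimnames = list(gene_ids, cfg$subsets))
    effects[ifn_genes, ] <- cfg$ifn_log2fc
    if ("plasmablast" %in% cfg$subsets)
      effects[cc_genes, "plasmablast"] <-
        effects[cc_genes, "plasmablast"] + cfg$cc_log2fc

    donor_mat <- if (cfg$donor_sd > 0)
      matrix(rnorm(cfg$n_genes * length(donors), sd = cfg$donor_sd),
             nrow = cfg$n_genes, dimnames = list(gene_ids, donors))
    else NULL

    # latent module factor: nonzero only in SLE plasmablast samples
    factor_vec <- numeric(n_samp)
    is_sle_pb <- ann$group == "SLE" & ann$subset == "plasmablast"
    if (length(module_genes) && any(is_sle_pb))
      factor_vec[is_sle_pb] <- rnorm(sum(is_sle_pb),
                                     mean = cfg$foxm1_factor_mean,
                                     sd = cfg$foxm1_factor_sd)
    sd_f <- stats::sd(factor_vec)

    # mean profile without factor and residual noise: baseline + subset
    # offset + planted IFN/cell-cycle effect (+ donor effect)
    subset_idx <- match(ann$subset, cfg$subsets)
    M <- subset_off[, subset_idx, drop = FALSE] + baseline
    for (j in which(ann$group == "SLE"))
      M[, j] <- M[, j] + effects[, subset_idx[j]]
    if (!is.null(donor_mat)) M <- M + donor_mat[, ann$donor_id]

    noise <- matrix(rnorm(cfg$n_genes * n_samp), nrow = cfg$n_genes) *
      gene_sd
    loadings <- setNames(numeric(cfg$n_genes), gene_ids)
    if (length(module_genes) && sd_f > 0) {
      rho <- rep(cfg$foxm1_module_loading, length(module_genes))
      rho[1] <- cfg$anchor_loading
      # the gene's non-factor variation across samples is residual noise
      # plus its mean-profile variation; the loading a_g giving
      # corr(gene, factor) = rho against that total is
      # a = s_tot * rho / (sd_f * sqrt(1 - rho^2))
      idx <- match(module_genes, gene_ids)
      s_tot <- sqrt(gene_sd[module_genes]^2 + apply(M[idx, , drop = FALSE],
                                                    1L, var))
      a <- ifelse(rho < 1,
                  s_tot * rho / (sd_f * sqrt(pmax(1 - rho^2, 1e-12))),
                  2 * cfg$noise_sd / sd_f)
      loadings[module_genes] <- a
      # a loading-1 gene is an exact readout of the factor: flat profile
      # at its baseline, no residual noise
      pure_idx <- idx[rho >= 1]
      if (length(pure_idx)) {
        M[pure_idx, ] <- baseline[pure_idx]
        noise[pure_idx, ] <- 0
      }
      effects[module_genes, "plasmablast"] <-
        effects[module_genes, "plasmablast"] +
        loadings[module_genes] * cfg$foxm1_factor_mean
    }

    values <- M + noise + outer(loadings, factor_vec)
    mat <- expression_matrix(values, gene_ids = gene_ids,
                             sample_ids = ann$sample_id)
    truth <- list(ifn_genes = ifn_genes, cc_genes = cc_genes,
                  foxm1_anchor = anchor, foxm1_module_genes = module_genes,
                  gene_sd = gene_sd, effects = effects)
    list(matrix = mat, annotation = ann, truth = truth)
  })
}

#' Gene sets corresponding to a simulation's planted signatures
#'
#' @param truth the `truth` element returned by
#'   [simulate_expression_study()].
#' @return a named list of [gene_set()] objects (`IFN_SIGNATURE`,
#'   `CELL_CYCLE`, `FOXM1_MODULE`; absent sets are dropped).
#' @export
truth_gene_sets <- function(truth) {
  sets <- list()
  if (length(truth$ifn_genes))
    sets$IFN_SIGNATURE <- gene_set("IFN_SIGNATURE",
      "planted type I interferon signature", truth$ifn_genes)
  if (length(truth$cc_genes))
    sets$CELL_CYCLE <- gene_set("CELL_CYCLE",
      "planted cell-cycle signature", truth$cc_genes)
  if (length(truth$foxm1_module_genes))
    sets$FOXM1_MODULE <- gene_set("FOXM1_MODULE",
      "planted anchor-correlated module", truth$foxm1_module_genes)
  sets
}
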