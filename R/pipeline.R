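# End-to-end driver: simulate -> normalize -> DEG -> ORA -> score ->
# similar -> proliferation/apoptosis, from one seeded YAML (or list)
# configuration, with a JSON run manifest recording config, checksums
# and versions. Stages communicate only through files in the run
# directory, so disabling a downstream stage never perturbs an upstream
# one, and a stage can consume files left by an earlier run.

pipeline_defaults <- function() {
  list(
    seed = NULL,
    out_dir = "bsig_run",
    stages = list(simulate = TRUE, deg = TRUE, ora = TRUE, score = TRUE,
                  similar = TRUE, proliferation = TRUE, apoptosis = TRUE),
    simulation = list(),
    division = list(),
    deg = list(percentile = 75, p_thresh = 0.05, fc_thresh = 2,
               adjust = "none"),
    ora = list(p_thresh = 0.01),
    score = list(scale = "linear"),
    similar = list(anchor = "FOXM1", r_min = 0.6, r_max = 1.0,
                   method = "pearson"),
    proliferation = list(gen0_mean = 10000, i_max = 5,
                         annexin_threshold = 600,
                         viability_threshold = 600))
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    config_error("a single integer `seed` is required")
  dg <- cfg$deg
  if (dg$p_thresh <= 0 || dg$p_thresh > 1)
    config_error("deg.p_thresh must be in (0, 1]")
  if (dg$fc_thresh < 1) config_error("deg.fc_thresh must be >= 1")
  if (dg$percentile <= 0 || dg$percentile > 100)
    config_error("deg.percentile must be in (0, 100]")
  if (cfg$ora$p_thresh <= 0 || cfg$ora$p_thresh > 1)
    config_error("ora.p_thresh must be in (0, 1]")
  sm <- cfg$similar
  if (sm$r_min > sm$r_max || sm$r_min < -1 || sm$r_max > 1)
    config_error("similar: need -1 <= r_min <= r_max <= 1")
  pr <- cfg$proliferation
  if (pr$gen0_mean <= 0) config_error("proliferation.gen0_mean must be > 0")
  if (pr$i_max < 0) config_error("proliferation.i_max must be >= 0")
  invisible(cfg)
}

#' Derive a stage sub-seed from the run seed
#'
#' Counter-based derivation so one top-level seed reproduces every
#' stochastic stage independently; results stay below 2^31.
#'
#' @param seed top-level run seed.
#' @param index stage counter (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * (index + 1)) %% 2147483647)
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_stage_file <- function(cfg, name, stage) {
  p <- stage_path(cfg, name)
  if (!file.exists(p))
    io_error(sprintf("stage '%s' needs %s; enable the producing stage %s",
                     stage, p, "or place the file in out_dir"))
  p
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order under `out_dir`,
#' writing TSV/CSV/JSON outputs per stage and a `manifest.json` last
#' (config snapshot, per-file MD5 checksums, package version,
#' timestamps). Configuration errors abort before any stage runs; a
#' stage failure aborts with the stage name in the error message.
#'
#' @param config a configuration list, or the path to a YAML file
#'   mirroring the list structure. Required: `seed`. Optional: `out_dir`,
#'   `stages` (logical toggles `simulate`, `deg`, `ora`, `score`,
#'   `similar`, `proliferation`, `apoptosis`), `simulation` and
#'   `division` ([simulation_config()] / [division_sim_config()]
#'   overrides), and per-stage parameter blocks `deg` (`percentile`,
#'   `p_thresh`, `fc_thresh`, `adjust`), `ora` (`p_thresh`), `score`
#'   (`scale`), `similar` (`anchor`, `r_min`, `r_max`, `method`),
#'   `proliferation` (`gen0_mean`, `i_max`, `annexin_threshold`,
#'   `viability_threshold`).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  outputs <- character(0)
  run_stage <- function(name, fn) {
    tryCatch(fn(), bsig_error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("bsig_stage_error", class(e))))
    })
  }

  if (isTRUE(cfg$stages$simulate)) {
    run_stage("simulate", function() {
      sim_cfg <- do.call(simulation_config,
                         merge_config(list(seed = derive_seed(cfg$seed, 0)),
                                      cfg$simulation))
      study <- simulate_expression_study(sim_cfg)
      write_expression(study$matrix, stage_path(cfg, "matrix.tsv"),
                       annotation = study$annotation,
                       metadata_path = stage_path(cfg, "metadata.tsv"))
      write_gmt(truth_gene_sets(study$truth), stage_path(cfg, "sets.gmt"))
      truth_json <- study$truth
      truth_json$gene_sd <- NULL
      truth_json$effects <- list(
        gene_id = rownames(study$truth$effects),
        subset = colnames(study$truth$effects),
        sle_log2_effect = unname(study$truth$effects))
      jsonlite::write_json(truth_json, stage_path(cfg, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      div_cfg <- do.call(division_sim_config,
                         merge_config(list(seed = derive_seed(cfg$seed, 1)),
                                      cfg$division))
      div <- simulate_division_experiment(div_cfg)
      write_flow_events(div$events, stage_path(cfg, "events.csv"))
      outputs <<- c(outputs, "matrix.tsv", "metadata.tsv", "sets.gmt",
                    "truth.json", "events.csv")
    })
  }

  load_study <- function(stage) {
    read_expression(require_stage_file(cfg, "matrix.tsv", stage),
                    require_stage_file(cfg, "metadata.tsv", stage))
  }

  if (isTRUE(cfg$stages$deg)) {
    run_stage("deg", function() {
      study <- load_study("deg")
      norm <- normalize_percentile(study$matrix, cfg$deg$percentile)
      for (sb in unique(study$annotation$subset)) {
        stats <- moderated_t_test(norm, study$annotation, sb)
        degs <- call_degs(stats, cfg$deg$p_thresh, cfg$deg$fc_thresh,
                          adjust = cfg$deg$adjust)
        tab <- degs$stats[, c("gene_id", "mean_a", "mean_b", "fc_signed",
                              "t_mod", "df_total", "p", "call")]
        names(tab)[2:3] <- c("mean_HC", "mean_SLE")
        f <- sprintf("deg_%s.tsv", sb)
        write_table(tab, stage_path(cfg, f))
        outputs <<- c(outputs, f)
      }
    })
  }

  read_deg_calls <- function(subset, stage) {
    read_result_table(require_stage_file(cfg, sprintf("deg_%s.tsv", subset),
                                         stage))
  }

  if (isTRUE(cfg$stages$ora)) {
    run_stage("ora", function() {
      deg <- read_deg_calls("plasmablast", "ora")
      sets <- read_gmt(require_stage_file(cfg, "sets.gmt", "ora"))
      res <- ora_fisher(deg$gene_id[deg$call != "ns"], deg$gene_id, sets,
                        p_thresh = cfg$ora$p_thresh)
      write_table(res, stage_path(cfg, "ora.tsv"))
      outputs <<- c(outputs, "ora.tsv")
    })
  }

  if (isTRUE(cfg$stages$score)) {
    run_stage("score", function() {
      study <- load_study("score")
      sets <- read_gmt(require_stage_file(cfg, "sets.gmt", "score"))
      all_scores <- do.call(rbind, lapply(sets, function(s)
        signature_score(study$matrix, s, annotation = study$annotation,
                        scale = cfg$score$scale)))
      write_table(all_scores, stage_path(cfg, "scores.tsv"))
      tests <- do.call(rbind, lapply(sets, function(s) {
        sc <- all_scores[all_scores$set_name == s$name, ]
        cmp <- compare_scores(sc)
        cbind(set_name = s$name, cmp$subset_contrasts)
      }))
      write_table(tests, stage_path(cfg, "score_tests.tsv"))
      outputs <<- c(outputs, "scores.tsv", "score_tests.tsv")
    })
  }

  if (isTRUE(cfg$stages$similar)) {
    run_stage("similar", function() {
      study <- load_study("similar")
      deg <- read_deg_calls("plasmablast", "similar")
      candidates <- deg$gene_id[deg$call != "ns"]
      if (!cfg$similar$anchor %in% candidates)
        candidates <- c(cfg$similar$anchor, candidates)
      res <- find_similar_entities(study$matrix, cfg$similar$anchor,
                                   candidates, r_min = cfg$similar$r_min,
                                   r_max = cfg$similar$r_max,
                                   method = cfg$similar$method)
      tab <- data.frame(gene_id = names(res$r), r = unname(res$r),
                        selected = names(res$r) %in% res$selected,
                        stringsAsFactors = FALSE)
      write_table(tab[!is.na(tab$r), ], stage_path(cfg, "similar.tsv"))
      outputs <<- c(outputs, "similar.tsv")
    })
  }

  if (isTRUE(cfg$stages$proliferation) || isTRUE(cfg$stages$apoptosis)) {
    events <- read_flow_events(
      require_stage_file(cfg, "events.csv", "proliferation"))
    if (isTRUE(cfg$stages$proliferation)) {
      run_stage("proliferation", function() {
        dist <- assign_generations(events, cfg$proliferation$gen0_mean,
                                   cfg$proliferation$i_max)
        res <- proliferation_index(dist)
        tab <- data.frame(generation = 0:dist$max_generation,
                          count = dist$counts, percent = dist$N)
        tab$pi <- res$pi
        tab$founders_equivalent <- res$founders_equivalent
        write_table(tab, stage_path(cfg, "pi.tsv"))
        outputs <<- c(outputs, "pi.tsv")
      })
    }
    if (isTRUE(cfg$stages$apoptosis)) {
      run_stage("apoptosis", function() {
        gate <- apoptosis_gate(cfg$proliferation$annexin_threshold,
                               cfg$proliferation$viability_threshold)
        fr <- apoptosis_fractions(events, gate)
        write_table(data.frame(class = names(fr), fraction = unname(fr)),
                    stage_path(cfg, "apoptosis.tsv"))
        outputs <<- c(outputs, "apoptosis.tsv")
      })
    }
  }

  outputs <- unique(outputs)
  checksums <- as.list(md5sum(file.path(cfg$out_dir, outputs)))
  names(checksums) <- outputs
  manifest <- list(config = cfg,
                   outputs = checksums,
                   package_version = as.character(packageVersion("bsig")),
                   started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, stage_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
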