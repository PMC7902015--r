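#' Configuration for a dye-dilution proliferation experiment
#'
#' Models a CellTrace-style labelling experiment: founders pass through a
#' per-generation Bernoulli progression chain; a founder whose cohort
#' reaches generation `i` contributes `2^i` descendant events whose dye
#' intensity is lognormal around `dye_gen0_mean / 2^i`. Apoptosis channels
#' (annexin, viability dye) are drawn per event from one of three classes
#' (live, early apoptotic, late apoptotic) with configured fractions.
#'
#' @param n_founders number of labelled founder cells.
#' @param max_generation last resolvable generation.
#' @param progression_probs probability that a cohort in generation `i`
#'   divides again, for `i = 0 .. max_generation - 1`.
#' @param dye_gen0_mean median linear dye intensity of undivided cells.
#' @param dye_cv lognormal coefficient of variation of each generation's
#'   peak (0 gives noiseless peaks at the exact centers).
#' @param apoptosis_params list with `fractions` (named `live`, `early`,
#'   `late`, summing to 1) and channel location/scale:
#'   `annexin_neg_mean`, `annexin_pos_mean`, `annexin_sd`,
#'   `viability_neg_mean`, `viability_pos_mean`, `viability_sd`
#'   (linear units). Early apoptotic cells are annexin-positive,
#'   viability-dye-negative; late apoptotic cells are double positive.
#' @param seed integer RNG seed.
#' @return a validated list of class `division_sim_config`.
#' @export
division_sim_config <- function(n_founders = 2000L,
                                max_generation = 5L,
                                progression_probs = rep(0.7, max_generation),
                                dye_gen0_mean = 10000,
                                dye_cv = 0.15,
                                apoptosis_params = list(
                                  fractions = c(live = 0.7, early = 0.2,
                                                late = 0.1),
                                  annexin_neg_mean = 200,
                                  annexin_pos_mean = 1000,
                                  annexin_sd = 150,
                                  viability_neg_mean = 200,
                                  viability_pos_mean = 1000,
                                  viability_sd = 150),
                                seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              max_generation = as.integer(max_generation),
              progression_probs = as.numeric(progression_probs),
              dye_gen0_mean = dye_gen0_mean, dye_cv = dye_cv,
              apoptosis_params = apoptosis_params,
              seed = as.integer(seed))
  if (cfg$n_founders < 1L) config_error("n_founders must be >= 1")
  if (cfg$max_generation < 0L) config_error("max_generation must be >= 0")
  if (length(cfg$progression_probs) != cfg$max_generation)
    config_error("progression_probs must have max_generation entries")
  if (any(cfg$progression_probs < 0 | cfg$progression_probs > 1))
    config_error("progression_probs must lie in [0, 1]")
  if (cfg$dye_gen0_mean <= 0) config_error("dye_gen0_mean must be > 0")
  if (cfg$dye_cv < 0) config_error("dye_cv must be >= 0")
  fr <- cfg$apoptosis_params$fractions
  if (is.null(fr) || length(fr) != 3L || any(fr < 0) ||
      abs(sum(fr) - 1) > 1e-9)
    config_error("apoptosis class fractions must be 3 nonnegatives summing to 1")
  structure(cfg, class = "division_sim_config")
}

#' Simulate a dye-dilution proliferation experiment
#'
#' @param config a [division_sim_config()].
#' @return a list with `events` (a [flow_event_table()] including
#'   `true_generation`) and `founder_count`.
#' @export
simulate_division_experiment <- function(config = division_sim_config()) {
  if (!inherits(config, "division_sim_config"))
    config <- do.call(division_sim_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    # terminal generation of each founder cohort via the Bernoulli chain
    gen <- integer(cfg$n_founders)
    alive <- rep(TRUE, cfg$n_founders)
    for (i in seq_len(cfg$max_generation)) {
      div <- alive & (runif(cfg$n_founders) < cfg$progression_probs[i])
      gen[div] <- i
      alive <- div
    }
    # a cohort ending at generation g contributes 2^g events
    true_generation <- rep(gen, times = 2^gen)
    n_events <- length(true_generation)

    sdlog <- sqrt(log(1 + cfg$dye_cv^2))
    meanlog <- log(cfg$dye_gen0_mean) - true_generation * log(2)
    dye <- if (sdlog > 0) rlnorm(n_events, meanlog, sdlog) else exp(meanlog)

    ap <- cfg$apoptosis_params
    cls <- sample(c("live", "early", "late"), n_events, replace = TRUE,
                  prob = ap$fractions[c("live", "early", "late")])
    annexin <- rnorm(n_events,
                     ifelse(cls == "live", ap$annexin_neg_mean,
                            ap$annexin_pos_mean), ap$annexin_sd)
    viability <- rnorm(n_events,
                       ifelse(cls == "late", ap$viability_pos_mean,
                              ap$viability_neg_mean), ap$viability_sd)

    events <- flow_event_table(data.frame(
      cell_id = sprintf("c%07d", seq_len(n_events)),
      dye_intensity = dye, annexin = annexin, viability = viability,
      true_generation = true_generation, stringsAsFactors = FALSE))
    list(events = events, founder_count = cfg$n_founders)
  })
}
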