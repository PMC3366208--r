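## Experiment campaigns: ensembles of runs with logged seeds and summary
## tables (lap times and falls for the parameter-characterisation runs;
## step size, dwell rate, duty ratio and velocity for the leg-length
## comparison).

#' Run an ensemble of simulations
#'
#' @param config `sim_config`.
#' @param n_runs number of runs.
#' @param base_seed seed of run 1; run `i` uses `base_seed + i - 1`.
#' @return list of trajectories (seeds recorded in each).
#' @export
run_ensemble <- function(config = default_config(), n_runs = 5L,
                         base_seed = 1L) {
  lapply(seq_len(n_runs), function(i) run_sim(config, base_seed + i - 1L))
}

#' Summary statistics of one leg-length model ensemble
#'
#' @param trajs list of trajectories of one model.
#' @return list with pooled step/dwell/duty/velocity statistics.
#' @export
summarise_ensemble <- function(trajs) {
  steps <- do.call(rbind, lapply(trajs, extract_steps))
  dwells <- do.call(rbind, lapply(trajs, extract_dwells))
  laps <- unlist(lapply(trajs, lap_time))
  duty_single <- vapply(trajs, function(t)
    mean(c(duty_ratio(t, 1), duty_ratio(t, 2))), 0)
  duty_dimer <- vapply(trajs, function(t) duty_ratio(t, "either"), 0)
  gauss <- if (nrow(steps) >= 2) fit_step_gaussian(steps) else c(NA, NA)
  kfit <- tryCatch(fit_dwell_rate(dwells), error = function(e) NULL)
  vel <- tryCatch(velocity_fit(trajs), error = function(e) list(slope = NA))
  bs <- count_backsteps(steps)
  list(n_runs = length(trajs),
       n_steps = nrow(steps),
       step_mean = unname(gauss[1]), step_sd = unname(gauss[2]),
       step_median = if (nrow(steps)) stats::median(steps$separation) else NA,
       step_mean_nm = unname(step_size_nm(gauss[1])),
       dwell_k = if (is.null(kfit)) NA else kfit$k12,
       dwell_mean = if (is.null(kfit)) NA else kfit$mean_lifetime,
       duty_single = mean(duty_single), duty_single_sd = stats::sd(duty_single),
       duty_dimer = mean(duty_dimer), duty_dimer_sd = stats::sd(duty_dimer),
       velocity = vel$slope,
       backstep_fraction = bs$fraction,
       lap_mean = if (length(laps)) mean(laps) else NA,
       lap_sd = if (length(laps) > 1) stats::sd(laps) else NA,
       falls = sum(vapply(trajs, function(t)
         attr(t, "termination") == "detached", TRUE)))
}

#' Run a named experiment suite
#'
#' `"table1"` runs an ensemble of the default 6IQ model and reports mean
#' lap time, its spread and the number of falls (detachments);
#' `"leglengths"` runs ensembles of the 2, 4 and 6 IQ models and reports
#' step-size, dwell, duty-ratio and velocity statistics per model.
#'
#' @param name `"table1"` or `"leglengths"`.
#' @param n_runs runs per ensemble (defaults: 20 for table1, 5 for
#'   leglengths).
#' @param base_seed first seed; ensembles use consecutive seeds.
#' @param n_laps laps per run (default 1 for table1, 2 for leglengths).
#' @param config_fn optional function `n_iq -> sim_config` to customise
#'   configurations.
#' @return report list with a `manifest` (seeds, configs) sufficient to
#'   regenerate it.
#' @export
run_experiment_suite <- function(name = c("table1", "leglengths"),
                                 n_runs = NULL, base_seed = 1L,
                                 n_laps = NULL, config_fn = default_config) {
  name <- match.arg(name)
  if (name == "table1") {
    if (is.null(n_runs)) n_runs <- 20L
    if (is.null(n_laps)) n_laps <- 1L
    cfg <- config_fn(6L)
    cfg$stop$n_laps <- n_laps
    trajs <- run_ensemble(cfg, n_runs, base_seed)
    laps <- unlist(lapply(trajs, lap_time))
    falls <- sum(vapply(trajs, function(t)
      attr(t, "termination") == "detached", TRUE))
    report <- list(
      lap_mean = mean(laps), lap_sd = stats::sd(laps),
      n_lap_obs = length(laps), falls = falls,
      runs = n_runs - falls,
      variance_ok = length(laps) > 1)
  } else {
    if (is.null(n_runs)) n_runs <- 5L
    if (is.null(n_laps)) n_laps <- 2L
    report <- list()
    for (niq in c(2L, 4L, 6L)) {
      cfg <- config_fn(niq)
      cfg$stop$n_laps <- n_laps
      trajs <- run_ensemble(cfg, n_runs, base_seed)
      s <- summarise_ensemble(trajs)
      s$variance_ok <- n_runs > 1
      report[[paste0("iq", niq)]] <- s
    }
  }
  report$manifest <- list(suite = name, n_runs = n_runs,
                          base_seed = base_seed, n_laps = n_laps,
                          seeds = base_seed + seq_len(n_runs) - 1L)
  report
}
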