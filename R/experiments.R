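#' Motor-experiment condition
#'
#' The three standard conditions of the evolutionary experiment: A (no
#' noise, valid:neutral:invalid cue ratio 8:5:2, the classic proportions),
#' B (no noise, 8:8:2, equating valid and neutral cue frequency) and C
#' (per-neuron Gaussian noise of SD 2 mV every time unit, 8:8:2).
#'
#' @param label `"A"`, `"B"` or `"C"`.
#' @param task `"SRT"` or `"CRT"`.
#' @return A list of class `condition_spec` with `label`, `task`,
#'   `cue_ratio`, `noise_sigma`.
#' @examples
#' condition_spec("C", "CRT")
#' @export
condition_spec <- function(label = c("A", "B", "C"), task = c("SRT", "CRT")) {
  label <- match.arg(label)
  task <- match.arg(task)
  structure(
    list(
      label = label, task = task,
      cue_ratio = if (label == "A") c(8L, 5L, 2L) else c(8L, 8L, 2L),
      noise_sigma = if (label == "C") 2 else 0
    ),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> %s (%s): cue ratio %s, noise sigma %g\n",
              x$label, x$task, paste(x$cue_ratio, collapse = ":"),
              x$noise_sigma))
  invisible(x)
}

#' Run the sensory experiment grid
#'
#' Simulates the Bayesian observer over a grid of task x signal intensity x
#' response threshold, with the standard trial mix (half lateral-cue, half
#' neutral-cue trials; target side per the cue-implied prior), and returns
#' per-configuration, per-cue-type accuracy, correct-trial mean RT and error
#' proportions, plus a pooled row (`cue_type == "all"`) per configuration.
#'
#' @param tasks character vector of tasks to run.
#' @param s_values signal intensities.
#' @param gamma_values response thresholds.
#' @param n_trials trials per configuration.
#' @param sigma noise standard deviation.
#' @param seed optional integer seed for the whole grid.
#' @return A tibble with columns `task`, `s`, `gamma`, `cue_type`, `n`,
#'   `accuracy`, `mean_rt`, `sd_rt`, `prop_anticipated`, `prop_incorrect`,
#'   `prop_slow`.
#' @examples
#' run_exp1(n_trials = 500, seed = 1)
#' @export
run_exp1 <- function(tasks = c("SRT", "CRT"), s_values = c(5, 0.5),
                     gamma_values = c(0.8, 0.95), n_trials = 1e5,
                     sigma = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(task = tasks, s = s_values, gamma = gamma_values)
  purrr::pmap_dfr(grid, function(task, s, gamma) {
    cfg <- bayes_config(s = s, sigma = sigma, gamma = gamma, task = task)
    trials <- simulate_bayes_trials(cfg, n_trials)
    by_cue <- summarize_bayes_trials(trials)
    pooled <- summarize_bayes_trials(dplyr::mutate(trials, cue_type = "all")) %>%
      mutate(cue_type = factor("all"))
    bind_rows(by_cue, pooled) %>%
      mutate(task = task, s = s, gamma = gamma, .before = 1) %>%
      mutate(cue_type = as.character(.data$cue_type))
  })
}

#' Run one evolutionary experiment
#'
#' Evolves spiking networks under one condition (A/B/C) and task (SRT/CRT),
#' wiring [condition_spec()] into [evolve_networks()].
#'
#' @param condition a [condition_spec()] or a label (`"A"`, `"B"`, `"C"`).
#' @param task task kind, used when `condition` is a label.
#' @param generations breeding steps (default the full 300).
#' @param ga a [ga_config()].
#' @param seed optional integer seed.
#' @return An `rt_evolution` object (see [evolve_networks()]).
#' @examples
#' \donttest{
#' run_exp2("A", "SRT", generations = 10, seed = 1)
#' }
#' @export
run_exp2 <- function(condition = "A", task = c("SRT", "CRT"),
                     generations = NULL, ga = ga_config(), seed = NULL) {
  if (!inherits(condition, "condition_spec")) {
    condition <- condition_spec(condition, match.arg(task))
  }
  arch <- lif_architecture(condition$task)
  trials <- lif_task_trials(condition$cue_ratio)
  protocol <- lif_protocol(noise_sigma = condition$noise_sigma)
  if (is.null(generations)) generations <- ga$generations
  ev <- evolve_networks(arch, trials, protocol, ga,
                        generations = generations, seed = seed)
  ev$condition <- condition
  ev
}

#' Population summary of individual median reaction times
#'
#' For each individual and cue type, the median RT over its correct trials
#' is taken (discarding slow, anticipated and wrong responses); an
#' individual with no correct response for a cue type is null for that cue
#' type and excluded. The summary reports mean, SD and normal-approximation
#' 95% CI half-width over the non-null individual medians.
#'
#' @param trial_results a tibble with columns `individual`, `cue_type`,
#'   `rt`, `outcome` (e.g. from [lif_trial_results()]).
#' @return A tibble with one row per cue type: `cue_type`, `n` (non-null
#'   individuals), `mean_median_rt`, `sd_median_rt`, `ci95_half_width`.
#' @examples
#' res <- tibble::tibble(individual = 1, cue_type = "valid",
#'                       rt = c(3, 5, 100), outcome = "correct")
#' population_rt_summary(res)
#' @export
population_rt_summary <- function(trial_results) {
  trial_results %>%
    filter(.data$outcome == "correct") %>%
    group_by(.data$individual, .data$cue_type) %>%
    summarise(median_rt = median(.data$rt), .groups = "drop") %>%
    group_by(.data$cue_type) %>%
    summarise(
      n = dplyr::n(),
      mean_median_rt = mean(.data$median_rt),
      sd_median_rt = if (dplyr::n() > 1L) sd(.data$median_rt) else NA_real_,
      ci95_half_width = if (dplyr::n() > 1L) {
        qnorm(0.975) * sd(.data$median_rt) / sqrt(dplyr::n())
      } else NA_real_,
      .groups = "drop"
    )
}
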