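#' Leaky integrate-and-fire neuron parameters
#'
#' Defaults used throughout: rest and reset potential -65 mV, firing
#' threshold -40 mV, membrane time constant 10 time units.
#'
#' @param v_rest,v_reset,v_threshold membrane potentials in mV.
#' @param tau membrane time constant in time units (> 0).
#' @return A named list of class `neuron_params`.
#' @export
neuron_params <- function(v_rest = -65, v_reset = -65, v_threshold = -40,
                          tau = 10) {
  stopifnot(v_reset <= v_rest, v_rest < v_threshold, tau > 0)
  structure(list(v_rest = v_rest, v_reset = v_reset,
                 v_threshold = v_threshold, tau = tau),
            class = "neuron_params")
}

#' Network architecture for the motor model
#'
#' Fully connected (all ordered pairs of distinct neurons, no self-loops)
#' spiking networks: three central cue inputs (left, neutral, right), two
#' peripheral target inputs (left, right), and one output neuron for the SRT
#' task or a left/right output pair for the CRT task. The genome holds one
#' bias per neuron followed by one weight per directed synapse, giving
#' 6 + 30 = 36 genes for SRT and 7 + 42 = 49 for CRT.
#'
#' @param task `"SRT"` or `"CRT"`.
#' @return A list of class `lif_architecture` with `task`, `roles`,
#'   `n_neurons`, `n_synapses`, `genome_length`.
#' @examples
#' lif_architecture("CRT")$genome_length  # 49
#' @export
lif_architecture <- function(task = c("SRT", "CRT")) {
  task <- match.arg(task)
  roles <- c("cue_left", "cue_neutral", "cue_right",
             "target_left", "target_right",
             if (task == "SRT") "output" else c("output_left", "output_right"))
  n <- length(roles)
  structure(
    list(task = task, roles = roles, n_neurons = n,
         n_synapses = n * (n - 1L), genome_length = n + n * (n - 1L)),
    class = "lif_architecture"
  )
}

#' Trial protocol for the motor model
#'
#' A trial starts from rest, runs `pre_cue` silent time units, presents the
#' cue (a `stim_current` mV input to one central neuron) for a uniformly
#' drawn integer duration in `[cue_min, cue_max]`, then presents the target
#' (the same current to one peripheral neuron) in addition to the cue. The
#' trial ends at the first output spike or `post_target_limit` time units
#' after target onset. With `noise_sigma > 0`, every neuron receives an
#' independent Gaussian current each time unit in every phase.
#'
#' @param pre_cue silent lead-in, time units.
#' @param cue_min,cue_max bounds of the uniform integer cue duration.
#' @param stim_current external input current, mV.
#' @param post_target_limit slow-response cutoff after target onset.
#' @param noise_sigma internal noise standard deviation, mV (>= 0).
#' @return A named list of class `lif_protocol`.
#' @export
lif_protocol <- function(pre_cue = 50L, cue_min = 100L, cue_max = 200L,
                         stim_current = 5, post_target_limit = 1000L,
                         noise_sigma = 0) {
  stopifnot(stim_current > 0, noise_sigma >= 0, cue_min <= cue_max)
  structure(list(pre_cue = as.integer(pre_cue), cue_min = as.integer(cue_min),
                 cue_max = as.integer(cue_max), stim_current = stim_current,
                 post_target_limit = as.integer(post_target_limit),
                 noise_sigma = noise_sigma),
            class = "lif_protocol")
}

#' One membrane-potential update of a LIF neuron
#'
#' `V_next = v_rest + (V - v_rest) * exp(-1/tau) + I`; if `V_next` reaches
#' the threshold the neuron spikes and the stored potential is immediately
#' reset. Vectorised over neurons.
#'
#' @param v membrane potential(s), mV.
#' @param i_input total input current(s), mV.
#' @param params a [neuron_params()].
#' @return A list with `v` (post-step potentials) and `spiked` (logical).
#' @export
step_neuron <- function(v, i_input, params = neuron_params()) {
  stopifnot(all(is.finite(v)), all(is.finite(i_input)))
  v_next <- params$v_rest + (v - params$v_rest) * exp(-1 / params$tau) + i_input
  spiked <- v_next >= params$v_threshold
  v_next[spiked] <- params$v_reset
  list(v = v_next, spiked = spiked)
}

weight_matrix <- function(genome, arch) {
  n <- arch$n_neurons
  w <- matrix(0, n, n)
  k <- n + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      w[i, j] <- genome[k]
      k <- k + 1L
    }
  }
  w
}

#' Synchronous network update (reference implementation)
#'
#' Computes each neuron's input -- bias, external stimulus current, weights
#' from neurons that spiked on the previous step, plus optional noise draws
#' -- and applies [step_neuron()] to all neurons at once. This is the plain-R
#' reference used in tests; large runs go through the compiled population
#' evaluator in [evaluate_lif_task()].
#'
#' @param v membrane potentials (length `n_neurons`).
#' @param prev_spiked logical vector, spikes emitted on the previous step.
#' @param genome numeric genome (biases then weights, see
#'   [lif_architecture()]).
#' @param arch a [lif_architecture()].
#' @param external external current per neuron (e.g. 5 on a stimulated
#'   input neuron, 0 elsewhere).
#' @param noise per-neuron noise currents (default 0).
#' @inheritParams step_neuron
#' @return A list with `v` and `spiked`.
#' @export
step_lif_network <- function(v, prev_spiked, genome, arch, external = 0,
                             noise = 0, params = neuron_params()) {
  n <- arch$n_neurons
  if (length(v) != n || length(prev_spiked) != n) {
    stop("state dimensions do not match the architecture", call. = FALSE)
  }
  if (length(genome) != arch$genome_length) {
    stop("genome length does not match the architecture", call. = FALSE)
  }
  w <- weight_matrix(genome, arch)
  i_syn <- as.numeric(crossprod(w, as.numeric(prev_spiked)))
  i_tot <- genome[seq_len(n)] + rep_len(external, n) + i_syn +
    rep_len(noise, n)
  step_neuron(v, i_tot, params)
}

cue_neuron_index <- function(cue) {
  unname(c(left = 1L, neutral = 2L, right = 3L)[cue])
}

target_neuron_index <- function(target_side) {
  unname(c(left = 4L, right = 5L)[target_side])
}

#' Run one motor-model trial (reference implementation)
#'
#' Pure-R trial loop over [step_lif_network()]: reset to rest, `pre_cue`
#' silent units, cue stimulation for `cue_duration` units, then target
#' stimulation in addition to the cue, ending at the first output spike or
#' after `post_target_limit` target-stimulated units. The reaction time is
#' the response step minus the target-onset step, so the earliest response
#' mediated by a target-neuron spike has `rt = 1` (the discrete-time floor);
#' a response at or before onset (`rt <= 0`) is not target-driven and is
#' anticipated. In CRT, a response from the output on the target's side
#' is correct, from the other output incorrect; simultaneous output spikes
#' are resolved by a fair coin.
#'
#' @inheritParams step_lif_network
#' @param cue `"left"`, `"neutral"` or `"right"`.
#' @param target_side `"left"` or `"right"`.
#' @param protocol a [lif_protocol()].
#' @param cue_duration optional fixed cue duration; drawn uniformly from
#'   `[cue_min, cue_max]` if `NULL`.
#' @return A one-row tibble: `cue`, `target_side`, `cue_type`,
#'   `cue_duration`, `rt`, `responding_output`, `outcome`, `fitness`.
#' @export
run_lif_trial <- function(genome, arch, cue, target_side,
                          protocol = lif_protocol(), cue_duration = NULL,
                          params = neuron_params()) {
  cue <- match.arg(cue, c("left", "neutral", "right"))
  target_side <- match.arg(target_side, c("left", "right"))
  if (is.null(cue_duration)) {
    cue_duration <- sample(protocol$cue_min:protocol$cue_max, 1L)
  }
  n <- arch$n_neurons
  t_first <- protocol$pre_cue + cue_duration + 1L # target-onset step
  t_end <- t_first + protocol$post_target_limit - 1L
  cn <- cue_neuron_index(cue)
  tn <- target_neuron_index(target_side)
  out_idx <- if (arch$task == "SRT") 6L else c(6L, 7L)

  v <- rep(params$v_rest, n)
  prev <- rep(FALSE, n)
  resp_t <- NA_integer_
  resp_out <- NA_integer_
  for (t in seq_len(t_end)) {
    ext <- numeric(n)
    if (t > protocol$pre_cue) ext[cn] <- protocol$stim_current
    if (t >= t_first) ext[tn] <- ext[tn] + protocol$stim_current
    noise <- if (protocol$noise_sigma > 0) {
      rnorm(n, 0, protocol$noise_sigma)
    } else 0
    st <- step_lif_network(v, prev, genome, arch, ext, noise, params)
    v <- st$v
    fired <- which(st$spiked[out_idx])
    if (length(fired) > 0L) {
      resp_t <- t
      resp_out <- if (length(fired) == 2L) {
        out_idx[if (runif(1) < 0.5) 1L else 2L]
      } else {
        out_idx[fired]
      }
      break
    }
    prev <- st$spiked
  }

  if (is.na(resp_t)) {
    rt <- NA_integer_
    outcome <- "slow"
    responding <- "none"
  } else {
    rt <- resp_t - t_first
    responding <- if (arch$task == "SRT") "single" else {
      if (resp_out == 6L) "left" else "right"
    }
    outcome <- if (rt <= 0L) {
      "anticipated"
    } else if (arch$task == "SRT" || responding == target_side) {
      "correct"
    } else {
      "incorrect"
    }
  }
  tibble(
    cue = cue, target_side = target_side,
    cue_type = classify_cue_type(cue, target_side),
    cue_duration = as.integer(cue_duration),
    rt = rt, responding_output = responding, outcome = outcome,
    fitness = fitness_of_trial(rt, outcome)
  )
}

#' Fitness awarded to one trial
#'
#' A correct response earns `1000 * exp(-0.01 * rt)`; anticipated, incorrect
#' and slow responses earn nothing.
#'
#' @param rt integer reaction time (may be `NA` for slow trials).
#' @param outcome one of `"correct"`, `"anticipated"`, `"incorrect"`,
#'   `"slow"`.
#' @return Non-negative numeric fitness, vectorised.
#' @examples
#' fitness_of_trial(100, "correct")  # 1000 * exp(-1)
#' @export
fitness_of_trial <- function(rt, outcome) {
  ifelse(outcome == "correct", 1000 * exp(-0.01 * rt), 0)
}

#' Trial list for a cue-frequency ratio
#'
#' Builds the fixed trial set of one task evaluation: for each target side,
#' the valid / neutral / invalid cue appears `cue_ratio[1:3]` times, so the
#' 8:5:2 ratio gives 30 trials and 8:8:2 gives 36.
#'
#' @param cue_ratio integer vector `c(valid, neutral, invalid)`.
#' @return A tibble with columns `cue`, `target_side`, `cue_type`.
#' @examples
#' nrow(lif_task_trials(c(8, 5, 2)))  # 30
#' @export
lif_task_trials <- function(cue_ratio = c(8, 5, 2)) {
  stopifnot(length(cue_ratio) == 3, all(cue_ratio >= 0))
  per_side <- function(side) {
    other <- if (side == "left") "right" else "left"
    tibble(
      cue = c(rep(side, cue_ratio[1]), rep("neutral", cue_ratio[2]),
              rep(other, cue_ratio[3])),
      target_side = side
    )
  }
  out <- bind_rows(per_side("left"), per_side("right"))
  out$cue_type <- classify_cue_type(out$cue, out$target_side)
  out
}

#' Evaluate genomes on a reaction-time task (compiled evaluator)
#'
#' Runs every genome through the full trial list via the compiled LIF
#' simulator and returns per-trial reaction times, outcome classes and the
#' summed fitness. Cue durations are drawn independently per (genome, trial)
#' unless a fixed matrix is supplied (used for deterministic objectives in
#' tests). Uses R's RNG; seed with `set.seed()`.
#'
#' @param genomes a numeric matrix (one genome per row) or a single genome
#'   vector.
#' @param arch a [lif_architecture()].
#' @param trials a trial list from [lif_task_trials()].
#' @param protocol a [lif_protocol()] (carries `noise_sigma`).
#' @param params a [neuron_params()].
#' @param cue_durations optional integer matrix
#'   (`n_genomes` x `n_trials`) of fixed cue durations.
#' @return A list with `fitness` (numeric vector), `rt` and `outcome`
#'   (integer matrices, `n_genomes` x `n_trials`; outcome codes 0 correct,
#'   1 anticipated, 2 incorrect, 3 slow) and the `trials` tibble.
#' @export
evaluate_lif_task <- function(genomes, arch, trials,
                              protocol = lif_protocol(),
                              params = neuron_params(),
                              cue_durations = NULL) {
  if (is.vector(genomes)) genomes <- matrix(genomes, nrow = 1L)
  if (ncol(genomes) != arch$genome_length) {
    stop("genome length does not match the architecture", call. = FALSE)
  }
  cd <- if (is.null(cue_durations)) {
    matrix(integer(), 0, 0)
  } else {
    storage.mode(cue_durations) <- "integer"
    cue_durations
  }
  res <- eval_lif_population_cpp(
    genomes, crt = arch$task == "CRT",
    cue_neuron = cue_neuron_index(trials$cue) - 1L,
    target_neuron = target_neuron_index(trials$target_side) - 1L,
    noise_sigma = protocol$noise_sigma,
    pre_cue = protocol$pre_cue, cue_min = protocol$cue_min,
    cue_max = protocol$cue_max, stim_current = protocol$stim_current,
    post_target_limit = protocol$post_target_limit,
    v_rest = params$v_rest, v_reset = params$v_reset,
    v_threshold = params$v_threshold, tau = params$tau,
    cue_durations = cd
  )
  res$trials <- trials
  res
}

outcome_labels <- c("correct", "anticipated", "incorrect", "slow")

#' Tidy per-trial results of a task evaluation
#'
#' @param eval_result the list returned by [evaluate_lif_task()].
#' @return A tibble with one row per (individual, trial): `individual`,
#'   `trial`, `cue`, `target_side`, `cue_type`, `rt`, `outcome`, `fitness`.
#' @export
lif_trial_results <- function(eval_result) {
  n_ind <- nrow(eval_result$rt)
  n_tr <- ncol(eval_result$rt)
  trials <- eval_result$trials
  out <- tibble(
    individual = rep(seq_len(n_ind), times = n_tr),
    trial = rep(seq_len(n_tr), each = n_ind),
    cue = rep(trials$cue, each = n_ind),
    target_side = rep(trials$target_side, each = n_ind),
    cue_type = rep(trials$cue_type, each = n_ind),
    rt = as.vector(eval_result$rt),
    outcome = outcome_labels[as.vector(eval_result$outcome) + 1L]
  )
  out$fitness <- fitness_of_trial(out$rt, out$outcome)
  arrange(out, .data$individual, .data$trial)
}

#' Save and load genomes as flat CSV vectors
#'
#' Writes one genome per row with a header naming the architecture
#' (`task` column plus `g1..gL` gene columns), so files are self-describing
#' and portable.
#'
#' @param genomes a numeric matrix (one genome per row) or single genome
#'   vector.
#' @param arch a [lif_architecture()].
#' @param path file path.
#' @return `write_genomes()` returns `path` invisibly; `read_genomes()`
#'   returns a list with `arch` and the genome matrix `genomes`.
#' @export
write_genomes <- function(genomes, arch, path) {
  if (is.vector(genomes)) genomes <- matrix(genomes, nrow = 1L)
  stopifnot(ncol(genomes) == arch$genome_length)
  df <- data.frame(task = arch$task, genomes)
  names(df) <- c("task", paste0("g", seq_len(arch$genome_length)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genomes
#' @export
read_genomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  arch <- lif_architecture(df$task[1])
  g <- as.matrix(df[, -1, drop = FALSE])
  dimnames(g) <- NULL
  if (ncol(g) != arch$genome_length) {
    stop("genome columns do not match the architecture in the header",
         call. = FALSE)
  }
  list(arch = arch, genomes = g)
}
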