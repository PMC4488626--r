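# shared fixtures, all generated in code

random_history <- function(n, s = 0.5, sigma = 2, signal_side = NULL,
                           onset = NULL) {
  mu_l <- rep(0, n)
  mu_r <- rep(0, n)
  if (!is.null(signal_side)) {
    on <- seq_len(n) >= onset
    if (signal_side == "left") mu_l[on] <- s else mu_r[on] <- s
  }
  data.frame(s_left = rnorm(n, mu_l, sigma), s_right = rnorm(n, mu_r, sigma))
}

chain_posteriors <- function(history, config) {
  st <- bayes_init(config)
  out <- vector("list", nrow(history))
  for (i in seq_len(nrow(history))) {
    st <- bayes_update(st, history$s_left[i], history$s_right[i], config)
    out[[i]] <- bayes_posteriors(st, config)
  }
  dplyr::bind_rows(out)
}

# a hand-built SRT genome that responds one step after target onset:
# input neurons biased just below their firing point, a saturated
# target->output synapse, output biased just below threshold
optimal_srt_genome <- function() {
  arch <- lif_architecture("SRT")
  g <- numeric(arch$genome_length)
  g[4] <- 2.3  # target_left bias: steady state ~ rest + 24.2 < 25
  g[5] <- 2.3  # target_right bias
  g[6] <- 2.2  # output bias: steady state ~ rest + 23.1 < 25
  w_idx <- function(i, j, n = 6) {
    # row-major over ordered pairs (i, j), i != j, after the n biases
    n + (i - 1) * (n - 1) + j - (j > i)
  }
  g[w_idx(4, 6)] <- 2.9
  g[w_idx(5, 6)] <- 2.9
  g
}

tiny_ga <- function(generations = 5L, ...) {
  ga_config(n_populations = 2L, pop_size = 8L, generations = generations, ...)
}
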