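test_that("membrane update follows the leaky integrator with threshold reset", {
  p <- neuron_params()
  # rest is a fixed point
  st <- step_neuron(-65, 0, p)
  expect_equal(st$v, -65)
  expect_false(st$spiked)

  # one decay step from -55 with no input
  st <- step_neuron(-55, 0, p)
  expect_equal(st$v, -65 + 10 * exp(-0.1))
  expect_false(st$spiked)

  # -65 + 20 * exp(-0.1) + 10 = -36.90 crosses -40: spike and reset
  st <- step_neuron(-45, 10, p)
  expect_true(st$spiked)
  expect_equal(st$v, -65)
})

test_that("decay contracts toward rest and stored potentials stay subthreshold", {
  p <- neuron_params()
  set.seed(31)
  v <- runif(200, -80, -40.01)
  st <- step_neuron(v, 0, p)
  keep <- v != p$v_rest
  expect_true(all(abs(st$v - p$v_rest)[keep] < abs(v - p$v_rest)[keep]))

  # random inputs: the post-step potential never sits at/above threshold
  for (rep in 1:20) {
    st <- step_neuron(runif(50, -80, -41), rnorm(50, 0, 10), p)
    expect_true(all(st$v < p$v_threshold))
  }
})

test_that("architectures have the documented sizes", {
  srt <- lif_architecture("SRT")
  crt <- lif_architecture("CRT")
  expect_equal(c(srt$n_neurons, srt$n_synapses, srt$genome_length),
               c(6, 30, 36))
  expect_equal(c(crt$n_neurons, crt$n_synapses, crt$genome_length),
               c(7, 42, 49))
})

test_that("network stepping delivers synaptic current one step after a spike", {
  arch <- lif_architecture("SRT")
  p <- neuron_params()
  # an all-zero genome with no stimulus never leaves rest
  v <- rep(p$v_rest, 6)
  prev <- rep(FALSE, 6)
  g0 <- numeric(arch$genome_length)
  for (t in 1:50) {
    st <- step_lif_network(v, prev, g0, arch)
    expect_true(all(st$v == p$v_rest))
    expect_false(any(st$spiked))
    v <- st$v; prev <- st$spiked
  }

  # a single weight w from a neuron that spiked last step adds exactly w
  g <- numeric(arch$genome_length)
  g[6 + 3 * 5 + 5] <- 1.7  # weight target_left (4) -> output (6)
  prev <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  st <- step_lif_network(rep(p$v_rest, 6), prev, g, arch)
  expect_equal(st$v[6], p$v_rest + 1.7)
  expect_equal(st$v[-6], rep(p$v_rest, 5))

  expect_error(step_lif_network(rep(p$v_rest, 5), prev, g, arch),
               "dimensions")
  expect_error(step_lif_network(rep(p$v_rest, 6), prev, g[-1], arch),
               "genome length")
})

test_that("a constant bias accumulates as the geometric series predicts", {
  arch <- lif_architecture("SRT")
  p <- neuron_params()
  b <- 3
  g <- numeric(arch$genome_length)
  g[6] <- b  # output bias only
  d <- exp(-1 / p$tau)
  predicted <- which(b * (1 - d^(1:100)) / (1 - d) >=
                       p$v_threshold - p$v_rest)[1]
  v <- rep(p$v_rest, 6)
  prev <- rep(FALSE, 6)
  first_spike <- NA
  for (t in 1:100) {
    st <- step_lif_network(v, prev, g, arch)
    if (st$spiked[6]) { first_spike <- t; break }
    v <- st$v; prev <- st$spiked
  }
  expect_equal(first_spike, predicted)
})

test_that("trials classify slow, anticipated and optimal responses", {
  arch <- lif_architecture("SRT")
  # strongly inhibited network never responds
  g_neg <- rep(-2.5, arch$genome_length)
  res <- run_lif_trial(g_neg, arch, "neutral", "left", cue_duration = 120)
  expect_equal(res$outcome, "slow")
  expect_equal(res$responding_output, "none")
  expect_true(is.na(res$rt))
  expect_equal(res$fitness, 0)

  # over-excited output fires during the cue period
  g_ant <- numeric(arch$genome_length)
  g_ant[6] <- 3
  res <- run_lif_trial(g_ant, arch, "neutral", "left", cue_duration = 120)
  expect_equal(res$outcome, "anticipated")
  expect_lte(res$rt, 0)
  expect_equal(res$fitness, 0)

  # the hand-built near-threshold genome reaches the discrete-time floor
  res <- run_lif_trial(optimal_srt_genome(), arch, "left", "left",
                       cue_duration = 150)
  expect_equal(res$outcome, "correct")
  expect_equal(res$rt, 1)
  expect_equal(res$fitness, 1000 * exp(-0.01))
})

test_that("fitness rewards only fast correct responses", {
  expect_equal(fitness_of_trial(-5, "anticipated"), 0)
  expect_equal(fitness_of_trial(0, "correct"), 1000)
  expect_equal(fitness_of_trial(100, "correct"), 1000 * exp(-1))
  expect_equal(fitness_of_trial(NA, "slow"), 0)
  expect_equal(fitness_of_trial(10, "incorrect"), 0)
})

test_that("trial lists realise the cue-frequency ratios exactly", {
  t852 <- lif_task_trials(c(8, 5, 2))
  expect_equal(nrow(t852), 30)
  counts <- table(t852$cue_type, t852$target_side)
  expect_true(all(counts["valid", ] == 8))
  expect_true(all(counts["neutral", ] == 5))
  expect_true(all(counts["invalid", ] == 2))

  t882 <- lif_task_trials(c(8, 8, 2))
  expect_equal(nrow(t882), 36)
  expect_equal(as.vector(table(t882$cue_type)[c("valid", "neutral", "invalid")]),
               c(16, 16, 4))
})

test_that("compiled evaluator agrees with the R reference on deterministic trials", {
  set.seed(33)
  for (task in c("SRT", "CRT")) {
    arch <- lif_architecture(task)
    trials <- lif_task_trials(c(2, 1, 1))
    genomes <- matrix(runif(3 * arch$genome_length, -3, 3), nrow = 3)
    genomes <- rbind(genomes,
                     if (task == "SRT") optimal_srt_genome() else
                       runif(arch$genome_length, -1, 1))
    cd <- matrix(sample(100:200, nrow(genomes) * nrow(trials), replace = TRUE),
                 nrow(genomes), nrow(trials))
    res <- evaluate_lif_task(genomes, arch, trials, cue_durations = cd)
    for (i in seq_len(nrow(genomes))) {
      for (j in seq_len(nrow(trials))) {
        ref <- run_lif_trial(genomes[i, ], arch, trials$cue[j],
                             trials$target_side[j], cue_duration = cd[i, j])
        expect_equal(res$rt[i, j],
                     ifelse(is.na(ref$rt), NA_integer_, ref$rt))
        expect_equal(outcome_labels[res$outcome[i, j] + 1L], ref$outcome)
      }
    }
    # total fitness is the sum of per-trial fitness
    tr <- lif_trial_results(res)
    expect_equal(res$fitness,
                 as.numeric(tapply(tr$fitness, tr$individual, sum)))
  }
})

test_that("noisy evaluations are reproducible from the seed", {
  arch <- lif_architecture("CRT")
  trials <- lif_task_trials(c(2, 2, 1))
  g <- matrix(runif(2 * arch$genome_length, -3, 3), nrow = 2)
  prot <- lif_protocol(noise_sigma = 2)
  set.seed(55)
  a <- evaluate_lif_task(g, arch, trials, prot)
  set.seed(55)
  b <- evaluate_lif_task(g, arch, trials, prot)
  expect_identical(a$rt, b$rt)
  expect_identical(a$outcome, b$outcome)
  expect_identical(a$fitness, b$fitness)
})

test_that("genomes round-trip through the CSV interchange format", {
  arch <- lif_architecture("CRT")
  set.seed(71)
  g <- matrix(runif(3 * arch$genome_length, -3, 3), nrow = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genomes(g, arch, path)
  back <- read_genomes(path)
  expect_equal(back$arch$task, "CRT")
  expect_equal(back$genomes, g, tolerance = 1e-12)
  expect_error(write_genomes(g[, -1], arch, path))
})
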