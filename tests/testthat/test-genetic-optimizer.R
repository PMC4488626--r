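test_that("initial populations are uniform on the gene interval", {
  ga <- ga_config()
  set.seed(41)
  pops <- init_populations(ga, 36)
  expect_length(pops, 5)
  expect_true(all(vapply(pops, function(p) all(dim(p) == c(20, 36)),
                         logical(1))))
  genes <- unlist(pops)
  expect_true(all(genes >= -3 & genes < 3))
  # uniformity: mean near 0, spread near the uniform SD
  expect_lt(abs(mean(genes)), 0.1)
  expect_lt(abs(sd(genes) - 6 / sqrt(12)), 0.1)

  set.seed(41)
  expect_identical(init_populations(ga, 36), pops)
})

test_that("tournaments pick the fitter entrant and favour high ranks overall", {
  set.seed(42)
  expect_equal(tournament_select(c(10, 5)), 1L)
  expect_equal(tournament_select(7), 1L)

  fit <- 1:5
  picks <- tabulate(replicate(5000, tournament_select(fit)), 5)
  expect_true(all(diff(picks) > 0))
  # with two distinct entrants, rank k wins with probability (k-1)/C(n,2)
  expect_lt(max(abs(picks / 5000 - (0:4) / 10)), 0.025)
})

test_that("crossover copies each gene from a uniformly chosen parent", {
  a <- rep(1, 1e4)
  b <- rep(2, 1e4)
  set.seed(43)
  child <- crossover_uniform(a, b)
  expect_true(all(child %in% c(1, 2)))
  expect_equal(mean(child == 1), 0.5, tolerance = 0.02)

  expect_identical(crossover_uniform(a, a), a)
  expect_error(crossover_uniform(a, b[-1]), "length")
})

test_that("mutation hits ~5% of genes and respects the half-open gene interval", {
  ga <- ga_config()
  g <- rep(0, 1e4)
  set.seed(44)
  mutated <- mutate_genome(g, ga)
  frac <- mean(mutated != 0)
  expect_equal(frac, 0.05, tolerance = 0.015)
  expect_true(all(abs(mutated - g) < 0.3))

  expect_identical(mutate_genome(g, ga_config(mutation_rate = 0)), g)

  # forced mutation at the boundary is clipped below the open upper end
  push <- ga_config(mutation_rate = 1, mutation_min = 0.2, mutation_max = 0.2)
  out <- mutate_genome(rep(2.95, 100), push)
  expect_true(all(out < 3))
  out_low <- mutate_genome(rep(-2.95, 100),
                           ga_config(mutation_rate = 1, mutation_min = -0.2,
                                     mutation_max = -0.2))
  expect_true(all(out_low >= -3))
})

test_that("breeding preserves the elite and the population size", {
  ga <- ga_config(pop_size = 20)
  set.seed(45)
  pop <- matrix(runif(20 * 10, -3, 3), 20, 10)
  fit <- runif(20)
  nxt <- next_generation(pop, fit, ga)
  expect_equal(dim(nxt), dim(pop))
  expect_equal(nxt[1, ], pop[which.max(fit), ])
  expect_true(all(nxt >= -3 & nxt < 3))

  # without mutation an all-identical population stays identical
  clone <- matrix(1, 20, 10)
  nxt2 <- next_generation(clone, rep(5, 20), ga_config(mutation_rate = 0))
  expect_true(all(nxt2 == 1))
})

test_that("migration copies elites between islands without changing sizes", {
  ga <- ga_config(pop_size = 6, n_populations = 3)
  set.seed(46)
  pops <- init_populations(ga, 8)
  pops <- lapply(pops, function(p) p[1:6, , drop = FALSE])
  fits <- lapply(1:3, function(p) runif(6))
  mig <- migrate_populations(pops, fits, ga)
  expect_true(all(vapply(mig$populations, nrow, integer(1)) == 6))
  # every source island still contains its own elite genome
  for (p in 1:3) {
    elite <- pops[[p]][which.max(fits[[p]]), ]
    found <- any(apply(mig$populations[[p]], 1,
                       function(row) all(row == elite)))
    expect_true(found)
  }
  # all island genes remain in range
  expect_true(all(unlist(mig$populations) >= -3 &
                    unlist(mig$populations) < 3))

  single <- migrate_populations(pops[1], fits[1], ga)
  expect_identical(single$populations, pops[1])
})

test_that("elite fitness is non-decreasing under a frozen deterministic task", {
  ev <- evolve_networks(lif_architecture("SRT"), lif_task_trials(c(2, 1, 1)),
                        lif_protocol(noise_sigma = 0),
                        tiny_ga(generations = 15L), seed = 47,
                        freeze_cue_durations = TRUE)
  for (p in unique(ev$history$population)) {
    best <- ev$history$best_fitness[ev$history$population == p]
    expect_true(all(diff(best) >= -1e-9))
  }
})

test_that("evolution runs are reproducible from the seed and stay in bounds", {
  arch <- lif_architecture("SRT")
  trials <- lif_task_trials(c(2, 1, 1))
  prot <- lif_protocol(noise_sigma = 2)
  a <- evolve_networks(arch, trials, prot, tiny_ga(), seed = 48)
  b <- evolve_networks(arch, trials, prot, tiny_ga(), seed = 48)
  expect_identical(a$history, b$history)
  expect_identical(a$populations, b$populations)

  genes <- unlist(a$populations)
  expect_true(all(genes >= -3 & genes < 3))
  expect_true(all(vapply(a$populations, nrow, integer(1)) == 8))
  # one history row per (generation, population)
  expect_equal(nrow(a$history), 6 * 2)
})
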