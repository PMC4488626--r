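#' Island-model genetic algorithm settings
#'
#' Defaults follow the evolutionary setup used for the motor model: 100
#' genomes split into 5 islands of 20, one elite copied unchanged per island
#' per generation, parents picked by size-2 tournaments, uniform crossover,
#' per-gene mutation with probability 0.05 adding a uniform draw from
#' `[-0.3, 0.3)` (genes clipped back into `[-3, 3)`), and the fittest genome
#' of every island migrating to a random other island every 10 generations.
#'
#' @param n_populations number of islands.
#' @param pop_size individuals per island.
#' @param generations breeding steps of a full run.
#' @param elite_count elites copied unchanged (1).
#' @param tournament_size entrants per tournament (2, drawn without
#'   replacement within a tournament).
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_min,mutation_max bounds of the uniform mutation increment.
#' @param gene_min,gene_max gene bounds; the interval is half-open at
#'   `gene_max`.
#' @param migration_interval generations between migrations.
#' @return A named list of class `ga_config`.
#' @export
ga_config <- function(n_populations = 5L, pop_size = 20L, generations = 300L,
                      elite_count = 1L, tournament_size = 2L,
                      mutation_rate = 0.05, mutation_min = -0.3,
                      mutation_max = 0.3, gene_min = -3, gene_max = 3,
                      migration_interval = 10L) {
  stopifnot(pop_size > elite_count, mutation_rate >= 0, mutation_rate <= 1,
            gene_min < gene_max, mutation_min <= mutation_max,
            tournament_size >= 1, migration_interval >= 1)
  structure(
    list(n_populations = as.integer(n_populations),
         pop_size = as.integer(pop_size),
         generations = as.integer(generations),
         elite_count = as.integer(elite_count),
         tournament_size = as.integer(tournament_size),
         mutation_rate = mutation_rate,
         mutation_min = mutation_min, mutation_max = mutation_max,
         gene_min = gene_min, gene_max = gene_max,
         migration_interval = as.integer(migration_interval)),
    class = "ga_config"
  )
}

# genes live in [gene_min, gene_max); clip keeps mutated values inside with
# the upper end open
clip_genes <- function(x, ga) {
  pmin(pmax(x, ga$gene_min), ga$gene_max * (1 - 1e-12))
}

#' Random initial populations
#'
#' Every gene is drawn i.i.d. uniform on `[gene_min, gene_max)`.
#'
#' @param ga a [ga_config()].
#' @param genome_length genes per genome (see [lif_architecture()]).
#' @return A list of `n_populations` matrices, each
#'   `pop_size x genome_length`.
#' @export
init_populations <- function(ga, genome_length) {
  stopifnot(genome_length > 0)
  lapply(seq_len(ga$n_populations), function(p) {
    matrix(runif(ga$pop_size * genome_length, ga$gene_min, ga$gene_max),
           nrow = ga$pop_size, ncol = genome_length)
  })
}

#' Tournament selection
#'
#' Draws `tournament_size` distinct individuals uniformly from one island
#' and returns the index of the fittest; exact fitness ties are broken
#' uniformly at random. Successive tournaments draw with replacement.
#'
#' @param fitness numeric fitness vector of one island.
#' @param size entrants per tournament.
#' @return The selected individual's index.
#' @export
tournament_select <- function(fitness, size = 2L) {
  n <- length(fitness)
  if (n == 1L) return(1L)
  entrants <- sample.int(n, min(size, n))
  f <- fitness[entrants]
  winners <- entrants[f == max(f)]
  if (length(winners) == 1L) winners else winners[sample.int(length(winners), 1L)]
}

#' Uniform crossover
#'
#' Each gene is copied from a uniformly chosen parent, independently per
#' gene.
#'
#' @param parent_a,parent_b numeric genomes of equal length.
#' @return The child genome.
#' @export
crossover_uniform <- function(parent_a, parent_b) {
  if (length(parent_a) != length(parent_b)) {
    stop("parent genomes differ in length", call. = FALSE)
  }
  from_a <- runif(length(parent_a)) < 0.5
  ifelse(from_a, parent_a, parent_b)
}

#' Per-gene mutation
#'
#' With probability `mutation_rate` a gene receives a uniform increment from
#' `[mutation_min, mutation_max)` and is clipped back into
#' `[gene_min, gene_max)`.
#'
#' @param genome numeric genome.
#' @inheritParams init_populations
#' @return The mutated genome.
#' @export
mutate_genome <- function(genome, ga) {
  hit <- runif(length(genome)) < ga$mutation_rate
  n_hit <- sum(hit)
  if (n_hit > 0L) {
    genome[hit] <- genome[hit] + runif(n_hit, ga$mutation_min, ga$mutation_max)
    genome <- clip_genes(genome, ga)
  }
  genome
}

#' Breed the next generation of one island
#'
#' The fittest genome is copied unchanged (row 1 of the result); the
#' remaining `pop_size - 1` children come from tournament-selected parent
#' pairs via uniform crossover followed by mutation.
#'
#' @param population `pop_size x genome_length` matrix.
#' @param fitness fitness vector aligned with the rows.
#' @inheritParams init_populations
#' @return A matrix of the same dimensions.
#' @export
next_generation <- function(population, fitness, ga) {
  stopifnot(nrow(population) == length(fitness))
  elite <- which.max(fitness)
  children <- matrix(NA_real_, ga$pop_size, ncol(population))
  children[1L, ] <- population[elite, ]
  for (k in 2:ga$pop_size) {
    pa <- tournament_select(fitness, ga$tournament_size)
    pb <- tournament_select(fitness, ga$tournament_size)
    children[k, ] <- mutate_genome(
      crossover_uniform(population[pa, ], population[pb, ]), ga
    )
  }
  children
}

#' Migration between islands
#'
#' A copy of each island's fittest genome is inserted into a uniformly
#' chosen *other* island, replacing a uniformly chosen non-elite member
#' there; the source island keeps its elite and all island sizes are
#' preserved. The migrant carries its fitness with it.
#'
#' @param populations list of island matrices.
#' @param fitness list of fitness vectors aligned with `populations`.
#' @inheritParams init_populations
#' @return A list with updated `populations` and `fitness`.
#' @export
migrate_populations <- function(populations, fitness, ga) {
  n_pop <- length(populations)
  if (n_pop < 2L) return(list(populations = populations, fitness = fitness))
  elites <- vapply(fitness, which.max, integer(1))
  migrants <- lapply(seq_len(n_pop), function(p) {
    list(genome = populations[[p]][elites[p], ], fit = fitness[[p]][elites[p]])
  })
  for (p in seq_len(n_pop)) {
    dest <- sample(setdiff(seq_len(n_pop), p), 1L)
    dest_elite <- which.max(fitness[[dest]])
    candidates <- setdiff(seq_len(nrow(populations[[dest]])), dest_elite)
    slot <- candidates[sample.int(length(candidates), 1L)]
    populations[[dest]][slot, ] <- migrants[[p]]$genome
    fitness[[dest]][slot] <- migrants[[p]]$fit
  }
  list(populations = populations, fitness = fitness)
}

individual_median_rts <- function(eval_result) {
  cts <- c("valid", "neutral", "invalid")
  sapply(cts, function(ct) {
    cols <- which(eval_result$trials$cue_type == ct)
    rtm <- eval_result$rt[, cols, drop = FALSE]
    rtm[eval_result$outcome[, cols, drop = FALSE] != 0L] <- NA_integer_
    apply(rtm, 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) NA_real_ else median(x)
    })
  })
}

#' Evolve spiking networks on a reaction-time task
#'
#' Full island-model loop: evaluate all genomes on the task (freshly drawn
#' cue durations and noise each generation), record per-island and pooled
#' statistics, copy the elite, breed children by tournament selection,
#' uniform crossover and mutation, and migrate elites every
#' `migration_interval` generations. Generation 0 is the random initial
#' population; the run ends after evaluating generation `generations`.
#'
#' @param arch a [lif_architecture()].
#' @param trials a trial list from [lif_task_trials()].
#' @param protocol a [lif_protocol()] (carries the noise level).
#' @param ga a [ga_config()].
#' @param generations number of breeding steps (defaults to
#'   `ga$generations`).
#' @param seed optional integer seed for the whole run.
#' @param freeze_cue_durations if `TRUE`, one cue-duration schedule is drawn
#'   up front and reused for every genome and generation, which (with
#'   `noise_sigma = 0`) makes the objective deterministic -- used to test
#'   elitism monotonicity.
#' @return An object of class `rt_evolution`: a list with `history`
#'   (tibble: generation, population, best_fitness, the elite's `error_rate`
#'   -- anticipated + slow + incorrect fraction -- the island's
#'   `mean_error_rate` over all its individuals, and the elite's median RT
#'   per cue type), `rt_summary` (tibble: per generation
#'   and cue type, the mean, median, SD and 95% CI over all individuals'
#'   median correct RTs, nulls excluded), final `populations` and `fitness`,
#'   and the run configuration.
#' @examples
#' \donttest{
#' ev <- evolve_networks(lif_architecture("SRT"), lif_task_trials(c(8, 5, 2)),
#'                       generations = 5, seed = 1)
#' glance(ev)
#' }
#' @export
evolve_networks <- function(arch, trials, protocol = lif_protocol(),
                            ga = ga_config(), generations = ga$generations,
                            seed = NULL, freeze_cue_durations = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n_trials <- nrow(trials)
  pops <- init_populations(ga, arch$genome_length)
  frozen_cd <- if (freeze_cue_durations) {
    cd <- sample(protocol$cue_min:protocol$cue_max, n_trials, replace = TRUE)
    matrix(cd, nrow = ga$n_populations * ga$pop_size, ncol = n_trials,
           byrow = TRUE)
  } else NULL

  hist_rows <- vector("list", generations + 1L)
  rt_rows <- vector("list", generations + 1L)
  pop_id <- rep(seq_len(ga$n_populations), each = ga$pop_size)

  for (gen in 0:generations) {
    all_genomes <- do.call(rbind, pops)
    ev <- evaluate_lif_task(all_genomes, arch, trials, protocol,
                            cue_durations = frozen_cd)
    fit_by_pop <- split(ev$fitness, pop_id)

    err_all <- rowMeans(ev$outcome != 0L)
    med <- individual_median_rts(ev)
    elite_idx <- vapply(seq_len(ga$n_populations), function(p) {
      (p - 1L) * ga$pop_size + which.max(fit_by_pop[[p]])
    }, integer(1))
    hist_rows[[gen + 1L]] <- tibble(
      generation = gen,
      population = seq_len(ga$n_populations),
      best_fitness = vapply(fit_by_pop, max, numeric(1)),
      error_rate = err_all[elite_idx],
      mean_error_rate = vapply(split(err_all, pop_id), mean, numeric(1)),
      median_rt_valid = med[elite_idx, "valid"],
      median_rt_neutral = med[elite_idx, "neutral"],
      median_rt_invalid = med[elite_idx, "invalid"]
    )
    rt_rows[[gen + 1L]] <- summarise_median_matrix(med, gen)

    if (gen == generations) break

    if (gen > 0L && gen %% ga$migration_interval == 0L) {
      mig <- migrate_populations(pops, fit_by_pop, ga)
      pops <- mig$populations
      fit_by_pop <- mig$fitness
    }
    pops <- lapply(seq_len(ga$n_populations), function(p) {
      next_generation(pops[[p]], fit_by_pop[[p]], ga)
    })
  }

  structure(
    list(history = bind_rows(hist_rows), rt_summary = bind_rows(rt_rows),
         populations = pops,
         fitness = fit_by_pop,
         arch = arch, trials = trials, protocol = protocol, ga = ga,
         generations = generations, seed = seed),
    class = "rt_evolution"
  )
}

summarise_median_matrix <- function(med, gen) {
  bind_rows(lapply(colnames(med), function(ct) {
    x <- med[, ct]
    x <- x[!is.na(x)]
    n <- length(x)
    tibble(
      generation = gen, cue_type = ct, n = n,
      mean_median_rt = if (n > 0L) mean(x) else NA_real_,
      median_median_rt = if (n > 0L) median(x) else NA_real_,
      sd_median_rt = if (n > 1L) sd(x) else NA_real_,
      ci95_half_width = if (n > 1L) qnorm(0.975) * sd(x) / sqrt(n) else NA_real_
    )
  }))
}
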