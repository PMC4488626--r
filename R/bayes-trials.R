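cue_to_rho <- function(cue) {
  unname(c(left = 0.8, neutral = 0.5, right = 0.2)[cue])
}

classify_cue_type <- function(cue, target_side) {
  dplyr::case_when(
    cue == "neutral" ~ "neutral",
    cue == target_side ~ "valid",
    TRUE ~ "invalid"
  )
}

#' Simulate one trial of the Bayesian observer
#'
#' Draws a target onset time (uniform on `1..t_max`) and side (per the
#' cue-implied prior), streams stimulus pairs through [bayes_update()], and
#' responds at the first step the task's rule fires: in SRT when the summed
#' posterior reaches `gamma`, in CRT when either side's posterior does (a
#' simultaneous crossing is resolved by a fair coin). The trial ends at the
#' response; a CRT trial with no response by `t_deadline` is slow. The
#' reaction time is measured from target onset, so an anticipation has a
#' negative `rt`.
#'
#' Random draws occur in a fixed order (onset time, target side, then per
#' step the left and right stimulus, then any tie-break coin), so results are
#' reproducible under `set.seed()`.
#'
#' @inheritParams prior_appearance
#' @param cue `"left"`, `"neutral"` or `"right"`; sets the prior
#'   `rho` to 0.8, 0.5 or 0.2 (probability the target appears on the left).
#' @return A one-row tibble: `cue`, `cue_type`, `target_side`, `target_time`,
#'   `response_side`, `rt`, `outcome`.
#' @examples
#' set.seed(1)
#' simulate_bayes_trial(bayes_config(s = 5, gamma = 0.8), cue = "left")
#' @export
simulate_bayes_trial <- function(config, cue = c("neutral", "left", "right")) {
  cue <- match.arg(cue)
  cfg <- config
  cfg$rho <- cue_to_rho(cue)

  target_time <- sample.int(cfg$t_max, 1L)
  target_side <- if (runif(1) < cfg$rho) "left" else "right"

  state <- bayes_init(cfg)
  t_limit <- if (cfg$task == "SRT") cfg$t_max else cfg$t_deadline
  response_t <- NA_integer_
  response_side <- NA_character_

  for (t in seq_len(t_limit)) {
    mu_l <- if (target_side == "left" && t >= target_time) cfg$s else 0
    mu_r <- if (target_side == "right" && t >= target_time) cfg$s else 0
    s_l <- rnorm(1, mu_l, cfg$sigma)
    s_r <- rnorm(1, mu_r, cfg$sigma)
    state <- bayes_update(state, s_l, s_r, cfg)
    # threshold test on the unnormalised accumulators (g >= gamma * total):
    # algebraically the posterior rule, but exact when the no-target mass
    # hits zero at t_max
    g_none <- state$f_bar * max(0, 1 - state$t_now / cfg$t_max)
    total <- state$g_left + state$g_right + g_none
    if (cfg$task == "SRT") {
      if (state$g_left + state$g_right >= cfg$gamma * total) {
        response_t <- t
        break
      }
    } else {
      hit_l <- state$g_left >= cfg$gamma * total
      hit_r <- state$g_right >= cfg$gamma * total
      if (hit_l || hit_r) {
        response_t <- t
        response_side <- if (hit_l && hit_r) {
          if (runif(1) < 0.5) "left" else "right"
        } else if (hit_l) "left" else "right"
        break
      }
    }
  }

  rt <- if (is.na(response_t)) NA_integer_ else response_t - target_time
  if (cfg$task == "CRT" && is.na(response_t)) response_side <- "none"
  outcome <- classify_bayes_outcome(cfg$task, rt, response_side, target_side)
  tibble(
    cue = cue,
    cue_type = classify_cue_type(cue, target_side),
    target_side = target_side,
    target_time = target_time,
    response_side = response_side,
    rt = rt,
    outcome = outcome
  )
}

classify_bayes_outcome <- function(task, rt, response_side, target_side) {
  if (task == "SRT") {
    return(ifelse(is.na(rt), "slow", ifelse(rt < 0, "anticipated", "correct")))
  }
  dplyr::case_when(
    is.na(rt) ~ "slow",
    rt < 0 ~ "anticipated",
    response_side == target_side ~ "correct",
    TRUE ~ "incorrect"
  )
}

#' Simulate a block of Bayesian-observer trials
#'
#' Vectorised Monte-Carlo engine: all trials advance in lockstep through
#' time, carrying the sequential-update accumulators as vectors, so runs of
#' 10^5 trials take seconds. Cues are drawn per trial from the configured mix
#' (default half lateral -- split evenly left/right -- and half neutral, the
#' standard Posner block structure); the target side then follows the
#' cue-implied prior. With `n_trials = 1` and a fixed `cue`, the stream of
#' random draws matches [simulate_bayes_trial()] exactly.
#'
#' @inheritParams prior_appearance
#' @param n_trials number of trials to simulate.
#' @param cue optional fixed cue (`"left"`, `"neutral"`, `"right"`); if
#'   `NULL`, cues are drawn from `p_lateral`.
#' @param p_lateral probability that a trial has a lateral (left or right)
#'   cue rather than a neutral one; lateral cues are split evenly.
#' @return A tibble with one row per trial, columns as in
#'   [simulate_bayes_trial()] plus `trial`.
#' @examples
#' set.seed(1)
#' trials <- simulate_bayes_trials(bayes_config(s = 5, gamma = 0.8), 200)
#' summarize_bayes_trials(trials)
#' @export
simulate_bayes_trials <- function(config, n_trials, cue = NULL,
                                  p_lateral = 0.5) {
  stopifnot(n_trials >= 0)
  n <- as.integer(n_trials)
  if (n == 0L) {
    return(tibble(trial = integer(), cue = character(),
                  cue_type = character(), target_side = character(),
                  target_time = integer(), response_side = character(),
                  rt = integer(), outcome = character()))
  }
  cfg <- config
  if (is.null(cue)) {
    cues <- sample(c("left", "right", "neutral"), n, replace = TRUE,
                   prob = c(p_lateral / 2, p_lateral / 2, 1 - p_lateral))
  } else {
    cues <- rep(match.arg(cue, c("neutral", "left", "right")), n)
  }
  rho <- cue_to_rho(cues)
  target_time <- sample.int(cfg$t_max, n, replace = TRUE)
  target_left <- runif(n) < rho

  # lockstep state
  g_l <- numeric(n)
  g_r <- numeric(n)
  fb <- rep(1, n)
  resp_t <- rep(NA_integer_, n)
  resp_left <- rep(NA, n)
  active <- rep(TRUE, n)
  t_limit <- if (cfg$task == "SRT") cfg$t_max else cfg$t_deadline
  v2 <- 2 * cfg$sigma^2
  is_srt <- cfg$task == "SRT"

  for (t in seq_len(t_limit)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    on <- t >= target_time[idx]
    mu_l <- ifelse(target_left[idx] & on, cfg$s, 0)
    mu_r <- ifelse(!target_left[idx] & on, cfg$s, 0)
    s_l <- rnorm(length(idx), mu_l, cfg$sigma)
    s_r <- rnorm(length(idx), mu_r, cfg$sigma)

    e_l0 <- exp(-s_l^2 / v2)
    e_ls <- exp(-(s_l - cfg$s)^2 / v2)
    e_r0 <- exp(-s_r^2 / v2)
    e_rs <- exp(-(s_r - cfg$s)^2 / v2)
    f_l <- e_ls * e_r0
    f_r <- e_l0 * e_rs
    f_n <- e_l0 * e_r0

    in_window <- t <= cfg$t_max
    p_l <- if (in_window) rho[idx] / cfg$t_max else 0
    p_r <- if (in_window) (1 - rho[idx]) / cfg$t_max else 0
    gl <- f_l * (g_l[idx] + p_l * fb[idx])
    gr <- f_r * (g_r[idx] + p_r * fb[idx])
    fbn <- f_n * fb[idx]
    scale <- gl + gr + fbn
    gl <- gl / scale; gr <- gr / scale; fbn <- fbn / scale

    gn <- fbn * max(0, 1 - t / cfg$t_max)
    gth <- cfg$gamma * (gl + gr + gn)

    if (is_srt) {
      fired <- gl + gr >= gth
      if (any(fired)) {
        resp_t[idx[fired]] <- t
      }
    } else {
      hit_l <- gl >= gth
      hit_r <- gr >= gth
      fired <- hit_l | hit_r
      if (any(fired)) {
        side_left <- hit_l[fired] & !hit_r[fired]
        both <- hit_l[fired] & hit_r[fired]
        if (any(both)) {
          side_left[both] <- runif(sum(both)) < 0.5
        }
        resp_t[idx[fired]] <- t
        resp_left[idx[fired]] <- side_left
      }
    }
    g_l[idx] <- gl; g_r[idx] <- gr; fb[idx] <- fbn
    active[idx[fired]] <- FALSE
  }

  target_side <- ifelse(target_left, "left", "right")
  response_side <- if (is_srt) {
    # a simple response has no side
    rep(NA_character_, n)
  } else {
    ifelse(is.na(resp_left), "none", ifelse(resp_left, "left", "right"))
  }
  rt <- resp_t - target_time
  outcome <- classify_bayes_outcome(cfg$task, rt, response_side, target_side)
  tibble(
    trial = seq_len(n),
    cue = cues,
    cue_type = classify_cue_type(cues, target_side),
    target_side = target_side,
    target_time = target_time,
    response_side = response_side,
    rt = rt,
    outcome = outcome
  )
}

#' Summarise Bayesian-observer trials by cue type
#'
#' @param trials a tibble from [simulate_bayes_trials()].
#' @return A tibble with one row per cue type: `n`, `accuracy` (fraction
#'   correct), `mean_rt` and `sd_rt` over correct trials only, and the
#'   anticipated / incorrect / slow proportions.
#' @export
summarize_bayes_trials <- function(trials) {
  trials %>%
    group_by(cue_type = factor(.data$cue_type,
                               c("valid", "neutral", "invalid"))) %>%
    summarise(
      n = dplyr::n(),
      accuracy = mean(.data$outcome == "correct"),
      mean_rt = mean(.data$rt[.data$outcome == "correct"]),
      sd_rt = sd(.data$rt[.data$outcome == "correct"]),
      prop_anticipated = mean(.data$outcome == "anticipated"),
      prop_incorrect = mean(.data$outcome == "incorrect"),
      prop_slow = mean(.data$outcome == "slow"),
      .groups = "drop"
    ) %>%
    arrange(.data$cue_type)
}
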