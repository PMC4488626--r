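#' Configuration of the Bayesian target detector
#'
#' Bundles the task parameters of the sensory model: on each trial a target
#' appears at a uniformly drawn time unit in `1..t_max`, on the left with
#' prior probability `rho` (implied by the cue) or the right with `1 - rho`,
#' and from then on the stimulus on the target side has mean `s` instead of 0.
#' Both channels carry Gaussian noise of standard deviation `sigma`. The
#' observer responds when a posterior probability reaches the threshold
#' `gamma`: in a simple reaction-time (SRT) task the posterior that the target
#' has appeared anywhere, in a choice (CRT) task the posterior for either side
#' separately. A CRT trial without a response by the absolute time index
#' `t_deadline` is classified slow.
#'
#' @param t_max integer, length of the target-onset window (time units).
#' @param s signal intensity added to the target-side stimulus mean.
#' @param sigma noise standard deviation of both stimulus channels (> 0).
#' @param gamma response threshold on the posterior probability, in `[0, 1]`.
#' @param rho prior probability that the target appears on the left
#'   (0.8 for a left cue, 0.5 neutral, 0.2 for a right cue), in `(0, 1)`.
#' @param task `"SRT"` or `"CRT"`.
#' @param t_deadline absolute time index after which a CRT non-response is
#'   slow; must be `>= t_max`.
#'
#' @return An object of class `bayes_config` (a named list).
#' @examples
#' bayes_config(s = 5, gamma = 0.8, rho = 0.8, task = "SRT")
#' @export
bayes_config <- function(t_max = 100L, s = 5, sigma = 2, gamma = 0.8,
                         rho = 0.5, task = c("SRT", "CRT"),
                         t_deadline = 1000L) {
  task <- match.arg(task)
  t_max <- as.integer(t_max)
  t_deadline <- as.integer(t_deadline)
  stopifnot(
    t_max >= 1L,
    is.finite(s),
    sigma > 0,
    gamma >= 0, gamma <= 1,
    rho > 0, rho < 1,
    t_deadline >= t_max
  )
  structure(
    list(t_max = t_max, s = s, sigma = sigma, gamma = gamma, rho = rho,
         task = task, t_deadline = t_deadline),
    class = "bayes_config"
  )
}

#' @export
print.bayes_config <- function(x, ...) {
  cat(sprintf(
    "<bayes_config> %s task: t_max=%d, s=%g, sigma=%g, gamma=%g, rho=%g, deadline=%d\n",
    x$task, x$t_max, x$s, x$sigma, x$gamma, x$rho, x$t_deadline
  ))
  invisible(x)
}

#' Prior probability that the target appears at a given time unit
#'
#' The onset time is uniform on `1..t_max` and the side follows the
#' cue-implied prior, so the target appears on the left exactly at time `t`
#' with probability `rho / t_max` and on the right with `(1 - rho) / t_max`;
#' both are 0 outside the onset window.
#'
#' @param t integer vector of time indices (>= 1).
#' @param config a [bayes_config()].
#' @return A tibble with columns `t`, `p_left`, `p_right`.
#' @examples
#' prior_appearance(c(1, 5, 101), bayes_config(rho = 0.8))
#' @export
prior_appearance <- function(t, config) {
  t <- as.integer(t)
  if (any(t < 1L)) {
    stop("time index `t` must be >= 1", call. = FALSE)
  }
  inside <- t <= config$t_max
  tibble(
    t = t,
    p_left = ifelse(inside, config$rho / config$t_max, 0),
    p_right = ifelse(inside, (1 - config$rho) / config$t_max, 0)
  )
}

#' Per-step stimulus likelihood factors
#'
#' Evaluates, for one stimulus pair, the three Gaussian likelihood factors
#' used by the sequential update -- under "target already on the left"
#' (left channel mean `s`, right mean 0), "target already on the right",
#' and "target not appeared yet" (both means 0) -- with the common normal
#' normalising constant dropped, so each factor lies in `(0, 1]`.
#'
#' @param s_left,s_right numeric vectors, the left/right stimulus values.
#' @inheritParams prior_appearance
#' @return A tibble with columns `f_left`, `f_right`, `f_none`.
#' @examples
#' step_likelihoods(0.5, -0.3, bayes_config(s = 0.5))
#' @export
step_likelihoods <- function(s_left, s_right, config) {
  if (!all(is.finite(s_left)) || !all(is.finite(s_right))) {
    stop("stimulus values must be finite", call. = FALSE)
  }
  v2 <- 2 * config$sigma^2
  g <- function(x, mu) exp(-(x - mu)^2 / v2)
  tibble(
    f_left = g(s_left, config$s) * g(s_right, 0),
    f_right = g(s_left, 0) * g(s_right, config$s),
    f_none = g(s_left, 0) * g(s_right, 0)
  )
}

#' Initial posterior state of the observer
#'
#' At the start of a trial the probabilities that the target has already
#' appeared on either side are zero. The state carries the two scaled
#' likelihood-weighted prior accumulators (`g_left`, `g_right`), the running
#' no-target likelihood product `f_bar`, and the time index; all three
#' accumulators are rescaled by their common sum each step, which leaves the
#' normalised posteriors unchanged and prevents underflow.
#'
#' @inheritParams prior_appearance
#' @return An object of class `bayes_state`.
#' @export
bayes_init <- function(config) {
  structure(
    list(t_now = 0L, g_left = 0, g_right = 0, f_bar = 1),
    class = "bayes_state"
  )
}

#' Normalised posterior probabilities of a state
#'
#' @param state a `bayes_state` from [bayes_init()] or [bayes_update()].
#' @inheritParams prior_appearance
#' @return A tibble with one row: `t_now`, `posterior_left`,
#'   `posterior_right`, `posterior_none`.
#' @export
bayes_posteriors <- function(state, config) {
  frac_left <- max(0, 1 - state$t_now / config$t_max)
  g_none <- state$f_bar * frac_left
  total <- state$g_left + state$g_right + g_none
  tibble(
    t_now = state$t_now,
    posterior_left = state$g_left / total,
    posterior_right = state$g_right / total,
    posterior_none = g_none / total
  )
}

#' Advance the posterior by one stimulus pair
#'
#' Performs one step of the iterative form of the sequential Bayesian update.
#' With `F(t)` the running product of no-target likelihood factors and
#' `p_side(t)` the per-step appearance prior, the accumulators obey
#' \deqn{g_{side}(t) = f_{side}(t)\,[g_{side}(t-1) + p_{side}(t)\,F(t-1)]}
#' and the no-target mass is `F(t) (1 - t/t_max)` (zero past `t_max`; no new
#' onset hypotheses are added after `t_max` but existing ones keep
#' accumulating likelihood). The result matches the direct evaluation of the
#' full-history posterior (see [naive_posterior()]) at constant cost per step.
#'
#' @inheritParams bayes_posteriors
#' @param s_left,s_right the stimulus pair observed at the new time step.
#' @return The advanced `bayes_state`.
#' @export
bayes_update <- function(state, s_left, s_right, config) {
  if (!is.finite(s_left) || !is.finite(s_right)) {
    stop("stimulus values must be finite", call. = FALSE)
  }
  t_new <- state$t_now + 1L
  f <- step_likelihoods(s_left, s_right, config)
  pri <- if (t_new <= config$t_max) {
    c(config$rho, 1 - config$rho) / config$t_max
  } else {
    c(0, 0)
  }
  g_left <- f$f_left * (state$g_left + pri[1] * state$f_bar)
  g_right <- f$f_right * (state$g_right + pri[2] * state$f_bar)
  f_bar <- f$f_none * state$f_bar
  # common rescale: posteriors are invariant, accumulators stay O(1)
  scale <- g_left + g_right + f_bar
  structure(
    list(t_now = t_new, g_left = g_left / scale, g_right = g_right / scale,
         f_bar = f_bar / scale),
    class = "bayes_state"
  )
}

#' Brute-force posterior over a full stimulus history
#'
#' Literal evaluation of the sequential-detection posterior: for every
#' candidate onset time `t <= t'` the likelihood of the whole stimulus
#' sequence is the product of no-target factors before `t` and target-side
#' factors from `t` on, weighted by the appearance prior; the no-target
#' hypothesis contributes the plain product of no-target factors times the
#' remaining prior mass. Cost is quadratic in the history length -- this is
#' the reference implementation used to validate [bayes_update()], not a
#' simulation engine.
#'
#' @param history a data frame with columns `s_left`, `s_right`, one row per
#'   time step (at most 50 rows).
#' @inheritParams prior_appearance
#' @return A tibble with one row per step: `t_now`, `posterior_left`,
#'   `posterior_right`, `posterior_none`.
#' @export
naive_posterior <- function(history, config) {
  history <- as.data.frame(history)
  n <- nrow(history)
  if (n > 50L) {
    stop("naive_posterior is a quadratic-cost reference; history too long",
         call. = FALSE)
  }
  if (n == 0L) {
    return(tibble(t_now = integer(), posterior_left = numeric(),
                  posterior_right = numeric(), posterior_none = numeric()))
  }
  f <- step_likelihoods(history$s_left, history$s_right, config)
  out <- vector("list", n)
  for (tp in seq_len(n)) {
    g_left <- 0
    g_right <- 0
    for (tt in seq_len(min(tp, config$t_max))) {
      # likelihood of the sequence if the target appeared at time tt
      before <- if (tt > 1L) prod(f$f_none[seq_len(tt - 1L)]) else 1
      lik_l <- before * prod(f$f_left[tt:tp])
      lik_r <- before * prod(f$f_right[tt:tp])
      g_left <- g_left + lik_l * config$rho / config$t_max
      g_right <- g_right + lik_r * (1 - config$rho) / config$t_max
    }
    g_none <- prod(f$f_none[seq_len(tp)]) * max(0, 1 - tp / config$t_max)
    total <- g_left + g_right + g_none
    out[[tp]] <- tibble(
      t_now = tp,
      posterior_left = g_left / total,
      posterior_right = g_right / total,
      posterior_none = g_none / total
    )
  }
  bind_rows(out)
}
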