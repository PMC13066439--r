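#' Create an empty 3-up-1-down staircase state
#'
#' Levels are jitter-level indices: 0 (harmonic, easiest) to 10 (maximal
#' jitter, hardest). "Up" always means toward more inharmonic, i.e. harder.
#'
#' @param start_level Initial level index.
#' @param min_level,max_level Level bounds (defaults 0 and 10).
#' @return Object of class `staircase_run`.
#' @export
new_staircase <- function(start_level, min_level = 0L, max_level = 10L) {
  stopifnot(start_level >= min_level, start_level <= max_level)
  structure(list(
    level = as.integer(start_level), start_level = as.integer(start_level),
    min_level = as.integer(min_level), max_level = as.integer(max_level),
    n_correct = 0L, last_direction = 0L,
    levels = integer(0), responses = logical(0),
    reversal_trial = integer(0), reversal_level = integer(0),
    threshold_level = NA_real_
  ), class = "staircase_run")
}

#' Advance a 3-up-1-down staircase by one trial
#'
#' After three consecutive correct responses the level moves one step up
#' (harder, more jitter) and the consecutive-correct counter resets; after
#' any incorrect response it moves one step down (easier) and the counter
#' resets. Levels clamp at the bounds; a move blocked by a bound records no
#' reversal and leaves the direction memory untouched — only realized
#' direction changes count as reversals, recorded at the turning-point
#' level. This rule converges where `p(correct)^3 = 1/2`, i.e. at the
#' 79.37%-correct point of the psychometric function.
#'
#' @param state A `staircase_run`.
#' @param correct Logical, whether the response on this trial was correct.
#' @return Updated state.
#' @export
#' @examples
#' st <- new_staircase(5)
#' for (r in c(TRUE, TRUE, TRUE)) st <- staircase_step(st, r)
#' st$level # 6
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_run"), is.logical(correct))
  state$levels <- c(state$levels, state$level)
  state$responses <- c(state$responses, correct)
  move <- 0L
  if (correct) {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct >= 3L) {
      move <- 1L
      state$n_correct <- 0L
    }
  } else {
    move <- -1L
    state$n_correct <- 0L
  }
  if (move != 0L) {
    new_level <- max(state$min_level, min(state$max_level, state$level + move))
    if (new_level != state$level) {
      if (state$last_direction != 0L && move != state$last_direction) {
        state$reversal_trial <- c(state$reversal_trial, length(state$levels))
        state$reversal_level <- c(state$reversal_level, state$level)
      }
      state$last_direction <- move
      state$level <- new_level
    }
  }
  state
}

#' Run one staircase block against a simulated observer
#'
#' Presents trials at the current level, draws a correct/incorrect response
#' from `observer(level)`, and applies [staircase_step()] until the
#' `n_reversals`-th reversal. The block threshold is the level at the final
#' reversal.
#'
#' @param observer Function mapping a level index to probability correct in
#'   (0, 1); see [logistic_observer()].
#' @param start_level Starting level (the study design starts at 0 or 10 at
#'   random).
#' @param n_reversals Reversals at which the block halts (default 6).
#' @param max_trials Safety cap; hitting it warns about a pathological
#'   observer (e.g. `p = 1` everywhere never reverses) and reports the
#'   current level as the threshold.
#' @inheritParams new_staircase
#' @return Completed `staircase_run` with `threshold_level` set.
#' @export
run_staircase <- function(observer, start_level, n_reversals = 6L,
                          min_level = 0L, max_level = 10L,
                          max_trials = 1000L) {
  st <- new_staircase(start_level, min_level, max_level)
  while (length(st$reversal_level) < n_reversals &&
         length(st$levels) < max_trials) {
    p <- observer(st$level)
    st <- staircase_step(st, stats::runif(1) < p)
  }
  if (length(st$reversal_level) < n_reversals) {
    warning("staircase hit the trial cap before ", n_reversals,
            " reversals; observer may be degenerate")
    st$threshold_level <- st$level
  } else {
    st$threshold_level <- st$reversal_level[n_reversals]
  }
  st
}

#' Average block thresholds into one participant threshold
#'
#' Arithmetic mean of the final-reversal levels across staircase blocks.
#'
#' @param runs List of completed `staircase_run` objects.
#' @return Mean threshold in jitter-level units.
#' @export
threshold_from_blocks <- function(runs) {
  if (length(runs) == 0L) stop("no staircase runs supplied")
  mean(vapply(runs, function(r) as.numeric(r$threshold_level), numeric(1)))
}

#' Logistic simulated observer for the 2AFC pitch task
#'
#' Probability correct as a decreasing logistic function of the jitter-level
#' index. Because the jitter schedule is geometric, the level index is an
#' affine function of `log10` jitter rate, so a logistic in level index is a
#' logistic in log jitter. For a 2AFC task the guess rate is 0.5.
#'
#' @param midpoint Level at which performance is halfway between the guess
#'   rate and `1 - lapse`.
#' @param slope Logistic scale in level units (larger = shallower).
#' @param guess Lower asymptote (0.5 for 2AFC).
#' @param lapse Lapse rate subtracted from the upper asymptote.
#' @return Function `level -> p(correct)`, vectorized over `level`.
#' @export
#' @examples
#' obs <- logistic_observer(midpoint = 5)
#' obs(c(0, 5, 10))
logistic_observer <- function(midpoint = 5, slope = 1.5,
                              guess = 0.5, lapse = 0) {
  stopifnot(slope > 0, guess >= 0, guess < 1, lapse >= 0, guess + lapse < 1)
  function(level) {
    guess + (1 - guess - lapse) / (1 + exp((level - midpoint) / slope))
  }
}

#' Convert jitter-level indices to jitter rates
#'
#' @param level Integer level indices 0..10.
#' @return Jitter rates from [jitter_schedule()].
#' @export
level_to_jitter <- function(level) {
  stopifnot(all(level >= 0), all(level <= 10))
  unname(jitter_schedule()[level + 1L])
}
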