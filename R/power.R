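#' Configuration of the simulation-based power analysis
#'
#' Design of the pre-study power simulation: a worst-case amplitude
#' structure where all conditions share one mean except a single condition
#' offset by `effect` (default 1 uV), participant random intercepts, and
#' Gaussian residuals. The between-participant and residual SDs are
#' configuration values (1.5 uV each by default), chosen as plausible for
#' fronto-central MMN mean amplitudes.
#'
#' @param effect Offset of the odd condition in uV.
#' @param n_conditions Number of conditions (default 8).
#' @param n_range Participant range scanned by [minimal_n()].
#' @param n_reps Monte-Carlo replicates per sample size.
#' @param alpha Significance level.
#' @param participant_sd Between-participant intercept SD, uV.
#' @param resid_sd Residual SD, uV.
#' @return Object of class `power_config`.
#' @export
power_config <- function(effect = 1.0, n_conditions = 8L,
                         n_range = c(20L, 40L), n_reps = 1000L,
                         alpha = 0.05, participant_sd = 1.5,
                         resid_sd = 1.5) {
  stopifnot(effect >= 0, n_conditions >= 2, n_reps >= 1,
            alpha > 0, alpha < 1, participant_sd >= 0, resid_sd >= 0)
  structure(list(effect = effect, n_conditions = as.integer(n_conditions),
                 n_range = as.integer(n_range), n_reps = as.integer(n_reps),
                 alpha = alpha, participant_sd = participant_sd,
                 resid_sd = resid_sd),
            class = "power_config")
}

#' Simulate one dataset under the power-analysis model
#'
#' Long-format amplitudes for `n` participants x `n_conditions` conditions:
#' participant intercepts `N(0, participant_sd^2)`, a fixed `effect` added
#' to the first condition, residuals `N(0, resid_sd^2)`.
#'
#' @param config A `power_config`.
#' @param n Number of participants.
#' @return `data.frame` with `participant`, `condition`, `amplitude`.
#' @export
simulate_dataset <- function(config, n) {
  stopifnot(inherits(config, "power_config"))
  p <- config$n_conditions
  Y <- simulate_dataset_matrix(config, n)
  data.frame(participant = rep(seq_len(n), each = p),
             condition = rep(paste0("c", seq_len(p)), n),
             amplitude = as.vector(t(Y)))
}

# matrix form used directly in the replicate loop (rows = participants)
simulate_dataset_matrix <- function(config, n) {
  p <- config$n_conditions
  intercepts <- stats::rnorm(n, 0, config$participant_sd)
  Y <- matrix(stats::rnorm(n * p, 0, config$resid_sd), n, p) + intercepts
  Y[, 1] <- Y[, 1] + config$effect
  Y
}

#' Estimate power at a given sample size
#'
#' Fraction of simulated datasets whose condition effect is significant in
#' the repeated-measures ANOVA (Greenhouse-Geisser corrected p) at the
#' configured alpha, with the binomial Monte-Carlo standard error.
#'
#' @param config A `power_config`.
#' @param n Number of participants per simulated dataset.
#' @param n_reps Override of `config$n_reps`.
#' @return List with `n`, `power`, `se`, `n_reps`, `alpha`.
#' @export
power_at_n <- function(config, n, n_reps = config$n_reps) {
  stopifnot(inherits(config, "power_config"))
  hits <- 0L
  for (r in seq_len(n_reps)) {
    Y <- simulate_dataset_matrix(config, n)
    if (rm_anova_matrix(Y)$p_gg < config$alpha) hits <- hits + 1L
  }
  pow <- hits / n_reps
  list(n = n, power = pow, se = sqrt(pow * (1 - pow) / n_reps),
       n_reps = n_reps, alpha = config$alpha)
}

#' Smallest sample size reaching a power target
#'
#' Scans `config$n_range` in ascending order and returns the first sample
#' size whose estimated power reaches `target_power`.
#'
#' @param config A `power_config`.
#' @param target_power Power target (default 0.8).
#' @param step Scan step over the range.
#' @return List with `n` (the minimal sample size, or `NA` when even the
#'   top of the range falls short) and `scan`, a data frame of
#'   `(n, power, se)` for every size visited.
#' @export
minimal_n <- function(config, target_power = 0.8, step = 1L) {
  stopifnot(inherits(config, "power_config"))
  ns <- seq.int(config$n_range[1], config$n_range[2], by = step)
  scan <- data.frame(n = integer(0), power = numeric(0), se = numeric(0))
  found <- NA_integer_
  for (n in ns) {
    res <- power_at_n(config, n)
    scan <- rbind(scan, data.frame(n = n, power = res$power, se = res$se))
    if (res$power >= target_power) {
      found <- n
      break
    }
  }
  list(n = found, scan = scan, target_power = target_power)
}
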