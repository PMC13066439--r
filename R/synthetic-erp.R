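#' Generative parameters for synthetic mismatch-response data
#'
#' Parameters of the data-generating process the statistical models assume:
#' MMN amplitudes follow `L_p / (1 + exp(k * (I - I0)))` with a
#' participant-random asymptote `L_p ~ N(L_mean, L_sd^2)` and Gaussian
#' residual noise, where `I = log10(2 * jc)` is the differential entropy of
#' the jitter distribution; P3a amplitudes follow an inverted parabola in
#' `I`; peak latencies are condition-independent.
#'
#' Defaults mimic the regime of a 34-participant study over the seven
#' jittered EEG conditions (`j1`..`j7`): asymptote -1.5 uV with 0.5 uV
#' between-participant SD, slope 8 per log10 unit, inflection at
#' `I0 = -1.18`, residual SD 0.5 uV, and a P3a parabola peaking ~1 uV at
#' entropy -1.41. The spread parameters are configuration, not reported
#' constants.
#'
#' @param L_mean Sigmoid left asymptote in uV (negative: MMN polarity).
#' @param L_sd Between-participant SD of the asymptote, uV.
#' @param k Sigmoid slope at the inflection (per log10 unit of entropy).
#' @param I0 Inflection-point entropy.
#' @param resid_sd Residual SD, uV.
#' @param p3a_quad Quadratic coefficients `c(a, b, c)` of the P3a amplitude
#'   in entropy (a < 0 gives the inverted-U).
#' @param latency_means Named ms means `c(mmn = , p3a = )`.
#' @param latency_sd Latency SD in ms.
#' @param n_participants Number of simulated participants.
#' @param conditions Jitter rates (all > 0 so entropy is defined).
#' @param seed Optional integer seed applied by the generators.
#' @return Object of class `generative_params`.
#' @export
generative_params <- function(L_mean = -1.5, L_sd = 0.5, k = 8, I0 = -1.18,
                              resid_sd = 0.5,
                              p3a_quad = c(a = -0.8, b = -2.256, c = -0.59),
                              latency_means = c(mmn = 150, p3a = 250),
                              latency_sd = 10,
                              n_participants = 34,
                              conditions = jitter_schedule()[2:8],
                              seed = NULL) {
  stopifnot(L_sd >= 0, resid_sd >= 0, latency_sd >= 0,
            n_participants >= 1, all(conditions > 0),
            length(p3a_quad) == 3)
  structure(list(L_mean = L_mean, L_sd = L_sd, k = k, I0 = I0,
                 resid_sd = resid_sd, p3a_quad = p3a_quad,
                 latency_means = latency_means, latency_sd = latency_sd,
                 n_participants = as.integer(n_participants),
                 conditions = conditions, seed = seed),
            class = "generative_params")
}

sigmoid_mean <- function(L, k, I0, I) L / (1 + exp(k * (I - I0)))

#' Generate a synthetic per-participant, per-condition peak table
#'
#' One row per participant x condition with MMN and P3a amplitudes and
#' latencies drawn from the generative model of [generative_params()].
#' With `L_sd = 0` and `resid_sd = 0` the MMN column equals the
#' deterministic sigmoid evaluated at each condition's entropy.
#'
#' @param params A `generative_params` object.
#' @return `data.frame` with columns `participant`, `condition`,
#'   `jitter_rate`, `entropy`, `mmn_amplitude`, `mmn_latency`,
#'   `p3a_amplitude`, `p3a_latency`.
#' @export
#' @examples
#' tab <- generate_peak_table(generative_params(n_participants = 4, seed = 1))
#' head(tab)
generate_peak_table <- function(params) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  P <- params$n_participants
  jc <- params$conditions
  if (is.null(names(jc))) names(jc) <- paste0("c", seq_along(jc))
  I <- differential_entropy(jc)
  C <- length(jc)
  L_p <- stats::rnorm(P, params$L_mean, params$L_sd)
  q <- params$p3a_quad

  out <- expand.grid(condition = names(jc), participant = seq_len(P),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("participant", "condition")]
  out$jitter_rate <- jc[out$condition]
  out$entropy <- I[out$condition]
  out$mmn_amplitude <- sigmoid_mean(L_p[out$participant], params$k,
                                    params$I0, out$entropy) +
    stats::rnorm(P * C, 0, params$resid_sd)
  out$p3a_amplitude <- q[1] * out$entropy^2 + q[2] * out$entropy + q[3] +
    stats::rnorm(P * C, 0, params$resid_sd)
  out$mmn_latency <- stats::rnorm(P * C, params$latency_means[["mmn"]],
                                  params$latency_sd)
  out$p3a_latency <- stats::rnorm(P * C, params$latency_means[["p3a"]],
                                  params$latency_sd)
  rownames(out) <- NULL
  out[, c("participant", "condition", "jitter_rate", "entropy",
          "mmn_amplitude", "mmn_latency", "p3a_amplitude", "p3a_latency")]
}

# common ERP carried by every event (small fronto-central N1/P2-like shape);
# deviants additionally carry the MMN and P3a deflections
base_erp_shape <- function(times_ms) {
  -0.4 * exp(-(times_ms - 100)^2 / (2 * 30^2)) +
    0.25 * exp(-(times_ms - 200)^2 / (2 * 50^2))
}

gaussian_deflection <- function(times_ms, center, sd, height) {
  height * exp(-(times_ms - center)^2 / (2 * sd^2))
}

#' Generate synthetic epochs for one participant and condition
#'
#' Produces one epoch per event of a labeled roving sequence. Every epoch
#' carries a common ERP shape; deviant epochs additionally carry a negative
#' Gaussian MMN deflection (depth = the participant-condition sigmoid value)
#' and a positive Gaussian P3a deflection (height from the generative
#' quadratic). Additive noise is white Gaussian by default, or 1/f
#' ("pink") noise for more realistic spectra.
#'
#' @param params A `generative_params`.
#' @param sequence A labeled `roving_sequence` (see [label_events()]).
#' @param participant Participant index (selects the random asymptote draw).
#' @param condition Condition name or index into `params$conditions`.
#' @param sfreq Sampling rate of the epochs in Hz.
#' @param tmin,tmax Epoch window in ms relative to stimulus onset.
#' @param noise_sd Noise SD in uV (0 gives noise-free epochs).
#' @param noise `"white"` or `"pink"`.
#' @param mmn_center,mmn_sd,p3a_center,p3a_sd Deflection centers and widths
#'   in ms.
#' @return Object of class `epoch_set`: list with `times` (ms), `data`
#'   (events x samples matrix, uV), `info` (the sequence's labeled events),
#'   `participant`, `condition`, `injected` (the true deflection parameters,
#'   kept for oracle tests).
#' @export
generate_epochs <- function(params, sequence, participant = 1L,
                            condition = 1L, sfreq = 500,
                            tmin = -100, tmax = 500,
                            noise_sd = 1, noise = c("white", "pink"),
                            mmn_center = 150, mmn_sd = 40,
                            p3a_center = 250, p3a_sd = 40) {
  stopifnot(inherits(params, "generative_params"),
            inherits(sequence, "roving_sequence"))
  noise <- match.arg(noise)
  if (any(is.na(sequence$events$role)))
    stop("sequence is unlabeled; run label_events() first")
  jc <- params$conditions
  if (is.null(names(jc))) names(jc) <- paste0("c", seq_along(jc))
  cond_name <- if (is.character(condition)) condition else names(jc)[condition]
  I <- differential_entropy(jc[[cond_name]])

  # participant asymptote drawn reproducibly from the participant index
  if (!is.null(params$seed)) set.seed(params$seed + participant)
  L_p <- stats::rnorm(1, params$L_mean, params$L_sd)
  mmn_depth <- sigmoid_mean(L_p, params$k, params$I0, I)
  q <- params$p3a_quad
  p3a_height <- q[[1]] * I^2 + q[[2]] * I + q[[3]]

  step <- 1000 / sfreq
  times <- seq(tmin, tmax, by = step)
  n_t <- length(times)
  ev <- sequence$events
  n_ev <- nrow(ev)

  base <- base_erp_shape(times)
  deflect <- gaussian_deflection(times, mmn_center, mmn_sd, mmn_depth) +
    gaussian_deflection(times, p3a_center, p3a_sd, p3a_height)

  data <- matrix(rep(base, each = n_ev), n_ev, n_t)
  is_dev <- ev$role == "deviant"
  if (any(is_dev))
    data[is_dev, ] <- data[is_dev, , drop = FALSE] +
      matrix(rep(deflect, each = sum(is_dev)), sum(is_dev), n_t)
  if (noise_sd > 0) {
    eps <- if (noise == "white") {
      matrix(stats::rnorm(n_ev * n_t, 0, noise_sd), n_ev, n_t)
    } else {
      t(vapply(seq_len(n_ev), function(i) pink_noise(n_t) * noise_sd,
               numeric(n_t)))
    }
    data <- data + eps
  }
  structure(list(times = times, data = data, info = ev,
                 participant = as.integer(participant),
                 condition = cond_name,
                 injected = list(mmn_depth = mmn_depth, mmn_center = mmn_center,
                                 mmn_sd = mmn_sd, p3a_height = p3a_height,
                                 p3a_center = p3a_center, p3a_sd = p3a_sd)),
            class = "epoch_set")
}

# unit-variance 1/f noise via spectral shaping
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # mirror for negative frequencies
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Simulate a behavioral staircase dataset
#'
#' Runs the 3-up-1-down staircase for a population of logistic observers
#' whose midpoints vary between participants, mirroring the behavioral
#' session design (15 blocks per participant, random start at the easiest or
#' hardest level).
#'
#' @param n_participants Number of simulated participants.
#' @param blocks Staircase blocks per participant.
#' @param midpoint,midpoint_sd Population mean and SD of the observer
#'   midpoint (level units).
#' @param slope,guess,lapse Passed to [logistic_observer()].
#' @param n_reversals Reversals per block.
#' @return List with `log` (data frame: `participant`, `block`, `trial`,
#'   `level`, `jitter_rate`, `correct`, `is_reversal`) and `thresholds`
#'   (data frame: `participant`, `midpoint`, `threshold`).
#' @export
generate_behavioral_dataset <- function(n_participants = 30, blocks = 15,
                                        midpoint = 5, midpoint_sd = 1,
                                        slope = 1.5, guess = 0.5, lapse = 0,
                                        n_reversals = 6L) {
  logs <- vector("list", n_participants * blocks)
  thresholds <- numeric(n_participants)
  midpoints <- stats::rnorm(n_participants, midpoint, midpoint_sd)
  li <- 1L
  for (p in seq_len(n_participants)) {
    obs <- logistic_observer(midpoints[p], slope, guess, lapse)
    runs <- vector("list", blocks)
    for (b in seq_len(blocks)) {
      start <- sample(c(0L, 10L), 1L)
      run <- run_staircase(obs, start, n_reversals = n_reversals)
      runs[[b]] <- run
      n_tr <- length(run$levels)
      logs[[li]] <- data.frame(
        participant = p, block = b, trial = seq_len(n_tr),
        level = run$levels, jitter_rate = level_to_jitter(run$levels),
        correct = run$responses,
        is_reversal = seq_len(n_tr) %in% run$reversal_trial)
      li <- li + 1L
    }
    thresholds[p] <- threshold_from_blocks(runs)
  }
  list(log = do.call(rbind, logs),
       thresholds = data.frame(participant = seq_len(n_participants),
                               midpoint = midpoints,
                               threshold = thresholds))
}
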