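#' Specification of a single complex tone
#'
#' Bundles the parameters needed to realize and render one harmonic or
#' jittered complex tone: fundamental frequency, jitter rate, duration,
#' sample rate, onset/offset ramp length, high-pass filter settings and the
#' loudness-normalization target.
#'
#' @param f0 Fundamental frequency in Hz (must be positive).
#' @param jitter_rate Jitter rate `jc` in `[0, 0.5]`. Each harmonic above the
#'   fundamental is scaled by `1 + J` with `J ~ U(-jc, jc)`; 0.5 is the
#'   largest rate that cannot reorder adjacent components.
#' @param duration Tone duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param ramp Length of each half-Hanning onset/offset ramp in seconds.
#' @param hp_cutoff High-pass cutoff frequency in Hz; must be below Nyquist.
#' @param hp_order Butterworth filter order.
#' @param loudness_target Integrated loudness target in LUFS.
#' @param min_spacing Minimum spacing between adjacent components in Hz;
#'   jitter vectors violating it are rejected and redrawn.
#' @param seed Optional integer seed recorded with the spec so a stimulus can
#'   be re-rendered bit-identically.
#'
#' @return An object of class `tone_spec`.
#' @seealso [jitter_frequencies()], [synthesize_tone()]
#' @export
#' @examples
#' spec <- tone_spec(400, jitter_rate = 0.108)
#' spec$nyquist
tone_spec <- function(f0, jitter_rate = 0, duration = 0.070,
                      sample_rate = 48000, ramp = 0.005,
                      hp_cutoff = 3500, hp_order = 4L,
                      loudness_target = -12, min_spacing = 30,
                      seed = NULL) {
  stopifnot(is.numeric(f0), length(f0) == 1L, f0 > 0)
  if (jitter_rate < 0 || jitter_rate > 0.5)
    stop("`jitter_rate` must lie in [0, 0.5]")
  nyquist <- sample_rate / 2
  if (hp_cutoff >= nyquist)
    stop("`hp_cutoff` must be below the Nyquist frequency")
  if (duration <= 2 * ramp)
    stop("`duration` must exceed twice the ramp length")
  structure(list(
    f0 = f0, jitter_rate = jitter_rate, duration = duration,
    sample_rate = sample_rate, ramp = ramp,
    hp_cutoff = hp_cutoff, hp_order = as.integer(hp_order),
    loudness_target = loudness_target, min_spacing = min_spacing,
    nyquist = nyquist, seed = seed
  ), class = "tone_spec")
}

#' Geometric schedule of jitter rates
#'
#' Returns `n_levels` jitter rates progressing geometrically from `j_min` to
#' `j_max`, rounded to three decimals. A geometric progression concentrates
#' resolution at small jitter rates, where pitch discrimination is still
#' possible; the harmonic (zero-jitter) condition is not part of the
#' progression and is prepended by the caller when needed (see
#' [jitter_schedule()]).
#'
#' @param j_min,j_max Smallest and largest jitter rate; `0 < j_min < j_max`.
#' @param n_levels Number of levels (at least 2).
#' @return Numeric vector of length `n_levels`, rounded to 3 decimals.
#' @export
#' @examples
#' geometric_jitter_levels(0.005, 0.5, 10)
geometric_jitter_levels <- function(j_min, j_max, n_levels) {
  if (!is.numeric(j_min) || j_min <= 0)
    stop("`j_min` must be positive: a geometric progression from 0 is undefined")
  stopifnot(j_max > j_min, n_levels >= 2)
  round(exp(seq(log(j_min), log(j_max), length.out = n_levels)), 3)
}

#' The standard 11-level jitter schedule
#'
#' Named vector `j0 = 0` (harmonic) followed by the ten geometric levels
#' from 0.005 to 0.5.
#'
#' @return Named numeric vector of length 11 (`j0` ... `j10`).
#' @export
#' @examples
#' jitter_schedule()[c("j0", "j5", "j10")]
jitter_schedule <- function() {
  levels <- c(0, geometric_jitter_levels(0.005, 0.5, 10))
  names(levels) <- paste0("j", 0:10)
  levels
}

#' Differential entropy of the jitter distribution
#'
#' For jitter drawn uniformly on `(-jc, jc)` the differential entropy of the
#' distribution is `log10(2 * jc)` (in log10 units). It is negative for
#' `jc < 0.5` and undefined for the harmonic condition `jc = 0`, which is why
#' the entropy-based models omit that condition.
#'
#' @param jc Jitter rate(s), strictly positive.
#' @return `log10(2 * jc)`, same length as `jc`.
#' @seealso [inflection_to_jitter()] for the exact inverse.
#' @export
#' @examples
#' differential_entropy(0.5)   # 0
#' differential_entropy(0.039) # about -1.11
differential_entropy <- function(jc) {
  if (any(!is.finite(jc)) || any(jc <= 0))
    stop("differential entropy is undefined for jitter rate <= 0")
  log10(2 * jc)
}

#' Realize the component frequencies of one tone
#'
#' Enumerates the harmonics `n * f0` up to the Nyquist limit, then applies a
#' multiplicative jitter `F_n' = F_n * (1 + J)`, `J ~ U(-jc, jc)`, to every
#' component above the fundamental. The fundamental itself is never jittered.
#' Rejection sampling enforces a minimum spacing of `min_spacing` Hz between
#' adjacent components (avoiding beating artifacts): components are realized
#' in ascending order and a draw that lands within `min_spacing` of the
#' previously accepted component is redrawn. Per-component redrawing always
#' terminates, because consecutive base harmonics are at least
#' `f0 * (1 - jc) > min_spacing` apart for the frequencies used here;
#' redrawing entire jitter vectors, by contrast, has vanishing acceptance
#' probability once harmonics reach into the kHz range. A jittered component
#' pushed above Nyquist is dropped from the list.
#'
#' @param spec A [tone_spec()]. Uses the current RNG state; seed externally
#'   (or via [render_stimulus()]) for reproducibility.
#' @param max_attempts Redraw attempts per component before giving up with a
#'   diagnostic error (only reachable when `f0 * (1 - jc)` approaches
#'   `min_spacing`).
#' @return An object of class `jitter_realization`: list with `components`
#'   (strictly increasing frequencies in Hz, first equal to `f0`),
#'   `base_harmonics`, `jitter_draws` and `attempts` (total draws used).
#' @export
#' @examples
#' set.seed(1)
#' r <- jitter_frequencies(tone_spec(400, 0.108))
#' head(r$components)
jitter_frequencies <- function(spec, max_attempts = 10000L) {
  stopifnot(inherits(spec, "tone_spec"))
  n_harm <- floor((spec$nyquist - 1e-9) / spec$f0)
  if (n_harm < 1L) stop("fundamental lies above the Nyquist limit")
  base <- spec$f0 * seq_len(n_harm)
  jc <- spec$jitter_rate

  if (jc == 0) {
    out <- list(components = base, base_harmonics = base,
                jitter_draws = rep(0, n_harm), attempts = 1L)
    class(out) <- "jitter_realization"
    return(out)
  }

  comps <- spec$f0
  kept_base <- spec$f0
  draws <- 0
  total_attempts <- 1L
  prev <- spec$f0
  for (i in seq_len(n_harm - 1L) + 1L) {
    accepted <- FALSE
    for (attempt in seq_len(max_attempts)) {
      total_attempts <- total_attempts + 1L
      j <- stats::runif(1, -jc, jc)
      f <- base[i] * (1 + j)
      if (f >= spec$nyquist) { # clipped from the list, draw accepted
        accepted <- TRUE
        break
      }
      if (f - prev >= spec$min_spacing) {
        comps <- c(comps, f)
        kept_base <- c(kept_base, base[i])
        draws <- c(draws, j)
        prev <- f
        accepted <- TRUE
        break
      }
    }
    if (!accepted)
      stop(sprintf(
        "component %d could not satisfy the %g Hz spacing in %d attempts (f0 = %g, jc = %g)",
        i, spec$min_spacing, max_attempts, spec$f0, jc))
  }
  out <- list(components = comps, base_harmonics = kept_base,
              jitter_draws = draws, attempts = total_attempts)
  class(out) <- "jitter_realization"
  out
}

#' Synthesize a complex tone from a realized component set
#'
#' Adds one sinusoid per component with independent random phases drawn
#' uniformly on `[0, 2*pi)`, applies a stationary Butterworth high-pass
#' filter, half-Hanning onset/offset ramps, and loudness normalization to the
#' spec's LUFS target, in that order (so normalization is authoritative on
#' the final signal). Each stage can be disabled, which the test oracles use
#' to inspect the raw spectrum.
#'
#' @param spec A [tone_spec()].
#' @param realization A `jitter_realization` consistent with `spec`; if
#'   missing, one is drawn with [jitter_frequencies()].
#' @param apply_filter,apply_ramp,normalize Logical switches for the three
#'   post-processing stages.
#' @param loudness_method `"bs1770"` (K-weighted integrated loudness) or
#'   `"rms"` (plain RMS reference, faster, used in tight test loops).
#' @return Numeric vector of `duration * sample_rate` amplitude samples.
#'   A tone that would clip after normalization triggers a warning; samples
#'   are not silently clipped.
#' @export
#' @examples
#' set.seed(1)
#' spec <- tone_spec(400)
#' w <- synthesize_tone(spec)
#' length(w) # 3360 samples at 48 kHz
synthesize_tone <- function(spec, realization = NULL,
                            apply_filter = TRUE, apply_ramp = TRUE,
                            normalize = TRUE,
                            loudness_method = c("bs1770", "rms")) {
  stopifnot(inherits(spec, "tone_spec"))
  loudness_method <- match.arg(loudness_method)
  if (is.null(realization)) realization <- jitter_frequencies(spec)
  freqs <- realization$components
  if (length(freqs) == 0L) stop("realization has no components")

  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  # outer() keeps this vectorized; component count is <= nyquist/f0 (~120)
  x <- as.vector(sin(outer(t, 2 * pi * freqs) +
                       matrix(phases, n, length(freqs), byrow = TRUE)) %*%
                   rep(1, length(freqs)))
  x <- x / length(freqs) # unit headroom before filtering

  if (apply_filter) {
    bf <- signal::butter(spec$hp_order, spec$hp_cutoff / spec$nyquist,
                         type = "high")
    x <- as.numeric(signal::filter(bf, x))
  }
  if (apply_ramp) x <- apply_ramps(x, spec$sample_rate, spec$ramp)
  if (normalize) {
    x <- normalize_loudness(x, spec$sample_rate, spec$loudness_target,
                            method = loudness_method)
    if (max(abs(x)) > 1)
      warning(sprintf("normalized tone clips (peak %.2f); not clipped silently",
                      max(abs(x))))
  }
  x
}

# half-Hanning fade-in/out over `ramp` seconds at each end
apply_ramps <- function(x, sample_rate, ramp) {
  nr <- round(ramp * sample_rate)
  if (nr < 2L || 2L * nr > length(x)) return(x)
  w <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 1) / (nr - 1))
  x[seq_len(nr)] <- x[seq_len(nr)] * w
  x[(length(x) - nr + 1L):length(x)] <- x[(length(x) - nr + 1L):length(x)] * rev(w)
  x
}

#' Render one stimulus reproducibly
#'
#' Convenience wrapper that seeds the RNG from `spec$seed` (when present),
#' realizes the jitter and synthesizes the waveform, so a manifest row can be
#' re-rendered bit-identically.
#'
#' @inheritParams synthesize_tone
#' @return List with `spec`, `realization` and `waveform`.
#' @export
render_stimulus <- function(spec, loudness_method = c("bs1770", "rms")) {
  loudness_method <- match.arg(loudness_method)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  realization <- jitter_frequencies(spec)
  waveform <- synthesize_tone(spec, realization,
                              loudness_method = loudness_method)
  list(spec = spec, realization = realization, waveform = waveform)
}

#' Build a stimulus manifest without rendering audio
#'
#' One row per stimulus to be rendered: every combination of fundamental
#' frequency, jitter condition and pattern index, with a per-row seed derived
#' deterministically from `seed` so any single row can be re-rendered alone.
#'
#' @param f0_grid Fundamental frequencies in Hz.
#' @param conditions Named vector of jitter rates (names become condition
#'   labels, e.g. the `j0`..`j7` subset of [jitter_schedule()]).
#' @param n_per_cell Number of distinct jitter patterns per (f0, condition).
#' @param seed Integer base seed.
#' @param dir Directory prefix recorded in `file_path`.
#' @return `data.frame` with columns `f0_hz`, `jitter_condition`,
#'   `jitter_rate`, `pattern`, `seed`, `file_path`.
#' @export
#' @examples
#' m <- stimulus_manifest(seq(200, 500, 50), jitter_schedule()[1:8], 10)
#' nrow(m) # 7 * 8 * 10
stimulus_manifest <- function(f0_grid, conditions, n_per_cell,
                              seed = 1L, dir = "stimuli") {
  stopifnot(length(f0_grid) >= 1, length(conditions) >= 1, n_per_cell >= 1)
  if (is.null(names(conditions)))
    names(conditions) <- paste0("j", seq_along(conditions) - 1)
  grid <- expand.grid(pattern = seq_len(n_per_cell),
                      jitter_condition = names(conditions),
                      f0_hz = f0_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("f0_hz", "jitter_condition", "pattern")]
  grid$jitter_rate <- unname(conditions[grid$jitter_condition])
  grid$seed <- (as.integer(seed) + seq_len(nrow(grid))) %% .Machine$integer.max
  grid$file_path <- file.path(dir, sprintf("%s_f%04d_p%04d.wav",
                                           grid$jitter_condition,
                                           grid$f0_hz, grid$pattern))
  rownames(grid) <- NULL
  grid[, c("f0_hz", "jitter_condition", "jitter_rate", "pattern",
           "seed", "file_path")]
}
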