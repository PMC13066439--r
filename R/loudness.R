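# Integrated loudness measurement (ITU-R BS.1770 style) and normalization.
# Mono only. For signals shorter than one 400 ms gating block the whole
# signal is treated as a single block (the stimuli here are 70 ms tones).

# Published K-weighting coefficients at 48 kHz: stage 1 high-shelf, stage 2
# high-pass. For other rates the two stages are designed as RBJ biquads
# (shelf: +4 dB at 1681.97 Hz, Q 0.7072; high-pass: 38.14 Hz, Q 0.5003).
k_weighting_coefficients <- function(sample_rate) {
  if (sample_rate == 48000) {
    return(list(
      shelf = list(b = c(1.53512485958697, -2.69169618940638, 1.19839281085285),
                   a = c(1, -1.69065929318241, 0.73248077421585)),
      highpass = list(b = c(1.0, -2.0, 1.0),
                      a = c(1, -1.99004745483398, 0.99007225036621))
    ))
  }
  list(shelf = rbj_highshelf(1681.974450955533, sample_rate,
                             gain_db = 3.999843853973347,
                             q = 0.7071752369554196),
       highpass = rbj_highpass(38.13547087602444, sample_rate,
                               q = 0.5003270373238773))
}

rbj_highshelf <- function(fc, fs, gain_db, q) {
  A <- 10^(gain_db / 40)
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / (2 * q)
  cw <- cos(w0)
  b <- c(A * ((A + 1) + (A - 1) * cw + 2 * sqrt(A) * alpha),
         -2 * A * ((A - 1) + (A + 1) * cw),
         A * ((A + 1) + (A - 1) * cw - 2 * sqrt(A) * alpha))
  a <- c((A + 1) - (A - 1) * cw + 2 * sqrt(A) * alpha,
         2 * ((A - 1) - (A + 1) * cw),
         (A + 1) - (A - 1) * cw - 2 * sqrt(A) * alpha)
  list(b = b / a[1], a = a / a[1])
}

rbj_highpass <- function(fc, fs, q) {
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / (2 * q)
  cw <- cos(w0)
  b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

biquad_filter <- function(coef, x) {
  as.numeric(signal::filter(signal::Arma(b = coef$b, a = coef$a), x))
}

#' Measure integrated loudness
#'
#' K-weighted integrated loudness in LUFS with 400 ms / 75%-overlap gating
#' blocks, an absolute gate at -70 LUFS and a relative gate 10 LU below the
#' absolute-gated mean, following the BS.1770 recipe for a mono signal.
#' Signals shorter than one block are measured ungated over their full
#' length. `method = "rms"` skips the weighting and gating and reports
#' `10*log10(mean(x^2))`, a fast proxy used in test loops.
#'
#' @param x Numeric waveform in `[-1, 1]` full-scale units.
#' @param sample_rate Sampling rate in Hz.
#' @param method `"bs1770"` or `"rms"`.
#' @return Loudness in LUFS (dBFS for `"rms"`).
#' @export
measure_loudness <- function(x, sample_rate, method = c("bs1770", "rms")) {
  method <- match.arg(method)
  if (length(x) == 0L) stop("empty waveform")
  if (method == "rms") return(10 * log10(mean(x^2)))

  coefs <- k_weighting_coefficients(sample_rate)
  y <- biquad_filter(coefs$highpass, biquad_filter(coefs$shelf, x))

  block <- round(0.400 * sample_rate)
  if (length(y) <= block)
    return(-0.691 + 10 * log10(mean(y^2)))

  step <- round(0.100 * sample_rate)
  starts <- seq(1L, length(y) - block + 1L, by = step)
  z <- vapply(starts, function(s) mean(y[s:(s + block - 1L)]^2), numeric(1))
  lb <- -0.691 + 10 * log10(z)
  abs_gated <- z[lb > -70]
  if (length(abs_gated) == 0L) return(-Inf)
  rel_thresh <- -0.691 + 10 * log10(mean(abs_gated)) - 10
  gated <- z[lb > -70 & lb > rel_thresh]
  if (length(gated) == 0L) gated <- abs_gated
  -0.691 + 10 * log10(mean(gated))
}

#' Normalize a waveform to a loudness target
#'
#' Applies the single gain that moves the measured loudness to `target`
#' (in LUFS for `"bs1770"`, dBFS for `"rms"`).
#'
#' @inheritParams measure_loudness
#' @param target Target level.
#' @return Rescaled waveform.
#' @export
normalize_loudness <- function(x, sample_rate, target,
                               method = c("bs1770", "rms")) {
  method <- match.arg(method)
  measured <- measure_loudness(x, sample_rate, method)
  x * 10^((target - measured) / 20)
}
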