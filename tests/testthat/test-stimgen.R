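test_that("geometric jitter schedule reproduces the printed levels", {
  expect_identical(geometric_jitter_levels(0.005, 0.5, 10),
                   c(0.005, 0.008, 0.014, 0.023, 0.039, 0.065,
                     0.108, 0.180, 0.300, 0.500))
  expect_identical(geometric_jitter_levels(0.005, 0.5, 2), c(0.005, 0.5))
  # common ratio of the 10-level schedule solves r^9 = 100
  expect_equal(100^(1 / 9), 1.668, tolerance = 1e-3)
  expect_error(geometric_jitter_levels(0, 0.5, 10), "positive")
  sched <- jitter_schedule()
  expect_named(sched, paste0("j", 0:10))
  expect_identical(unname(sched[1]), 0)
})

test_that("differential entropy is log10(2 jc), increasing, inverse-paired", {
  expect_identical(differential_entropy(0.5), 0)
  expect_equal(differential_entropy(0.039), log10(0.078), tolerance = 1e-12)
  expect_equal(differential_entropy(0.039), -1.108, tolerance = 1e-3)
  jc <- jitter_schedule()[-1]
  expect_true(all(diff(differential_entropy(jc)) > 0))
  # exact round trip with the inflection transform
  expect_equal(unname(inflection_to_jitter(differential_entropy(jc))),
               unname(jc), tolerance = 1e-12)
  expect_error(differential_entropy(0), "undefined")
  expect_error(differential_entropy(-0.1), "undefined")
})

test_that("jitter realization honors all component invariants", {
  spec <- tone_spec(400, 0)
  r0 <- jitter_frequencies(spec)
  expect_identical(r0$components, 400 * seq_len(length(r0$components)))
  expect_true(all(r0$components < spec$nyquist))

  set.seed(101)
  for (jc in c(0.023, 0.108, 0.5)) {
    sp <- tone_spec(250, jc)
    for (i in 1:20) {
      r <- jitter_frequencies(sp)
      expect_identical(r$components[1], 250)
      expect_true(all(abs(r$components / r$base_harmonics - 1) <= jc + 1e-12))
      expect_true(all(diff(r$components) >= sp$min_spacing - 1e-9))
      expect_true(all(r$components < sp$nyquist))
    }
  }
})

test_that("accepted draws keep 30 Hz spacing even at maximal jitter", {
  set.seed(202)
  sp <- tone_spec(200, 0.5)
  min_gap <- replicate(300, min(diff(jitter_frequencies(sp)$components)))
  expect_true(all(min_gap >= 30 - 1e-9))
})

test_that("jitter draws are zero-mean where the spacing constraint is slack", {
  # widely spaced harmonics: rejection essentially never triggers, so the
  # accepted draws follow the raw U(-jc, jc) law
  set.seed(303)
  sp <- tone_spec(2000, 0.05)
  draws <- replicate(4000, jitter_frequencies(sp)$jitter_draws[2])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
  expect_lt(max(abs(draws)), 0.05 + 1e-12)
})

test_that("synthesis yields the right length and spectral content", {
  set.seed(7)
  spec <- tone_spec(400, 0)
  w <- synthesize_tone(spec)
  expect_length(w, 3360) # 0.070 s x 48 kHz

  # spectral oracle: unfiltered, unramped render has FFT peaks at the
  # realized components (within one bin)
  sp2 <- tone_spec(3000, 0, duration = 0.2)
  r <- jitter_frequencies(sp2)
  x <- synthesize_tone(sp2, r, apply_filter = FALSE, apply_ramp = FALSE,
                       normalize = FALSE)
  mag <- Mod(fft(x))[1:(length(x) / 2)]
  bin <- 48000 / length(x)
  peaks <- which(diff(sign(diff(mag))) < 0) + 1L
  peaks <- peaks[order(mag[peaks], decreasing = TRUE)][seq_along(r$components)]
  got <- sort((peaks - 1) * bin)
  expect_true(all(abs(got - r$components) <= bin))
})

test_that("high-pass filter attenuates the fundamental region steeply", {
  # 4th-order Butterworth, 24 dB/octave: 400 Hz sits ~3.1 octaves below
  # 3500 Hz, so relative attenuation must exceed 70 dB
  bf <- signal::butter(4, 3500 / 24000, type = "high")
  h <- signal::freqz(bf$b, bf$a, region = NULL,
                     w = 2 * pi * c(400, 3500) / 48000)
  rel_db <- 20 * log10(Mod(h$h[1]) / Mod(h$h[2]))
  expect_lt(rel_db, -70)

  # and the rendered tone's spectrum reflects it
  set.seed(8)
  spec <- tone_spec(400, 0, duration = 0.2)
  r <- jitter_frequencies(spec)
  x <- synthesize_tone(spec, r, apply_ramp = FALSE, normalize = FALSE)
  mag <- Mod(fft(x))
  at <- function(f) mag[round(f * length(x) / 48000) + 1]
  expect_lt(20 * log10(at(400) / at(4000)), -50)
})

test_that("synthesis is bit-reproducible under a fixed seed", {
  spec <- tone_spec(300, 0.065, seed = 77L)
  a <- render_stimulus(spec)
  b <- render_stimulus(spec)
  expect_identical(a$waveform, b$waveform)
  expect_identical(a$realization$components, b$realization$components)
})

test_that("stimulus manifest enumerates every cell without rendering", {
  m <- stimulus_manifest(seq(200, 500, 50), jitter_schedule()[1:8], 3,
                         seed = 5)
  expect_identical(nrow(m), 7L * 8L * 3L)
  expect_setequal(unique(m$jitter_condition), paste0("j", 0:7))
  expect_identical(anyDuplicated(m$seed), 0L)
  expect_true(all(m$jitter_rate[m$jitter_condition == "j0"] == 0))
})
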