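# Shared deterministic fixtures, built in code at load time.

fix_small <- make_fixtures("small", seed = 42L)

# closed-form mean of a Gaussian deflection over a +/- half_width window
# centered on `center` (continuous-time reference for peak-amplitude tests)
gaussian_window_mean <- function(height, sd, half_width = 25) {
  height * sd * sqrt(2 * pi) * (2 * stats::pnorm(half_width / sd) - 1) /
    (2 * half_width)
}
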