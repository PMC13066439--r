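test_that("sigmoid fit recovers noise-free generating parameters", {
  gp <- generative_params(L_sd = 0, resid_sd = 0, seed = 1)
  fit <- fit_sigmoid_mixed(generate_peak_table(gp))
  expect_true(fit$converged)
  expect_equal(fit$L, gp$L_mean, tolerance = 1e-5)
  expect_equal(fit$k, gp$k, tolerance = 1e-5)
  expect_equal(fit$I0, gp$I0, tolerance = 1e-5)
  expect_lt(fit$sigma, 1e-4) # residual variance collapses on exact data

  # no participant spread but real noise: the random asymptote stays small
  gp2 <- generative_params(L_sd = 0, resid_sd = 0.3, seed = 2)
  fit2 <- fit_sigmoid_mixed(generate_peak_table(gp2))
  expect_lt(fit2$sigma_L, 0.15)
})

test_that("sigmoid fit matches (or beats) an independent NLME fit", {
  tab <- generate_peak_table(generative_params(seed = 7))
  mine <- fit_sigmoid_mixed(tab)
  d <- tab
  d$participant <- factor(d$participant)
  ref <- nlme::nlme(mmn_amplitude ~ L / (1 + exp(k * (entropy - I0))),
                    data = d, fixed = L + k + I0 ~ 1,
                    random = L ~ 1 | participant,
                    start = c(L = -1.5, k = 8, I0 = -1.2), method = "ML")
  # same likelihood surface: the profiled optimizer must not fall short
  expect_gte(mine$loglik, as.numeric(stats::logLik(ref)) - 1e-3)
  fe <- nlme::fixef(ref)
  expect_equal(mine$L, unname(fe["L"]), tolerance = 0.05)
  expect_equal(mine$I0, unname(fe["I0"]), tolerance = 0.05)
  expect_equal(mine$sigma, ref$sigma, tolerance = 0.05)
})

test_that("information-criterion identities hold for every fit type", {
  tab <- fix_small$peaks
  for (fit in list(fit_sigmoid_mixed(tab), fit_null_mixed(tab),
                   fit_polynomial_mixed(tab, degree = 2))) {
    expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-10)
    expect_equal(fit$bic, fit$n_params * log(fit$n_obs) - 2 * fit$loglik,
                 tolerance = 1e-10)
  }
})

test_that("fits refuse tables containing the harmonic condition", {
  tab <- fix_small$peaks
  tab$entropy[1] <- NA_real_
  expect_error(fit_sigmoid_mixed(tab), "entropy")
  expect_error(fit_polynomial_mixed(tab), "entropy")
})

test_that("polynomial fits are exact on noise-free polynomial data", {
  I <- differential_entropy(jitter_schedule()[2:8])
  tab <- expand.grid(participant = 1:6, entropy = I)
  tab$mmn_amplitude <- 2 - 1.5 * tab$entropy
  lin <- fit_polynomial_mixed(tab, degree = 1)
  expect_equal(unname(lin$coefficients), c(2, -1.5), tolerance = 1e-7)
  expect_lt(lin$sigma, 1e-4)

  # inverted parabola: vertex recovered in closed form
  tab$p3a_amplitude <- -0.8 * tab$entropy^2 - 2.256 * tab$entropy - 0.59
  quad <- fit_polynomial_mixed(tab, response = "p3a_amplitude", degree = 2)
  v <- quadratic_vertex(quad)
  expect_equal(v$vertex, 2.256 / (2 * -0.8), tolerance = 1e-6) # -b/(2a)
  expect_identical(v$type, "maximum")
})

test_that("mixed-model likelihood agrees with a brute-force marginal grid", {
  # tiny balanced table: compare the lme ML likelihood with a direct
  # evaluation of the Gaussian marginal likelihood maximized on a grid
  set.seed(61)
  I <- differential_entropy(jitter_schedule()[2:5])
  tab <- expand.grid(participant = 1:4, entropy = I)
  tab$mmn_amplitude <- -1 + 0.8 * tab$entropy +
    rep(rnorm(4, 0, 0.5), 4) + rnorm(16, 0, 0.3)
  fit <- fit_polynomial_mixed(tab, degree = 1)

  marg_ll <- function(b0, b1, s_u, s_e) {
    ll <- 0
    for (p in 1:4) {
      d <- tab[tab$participant == p, ]
      r <- d$mmn_amplitude - b0 - b1 * d$entropy
      V <- diag(s_e^2, 4) + s_u^2
      ll <- ll - 0.5 * (4 * log(2 * pi) + determinant(V)$modulus +
                          t(r) %*% solve(V, r))
    }
    as.numeric(ll)
  }
  at_fit <- marg_ll(fit$coefficients[1], fit$coefficients[2],
                    fit$random_intercept_sd, fit$sigma)
  expect_equal(at_fit, fit$loglik, tolerance = 1e-6)
  # no grid point beats the reported optimum
  grid <- expand.grid(b0 = fit$coefficients[1] + c(-0.2, 0, 0.2),
                      b1 = fit$coefficients[2] + c(-0.2, 0, 0.2),
                      s_u = pmax(fit$random_intercept_sd + c(-0.1, 0, 0.1), 1e-3),
                      s_e = pmax(fit$sigma + c(-0.1, 0, 0.1), 1e-3))
  vals <- mapply(marg_ll, grid$b0, grid$b1, grid$s_u, grid$s_e)
  expect_lte(max(vals), fit$loglik + 1e-6)
})

test_that("likelihood-ratio testing enforces nesting and the chi-square map", {
  tab <- fix_small$peaks
  null <- fit_null_mixed(tab)
  sig <- fit_sigmoid_mixed(tab)
  lin <- fit_polynomial_mixed(tab, degree = 1)
  quad <- fit_polynomial_mixed(tab, degree = 2)

  lrt <- lr_test(null, sig)
  expect_identical(lrt$df, 2L)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$p, pchisq(lrt$chi2, 2, lower.tail = FALSE))

  expect_identical(lr_test(null, lin)$df, 1L)
  expect_identical(lr_test(lin, quad)$df, 1L)
  expect_error(lr_test(lin, sig), "not nested")
  expect_error(lr_test(quad, lin), "not nested")

  # identical fits: chi2 = 0, p = 1
  same <- lr_test(null, structure(modifyList(null, list(model = "poly1",
                                                        degree = 1L,
                                                        n_params = 4L)),
                                  class = class(null)))
  expect_identical(same$chi2, 0)
  expect_identical(same$p, 1)
})

test_that("entropy transform and inflection inversion are exact inverses", {
  expect_identical(inflection_to_jitter(0), 0.5)
  expect_identical(round(inflection_to_jitter(-1.18), 3), 0.033)
  jc <- jitter_schedule()[-1]
  expect_equal(unname(inflection_to_jitter(differential_entropy(jc))),
               unname(jc), tolerance = 1e-12)
})

test_that("quadratic vertex arithmetic and orientation flags", {
  v <- quadratic_vertex(c(0, -2.82, -1))
  expect_equal(v$vertex, -1.41, tolerance = 1e-12)
  expect_identical(v$type, "maximum")
  expect_identical(quadratic_vertex(c(0, 2, 1))$type, "minimum")
  expect_error(quadratic_vertex(c(1, 2, 0)), "zero")
})
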