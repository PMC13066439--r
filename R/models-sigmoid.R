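# Sigmoid mixed-effects model of MMN amplitude versus differential entropy:
#
#   y_pc = L_p * s_c(k, I0) + e_pc,   s_c = 1 / (1 + exp(k * (I_c - I0)))
#   L_p ~ N(L, sigma_L^2),            e_pc ~ N(0, sigma^2)
#
# Conditional on (k, I0) the model is linear in L_p, so the marginal
# likelihood is Gaussian in closed form — no quadrature. With the variance
# ratio lambda = sigma_L^2 / sigma^2, both L (by GLS) and sigma^2 are
# profiled out analytically, leaving a 3-parameter optimization over
# (log k, I0, log lambda), multi-started from a coarse grid to dodge the
# local optima typical of logistic fits.

# per-participant data: list of list(y, I)
split_by_participant <- function(table, response) {
  stopifnot(all(c("participant", "entropy", response) %in% names(table)))
  if (any(!is.finite(table$entropy)))
    stop("table contains rows with undefined entropy (harmonic condition?); ",
         "drop them before fitting")
  lapply(split(table, table$participant),
         function(d) list(y = d[[response]], I = d$entropy))
}

# profiled marginal log-likelihood and the profiled estimates at theta
sigmoid_profile <- function(theta, data) {
  k <- exp(theta[1]); I0 <- theta[2]; lam <- exp(theta[3])
  num <- 0; den <- 0
  ss_list <- vector("list", length(data))
  for (i in seq_along(data)) {
    d <- data[[i]]
    s <- 1 / (1 + exp(k * (d$I - I0)))
    ss <- sum(s * s)
    dd <- 1 + lam * ss
    num <- num + sum(s * d$y) / dd
    den <- den + ss / dd
    ss_list[[i]] <- list(s = s, ss = ss, dd = dd)
  }
  L <- num / den
  quad <- 0; logdet <- 0; N <- 0
  for (i in seq_along(data)) {
    d <- data[[i]]; sl <- ss_list[[i]]
    r <- d$y - L * sl$s
    quad <- quad + sum(r * r) - lam * sum(sl$s * r)^2 / sl$dd
    logdet <- logdet + log(sl$dd)
    N <- N + length(d$y)
  }
  sigma2 <- max(quad / N, 1e-12)
  ll <- -N / 2 * (log(2 * pi) + 1 + log(sigma2)) - logdet / 2
  list(loglik = ll, L = L, k = k, I0 = I0,
       sigma = sqrt(sigma2), sigma_L = sqrt(lam * sigma2), N = N)
}

#' Fit the sigmoid mixed-effects model with random asymptote
#'
#' Maximum-likelihood fit of
#' `amplitude = L_p / (1 + exp(k * (I - I0)))` with a participant-random
#' left asymptote `L_p ~ N(L, sigma_L^2)` and Gaussian residuals, where `I`
#' is the differential entropy of the jitter distribution. The marginal
#' likelihood is Gaussian and is profiled analytically over `L` and the
#' residual variance, so only `(k, I0, sigma_L/sigma)` are optimized
#' numerically (multi-start Nelder-Mead plus BFGS polish).
#'
#' @param table Peak table (long format) with columns `participant`,
#'   `entropy` and the response; must exclude the harmonic condition, whose
#'   entropy is undefined.
#' @param response Response column (default `"mmn_amplitude"`).
#' @param start Optional named starting values `c(k =, I0 =)`.
#' @param n_starts Number of coarse-grid starts refined by Nelder-Mead.
#' @return Object of classes `sigmoid_fit`/`mmn_fit`: `L`, `k`, `I0`,
#'   `sigma_L`, `sigma`, `loglik`, `aic`, `bic`, `n_obs`, `n_participants`,
#'   `n_params` (5: three fixed effects and two variance components),
#'   `converged`, `boundary` (`TRUE` when `sigma_L` collapsed to ~0).
#' @export
#' @examples
#' tab <- generate_peak_table(generative_params(seed = 1))
#' fit <- fit_sigmoid_mixed(tab)
#' c(fit$L, fit$k, fit$I0)
fit_sigmoid_mixed <- function(table, response = "mmn_amplitude",
                              start = NULL, n_starts = 3L) {
  data <- split_by_participant(table, response)
  if (length(data) < 2L) stop("need at least 2 participants")
  if (length(unique(table$entropy)) < 3L)
    stop("need at least 3 distinct conditions")
  I_all <- table$entropy

  obj <- function(theta) -sigmoid_profile(theta, data)$loglik

  if (!is.null(start)) {
    starts <- list(c(log(start[["k"]]), start[["I0"]], 0))
  } else {
    grid <- expand.grid(logk = log(c(2, 5, 10, 20)),
                        I0 = seq(min(I_all), max(I_all), length.out = 5),
                        loglam = c(-2, 0))
    vals <- apply(grid, 1, obj)
    ord <- order(vals)[seq_len(min(n_starts, nrow(grid)))]
    starts <- lapply(ord, function(i) as.numeric(grid[i, ]))
  }

  best <- NULL
  for (s0 in starts) {
    opt <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  polish <- tryCatch(
    stats::optim(best$par, obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  prof <- sigmoid_profile(best$par, data)
  n_params <- 5L
  boundary <- prof$sigma_L < 1e-3 * max(prof$sigma, 1e-12)
  structure(list(
    model = "sigmoid", L = prof$L, k = prof$k, I0 = prof$I0,
    sigma_L = prof$sigma_L, sigma = prof$sigma,
    loglik = prof$loglik,
    aic = 2 * n_params - 2 * prof$loglik,
    bic = n_params * log(prof$N) - 2 * prof$loglik,
    n_obs = prof$N, n_participants = length(data),
    n_params = n_params,
    converged = best$convergence == 0, boundary = boundary,
    response = response
  ), class = c("sigmoid_fit", "mmn_fit"))
}

#' Jitter rate at a given differential entropy
#'
#' Exact inverse of [differential_entropy()]: `10^I0 / 2`. Used to translate
#' a fitted inflection point back to a jitter rate.
#'
#' @param I0 Entropy value(s) in log10 units.
#' @return Jitter rate(s).
#' @export
#' @examples
#' inflection_to_jitter(-1.18) # about 0.033
inflection_to_jitter <- function(I0) 10^I0 / 2

#' @export
print.mmn_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects fit (%s) of %s, ML\n", x$model, x$response))
  if (x$model == "sigmoid") {
    cat(sprintf("  L = %.3f uV, k = %.2f, I0 = %.3f (jitter %.4f)\n",
                x$L, x$k, x$I0, inflection_to_jitter(x$I0)))
    cat(sprintf("  sigma_L = %.3f, sigma = %.3f%s\n", x$sigma_L, x$sigma,
                if (isTRUE(x$boundary)) " [boundary]" else ""))
  } else if (!is.null(x$coefficients)) {
    cat("  fixed effects:", paste(sprintf("%.4f", x$coefficients),
                                  collapse = ", "), "\n")
    cat(sprintf("  random-intercept SD = %.3f, sigma = %.3f\n",
                x$random_intercept_sd, x$sigma))
  }
  cat(sprintf("  logLik = %.2f, AIC = %.1f, BIC = %.1f (n = %d, %d params)\n",
              x$loglik, x$aic, x$bic, x$n_obs, x$n_params))
  invisible(x)
}
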