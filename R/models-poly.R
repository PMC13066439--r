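# Polynomial and null mixed models (random intercept) via nlme::lme with
# ML estimation — ML, not REML, so likelihood-ratio tests and information
# criteria are comparable across fixed-effect structures.

lme_to_fit <- function(m, model, degree, n_fixed, response) {
  ll <- as.numeric(stats::logLik(m))
  n_obs <- m$dims$N
  n_params <- n_fixed + 2L # fixed effects + random-intercept SD + residual SD
  vc <- nlme::VarCorr(m)
  structure(list(
    model = model, degree = degree,
    coefficients = nlme::fixef(m),
    random_intercept_sd = as.numeric(vc["(Intercept)", "StdDev"]),
    sigma = m$sigma, loglik = ll,
    aic = 2 * n_params - 2 * ll,
    bic = n_params * log(n_obs) - 2 * ll,
    n_obs = n_obs, n_participants = m$dims$ngrps[[1]],
    n_params = n_params, converged = TRUE,
    response = response, lme = m
  ), class = c("poly_fit", "mmn_fit"))
}

#' Fit a polynomial mixed model of amplitude versus entropy
#'
#' Random-intercept model with fixed-effect powers of the differential
#' entropy `I` up to `degree` (1 to 4), estimated by maximum likelihood with
#' [nlme::lme()]. Degree-2 fits feed [quadratic_vertex()].
#'
#' @inheritParams fit_sigmoid_mixed
#' @param degree Polynomial degree, 1-4.
#' @return Object of classes `poly_fit`/`mmn_fit` with raw-power
#'   `coefficients` (intercept first), `random_intercept_sd`, `sigma`,
#'   `loglik`, `aic`, `bic`.
#' @export
fit_polynomial_mixed <- function(table, response = "mmn_amplitude", degree = 1L) {
  degree <- as.integer(degree)
  stopifnot(degree >= 1L, degree <= 4L)
  data <- data.frame(y = table[[response]], I = table$entropy,
                     participant = factor(table$participant))
  if (any(!is.finite(data$I)))
    stop("table contains rows with undefined entropy; drop them before fitting")
  if (length(unique(data$I)) <= degree)
    stop("need more distinct conditions than the polynomial degree")
  form <- stats::as.formula(sprintf("y ~ poly(I, %d, raw = TRUE)", degree))
  m <- nlme::lme(form, random = ~ 1 | participant,
                 data = data, method = "ML")
  fit <- lme_to_fit(m, paste0("poly", degree), as.integer(degree),
                    n_fixed = degree + 1L, response = response)
  names(fit$coefficients) <- c("(Intercept)", paste0("I^", seq_len(degree)))
  fit
}

#' Fit the intercept-only null mixed model
#'
#' Random-intercept model with no entropy effect; the baseline for
#' likelihood-ratio tests against the polynomial and sigmoid fits.
#'
#' @inheritParams fit_sigmoid_mixed
#' @return Object of classes `poly_fit`/`mmn_fit` (3 parameters).
#' @export
fit_null_mixed <- function(table, response = "mmn_amplitude") {
  data <- data.frame(y = table[[response]],
                     participant = factor(table$participant))
  m <- nlme::lme(y ~ 1, random = ~ 1 | participant, data = data, method = "ML")
  lme_to_fit(m, "null", 0L, n_fixed = 1L, response = response)
}

# nesting rules for likelihood-ratio testing
models_nested <- function(smaller, larger) {
  s <- smaller$model; l <- larger$model
  if (s == "null" && l == "sigmoid") return(TRUE)
  if (s == "null" && grepl("^poly", l)) return(TRUE)
  if (grepl("^poly", s) && grepl("^poly", l))
    return(smaller$degree < larger$degree)
  FALSE
}

#' Likelihood-ratio test of two nested ML fits
#'
#' `chi2 = 2 * (logLik_larger - logLik_smaller)` referred to a chi-square
#' with df equal to the parameter-count difference. Refuses non-nested
#' pairs (e.g. sigmoid versus linear), whose likelihood-ratio distribution
#' is unknown for mixed models — compare those by AIC/BIC instead. A larger
#' model with a materially lower log-likelihood signals an optimization
#' failure and is an error.
#'
#' @param smaller,larger `mmn_fit` objects fit by ML on the same data.
#' @return List with `chi2`, `df`, `p`.
#' @export
#' @examples
#' tab <- generate_peak_table(generative_params(seed = 2))
#' lr_test(fit_null_mixed(tab), fit_sigmoid_mixed(tab))
lr_test <- function(smaller, larger) {
  stopifnot(inherits(smaller, "mmn_fit"), inherits(larger, "mmn_fit"))
  if (smaller$n_obs != larger$n_obs)
    stop("fits are not on the same data (different n_obs)")
  if (!models_nested(smaller, larger))
    stop("models '", smaller$model, "' and '", larger$model,
         "' are not nested; the likelihood-ratio distribution is unknown ",
         "for non-nested mixed models, compare AIC/BIC instead")
  chi2 <- 2 * (larger$loglik - smaller$loglik)
  if (chi2 < -1e-6)
    stop("larger model has a lower log-likelihood; optimization failure")
  chi2 <- max(chi2, 0)
  df <- larger$n_params - smaller$n_params
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Vertex of a quadratic fit
#'
#' Location `-b / (2a)` of the extremum of a degree-2 fit in entropy units,
#' flagged as a maximum (inverted-U, `a < 0`) or minimum.
#'
#' @param fit A degree-2 `poly_fit`, or a numeric vector
#'   `c(intercept, b, a)` of raw-power coefficients.
#' @return List with `vertex` (entropy), `value` (fitted amplitude there)
#'   and `type` (`"maximum"` or `"minimum"`).
#' @export
quadratic_vertex <- function(fit) {
  co <- if (inherits(fit, "mmn_fit")) {
    if (!identical(fit$degree, 2L)) stop("need a degree-2 fit")
    fit$coefficients
  } else fit
  stopifnot(length(co) == 3)
  a <- co[[3]]; b <- co[[2]]; c0 <- co[[1]]
  if (a == 0) stop("leading coefficient is zero; no vertex")
  v <- -b / (2 * a)
  list(vertex = v, value = a * v^2 + b * v + c0,
       type = if (a < 0) "maximum" else "minimum")
}
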