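#' Per-condition one-sample t-tests with FDR control
#'
#' Two-tailed one-sample t-tests of the response against zero, one per
#' condition, with Benjamini-Hochberg adjustment across the conditions of
#' this one response family (run MMN and P3a separately so each family is
#' corrected on its own).
#'
#' @param table Peak table with `participant`, `condition` and the response.
#' @param response Response column.
#' @param q FDR level recorded alongside the decisions.
#' @return `data.frame`: `condition`, `mean`, `t`, `df`, `p`, `p_adj`,
#'   `significant`.
#' @export
amplitude_ttests <- function(table, response = "mmn_amplitude", q = 0.05) {
  groups <- split(table[[response]], table$condition)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("need at least 2 participants per condition")
  rows <- lapply(names(groups), function(cn) {
    x <- groups[[cn]]
    if (stats::sd(x) == 0 && mean(x) == 0) {
      data.frame(condition = cn, mean = 0, t = 0,
                 df = length(x) - 1, p = 1)
    } else {
      tt <- stats::t.test(x, mu = 0)
      data.frame(condition = cn, mean = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < q
  rownames(out) <- NULL
  out
}

# core one-way repeated-measures ANOVA on a participants x conditions matrix
rm_anova_matrix <- function(Y) {
  n <- nrow(Y); p <- ncol(Y)
  stopifnot(n >= 2, p >= 2)
  gm <- mean(Y)
  cm <- colMeans(Y)
  pm <- rowMeans(Y)
  ss_cond <- n * sum((cm - gm)^2)
  resid <- Y - matrix(pm, n, p) - matrix(cm, n, p, byrow = TRUE) + gm
  ss_err <- sum(resid^2)
  df1 <- p - 1L
  df2 <- (n - 1L) * (p - 1L)
  ms_err <- ss_err / df2
  f_value <- (ss_cond / df1) / ms_err

  # Greenhouse-Geisser epsilon from the double-centered condition covariance
  S <- stats::cov(Y)
  Sc <- S - matrix(rowMeans(S), p, p) - matrix(colMeans(S), p, p, byrow = TRUE) +
    mean(S)
  eps <- sum(diag(Sc))^2 / (df1 * sum(Sc^2))
  eps <- min(1, max(eps, 1 / df1))

  # Mauchly's sphericity test on orthonormalized contrasts
  H <- stats::contr.helmert(p)
  H <- H %*% diag(1 / sqrt(colSums(H^2)), df1, df1)
  A <- t(H) %*% S %*% H
  detA <- det(A)
  mauchly_w <- if (detA <= 0) 0 else detA / (sum(diag(A)) / df1)^df1
  fcorr <- 1 - (2 * df1^2 + df1 + 2) / (6 * df1 * (n - 1))
  df_m <- df1 * (df1 + 1) / 2 - 1
  mauchly_p <- if (df_m < 1 || mauchly_w <= 0) NA_real_ else
    stats::pchisq(-(n - 1) * fcorr * log(mauchly_w), df_m, lower.tail = FALSE)

  list(f_value = f_value, df_num = df1, df_den = df2,
       ss_cond = ss_cond, ss_err = ss_err, ms_err = ms_err,
       gg_epsilon = eps,
       p_uncorrected = stats::pf(f_value, df1, df2, lower.tail = FALSE),
       p_gg = stats::pf(f_value, eps * df1, eps * df2, lower.tail = FALSE),
       mauchly_w = mauchly_w, mauchly_p = mauchly_p,
       n_participants = n, n_conditions = p, condition_means = cm)
}

table_to_wide <- function(table, response) {
  tab <- table[, c("participant", "condition", response)]
  wide <- stats::reshape(tab, idvar = "participant", timevar = "condition",
                         direction = "wide")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  if (any(is.na(Y)))
    stop("incomplete participant x condition grid")
  colnames(Y) <- sub(paste0("^", response, "\\."), "", colnames(Y))
  Y
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate within-participant F-test of a condition effect on a complete
#' participant x condition grid. The Greenhouse-Geisser epsilon is computed
#' from the double-centered condition covariance matrix and applied to the
#' degrees of freedom; Mauchly's sphericity test is reported so callers can
#' decide when the correction matters (the corrected p is always available).
#'
#' @param table Long peak table with `participant`, `condition` and the
#'   response; the grid must be complete.
#' @param response Response column.
#' @return Object of class `rm_anova`: `f_value`, `df_num`, `df_den`,
#'   `gg_epsilon`, `p_uncorrected`, `p_gg`, `mauchly_w`, `mauchly_p`, plus
#'   the error-term components used by [posthoc_pairwise()].
#' @export
#' @examples
#' tab <- generate_peak_table(generative_params(seed = 3))
#' rm_anova(tab)$df_num
rm_anova <- function(table, response = "mmn_amplitude") {
  res <- rm_anova_matrix(table_to_wide(table, response))
  res$response <- response
  class(res) <- "rm_anova"
  res
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s\n", x$response))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.4g; GG epsilon = %.3f, p_GG = %.4g\n",
              x$df_num, x$df_den, x$f_value, x$p_uncorrected,
              x$gg_epsilon, x$p_gg))
  cat(sprintf("  Mauchly W = %.3f, p = %.4g\n", x$mauchly_w, x$mauchly_p))
  invisible(x)
}

#' Tukey-adjusted pairwise comparisons between conditions
#'
#' All pairwise paired mean differences between conditions, tested against
#' the repeated-measures ANOVA error term and adjusted with the studentized
#' range (Tukey) distribution, the same adjustment estimated-marginal-means
#' software applies to a balanced within-participant design.
#'
#' @inheritParams rm_anova
#' @return `data.frame`: `condition_1`, `condition_2`, `diff`, `se`, `t`,
#'   `p_adj` (one row per unordered pair).
#' @export
posthoc_pairwise <- function(table, response = "mmn_amplitude") {
  Y <- table_to_wide(table, response)
  if (ncol(Y) < 2L) stop("need at least 2 conditions")
  an <- rm_anova_matrix(Y)
  n <- an$n_participants; p <- an$n_conditions
  cm <- an$condition_means
  se <- sqrt(2 * an$ms_err / n)
  pairs <- utils::combn(colnames(Y), 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- cm[[pr[1]]] - cm[[pr[2]]]
    tval <- d / se
    data.frame(condition_1 = pr[1], condition_2 = pr[2], diff = d, se = se,
               t = tval,
               p_adj = stats::ptukey(abs(tval) * sqrt(2), nmeans = p,
                                     df = an$df_den, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
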