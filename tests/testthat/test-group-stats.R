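test_that("one-sample t-tests match stats::t.test with BH adjustment", {
  tab <- fix_small$peaks
  res <- amplitude_ttests(tab)
  for (i in seq_len(nrow(res))) {
    x <- tab$mmn_amplitude[tab$condition == res$condition[i]]
    ref <- t.test(x, mu = 0)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
  }
  expect_equal(res$p_adj, p.adjust(res$p, "BH"), tolerance = 1e-14)
  # adjusted p non-decreasing in raw-p order
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-14))
})

test_that("BH step-up rule rejects all of a tight ascending p set", {
  # p = (0.01, 0.02, 0.03, 0.04) at q = 0.05: max i with p_i <= 0.05*i/4
  # is i = 4, so every hypothesis is rejected
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_true(all(p.adjust(p, "BH") < 0.05))
})

test_that("all-zero data give t = 0 and p = 1", {
  tab <- data.frame(participant = rep(1:5, 2),
                    condition = rep(c("a", "b"), each = 5),
                    mmn_amplitude = 0)
  res <- amplitude_ttests(tab)
  expect_identical(res$t, c(0, 0))
  expect_identical(res$p, c(1, 1))
})

test_that("repeated-measures ANOVA agrees with car's univariate tests", {
  skip_if_not_installed("car")
  tab <- generate_peak_table(generative_params(n_participants = 20,
                                               seed = 5))
  a <- rm_anova(tab)
  Y <- inharmmn:::table_to_wide(tab, "mmn_amplitude")
  av <- car::Anova(lm(Y ~ 1),
                   idata = data.frame(cond = factor(colnames(Y))),
                   idesign = ~cond, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  expect_equal(a$f_value, s$univariate.tests["cond", "F value"],
               tolerance = 1e-8)
  expect_equal(a$gg_epsilon, s$pval.adjustments["cond", "GG eps"],
               tolerance = 1e-8)
  expect_equal(a$p_gg, s$pval.adjustments["cond", "Pr(>F[GG])"],
               tolerance = 1e-8)
})

test_that("Mauchly statistic matches stats::mauchly.test", {
  tab <- generate_peak_table(generative_params(n_participants = 20,
                                               conditions = jitter_schedule()[2:6],
                                               seed = 9))
  a <- rm_anova(tab)
  Y <- inharmmn:::table_to_wide(tab, "mmn_amplitude")
  ref <- mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(a$mauchly_w, unname(ref$statistic), tolerance = 1e-10)
  # chi-square approximations differ in a higher-order term; p agrees closely
  expect_equal(a$mauchly_p, ref$p.value, tolerance = 0.01)
})

test_that("ANOVA degrees of freedom follow the design size", {
  tab <- generate_peak_table(generative_params(n_participants = 35,
                                               seed = 6))
  tab$condition2 <- tab$condition
  a <- rm_anova(tab)
  expect_identical(c(a$df_num, a$df_den), c(6L, 204L)) # 7 conditions
  expect_error(rm_anova(tab[-1, ]), "incomplete")
})

test_that("compound-symmetric data give epsilon near 1", {
  set.seed(62)
  n <- 200
  Y <- matrix(rnorm(n * 5, 0, 1), n, 5) + rnorm(n, 0, 1.5)
  a <- inharmmn:::rm_anova_matrix(Y)
  expect_gt(a$gg_epsilon, 0.95)
  expect_lte(a$gg_epsilon, 1)
})

test_that("Tukey post-hocs match emmeans on a balanced design", {
  skip_if_not_installed("emmeans")
  tab <- generate_peak_table(generative_params(
    n_participants = 20, conditions = jitter_schedule()[2:6], seed = 9))
  ph <- posthoc_pairwise(tab)
  expect_identical(nrow(ph), 10L) # C(5, 2) pairs
  d <- tab
  d$participant <- factor(d$participant)
  d$condition <- factor(d$condition)
  # inline the data frame into the call so emmeans can re-evaluate it
  m <- eval(bquote(stats::aov(
    mmn_amplitude ~ condition + Error(participant / condition), data = .(d))))
  pe <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(m, ~condition), "pairwise", adjust = "tukey"))
  expect_equal(ph$diff, pe$estimate, tolerance = 1e-10)
  expect_equal(ph$p_adj, pe$p.value, tolerance = 1e-8)
})

test_that("null condition effects produce uniformly high adjusted p", {
  set.seed(63)
  tab <- data.frame(participant = rep(1:15, each = 3),
                    condition = rep(c("a", "b", "c"), 15))
  tab$mmn_amplitude <- rnorm(45) + rep(rnorm(15), each = 3)
  ph <- posthoc_pairwise(tab)
  expect_true(all(ph$p_adj > 0.05))

  # eight conditions -> 28 pairs
  tab8 <- generate_peak_table(generative_params(
    n_participants = 6, conditions = jitter_schedule()[2:9], seed = 3))
  expect_identical(nrow(posthoc_pairwise(tab8)), 28L)
})
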