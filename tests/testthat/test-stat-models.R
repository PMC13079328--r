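test_that("saturated two-group NB fit reproduces sample-mean ratio", {
  d <- data.frame(y = c(1, 2, 3, 2, 4, 6),
                  group = rep(c("A", "B"), each = 3))
  m <- fit_count_model(d, "y", predictors = "group", family = "nb",
                       group = "group", ref_level = "A")
  ratio <- m$results$beta_exp[m$results$term == "groupB"]
  expect_equal(ratio, 2, tolerance = 1e-6)  # 4/2, the sample-mean ratio
  mu_a <- m$results$beta_exp[m$results$term == "(Intercept)"]
  expect_equal(mu_a, 2, tolerance = 1e-6)
})

test_that("null and non-null NB effects behave as expected", {
  set.seed(131)
  d <- data.frame(y = rnbinom(400, size = 2, mu = 10),
                  group = rep(c("A", "B"), each = 200))
  m <- fit_count_model(d, "y", predictors = "group", family = "nb",
                       group = "group", ref_level = "A")
  row <- m$results[m$results$term == "groupB", ]
  expect_lt(abs(row$estimate), 3 * row$se)
  expect_true(row$ci_low < 1 && row$ci_high > 1)
  # dispersion is estimated near truth (alpha = 1/size = 0.5)
  expect_equal(m$dispersion_alpha, 0.5, tolerance = 0.25)
  expect_error(fit_count_model(d, "y", predictors = "group",
                               family = "nb", group = "group",
                               ref_level = "Z"))
  d0 <- data.frame(y = rep(0L, 30), group = rep(c("A", "B"), 15))
  expect_error(fit_count_model(d0, "y", family = "nb"), "all-zero")
})

test_that("ZINB recovers the structural-zero share and rate structure", {
  set.seed(141)
  n <- 600
  mu <- 8
  pi_true <- 0.4
  y <- ifelse(runif(n) < pi_true, 0L, rnbinom(n, size = 2, mu = mu))
  d <- data.frame(y = y, group = rep(c("A", "B"), each = n / 2))
  m <- fit_count_model(d, "y", predictors = "group", family = "zinb",
                       group = "group", ref_level = "A")
  expect_equal(m$zero_inflation_pi, pi_true, tolerance = 0.1)
  expect_equal(m$results$beta_exp[m$results$term == "(Intercept)"], mu,
               tolerance = 0.15 * mu)
  expect_true(m$results$converged[1])
})

test_that("log-volume model standardizes the outcome scale", {
  set.seed(151)
  n <- 1000
  d <- data.frame(
    vol = exp(c(rnorm(n, 0, 1), rnorm(n, 0.5, 1))),
    group = rep(c("A", "B"), each = n))
  m <- fit_log_volume_model(d, "vol", predictors = "group",
                            group = "group", ref_level = "A")
  b <- m$results$std_beta[m$results$term == "groupB"]
  # true difference 0.5 on pooled-SD ~ sqrt(1 + 0.25/4) scale
  expect_equal(b, 0.5 / sqrt(1 + 0.25 / 4), tolerance = 0.1)
  # identical groups give a near-zero beta
  d2 <- d
  d2$group <- sample(d2$group)
  m2 <- fit_log_volume_model(d2, "vol", predictors = "group",
                             group = "group", ref_level = "A")
  expect_lt(abs(m2$results$std_beta[m2$results$term == "groupB"]), 0.15)
  # zero volumes are excluded and reported
  d3 <- d[c(1:25, (n + 1):(n + 25)), ]
  d3$vol[1:7] <- 0
  m3 <- fit_log_volume_model(d3, "vol", predictors = "group",
                             group = "group", ref_level = "A")
  expect_equal(m3$n_excluded_zero, 7)
  expect_equal(m3$results$n_obs[1], 43)
  expect_error(fit_log_volume_model(data.frame(vol = c(0, 0, 1, 2)), "vol",
                                    predictors = NULL), "positive-volume")
})

test_that("interaction model needs two groups and reports product terms", {
  set.seed(161)
  n <- 300
  d <- data.frame(group = rep(c("A", "B"), each = n),
                  wml = rnorm(2 * n))
  d$y <- rnbinom(2 * n, size = 2, mu = exp(2 + 0.3 * d$wml))
  m <- interaction_model(d, "y", group = "group", wml_col = "wml",
                         outcome_type = "count", ref_level = "A")
  it <- m$results[grepl(":", m$results$term), ]
  expect_equal(nrow(it), 1)
  # no true slope difference: interaction near zero
  expect_lt(abs(it$estimate), 3 * it$se)
  d1 <- d[d$group == "A", ]
  expect_error(interaction_model(d1, "y", group = "group", wml_col = "wml",
                                 outcome_type = "count"), "single group")
})

test_that("sequential contrasts equal re-leveled coefficients", {
  set.seed(171)
  n <- 200
  d <- data.frame(group = rep(c("CU", "MCI", "AD"), each = n))
  mu <- c(CU = 10, MCI = 14, AD = 12)[d$group]
  d$y <- rnbinom(3 * n, size = 2, mu = mu)
  m <- fit_count_model(d, "y", predictors = "group", family = "nb",
                       group = "group", ref_level = "CU")
  con <- sequential_contrasts(m, c("CU", "MCI", "AD"), group = "group")
  expect_equal(nrow(con), 2)
  # the contrast including the reference equals the raw coefficient
  expect_equal(con$estimate[1],
               m$results$estimate[m$results$term == "groupMCI"])
  # antisymmetry
  con_rev <- sequential_contrasts(m, c("AD", "MCI"), group = "group")
  expect_equal(con_rev$estimate[1], -con$estimate[2])
  # re-leveling oracle: refit with MCI as reference
  m2 <- fit_count_model(d, "y", predictors = "group", family = "nb",
                        group = "group", ref_level = "MCI")
  expect_equal(con$estimate[2],
               m2$results$estimate[m2$results$term == "groupAD"],
               tolerance = 1e-5)
  expect_equal(con$se[2], m2$results$se[m2$results$term == "groupAD"],
               tolerance = 1e-5)
  expect_error(sequential_contrasts(m, c("CU", "XX"), group = "group"),
               "absent")
})

test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(181)
  for (r in 1:200) {
    p <- runif(sample(1:25, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, naive_bh(p))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("Breusch-Pagan statistic is n times the auxiliary R-squared", {
  set.seed(191)
  n <- 200
  x <- rnorm(n)
  # homoscedastic: constant squared residuals give statistic 0
  bp0 <- breusch_pagan(rep(2, n), cbind(x))
  expect_equal(bp0$statistic, 0)
  expect_equal(bp0$p_value, 1)
  # heteroscedastic residuals: variance grows with x
  res <- rnorm(n, sd = sqrt(exp(1 + 1.5 * x)))
  bp1 <- breusch_pagan(res, cbind(x))
  expect_lt(bp1$p_value, 0.01)
  # cross-check against the reference implementation
  y <- 1 + 2 * x + res
  fit <- lm(y ~ x)
  bp2 <- breusch_pagan(resid(fit), cbind(x))
  ref <- lmtest::bptest(fit)
  expect_equal(bp2$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(bp2$p_value, unname(ref$p.value), tolerance = 1e-8)
  expect_error(breusch_pagan(rnorm(3), cbind(rnorm(3), rnorm(3))), "n > k")
  expect_error(breusch_pagan(rnorm(10), cbind(x[1:10], x[1:10])),
               "rank")
})

test_that("effect-size labels follow the reporting conventions", {
  expect_equal(effect_size_label(0.54, "std_beta"), "large")
  expect_equal(effect_size_label(-0.05, "std_beta"), "small")
  expect_equal(effect_size_label(0.2, "std_beta"), "medium")
  expect_equal(effect_size_label(0.4, "std_beta"), "medium-large")
  expect_equal(effect_size_label(1.0, "beta_exp"), "no change")
  expect_equal(effect_size_label(0.7, "beta_exp"), "decrease")
  expect_equal(effect_size_label(1.4, "beta_exp"), "increase")
  expect_error(effect_size_label(Inf, "std_beta"), "finite")
})
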