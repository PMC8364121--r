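test_that("z-scoring to a reference group behaves like a location-scale map", {
  vals <- c(10, 12, 14, 20, 30)
  ref <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  z <- zscore_to_reference(vals, ref)
  expect_equal(mean(z[ref]), 0)
  expect_equal(z[2], 0)                       # equals the reference mean
  expect_equal(zscore_to_reference(c(vals, 12 + 2), c(ref, FALSE))[6], 1)
  expect_error(zscore_to_reference(c(1, 1, 5), c(TRUE, TRUE, FALSE)),
               "zero standard deviation")
  expect_error(zscore_to_reference(1:5, c(TRUE, FALSE, FALSE, FALSE, FALSE)),
               "at least 2")
})

test_that("linear association recovers exact and null designs", {
  set.seed(21)
  n <- 60
  tab <- data.frame(y = rnorm(n), age = rnorm(n))
  tab$y_copy <- tab$y
  r <- suppressWarnings(fit_linear_association(tab, "y_copy", "y"))
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-12)
  # orthogonal predictor by construction
  x <- rnorm(n); y <- rnorm(n)
  y <- residuals(lm(y ~ x))                   # force exact orthogonality
  tab2 <- data.frame(x = x, y = y)
  r2 <- fit_linear_association(tab2, "y", "x")
  expect_lt(abs(r2$t), 1e-8)
})

test_that("association beta and se match the normal-equations oracle", {
  set.seed(31)
  n <- 80
  tab <- data.frame(x = rnorm(n), age = rnorm(n, 70, 8), sex = rbinom(n, 1, .5),
                    tiv = rnorm(n, 1450, 100))
  tab$y <- 0.6 * tab$x - 0.02 * tab$age + 0.3 * tab$sex + rnorm(n)
  r <- fit_linear_association(tab, "y", "x", c("age", "sex", "tiv"))
  X <- cbind(1, tab$x, tab$age, tab$sex, tab$tiv)
  beta_hat <- solve(t(X) %*% X, t(X) %*% tab$y)
  resid <- tab$y - X %*% beta_hat
  s2 <- sum(resid^2) / (n - ncol(X))
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(r$beta, beta_hat[2], tolerance = 1e-8)
  expect_equal(r$se, se[2], tolerance = 1e-8)
  expect_equal(r$n, n)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  set.seed(41)
  tab <- data.frame(y = rnorm(30), x = rnorm(30))
  tab$x2 <- 2 * tab$x
  expect_error(fit_linear_association(tab, "y", "x", "x2"), "x2")
  expect_error(fit_linear_association(tab[1:8, ], "y", "x"),
               "degrees of freedom")
})

test_that("interaction tests report the product term", {
  set.seed(51)
  n <- 100
  tab <- data.frame(x = rnorm(n), g = rbinom(n, 1, 0.5))
  tab$y <- 0.2 * tab$x + 0.9 * tab$x * tab$g + rnorm(n, 0, 0.5)
  r <- fit_linear_association(tab, "y", "x", interaction_with = "g")
  expect_identical(r$term, "x:g")
  expect_equal(r$beta, 0.9, tolerance = 0.25)
  expect_lt(r$p, 0.001)
})

test_that("multiplicity adjustment matches arithmetic and the BH oracle", {
  expect_equal(adjust_pvalues(0.03, "fdr_bh"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.2, 0.2, 0.2, 0.2), "bonferroni")[1],
               0.05)
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(adjust_pvalues(p, "fdr_bh"), bf_bh(p), tolerance = 1e-12)
  set.seed(61)
  p2 <- runif(40)
  expect_equal(adjust_pvalues(p2, "fdr_bh"), bf_bh(p2), tolerance = 1e-12)
  # BH adjusted values are monotone in the raw p-values
  expect_true(all(diff(adjust_pvalues(p2, "fdr_bh")[order(p2)]) >= -1e-15))
  expect_true(all(adjust_pvalues(p2, "bonferroni") >= p2))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(0.5, "holm"), "arg")
})

test_that("the association suite z-scores, stratifies, and adjusts per tier", {
  set.seed(71)
  n <- 120
  tab <- data.frame(
    group = factor(rep(c("control", "preclinical", "prodromal", "dementia"),
                       each = n / 4),
                   levels = c("control", "preclinical", "prodromal", "dementia")),
    age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5), tiv = rnorm(n, 1450, 100),
    tau = rnorm(n, 1.8, 0.5), density = runif(n, 0.1, 0.2))
  tab$sigma <- 1.5 - 0.4 * tab$tau + rnorm(n, 0, 0.1)
  tab$size <- 1000 - 50 * tab$tau + rnorm(n, 0, 30)
  res <- run_association_suite(tab, c("size", "sigma"), "tau")
  expect_identical(nrow(res), 2L)
  # density enters only the higher-order model
  expect_false(grepl("density", res$covariates[res$outcome == "size"]))
  expect_true(grepl("density", res$covariates[res$outcome == "sigma"]))
  expect_true(all(res$beta < 0))
  expect_true(all(res$p_adjusted >= res$p - 1e-15))
  # single-outcome suite reduces to the single fit with identity adjustment
  one <- run_association_suite(tab, "sigma", "tau")
  expect_equal(one$p_adjusted, one$p)
  strat <- run_association_suite(tab, c("size", "sigma"), "tau", by_group = TRUE)
  expect_identical(nrow(strat), 10L)   # whole sample + 4 groups
  expect_true(all(c("whole_sample", levels(tab$group)) %in% strat$stratum))
})

test_that("group comparisons use ANOVA and chi-squared appropriately", {
  tab <- data.frame(g = rep(c("a", "b"), each = 20),
                    x = rep(c(1, 2), each = 20),
                    cat = rep(c("f", "m"), 20))
  # identical group samples -> F = 0
  tab0 <- data.frame(g = rep(c("a", "b"), each = 5), x = rep(1:5, 2))
  r0 <- compare_groups(tab0, "x", "g")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  # perfect homogeneity -> chi-squared 0, p = 1
  rc <- compare_groups(tab, "cat", "g")
  expect_identical(rc$test, "chi-squared")
  expect_equal(rc$statistic, 0, tolerance = 1e-12)
  expect_equal(rc$p, 1)
  expect_error(compare_groups(data.frame(g = c("a", "a", "b"), x = 1:3),
                              "x", "g"), ">= 2 observations")
})

test_that("ANOVA F matches a sums-of-squares oracle", {
  set.seed(81)
  tab <- data.frame(g = rep(c("a", "b", "c"), times = c(12, 15, 13)))
  tab$x <- rnorm(40) + as.integer(factor(tab$g)) * 0.5
  r <- compare_groups(tab, "x", "g")
  grand <- mean(tab$x)
  ssb <- sum(tapply(tab$x, tab$g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(tab$x, tab$g, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ssb / 2) / (ssw / (40 - 3))
  expect_equal(r$statistic, F_oracle, tolerance = 1e-8)
})

test_that("mediation: null designs, full mediation, and the linear identity", {
  set.seed(91)
  n <- 300
  t <- rnorm(n)
  # mediator independent of treatment -> acme ~ 0
  m_ind <- rnorm(n)
  y <- 0.8 * t + 0.5 * m_ind + rnorm(n)
  tab <- data.frame(t = t, m = m_ind, y = y)
  r <- mediation_analysis(tab, "t", "m", "y", n_boot = 500, seed = 1)
  expect_lt(abs(r$acme), 0.1)
  expect_lt(abs(r$prop_mediated), 0.12)
  # zero direct effect -> proportion mediated ~ 1
  m2 <- 0.9 * t + rnorm(n)
  y2 <- 0.7 * m2 + rnorm(n, 0, 0.4)
  tab2 <- data.frame(t = t, m = m2, y = y2)
  r2 <- mediation_analysis(tab2, "t", "m", "y", n_boot = 500, seed = 1)
  expect_equal(r2$prop_mediated, 1, tolerance = 0.12)
  # c - c' = a * b holds exactly in every bootstrap replicate
  gap <- r2$draws[, "c"] - r2$draws[, "c_prime"] - r2$draws[, "acme"]
  expect_lt(max(abs(gap)), 1e-10)
  expect_equal(r2$c - r2$c_prime, r2$acme, tolerance = 1e-10)
})

test_that("mediation bootstrap is deterministic given the seed", {
  set.seed(101)
  n <- 120
  t <- rnorm(n); m <- 0.5 * t + rnorm(n); y <- 0.4 * t + 0.6 * m + rnorm(n)
  tab <- data.frame(t = t, m = m, y = y)
  r1 <- mediation_analysis(tab, "t", "m", "y", n_boot = 500, seed = 7)
  r2 <- mediation_analysis(tab, "t", "m", "y", n_boot = 500, seed = 7)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$ci, r2$ci)
  r3 <- mediation_analysis(tab, "t", "m", "y", n_boot = 500, seed = 8)
  expect_false(identical(r1$ci, r3$ci))
})
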