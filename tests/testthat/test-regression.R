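# independent normal-equations oracle for ordinary least squares
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

test_that("a line through two points is recovered exactly", {
  d <- data.frame(rate = c(1e-2, 1e-3), timescale = c(1, 100))
  fit <- fit_loglog(d, "common_line")
  expect_equal(unname(fit$coefficients), c(-2, -0.5), tolerance = 1e-12)
})

test_that("zero-noise synthetic catalogs are fitted exactly", {
  truth <- c(I = -3.4, IV = -2.1)
  cat0 <- exact_catalog(slope = -0.65, intercepts = truth)
  f2 <- fit_loglog(cat0, "common_slope")
  expect_equal(f2$coefficients[names(truth)], truth, tolerance = 1e-9)
  expect_equal(unname(f2$slope), -0.65, tolerance = 1e-9)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)
  expect_lt(f2$rss, 1e-18)
})

test_that("all three forms match the normal-equations oracle", {
  withr::with_seed(21, {
    n <- 50
    d <- data.frame(
      rate = 10^rnorm(n, -4, 1.5),
      timescale = 10^runif(n, 0, 6),
      baltimore_group = sample(c("I", "IV", "V"), n, replace = TRUE))
    x <- log10(d$timescale)
    y <- log10(d$rate)
    g <- factor(d$baltimore_group)
    G <- stats::model.matrix(~ 0 + g)
    designs <- list(
      common_line = cbind(1, x),
      common_slope = cbind(G, x),
      group_slopes = cbind(G, G * x))
    for (form in names(designs)) {
      fit <- fit_loglog(d, form)
      ref <- ols_oracle(designs[[form]], y)
      expect_equal(unname(fit$coefficients), c(ref), tolerance = 1e-10)
    }
  })
})

test_that("R-squared never decreases along the nested forms", {
  withr::with_seed(22, {
    for (k in 1:20) {
      n <- 30
      d <- data.frame(rate = 10^rnorm(n, -4, 1),
                      timescale = 10^runif(n, 0, 5),
                      baltimore_group = sample(c("I", "IV"), n, TRUE))
      r2 <- vapply(c("common_line", "common_slope", "group_slopes"),
                   function(f) fit_loglog(d, f)$r_squared, numeric(1))
      expect_true(all(diff(r2) >= -1e-12))
    }
  })
})

test_that("degenerate designs raise fit errors", {
  d <- data.frame(rate = c(1e-3, 1e-4, 1e-5), timescale = c(10, 10, 10))
  expect_error(fit_loglog(d, "common_line"), "singular",
               class = "tdrp_fit_error")
  d2 <- data.frame(rate = c(1e-3, 2e-3, 1e-4, 5e-4),
                   timescale = rep(10, 4),
                   baltimore_group = c("I", "I", "IV", "IV"))
  expect_error(fit_loglog(d2, "common_slope"),
               class = "tdrp_fit_error")
  expect_error(fit_loglog(data.frame(rate = -1, timescale = 1),
                          "common_line"),
               class = "tdrp_fit_error")
})

test_that("identical fits compare as F = 0, p = 1", {
  d <- data.frame(rate = c(1e-2, 1e-3, 1e-4, 2e-3), timescale = c(1, 10, 100, 5))
  f1 <- fit_loglog(d, "common_line")
  cmp <- compare_forms(f1, f1)
  expect_equal(cmp$f_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("the form-comparison F test matches stats::anova", {
  withr::with_seed(23, {
    d <- data.frame(rate = 10^rnorm(40, -4, 1), timescale = 10^runif(40, 0, 5),
                    baltimore_group = sample(c("I", "IV", "V"), 40, TRUE))
    f1 <- fit_loglog(d, "common_line")
    f2 <- fit_loglog(d, "common_slope")
    cmp <- compare_forms(f1, f2)
    ref <- stats::anova(f1$lm, f2$lm)
    expect_equal(cmp$f_statistic, ref$F[2], tolerance = 1e-10)
    expect_equal(cmp$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  })
})

test_that("the F test holds its size and detects real group effects", {
  sim_p <- function(delta) {
    n <- 30
    g <- rep(c("I", "IV"), each = n / 2)
    t <- 10^runif(n, 0, 5)
    y <- -3 + delta * (g == "IV") - 0.6 * log10(t) + rnorm(n, 0, 0.4)
    d <- data.frame(rate = 10^y, timescale = t, baltimore_group = g)
    compare_forms(fit_loglog(d, "common_line"),
                  fit_loglog(d, "common_slope"))$p_value
  }
  withr::with_seed(24, {
    p_null <- replicate(1000, sim_p(0))
    # type-I error close to nominal, and p approximately uniform
    expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.021)
    expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.001)
    p_alt <- replicate(200, sim_p(1.5))
    expect_gte(mean(p_alt < 0.05), 0.95)
  })
})

test_that("pairwise contrasts are consistent and antisymmetric", {
  cat0 <- exact_catalog()
  f2 <- fit_loglog(cat0, "common_slope")
  pc <- pairwise_intercepts(f2)
  expect_equal(pc$estimate,
               f2$coefficients[pc$a] - f2$coefficients[pc$b],
               ignore_attr = TRUE)
  # relabelling the categories flips the sign of the difference
  rec <- cat0$records
  rec$baltimore_group <- c(I = "IV", IV = "I")[rec$baltimore_group]
  pc_flip <- pairwise_intercepts(fit_loglog(rec, "common_slope"))
  expect_equal(pc$estimate, -pc_flip$estimate, tolerance = 1e-12)
})

test_that("two categories need no multiplicity adjustment", {
  withr::with_seed(25, {
    d <- data.frame(rate = 10^rnorm(30, -4, 1), timescale = 10^runif(30, 0, 5),
                    baltimore_group = rep(c("I", "IV"), 15))
    pc <- pairwise_intercepts(fit_loglog(d, "common_slope"))
    expect_equal(nrow(pc), 1L)
    expect_equal(pc$p_adj, pc$p_raw, tolerance = 1e-12)
  })
})

test_that("single-step adjusted p-values agree with multcomp's", {
  skip_if_not_installed("multcomp")
  withr::with_seed(26, {
    d <- data.frame(rate = 10^rnorm(60, -4, 1), timescale = 10^runif(60, 0, 5),
                    baltimore_group = sample(c("I", "II", "IV", "V"), 60, TRUE))
    fit <- fit_loglog(d, "common_slope")
    pc <- pairwise_intercepts(fit)
    K <- matrix(0, nrow(pc), length(coef(fit$lm)),
                dimnames = list(NULL, names(coef(fit$lm))))
    for (j in seq_len(nrow(pc))) {
      K[j, paste0("g", pc$a[j])] <- 1
      K[j, paste0("g", pc$b[j])] <- -1
    }
    ref <- suppressWarnings(
      summary(multcomp::glht(fit$lm, linfct = K))$test$pvalues)
    expect_equal(pc$p_adj, c(ref), tolerance = 0.01, ignore_attr = TRUE)
  })
})

test_that("the single-step adjustment controls the familywise error", {
  sim_reject <- function() {
    n <- 30
    g <- rep(c("I", "IV", "V"), each = n / 3)
    t <- 10^runif(n, 0, 5)
    y <- -3 - 0.6 * log10(t) + rnorm(n, 0, 0.4)  # equal true intercepts
    d <- data.frame(rate = 10^y, timescale = t, baltimore_group = g)
    any(pairwise_intercepts(fit_loglog(d, "common_slope"),
                            n_mc = 5000)$p_adj < 0.05)
  }
  withr::with_seed(27, {
    fwe <- mean(replicate(1000, sim_reject()))
    # <= nominal 0.05 plus Monte-Carlo slack (3 binomial SEs ~ 0.021)
    expect_lte(fwe, 0.05 + 0.021)
  })
})

test_that("parameter draws follow the fitted sampling distribution", {
  cat0 <- exact_catalog()
  fit <- fit_loglog(cat0, "common_slope")
  # degenerate covariance: every draw is the point estimate
  fit0 <- fit
  fit0$vcov[] <- 0
  draws0 <- sample_parameter_sets(fit0, 10)
  expect_true(all(draws0 == rep(fit$coefficients, each = 10)))
  # draw mean converges to the point estimate at the 1/sqrt(n) rate
  withr::with_seed(28, {
    d <- data.frame(rate = 10^rnorm(40, -4, 1), timescale = 10^runif(40, 0, 5))
    fit <- fit_loglog(d, "common_line")
    n <- 20000
    draws <- sample_parameter_sets(fit, n)
    se <- sqrt(diag(fit$vcov) / n)
    expect_true(all(abs(colMeans(draws) - fit$coefficients) < 4 * se))
    cv <- stats::cov(draws)
    expect_equal(cv, fit$vcov, tolerance = 0.05)
  })
})

test_that("Fisher's method matches its closed forms", {
  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1))$p_value, 1)
  f <- fisher_combine(c(0.5, 0.5))
  expect_equal(f$statistic, -4 * log(0.5), tolerance = 1e-12)
  expect_equal(f$statistic, 2.7726, tolerance = 1e-4)
  # closed form for 4 df: exp(-X/2) * (1 + X/2)
  expect_equal(f$p_value, exp(-f$statistic / 2) * (1 + f$statistic / 2),
               tolerance = 1e-12)
  expect_equal(f$p_value, 0.5966, tolerance = 1e-4)
  expect_equal(fisher_combine(0.037)$p_value, 0.037, tolerance = 1e-12)
})

test_that("Fisher combination is order-invariant, monotone, and clamps 0", {
  withr::with_seed(29, {
    p <- runif(7)
    expect_equal(fisher_combine(p)$p_value,
                 fisher_combine(rev(p))$p_value)
    lowered <- p
    lowered[3] <- lowered[3] / 10
    expect_lt(fisher_combine(lowered)$p_value, fisher_combine(p)$p_value)
  })
  expect_true(is.finite(fisher_combine(c(0, 0.5))$p_value))
  expect_error(fisher_combine(c(0.5, 1.2)), class = "tdrp_domain_error")
  expect_error(fisher_combine(numeric(0)), class = "tdrp_usage_error")
})

test_that("HPD intervals are shortest windows with a leftmost tie-break", {
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  expect_equal(hpd_interval(c(5, 1, 3, 2, 4), 0.999),
               c(lower = 1, upper = 5))
  # skewed sample: the HPD hugs the mode, unlike the central interval
  withr::with_seed(30, {
    x <- rexp(20000)
    hp <- hpd_interval(x, 0.95)
    expect_lt(hp[["lower"]], stats::quantile(x, 0.025))
  })
  expect_error(hpd_interval(1), class = "tdrp_usage_error")
  expect_error(hpd_interval(1:10, 1.5), class = "tdrp_domain_error")
})

test_that("HPD of a large normal sample matches the analytic interval", {
  withr::with_seed(31, {
    x <- rnorm(100000)
    hp <- hpd_interval(x, 0.95)
    expect_lt(abs(hp[["lower"]] - (-1.96)), 0.05)
    expect_lt(abs(hp[["upper"]] - 1.96), 0.05)
    # width shrinks as the retained mass shrinks
    w <- vapply(c(0.99, 0.95, 0.8, 0.5),
                function(m) diff(hpd_interval(x, m)), numeric(1))
    expect_true(all(diff(w) < 0))
  })
})
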