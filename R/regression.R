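#' Fit a power-law rate-decay model on the log-log scale
#'
#' Ordinary least squares of log10(rate) on log10(timescale), the linear
#' form of the power law `rate = 10^alpha * timescale^beta`. Three nested
#' model forms are supported:
#' \describe{
#'   \item{`common_line`}{one intercept, one slope;}
#'   \item{`common_slope`}{one intercept per category, shared slope
#'     (the form whose intercepts are compared across viral groups);}
#'   \item{`group_slopes`}{one intercept and one slope per category.}
#' }
#' Categorical forms are parameterised without a reference level, so every
#' coefficient named `<category>` is that category's intercept in
#' log10(substitutions/site/year) at a 1-year timescale.
#'
#' @param data A [rate_dataset()] or a data frame with positive `rate` and
#'   `timescale` columns and, for the categorical forms, the column named by
#'   `category`.
#' @param form One of `"common_line"`, `"common_slope"`, `"group_slopes"`.
#' @param category Name of the category column (e.g. `"baltimore_group"` or
#'   `"genus"`); ignored by `common_line`.
#' @return A `fit_result`: coefficients, covariance matrix, residual df,
#'   R-squared (about the mean, identical definition for all forms),
#'   residual sum of squares, per-coefficient two-sided t-test p-values, the
#'   slope estimate/p-value, and the underlying `lm` object.
#' @examples
#' d <- data.frame(rate = c(1e-2, 1e-3), timescale = c(1, 100))
#' fit <- fit_loglog(d, "common_line")
#' coef(fit$lm)  # intercept -2, slope -0.5
#' @export
fit_loglog <- function(data, form = c("common_line", "common_slope",
                                      "group_slopes"),
                       category = "baltimore_group") {
  form <- match.arg(form)
  if (inherits(data, "rate_dataset")) data <- data$records
  if (any(data$rate <= 0) || any(data$timescale <= 0)) {
    tdrp_error("tdrp_fit_error", "rates and timescales must be positive")
  }
  df <- data.frame(y = log10(data$rate), x = log10(data$timescale))
  if (form != "common_line") {
    if (!category %in% names(data)) {
      tdrp_error("tdrp_fit_error", paste0("no category column '", category, "'"))
    }
    df$g <- factor(data[[category]])
    if (nlevels(df$g) < 1L || any(table(df$g) == 0L)) {
      tdrp_error("tdrp_fit_error", "empty category level")
    }
  }
  one_level <- form != "common_line" && nlevels(df$g) == 1L
  fml <- if (one_level) y ~ x else  # a single category reduces to one line
    switch(form,
           common_line = y ~ x,
           common_slope = y ~ 0 + g + x,
           group_slopes = y ~ 0 + g + g:x)
  n_coef <- switch(form, common_line = 2L,
                   common_slope = nlevels(df$g) + 1L,
                   group_slopes = 2L * nlevels(df$g))
  if (nrow(df) < n_coef) {
    tdrp_error("tdrp_fit_error",
               sprintf("%d records cannot identify %d coefficients",
                       nrow(df), n_coef))
  }
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    tdrp_error("tdrp_fit_error",
               paste0("singular design; unidentifiable: ",
                      paste(bad, collapse = ", ")))
  }
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((df$y - mean(df$y))^2)
  sm <- withCallingHandlers(  # zero-noise fixtures fit perfectly by design
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  coefs <- stats::coef(fit)
  names(coefs) <- if (one_level) c(levels(df$g), "x") else
    sub("^g", "", names(coefs))
  vc <- sm$sigma^2 * sm$cov.unscaled
  dimnames(vc) <- list(names(coefs), names(coefs))
  pvals <- sm$coefficients[, "Pr(>|t|)"]
  names(pvals) <- names(coefs)
  slope_idx <- grep("(^x$|:x$)", names(coefs))
  structure(list(form = form,
                 category = if (form == "common_line") NULL else category,
                 coefficients = coefs,
                 vcov = vc,
                 df_residual = fit$df.residual,
                 r_squared = if (tss > 0) 1 - rss / tss else 1,
                 rss = rss,
                 n = nrow(df),
                 p_values = pvals,
                 slope = coefs[slope_idx],
                 slope_p = pvals[slope_idx],
                 lm = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("rate-decay fit (%s): n = %d, R^2 = %.3f\n",
              x$form, x$n, x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Compare two nested rate-decay model forms
#'
#' Extra-sum-of-squares F test: does the richer model (extra intercepts, or
#' extra per-category slopes) explain significantly more variance than the
#' simpler one fitted to the same records?
#'
#' @param fit_simple,fit_complex `fit_result` objects from [fit_loglog()] on
#'   identical records, with `fit_complex` nesting `fit_simple`.
#' @return List with `f_statistic`, `df` (numerator, denominator) and
#'   `p_value`. Identical models (no added coefficient) give F = 0, p = 1.
#' @export
compare_forms <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "fit_result"),
            inherits(fit_complex, "fit_result"))
  if (fit_simple$n != fit_complex$n) {
    tdrp_error("tdrp_usage_error", "fits are not on the same records")
  }
  df1 <- fit_simple$df_residual
  df2 <- fit_complex$df_residual
  if (df2 > df1) {
    tdrp_error("tdrp_usage_error", "fit_complex must nest fit_simple")
  }
  dnum <- df1 - df2
  dss <- max(fit_simple$rss - fit_complex$rss, 0)
  if (dnum == 0L) {
    if (dss > 1e-8 * max(fit_simple$rss, 1e-300)) {
      tdrp_error("tdrp_usage_error", "models differ but have equal df")
    }
    return(list(f_statistic = 0, df = c(0L, df2), p_value = 1))
  }
  f <- (dss / dnum) / (fit_complex$rss / df2)
  list(f_statistic = f, df = c(dnum, df2),
       p_value = stats::pf(f, dnum, df2, lower.tail = FALSE))
}

#' Complete pairwise comparisons of category intercepts
#'
#' All pairwise differences between the per-category intercepts of a
#' categorical fit, with familywise-adjusted p-values from the single-step
#' max-|t| method: the adjusted p of contrast `j` is the probability, under
#' the joint t distribution of all contrast statistics implied by the
#' coefficient covariance, that the largest absolute statistic exceeds the
#' observed |t_j|. The joint tail probability is Monte-Carlo approximated
#' with `n_mc` draws under a fixed internal seed, so results are
#' reproducible and never smaller than the unadjusted p. Holm adjustment is
#' available as an exact, conservative fallback. Differences are reported
#' one way per pair; the reverse difference is the negation.
#'
#' @param fit A `fit_result` with at least two category intercepts
#'   (`common_slope` or `group_slopes` form).
#' @param adjust `"single-step"` (default) or `"holm"`.
#' @param n_mc Monte-Carlo draws for the single-step adjustment (default
#'   50,000).
#' @return Object of class `pairwise_contrasts`: data frame with columns
#'   `a`, `b`, `estimate` (intercept a minus intercept b, log10 units),
#'   `se`, `statistic`, `p_raw`, `p_adj`, `significant` (at 0.05).
#' @export
pairwise_intercepts <- function(fit, adjust = c("single-step", "holm"),
                                n_mc = 50000L) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "fit_result"))
  if (fit$form == "common_line") {
    tdrp_error("tdrp_usage_error", "fit has no category intercepts")
  }
  cn <- names(fit$coefficients)
  int_idx <- which(!grepl("(^x$|:x$)", cn))
  if (length(int_idx) < 2L) {
    tdrp_error("tdrp_usage_error", "need >= 2 category intercepts")
  }
  cats <- cn[int_idx]
  pairs <- utils::combn(length(int_idx), 2L)
  K <- matrix(0, ncol(pairs), length(cn))
  for (j in seq_len(ncol(pairs))) {
    K[j, int_idx[pairs[1, j]]] <- 1
    K[j, int_idx[pairs[2, j]]] <- -1
  }
  est <- as.numeric(K %*% fit$coefficients)
  cv <- K %*% fit$vcov %*% t(K)
  se <- sqrt(diag(cv))
  tstat <- est / se
  df <- fit$df_residual
  p_raw <- 2 * stats::pt(-abs(tstat), df = df)
  p_adj <- if (adjust == "holm") {
    stats::p.adjust(p_raw, "holm")
  } else if (length(tstat) == 1L) {
    p_raw
  } else {
    # max-|t| null sample: correlated normals scaled by a shared chi
    with_seed(271828L, {
      R <- stats::cov2cor(cv)
      Z <- MASS::mvrnorm(n_mc, rep(0, nrow(R)), R)
      Tmax <- do.call(pmax, as.data.frame(abs(Z))) /
        sqrt(stats::rchisq(n_mc, df) / df)
      vapply(abs(tstat), function(t0) mean(Tmax >= t0), numeric(1))
    })
  }
  out <- data.frame(a = cats[pairs[1, ]], b = cats[pairs[2, ]],
                    estimate = est, se = se, statistic = tstat,
                    p_raw = p_raw, p_adj = pmin(pmax(p_adj, p_raw), 1),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < 0.05
  class(out) <- c("pairwise_contrasts", "data.frame")
  out
}

#' Draw parameter sets from a fitted model's sampling distribution
#'
#' Multivariate normal draws centred on the coefficient estimates with the
#' estimated coefficient covariance — the frequentist analogue of posterior
#' parameter sampling, used to pool estimation uncertainty across
#' pseudoreplicates (100 draws per replicate in the published analysis).
#'
#' @param fit A `fit_result`.
#' @param n Number of draws.
#' @return Matrix `n x p` of parameter draws, columns named like the fit's
#'   coefficients.
#' @export
sample_parameter_sets <- function(fit, n) {
  stopifnot(inherits(fit, "fit_result"), n >= 1L)
  mu <- fit$coefficients
  sigma <- fit$vcov
  if (all(sigma == 0)) {
    return(matrix(rep(mu, each = n), nrow = n,
                  dimnames = list(NULL, names(mu))))
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    tdrp_error("tdrp_numeric_error",
               "coefficient covariance is not positive semidefinite")
  }
  if (min(ev) < 0) {  # clip numerically negative eigenvalues
    es <- eigen(sigma, symmetric = TRUE)
    sigma <- es$vectors %*% diag(pmax(es$values, 0), length(ev)) %*%
      t(es$vectors)
  }
  draws <- MASS::mvrnorm(n, mu, sigma)
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- names(mu)
  draws
}

#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(log(p))` referred to a chi-squared distribution with `2k`
#' degrees of freedom. Inputs of exactly zero (underflowed p-values) are
#' clamped to the smallest positive double before taking logs.
#'
#' @param pvalues Numeric vector of p-values in (0, 1] (zeros clamped).
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' fisher_combine(c(0.5, 0.5))$p_value  # 0.5966
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) {
    tdrp_error("tdrp_usage_error", "no p-values to combine")
  }
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    tdrp_error("tdrp_domain_error", "p-values must lie in [0, 1]")
  }
  p <- pmax(pvalues, .Machine$double.xmin)
  x <- -2 * sum(log(p))
  k <- length(p)
  list(statistic = x, df = 2L * k,
       p_value = stats::pchisq(x, df = 2 * k, lower.tail = FALSE))
}

#' Highest-density interval of a sample
#'
#' Shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * n)` of them; among tied windows the leftmost is returned.
#'
#' @param samples Numeric vector with at least 2 values.
#' @param mass Fraction of draws the interval must contain (0 < mass < 1).
#' @return Numeric `c(lower, upper)`.
#' @examples
#' hpd_interval(1:100, 0.95)  # c(1, 95)
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (length(samples) < 2L) {
    tdrp_error("tdrp_usage_error", "need at least 2 samples")
  }
  if (!(mass > 0 && mass < 1)) {
    tdrp_error("tdrp_domain_error", "mass must be in (0, 1)")
  }
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)  # which.min takes the leftmost tie
  c(lower = x[i], upper = x[i + m - 1L])
}
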