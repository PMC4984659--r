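#' Pooled rate-decay analysis over pseudoreplicated subsets
#'
#' The full group-level workflow: for each of `n_replicates`
#' phylogenetically independent subsets, fit the three nested model forms
#' ([fit_loglog()]), record the p-values for (a) the time term (from the
#' common-line and the common-slope form), (b) the category effect
#' (extra-sum-of-squares F, common line vs common slope) and (c) slope
#' heterogeneity (common slope vs per-category slopes), draw `n_draws`
#' parameter sets from the common-slope fit, and compute all pairwise
#' intercept contrasts. Draws are pooled into one overall distribution and
#' per-test p-values are combined with Fisher's method. Replicates whose fit
#' fails (singular design) are skipped and counted.
#'
#' @param dataset A [rate_dataset()] satisfying the resampling constraints.
#' @param category Category column, default `"baltimore_group"`.
#' @param n_replicates Number of pseudoreplicated subsets (published
#'   analysis: 1,000).
#' @param n_draws Parameter draws per replicate (published analysis: 100).
#' @param seed Optional integer seed.
#' @param require_long Passed to [sample_pseudoreplicate()]; `FALSE` for
#'   short-term-only data.
#' @param contrasts Compute pairwise intercept contrasts per replicate
#'   (default `TRUE`).
#' @param max_attempts Rejection-sampling budget per replicate.
#' @return A `pooled_summary` object; see Details.
#' @details The returned object contains: `draws` (pooled parameter matrix,
#'   `n_draws` rows per successful replicate), `coef_summary` (median and
#'   95% HPD per coefficient), `per_replicate` (per-subset p-values, R², and
#'   subset size), `combined` (Fisher-combined p per test), `n_significant`
#'   (replicates with p < 0.05 per test), `contrast_summary` (per pair:
#'   median difference, 95% HPD of the difference across replicates,
#'   fraction of replicates significant at 0.05, Fisher-combined adjusted
#'   p), and `n_failed`.
#' @examples
#' \donttest{
#' cat <- generate_synthetic_catalog(table1_config(seed = 1))
#' res <- run_replicate_analysis(cat, n_replicates = 20, seed = 2)
#' res$coef_summary
#' }
#' @export
run_replicate_analysis <- function(dataset, category = "baltimore_group",
                                   n_replicates = 1000L, n_draws = 100L,
                                   seed = NULL, require_long = TRUE,
                                   contrasts = TRUE, max_attempts = 10000L) {
  stopifnot(inherits(dataset, "rate_dataset"), n_replicates >= 1L)
  if (length(unique(dataset$records[[category]])) < 2L) contrasts <- FALSE
  with_seed(seed, {
    draws <- vector("list", n_replicates)
    per_rep <- vector("list", n_replicates)
    ctr <- vector("list", n_replicates)
    n_failed <- 0L
    for (i in seq_len(n_replicates)) {
      rep_i <- sample_pseudoreplicate(dataset, require_long = require_long,
                                      max_attempts = max_attempts,
                                      replicate_index = i)
      recs <- replicate_records(dataset, rep_i)
      fits <- tryCatch({
        f1 <- fit_loglog(recs, "common_line", category)
        f2 <- fit_loglog(recs, "common_slope", category)
        f3 <- fit_loglog(recs, "group_slopes", category)
        list(f1 = f1, f2 = f2, f3 = f3)
      }, tdrp_fit_error = function(e) NULL)
      if (is.null(fits)) {
        n_failed <- n_failed + 1L
        next
      }
      per_rep[[i]] <- data.frame(
        replicate_index = i,
        n_records = nrow(recs),
        r_squared = fits$f2$r_squared,
        p_slope_common = unname(fits$f1$slope_p),
        p_slope_adj = unname(fits$f2$slope_p),
        p_group = compare_forms(fits$f1, fits$f2)$p_value,
        p_slope_het = compare_forms(fits$f2, fits$f3)$p_value)
      draws[[i]] <- sample_parameter_sets(fits$f2, n_draws)
      if (contrasts) {
        cc <- pairwise_intercepts(fits$f2)
        cc$replicate_index <- i
        ctr[[i]] <- cc
      }
    }
    per_rep <- do.call(rbind, per_rep)
    if (is.null(per_rep) || nrow(per_rep) == 0L) {
      tdrp_error("tdrp_analysis_error", "every replicate failed to fit")
    }
    draws <- do.call(rbind, draws)
    combined <- lapply(per_rep[c("p_slope_common", "p_slope_adj", "p_group",
                                 "p_slope_het")],
                       function(p) fisher_combine(p)$p_value)
    n_sig <- vapply(per_rep[c("p_slope_common", "p_slope_adj", "p_group",
                              "p_slope_het")],
                    function(p) sum(p < 0.05), integer(1))
    contrast_summary <- NULL
    if (contrasts) {
      all_ctr <- do.call(rbind, ctr)
      contrast_summary <- do.call(rbind, lapply(
        split(all_ctr, paste(all_ctr$a, all_ctr$b)), function(d) {
          hp <- if (nrow(d) >= 2L) hpd_interval(d$estimate) else
            c(lower = d$estimate, upper = d$estimate)
          data.frame(a = d$a[1], b = d$b[1],
                     median_diff = stats::median(d$estimate),
                     hpd_lower = hp[["lower"]], hpd_upper = hp[["upper"]],
                     prop_significant = mean(d$p_adj < 0.05),
                     combined_p = fisher_combine(d$p_adj)$p_value,
                     stringsAsFactors = FALSE)
        }))
      rownames(contrast_summary) <- NULL
    }
    structure(list(draws = draws,
                   coef_summary = summarize_draws(draws),
                   per_replicate = per_rep,
                   combined = combined,
                   n_significant = n_sig,
                   contrast_summary = contrast_summary,
                   n_replicates = n_replicates,
                   n_failed = n_failed,
                   n_draws = n_draws,
                   category = category),
              class = "pooled_summary")
  })
}

summarize_draws <- function(draws) {
  out <- do.call(rbind, lapply(colnames(draws), function(cn) {
    hp <- hpd_interval(draws[, cn])
    data.frame(coefficient = cn, median = stats::median(draws[, cn]),
               hpd_lower = hp[["lower"]], hpd_upper = hp[["upper"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.pooled_summary <- function(x, ...) {
  ok <- nrow(x$per_replicate)
  cat(sprintf("pooled rate-decay analysis: %d/%d replicates (%d draws each)\n",
              ok, x$n_replicates, x$n_draws))
  cs <- x$coef_summary
  cs[c("median", "hpd_lower", "hpd_upper")] <-
    lapply(cs[c("median", "hpd_lower", "hpd_upper")], round, 3)
  print(cs)
  cat(sprintf("median R^2 = %.3f\n", stats::median(x$per_replicate$r_squared)))
  for (nm in names(x$combined)) {
    cat(sprintf("  %-14s combined p %s (p < 0.05 in %d/%d)\n", nm,
                format_floor_p(x$combined[[nm]]), x$n_significant[[nm]], ok))
  }
  invisible(x)
}

# display-only floor at 0.001; raw values stay in the object
format_floor_p <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("= %.3g", p)
}

#' Single-fit rate-decay analysis (no resampling)
#'
#' The genus-level workflow: rate estimates within genera are not
#' phylogenetically independent and too few for resampling, so the three
#' model forms are fitted once to the full data; uncertainty comes from
#' parameter draws of the common-slope fit. Records with an empty category
#' value are excluded.
#'
#' @inheritParams run_replicate_analysis
#' @return A `single_fit_analysis`: the three `fit_result`s, the two model
#'   comparisons, parameter draws with `coef_summary`, and pairwise
#'   contrasts of the common-slope intercepts.
#' @export
run_single_fit_analysis <- function(dataset, category = "genus",
                                    n_draws = 100L, seed = NULL) {
  stopifnot(inherits(dataset, "rate_dataset"))
  recs <- dataset$records
  recs <- recs[!is.na(recs[[category]]) & recs[[category]] != "", , drop = FALSE]
  tab <- table(recs[[category]])
  if (sum(tab >= 2L) < 2L) {
    tdrp_error("tdrp_usage_error",
               "need >= 2 categories with >= 2 records each")
  }
  with_seed(seed, {
    f1 <- fit_loglog(recs, "common_line", category)
    f2 <- fit_loglog(recs, "common_slope", category)
    f3 <- fit_loglog(recs, "group_slopes", category)
    draws <- sample_parameter_sets(f2, n_draws)
    structure(list(fits = list(common_line = f1, common_slope = f2,
                               group_slopes = f3),
                   category_effect = compare_forms(f1, f2),
                   slope_heterogeneity = compare_forms(f2, f3),
                   draws = draws,
                   coef_summary = summarize_draws(draws),
                   contrasts = pairwise_intercepts(f2),
                   category = category),
              class = "single_fit_analysis")
  })
}

#' @export
print.single_fit_analysis <- function(x, ...) {
  cat(sprintf("single-fit rate-decay analysis by %s\n", x$category))
  cat(sprintf("common-slope fit: R^2 = %.3f, slope p %s\n",
              x$fits$common_slope$r_squared,
              format_floor_p(x$fits$common_slope$slope_p)))
  cat(sprintf("category effect p %s; slope heterogeneity p %s\n",
              format_floor_p(x$category_effect$p_value),
              format_floor_p(x$slope_heterogeneity$p_value)))
  print(x$coef_summary)
  invisible(x)
}

#' Maximum phylogenetically independent short-term records per group
#'
#' For each Baltimore group, the largest number of short-term records that
#' can enter a single pseudoreplicate: one record per virus, and within each
#' block the alternative containing the most viruses with short-term
#' records.
#'
#' @param dataset A [rate_dataset()].
#' @return Named integer vector, one entry per group present.
#' @export
independent_short_capacity <- function(dataset) {
  rec <- dataset$records
  rec <- rec[term_class(rec$timescale) == "short", , drop = FALSE]
  groups <- sort(unique(dataset$records$baltimore_group))
  out <- stats::setNames(integer(length(groups)), groups)
  for (g in intersect(groups, rec$baltimore_group)) {
    rg <- rec[rec$baltimore_group == g, ]
    out[g] <- sum(vapply(split(rg, rg$block_id), function(b) {
      max(vapply(split(b, b$alternative_id),
                 function(a) length(unique(a$virus_name)), integer(1)))
    }, integer(1)))
  }
  out
}

#' Short-term rate-decay analysis
#'
#' Restricts the catalog to short-term records (timescale < 1,000 years) and
#' runs the pooled replicate analysis without the long-term constraint.
#' Groups whose maximum number of phylogenetically independent short-term
#' records is strictly below `min_independent` (default 10) are excluded
#' from the analysis, since their per-subset short-term sample would be too
#' small to estimate a decay slope reliably.
#'
#' @inheritParams run_replicate_analysis
#' @param groups Optional explicit character vector of groups to retain;
#'   default `NULL` applies the `min_independent` capacity rule.
#' @param min_independent Exclusion threshold on
#'   [independent_short_capacity()].
#' @return A `pooled_summary` with extra fields `groups_used` and
#'   `groups_excluded`.
#' @export
run_short_term_analysis <- function(dataset, groups = NULL,
                                    min_independent = 10L,
                                    n_replicates = 1000L, n_draws = 100L,
                                    seed = NULL, contrasts = TRUE,
                                    max_attempts = 10000L) {
  stopifnot(inherits(dataset, "rate_dataset"))
  all_groups <- sort(unique(dataset$records$baltimore_group))
  if (is.null(groups)) {
    cap <- independent_short_capacity(dataset)
    groups <- names(cap)[cap >= min_independent]
  }
  excluded <- setdiff(all_groups, groups)
  if (length(groups) == 0L) {
    tdrp_error("tdrp_analysis_error",
               "no group retains enough independent short-term records")
  }
  rec <- dataset$records
  keep <- rec$baltimore_group %in% groups &
    term_class(rec$timescale) == "short"
  short <- rate_dataset(rec[keep, , drop = FALSE],
                        label = paste0(dataset$label, " [short-term]"))
  out <- run_replicate_analysis(short, category = "baltimore_group",
                                n_replicates = n_replicates,
                                n_draws = n_draws, seed = seed,
                                require_long = FALSE, contrasts = contrasts,
                                max_attempts = max_attempts)
  out$groups_used <- groups
  out$groups_excluded <- excluded
  out
}
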