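#' A calibrated power-law rate-decay clock
#'
#' The pair `(alpha, beta)` defining the map between substitution-unit node
#' heights `s` and node ages `t` in years: `log10(s/t) = alpha + beta *
#' log10(t)`, i.e. `t = (s / 10^alpha)^(1/(beta + 1))`. `beta` must exceed
#' -1, otherwise the map is non-monotone.
#'
#' @param alpha Intercept, log10(substitutions/site/year) at a 1-year
#'   timescale.
#' @param beta Rate-decay slope, dimensionless, `> -1`.
#' @return A `tdrp_clock` list.
#' @export
tdrp_clock <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || beta <= -1) {
    tdrp_error("tdrp_domain_error", "need finite alpha and beta > -1")
  }
  structure(list(alpha = alpha, beta = beta), class = "tdrp_clock")
}

#' Solve the clock intercept from one calibrated node
#'
#' Given the substitution-unit height `s_cal` of a node whose age `t_cal`
#' (years) is known, and a rate-decay slope `beta`, the clock intercept is
#' `alpha = log10(s_cal) - (beta + 1) * log10(t_cal)`.
#'
#' @param s_cal Substitutions/site since the calibration node (> 0).
#' @param t_cal Calibration age in years (> 0).
#' @param beta Rate-decay slope (> -1).
#' @return `alpha` (log10 s/n/y).
#' @seealso [substitutions_to_time()] is its inverse at the calibration
#'   point.
#' @export
calibrate_alpha <- function(s_cal, t_cal, beta) {
  if (any(s_cal <= 0) || any(t_cal <= 0) || any(beta <= -1)) {
    tdrp_error("tdrp_domain_error",
               "need s_cal > 0, t_cal > 0 and beta > -1")
  }
  log10(s_cal) - (beta + 1) * log10(t_cal)
}

#' Convert substitution-unit heights to ages in years
#'
#' Inverts the power-law rate-decay relation: `t = (s / 10^alpha)^(1 /
#' (beta + 1))`, with `t = 0` at `s = 0`. Strictly increasing in `s` for
#' `beta > -1`, so node-age ordering equals node-height ordering.
#'
#' @param s Substitutions/site (>= 0, vectorised).
#' @param alpha,beta Clock parameters (see [tdrp_clock()]).
#' @return Ages in years.
#' @examples
#' substitutions_to_time(0.1, alpha = -2.20, beta = -0.65)  # ~2.68e3 years
#' @export
substitutions_to_time <- function(s, alpha, beta) {
  if (beta <= -1) {
    tdrp_error("tdrp_domain_error", "beta must be > -1")
  }
  if (any(s < 0)) tdrp_error("tdrp_domain_error", "s must be >= 0")
  ifelse(s == 0, 0, (s / 10^alpha)^(1 / (beta + 1)))
}

#' Load a posterior sample of substitution-unit trees
#'
#' Reads rooted trees with branch lengths in substitutions/site from a
#' Newick or Nexus file (Nexus translate tables are resolved by the reader).
#' All trees must be rooted, carry branch lengths, and share one leaf-label
#' set.
#'
#' @param path Tree file.
#' @param format `"auto"` (default; sniffs a `#NEXUS` header), `"newick"`,
#'   or `"nexus"`.
#' @return A `multiPhylo` list of trees.
#' @export
load_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    tdrp_error("tdrp_parse_error", paste0("file not found: ", path))
  }
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else
    ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!inherits(trees, "multiPhylo") || length(trees) == 0L) {
    tdrp_error("tdrp_parse_error", "no trees could be parsed")
  }
  labels <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (is.null(tr$edge.length)) {
      tdrp_error("tdrp_parse_error",
                 sprintf("tree %d has no branch lengths", i))
    }
    if (!ape::is.rooted(tr)) {
      tdrp_error("tdrp_parse_error", sprintf("tree %d is unrooted", i))
    }
    if (!identical(sort(tr$tip.label), labels)) {
      tdrp_error("tdrp_parse_error",
                 sprintf("tree %d has a different taxon set", i))
    }
  }
  trees
}

# tip-index sets per node (1..ntip tips, then internals), by postorder pass
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- c(as.list(seq_len(ntip)), vector("list", tree$Nnode))
  edge <- stats::reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    sets[[p]] <- c(sets[[p]], sets[[edge[k, 2]]])
  }
  sets
}

clade_key <- function(labels) paste(sort(labels), collapse = "|")

#' Node heights of an ultrametric substitution-unit tree
#'
#' Heights are distances from each node down to its tips. The tree must be
#' ultrametric within `tolerance`: the spread of root-to-tip path lengths
#' may not exceed `tolerance` times the tree height. Leaf heights are
#' exactly 0.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tolerance Relative ultrametricity tolerance (default 1e-6).
#' @return Data frame with one row per node: `clade` (sorted leaf labels
#'   joined by `|`), `n_tips`, `height`.
#' @export
node_heights <- function(tree, tolerance = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_len(ntip)]
  H <- max(tipd)
  spread <- H - min(tipd)
  if (H <= 0 || spread > tolerance * H) {
    tdrp_error("tdrp_validation_error",
               sprintf("tree is not ultrametric: root-to-tip spread %.3g on height %.3g",
                       spread, H))
  }
  sets <- clade_tip_sets(tree)
  height <- H - depth
  height[seq_len(ntip)] <- 0
  data.frame(
    clade = vapply(sets, function(s) clade_key(tree$tip.label[s]), ""),
    n_tips = lengths(sets),
    height = pmax(height, 0))
}

#' Specify the calibration of a rate-decay clock
#'
#' One calibrated node — the most recent common ancestor of two named taxa —
#' with a normally distributed age (truncated at zero when sampled) and a
#' sample of rate-decay slope draws carried over from the regression module.
#' The default calibration is the African mainland / Bioko island
#' geographic-separation date used to calibrate the lentivirus clock: mean
#' 10,500 years with standard error (11,000 - 10,500)/1.96 = 255.10 years.
#'
#' @param taxon_a,taxon_b Leaf labels; their MRCA is the calibration node.
#' @param date_mean Calibration age mean in years (default 10,500).
#' @param date_sd Calibration age standard deviation in years (default
#'   500/1.96 = 255.10).
#' @param beta_draws Numeric vector of slope draws (each ideally > -1;
#'   draws <= -1 are redrawn during dating).
#' @return A `calibration_spec` list.
#' @export
calibration_spec <- function(taxon_a, taxon_b, date_mean = 10500,
                             date_sd = 500 / 1.96, beta_draws) {
  if (date_mean <= 0 || date_sd < 0) {
    tdrp_error("tdrp_domain_error", "need date_mean > 0 and date_sd >= 0")
  }
  if (identical(taxon_a, taxon_b)) {
    tdrp_error("tdrp_usage_error", "calibration taxa must differ")
  }
  beta_draws <- as.numeric(beta_draws)
  if (length(beta_draws) == 0L || !any(beta_draws > -1)) {
    tdrp_error("tdrp_domain_error", "beta_draws must contain values > -1")
  }
  structure(list(taxon_a = taxon_a, taxon_b = taxon_b,
                 date_mean = date_mean, date_sd = date_sd,
                 beta_draws = beta_draws),
            class = "calibration_spec")
}

#' Date a posterior tree sample with a calibrated rate-decay clock
#'
#' For every posterior tree: extract the substitution-unit height of the
#' calibration MRCA (`s_cal`), draw one calibration age `t_cal` from the
#' positive-truncated normal, draw one rate-decay slope `beta` from the
#' supplied slope sample (redrawing any value <= -1), solve the intercept
#' with [calibrate_alpha()], and convert every internal node height to years
#' with [substitutions_to_time()]. Node ages are pooled across trees by
#' clade (matched on leaf-label sets; trees lacking a clade contribute no
#' draw) and summarised by posterior median, mean, 95% HPD and clade
#' support.
#'
#' @param trees A `multiPhylo` (or single `phylo`) of rooted ultrametric
#'   substitution-unit trees.
#' @param calibration A [calibration_spec()].
#' @param seed Optional integer seed.
#' @param tolerance Ultrametricity tolerance passed to [node_heights()].
#' @return A `node_age_summary`: `summary` data frame (clade, `n_tips`,
#'   `support`, `mean`, `median`, `hpd_lower`, `hpd_upper`, ages in years),
#'   `draws` (per-clade age draws), `alpha_draws` (per-tree calibrated
#'   intercepts), `n_trees`.
#' @export
date_posterior <- function(trees, calibration, seed = NULL,
                           tolerance = 1e-6) {
  stopifnot(inherits(calibration, "calibration_spec"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  taxa <- c(calibration$taxon_a, calibration$taxon_b)
  if (!all(taxa %in% trees[[1]]$tip.label)) {
    tdrp_error("tdrp_usage_error",
               paste0("calibration taxa not in trees: ",
                      paste(setdiff(taxa, trees[[1]]$tip.label),
                            collapse = ", ")))
  }
  with_seed(seed, {
    draws <- list()
    alpha_draws <- numeric(length(trees))
    ntips <- list()
    for (i in seq_along(trees)) {
      tr <- trees[[i]]
      nh <- node_heights(tr, tolerance)
      mrca <- ape::getMRCA(tr, taxa)
      s_cal <- nh$height[mrca]
      t_cal <- stats::rnorm(1, calibration$date_mean, calibration$date_sd)
      while (t_cal <= 0) {
        t_cal <- stats::rnorm(1, calibration$date_mean, calibration$date_sd)
      }
      beta <- sample(calibration$beta_draws, 1L)
      while (beta <= -1) beta <- sample(calibration$beta_draws, 1L)
      alpha <- calibrate_alpha(s_cal, t_cal, beta)
      alpha_draws[i] <- alpha
      internal <- nh[nh$n_tips >= 2L, , drop = FALSE]
      ages <- substitutions_to_time(internal$height, alpha, beta)
      for (k in seq_len(nrow(internal))) {
        key <- internal$clade[k]
        draws[[key]] <- c(draws[[key]], ages[k])
        ntips[[key]] <- internal$n_tips[k]
      }
    }
    summ <- do.call(rbind, lapply(names(draws), function(key) {
      d <- draws[[key]]
      hp <- if (length(d) >= 2L) hpd_interval(d) else c(lower = d, upper = d)
      data.frame(clade = key, n_tips = ntips[[key]],
                 support = length(d) / length(trees),
                 mean = mean(d), median = stats::median(d),
                 hpd_lower = hp[["lower"]], hpd_upper = hp[["upper"]],
                 stringsAsFactors = FALSE)
    }))
    summ <- summ[order(-summ$n_tips, summ$clade), ]
    rownames(summ) <- NULL
    structure(list(summary = summ, draws = draws,
                   alpha_draws = alpha_draws, n_trees = length(trees)),
              class = "node_age_summary")
  })
}

#' @export
print.node_age_summary <- function(x, ...) {
  cat(sprintf("node ages from %d posterior trees (years)\n", x$n_trees))
  s <- x$summary
  s$clade <- ifelse(nchar(s$clade) > 40, paste0(substr(s$clade, 1, 37), "..."),
                    s$clade)
  s[c("mean", "median", "hpd_lower", "hpd_upper")] <-
    lapply(s[c("mean", "median", "hpd_lower", "hpd_upper")], signif, 3)
  print(s)
  cat(sprintf("implied 1-year rate 10^alpha: median %.3g s/n/y\n",
              10^stats::median(x$alpha_draws)))
  invisible(x)
}

#' @export
as.data.frame.node_age_summary <- function(x, ...) x$summary

#' Generate a synthetic posterior of substitution-unit trees
#'
#' A fixture generator standing in for a Bayesian tree-inference run: given
#' a true time-scaled ultrametric tree (branch lengths in years) and a true
#' rate-decay clock, node heights are mapped to substitution units via
#' `s = 10^alpha * t^(beta + 1)`, multiplied by lognormal jitter, and
#' re-monotonised so every parent stays older than its children; each
#' posterior tree keeps the topology with jittered heights. With zero jitter
#' all trees are identical and dating recovers the true ages exactly.
#'
#' @param time_tree Rooted ultrametric `phylo` with branch lengths in years.
#' @param clock A [tdrp_clock()] (the true `alpha`, `beta`).
#' @param n_trees Number of posterior trees.
#' @param jitter_sd Standard deviation of the lognormal height jitter (log
#'   scale).
#' @param seed Optional integer seed.
#' @return A `multiPhylo` of ultrametric substitution-unit trees.
#' @export
generate_synthetic_posterior <- function(time_tree, clock, n_trees,
                                         jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(time_tree, "phylo"), inherits(clock, "tdrp_clock"),
            n_trees >= 1L, jitter_sd >= 0)
  ntip <- length(time_tree$tip.label)
  depth <- ape::node.depth.edgelength(time_tree)
  tipd <- depth[seq_len(ntip)]
  if (max(tipd) - min(tipd) > 1e-6 * max(tipd)) {
    tdrp_error("tdrp_config_error", "time_tree must be ultrametric")
  }
  t_node <- max(tipd) - depth
  t_node[seq_len(ntip)] <- 0
  edge <- stats::reorder(time_tree, "postorder")$edge
  with_seed(seed, {
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      s <- 10^clock$alpha * t_node^(clock$beta + 1)
      if (jitter_sd > 0) {
        jit <- exp(stats::rnorm(length(s), 0, jitter_sd))
        s[-seq_len(ntip)] <- s[-seq_len(ntip)] * jit[-seq_len(ntip)]
      }
      # re-monotonise: parents must be strictly above their children
      for (k in seq_len(nrow(edge))) {
        p <- edge[k, 1]
        s[p] <- max(s[p], s[edge[k, 2]] * (1 + 1e-9))
      }
      tr <- time_tree
      tr$edge.length <- s[tr$edge[, 1]] - s[tr$edge[, 2]]
      trees[[i]] <- tr
    }
    class(trees) <- "multiPhylo"
    trees
  })
}
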