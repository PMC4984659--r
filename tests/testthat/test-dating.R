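three_taxon_tree <- function() {
  ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.15);")
}

test_that("newick and nexus posterior samples load consistently", {
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.1,B:0.1):0.05,C:0.15);", nwk)
  trees <- load_trees(nwk)
  expect_length(trees, 1)
  expect_equal(sort(trees[[1]]$tip.label), c("A", "B", "C"))

  multi <- withr::local_tempfile(fileext = ".trees")
  writeLines(rep("((A:0.1,B:0.1):0.05,C:0.15);", 20), multi)
  expect_length(load_trees(multi), 20)

  nex <- withr::local_tempfile(fileext = ".nex")
  ape::write.nexus(c(three_taxon_tree(), three_taxon_tree()),
                   file = nex, translate = TRUE)
  tn <- load_trees(nex)  # format sniffed from the #NEXUS header
  expect_length(tn, 2)
  expect_setequal(tn[[1]]$tip.label, c("A", "B", "C"))
})

test_that("malformed posterior samples are rejected", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A:0.1,B:0.1):0.05,C:0.15);", "((A:0.1,D:0.1):0.05,C:0.15);"),
             f)
  expect_error(load_trees(f), "different taxon set",
               class = "tdrp_parse_error")
  writeLines("(A,B,C);", f)
  expect_error(load_trees(f), class = "tdrp_parse_error")
  expect_error(load_trees("no/such/file.nwk"), class = "tdrp_parse_error")
})

test_that("node heights are tip-anchored clade heights", {
  nh <- node_heights(three_taxon_tree())
  expect_equal(nh$height[nh$clade == "A|B"], 0.1)
  expect_equal(nh$height[nh$clade == "A|B|C"], 0.15)
  expect_true(all(nh$height[nh$n_tips == 1] == 0))
})

test_that("non-ultrametric trees fail validation beyond the tolerance", {
  tr <- three_taxon_tree()
  tr$edge.length[4] <- 0.17  # stretch tip C
  expect_error(node_heights(tr), "not ultrametric",
               class = "tdrp_validation_error")
  expect_silent(node_heights(tr, tolerance = 0.5))
})

test_that("calibration algebra matches its closed forms and inverts", {
  expect_equal(calibrate_alpha(1, 1, -0.5), 0)
  expect_equal(calibrate_alpha(0.05, 10500, -0.65), -2.708, tolerance = 1e-3)
  expect_equal(substitutions_to_time(0.1, -2.20, -0.65), 2.68e3,
               tolerance = 1e-2)
  # independent oracle: invert log10(s/t) = alpha + beta log10(t) numerically
  root <- stats::uniroot(function(t) -2.20 - 0.65 * log10(t) - log10(0.1 / t),
                         c(1, 1e9), tol = 1e-10)$root
  expect_equal(substitutions_to_time(0.1, -2.20, -0.65), root,
               tolerance = 1e-6)
  # mutual inversion across a parameter grid
  grid <- expand.grid(s = c(1e-4, 0.05, 0.7), t = c(10, 1e4, 1e7),
                      beta = c(-0.9, -0.65, -0.2, 0.3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- calibrate_alpha(g$s, g$t, g$beta)
    expect_equal(substitutions_to_time(g$s, a, g$beta), g$t,
                 tolerance = 1e-9)
    # the implied 1-year rate identity: 10^alpha = (s/t) * t^(-beta)
    expect_equal(10^a, (g$s / g$t) * g$t^(-g$beta), tolerance = 1e-9)
  }
  expect_equal(substitutions_to_time(c(0, 10^-2.2), -2.2, -0.65), c(0, 1))
  expect_error(substitutions_to_time(0.1, -2, -1.2),
               class = "tdrp_domain_error")
  expect_error(calibrate_alpha(0, 100, -0.5), class = "tdrp_domain_error")
})

test_that("age ordering preserves height ordering in every tree", {
  withr::with_seed(51, {
    for (k in 1:20) {
      h <- sort(runif(4, 0.001, 0.5))
      beta <- runif(1, -0.95, 0.5)
      ages <- substitutions_to_time(h, alpha = runif(1, -4, -1), beta = beta)
      expect_true(all(diff(ages) > 0))
    }
  })
})

test_that("a zero-jitter posterior is dated back exactly", {
  time_tree <- ladder_time_tree()
  clock <- tdrp_clock(-2.2, -0.65)
  post <- generate_synthetic_posterior(time_tree, clock, n_trees = 10,
                                       jitter_sd = 0, seed = 52)
  expect_length(post, 10)
  expect_identical(post[[1]], post[[7]])
  calib <- calibration_spec("A", "B", date_mean = 10500, date_sd = 0,
                            beta_draws = -0.65)
  res <- date_posterior(post, calib, seed = 53)
  truth <- ladder_true_ages()
  got <- setNames(res$summary$median, res$summary$clade)
  expect_equal(got[names(truth)], truth, tolerance = 1e-6)
  expect_true(all(res$summary$support == 1))
  # fixed calibration and slope: the calibration node is exact in every tree
  expect_equal(unique(round(res$draws[["A|B"]], 9)), 10500)
})

test_that("calibration taxa must exist and the date must be positive", {
  expect_error(calibration_spec("A", "A", beta_draws = -0.65),
               class = "tdrp_usage_error")
  expect_error(calibration_spec("A", "B", date_mean = -10, beta_draws = -0.65),
               class = "tdrp_domain_error")
  expect_error(calibration_spec("A", "B", beta_draws = -1.5),
               class = "tdrp_domain_error")
  post <- generate_synthetic_posterior(ladder_time_tree(),
                                       tdrp_clock(-2.2, -0.65), 2, seed = 1)
  calib <- calibration_spec("A", "nosuchtip", beta_draws = -0.65)
  expect_error(date_posterior(post, calib), "nosuchtip",
               class = "tdrp_usage_error")
})

test_that("wider height jitter widens the recovered age intervals", {
  time_tree <- ladder_time_tree()
  clock <- tdrp_clock(-2.2, -0.65)
  calib <- calibration_spec("A", "B", beta_draws =
                              withr::with_seed(60, rnorm(200, -0.65, 0.005)))
  widths <- vapply(c(0.02, 0.1, 0.3), function(j) {
    post <- generate_synthetic_posterior(time_tree, clock, n_trees = 60,
                                         jitter_sd = j, seed = 54)
    res <- date_posterior(post, calib, seed = 55)
    s <- res$summary
    log(s$hpd_upper[s$clade == "A|B|C|D|E|F"]) -
      log(s$hpd_lower[s$clade == "A|B|C|D|E|F"])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("posterior dating is reproducible under a seed", {
  post <- generate_synthetic_posterior(ladder_time_tree(),
                                       tdrp_clock(-2.2, -0.65), 20,
                                       jitter_sd = 0.05, seed = 56)
  calib <- calibration_spec("A", "B", beta_draws =
                              withr::with_seed(61, rnorm(100, -0.65, 0.01)))
  a <- date_posterior(post, calib, seed = 57)
  b <- date_posterior(post, calib, seed = 57)
  expect_identical(a$summary, b$summary)
})
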