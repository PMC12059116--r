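zero_gate <- structure(list(beta0 = 0, beta_y = 0, beta_d = 0, beta_yd = 0,
                            n = 0L, converged = TRUE, separation = FALSE,
                            se = rep(NA_real_, 4)),
                       class = "gate_model")

test_that("combination modes reproduce their defining hand values", {
  expect_equal(combine_arithmetic(2, 4, 0.5), 3)
  expect_equal(combine_arithmetic(2, 4, 1), 2)   # pure CUB endpoint
  expect_equal(combine_arithmetic(2, 4, 0), 4)   # pure phylogenetic endpoint
  expect_equal(combine_geometric(2, 8, 0.5), 4)
  expect_equal(combine_geometric(2, 8, 1), 2)
  expect_equal(combine_binary(2, 4, 0.6), 2)     # P > 0.5 routes to CUB
  expect_equal(combine_binary(2, 4, 0.5), 4)     # P <= 0.5 routes to phylo
  expect_equal(combine_binary(2, 4, 0.4), 4)
  expect_error(combine_arithmetic(2, 4, 1.2), class = "phygrow_domain_error")
  expect_error(combine_geometric(-1, 4, 0.5), class = "phygrow_domain_error")
})

test_that("combinations are convex on their inputs and obey AM-GM", {
  set.seed(91)
  for (i in 1:200) {
    y1 <- exp(rnorm(1)); y2 <- exp(rnorm(1)); p <- runif(1)
    a <- combine_arithmetic(y1, y2, p)
    g <- combine_geometric(y1, y2, p)
    expect_gte(a, min(y1, y2)); expect_lte(a, max(y1, y2))
    expect_gte(g, min(y1, y2)); expect_lte(g, max(y1, y2))
    expect_lte(g, a + 1e-12)
  }
})

test_that("gate probability evaluates the logistic linear predictor", {
  expect_equal(gate_probability(zero_gate, 7, 3), 0.5)
  g_d <- zero_gate; g_d$beta_d <- 1
  expect_equal(gate_probability(g_d, 2, 0), 0.5)
  expect_equal(gate_probability(g_d, 2, 1e4), 1, tolerance = 1e-10)
  ds <- seq(0, 5, by = 0.5)
  ps <- gate_probability(g_d, 2, ds)
  expect_true(all(diff(ps) > 0))  # monotone in d_p when beta_d > 0

  g <- zero_gate
  g$beta0 <- 0.3; g$beta_y <- -0.2; g$beta_d <- 0.5; g$beta_yd <- 0.1
  # independent direct evaluation of the linear predictor
  expected <- plogis(0.3 - 0.2 * log(2) + 0.5 * 1.5 + 0.1 * log(2) * 1.5)
  expect_equal(gate_probability(g, 2, 1.5), expected, tolerance = 1e-12)
  expect_error(gate_probability(g, -1, 1), class = "phygrow_domain_error")
  expect_error(gate_probability(g, 2, Inf), class = "phygrow_domain_error")
})

test_that("gate fitting recovers known coefficients within 3 standard errors", {
  set.seed(92)
  n <- 2000
  ly <- rnorm(n, log(3), 1)
  dp <- rexp(n, 1)
  beta_true <- c(0, -1, 2, 0)
  eta <- beta_true[1] + beta_true[2] * ly + beta_true[3] * dp +
    beta_true[4] * ly * dp
  lab <- rbinom(n, 1, plogis(eta))
  fit <- fit_gate(data.frame(y_cub = exp(ly), d_p = dp, label = lab))
  est <- c(fit$beta0, fit$beta_y, fit$beta_d, fit$beta_yd)
  expect_true(all(abs(est - beta_true) <= 3 * fit$se))
  expect_false(fit$separation)
})

test_that("degenerate gate fits fail loudly or stabilize", {
  df1 <- data.frame(y_cub = exp(rnorm(50)), d_p = rexp(50), label = 1)
  expect_error(fit_gate(df1), class = "phygrow_fit_error")
  expect_error(fit_gate(df1[1:5, ]), class = "phygrow_fit_error")
  # perfectly separable labels: ridge-stabilized finite coefficients
  set.seed(93)
  dp <- runif(100, 0, 4)
  sep <- data.frame(y_cub = 3, d_p = dp, label = as.integer(dp > 2))
  expect_warning(fit <- fit_gate(sep), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(c(fit$beta0, fit$beta_y, fit$beta_d, fit$beta_yd))))
  # the stabilized gate still orders the classes correctly
  expect_lt(gate_probability(fit, 3, 0.5), gate_probability(fit, 3, 3.5))
})

test_that("gate models serialize to text and back", {
  g <- zero_gate; g$beta0 <- 0.25; g$beta_y <- -1.5; g$n <- 77L
  tf <- withr::local_tempfile()
  write_gate_model(g, tf)
  g2 <- read_gate_model(tf)
  expect_equal(g2$beta0, 0.25)
  expect_equal(g2$beta_y, -1.5)
  expect_equal(g2$n, 77L)
})

test_that("hybrid prediction combines components and applies fallbacks", {
  bench <- make_benchmark(benchmark_config(n_species = 30, seed = 14))
  profs <- lapply(bench$genomes, cub_profile)
  cm <- fit_cub_model(profs, bench$traits)
  q <- "sp001"
  hp <- hybrid_predict(cm, zero_gate, bench$tree, bench$traits, profs[[q]],
                       mode = "arithmetic")
  expect_equal(hp$p_gate, 0.5)
  expect_equal(hp$y_hybrid, (hp$y_cub + hp$y_phylo) / 2, tolerance = 1e-12)
  expect_true(hp$y_hybrid >= min(hp$y_cub, hp$y_phylo) &&
                hp$y_hybrid <= max(hp$y_cub, hp$y_phylo))

  # CUB quality failure: falls back to the phylogenetic estimate, flagged
  g_bad <- bench$genomes[[q]]
  g_bad$ribosomal[] <- FALSE
  hp_bad <- hybrid_predict(cm, zero_gate, bench$tree, bench$traits, g_bad,
                           query = q)
  expect_equal(hp_bad$p_gate, 0)
  expect_equal(hp_bad$y_hybrid, hp_bad$y_phylo)
  expect_match(hp_bad$flags, "cub_failed")

  # query missing from the tree: CUB-only, flagged
  hp_no_tree <- hybrid_predict(cm, zero_gate, bench$tree, bench$traits,
                               profs[[q]], query = "not_a_tip")
  expect_equal(hp_no_tree$p_gate, 1)
  expect_equal(hp_no_tree$y_hybrid, hp_no_tree$y_cub)
  expect_match(hp_no_tree$flags, "no_phylogeny")
})
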