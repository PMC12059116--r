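# A small shared benchmark keeps the CV tests quick.
cv_bench <- local({
  b <- make_benchmark(benchmark_config(n_species = 60, seed = 17,
                                       bm_sigma2 = 0.6, cub_noise_sd = 0.3))
  b$profiles <- lapply(b$genomes, cub_profile)
  b
})

oracle_predictor <- function(truth) {
  list(name = "oracle",
       fit = function(tree, traits, train_tips, dmat) NULL,
       predict = function(state, tree, traits, test_tips, dmat)
         truth[test_tips])
}

constant_predictor <- function(value) {
  list(name = "constant",
       fit = function(tree, traits, train_tips, dmat) NULL,
       predict = function(state, tree, traits, test_tips, dmat)
         setNames(rep(value, length(test_tips)), test_tips))
}

test_that("blocked folds partition the tip set", {
  tr <- cv_bench$tree
  for (n in c(2, 10, 30, 60)) {
    folds <- make_folds(tr, n)
    tests <- unlist(lapply(folds, `[[`, "test"))
    expect_setequal(tests, tr$tip.label)
    expect_equal(anyDuplicated(tests), 0)
    for (f in folds) {
      expect_length(intersect(f$test, f$train), 0)
      expect_setequal(c(f$test, f$train), tr$tip.label)
    }
  }
  expect_equal(length(make_folds(tr, 60)), 60)  # leave-one-out
  expect_error(make_folds(tr, 1), class = "phygrow_domain_error")
})

test_that("fold MSE has the expected closed forms", {
  truth <- setNames(cv_bench$traits$doubling_h, cv_bench$traits$species)
  folds <- make_folds(cv_bench$tree, 10)
  cfg <- cv_config(n_values = c(10))
  res_oracle <- cv_evaluate(cv_bench$tree, cv_bench$traits, folds,
                            list(oracle_predictor(truth)), cfg)
  ok <- res_oracle[res_oracle$stratum == "all", ]
  expect_true(all(ok$mse == 0))

  # constant predictor on a 3-species toy: MSE = mean squared ln deviation
  toy <- toy_tree()
  toy_tr <- data.frame(species = c("A", "B", "C"), doubling_h = c(1, 2, 4))
  gm <- exp(mean(log(c(1, 2, 4))))
  folds3 <- make_folds(toy, 3)
  res <- cv_evaluate(toy, toy_tr, folds3, list(constant_predictor(gm)),
                     cv_config(n_values = c(2, 3)))
  all_rows <- res[res$stratum == "all", ]
  # equal-weight mean over the three singleton folds = population variance
  expect_equal(mean(all_rows$mse), mean((log(c(1, 2, 4)) - mean(log(c(1, 2, 4))))^2),
               tolerance = 1e-12)
})

test_that("growth strata split at 5 h with the boundary in 'fast'", {
  tr <- simulate_tree(8, seed = 23)
  d <- c(0.2, 0.4, 5, 5.01, 8, 20, 1, 3)  # one species exactly at 5 h
  traits <- data.frame(species = tr$tip.label, doubling_h = d)
  truth <- setNames(d, tr$tip.label)
  folds <- make_folds(tr, 2)
  res <- cv_evaluate(tr, traits, folds, list(oracle_predictor(truth)),
                     cv_config(n_values = c(2)))
  n_by_stratum <- tapply(res$n_species, res$stratum, sum)
  expect_equal(unname(n_by_stratum[["fast"]]), sum(d <= 5))   # 5 h is fast
  expect_equal(unname(n_by_stratum[["slow"]]), sum(d > 5))
  expect_equal(unname(n_by_stratum[["fast_inset"]]), sum(d < 0.5))
})

test_that("predictor failures are recorded, not dropped", {
  failing <- list(name = "fails",
                  fit = function(tree, traits, train_tips, dmat)
                    phygrow:::stop_fit("always fails"),
                  predict = function(...) NULL)
  folds <- make_folds(cv_bench$tree, 5)
  res <- cv_evaluate(cv_bench$tree, cv_bench$traits, folds, list(failing),
                     cv_config(n_values = c(5)))
  expect_equal(nrow(res), 5)
  expect_true(all(is.na(res$mse)))
  expect_true(all(grepl("always fails", res$status)))
})

test_that("the sweep emits one scenario per n and fold distances shrink", {
  cfg <- cv_config(n_values = seq(5, 30, by = 5))
  sw <- cv_sweep(cv_bench$tree, cv_bench$traits, list(predictor_nnm()), cfg)
  all_rows <- sw$summary[sw$summary$stratum == "all", ]
  expect_equal(nrow(all_rows), length(cfg$n_values))
  expect_true(all(diff(all_rows$fold_dp_min) <= 1e-12))
  expect_true(all(diff(all_rows$cut_depth) <= 1e-12))

  single <- cv_sweep(cv_bench$tree, cv_bench$traits, list(predictor_nnm()),
                     cv_config(n_values = c(10)))
  expect_equal(unique(single$summary$requested_n), 10)
})

test_that("phylopred error falls with n when the trait is heritable", {
  b <- make_benchmark(benchmark_config(n_species = 80, seed = 19,
                                       bm_sigma2 = 1.5, lambda_true = 1,
                                       cub_noise_sd = 0.3))
  cfg <- cv_config(n_values = seq(10, 80, by = 10))
  sw <- cv_sweep(b$tree, b$traits, list(predictor_phylopred()), cfg)
  curve <- sw$summary[sw$summary$stratum == "all", ]
  rho <- cor(curve$n, curve$mse, method = "spearman")
  expect_lt(rho, -0.8)
})

test_that("gate labels reflect which component carries the signal", {
  # CUB-dominant regime: no phylogenetic signal, noise-free codon bias;
  # relatives actively mislead the BM predictor, so CUB wins nearly always
  b_cub <- make_benchmark(regime_config("cub_dominant", seed = 25))
  profs <- lapply(b_cub$genomes, cub_profile)
  lab_cub <- derive_gate_labels(b_cub$tree, b_cub$traits, profs, inner_n = 30)
  expect_gte(mean(lab_cub$label), 0.9)

  # phylo-dominant regime: perfectly heritable trait, badly noisy CUB:
  # species with close relatives are labelled for the phylogenetic side
  b_ph <- make_benchmark(regime_config("phylo_dominant", seed = 26))
  profs_ph <- lapply(b_ph$genomes, cub_profile)
  lab_ph <- derive_gate_labels(b_ph$tree, b_ph$traits, profs_ph, inner_n = 50)
  near <- lab_ph[lab_ph$d_p <= median(lab_ph$d_p), ]
  expect_lt(mean(near$label), 0.5)

  expect_error(derive_gate_labels(b_ph$tree, b_ph$traits, list(), inner_n = 5),
               class = "phygrow_domain_error")
})
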