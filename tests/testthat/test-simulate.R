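test_that("simulation is deterministic given the seed", {
  a <- small_sim(seed = 9)
  b <- small_sim(seed = 9)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)
  expect_identical(a$design, b$design)
  c <- small_sim(seed = 10)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("gene classes are disjoint and sized as configured", {
  cfg <- simulation_config(n_genes = 500, n_transplant_genes = 40,
                           n_regression_up = 30, n_regression_down = 20,
                           seed = 2)
  ex <- simulate_experiment(cfg)
  tab <- table(ex$truth$class)
  expect_equal(unname(tab[["transplant"]]), 40)
  expect_equal(unname(tab[["regression_up"]]), 30)
  expect_equal(unname(tab[["regression_down"]]), 20)
  expect_equal(unname(tab[["causal_direct"]]), cfg$causal_spec$n_direct)
  expect_equal(sum(tab), 500)          # every gene exactly one class
  expect_equal(anyDuplicated(ex$truth$gene), 0)
  # causal edges reference only causal genes and T
  causal_genes <- ex$truth$gene[startsWith(ex$truth$class, "causal")]
  expect_true(all(ex$causal_edges$to %in% causal_genes))
  expect_true(all(ex$causal_edges$from %in% c("T", causal_genes)))
})

test_that("every sample has two arrays with opposite dye orientation", {
  ex <- small_sim(seed = 5, n_genes = 20)
  expect_silent(validate_design(ex$design))
  per <- split(ex$design$dye, ex$design$sample_id)
  expect_true(all(vapply(per, function(d) setequal(d, c("forward",
                                                        "reverse")),
                         logical(1))))
})

test_that("planted regression effect converges to the configured ratio", {
  # Monte-Carlo over 200 replicate simulations: the geometric-mean
  # regression-vs-progression ratio of planted up genes approaches 1.5.
  set.seed(77)
  deltas <- replicate(200, {
    ex <- simulate_experiment(simulation_config(
      n_genes = 60, n_transplant_genes = 0, n_regression_up = 50,
      n_regression_down = 0,
      causal_spec = causal_neighborhood_spec(n_direct = 1, n_mediated = 0,
                                             n_remote = 0),
      seed = sample.int(1e6, 1)))
    mat <- prep_matrix(ex)
    up <- ex$truth$gene[ex$truth$class == "regression_up"]
    mean(fold_change(mat, ex$design, "progression", "regression")[up])
  })
  expect_equal(mean(deltas), 1.5, tolerance = 0.01)
})

test_that("dye bias cancels exactly in the combined matrix", {
  base <- simulation_config(n_genes = 100, seed = 33, dye_bias_sd = 0,
                            n_transplant_genes = 10, n_regression_up = 10,
                            n_regression_down = 10)
  biased <- simulation_config(n_genes = 100, seed = 33, dye_bias_sd = 0.8,
                              n_transplant_genes = 10,
                              n_regression_up = 10,
                              n_regression_down = 10)
  m0 <- combine_dye_swap(simulate_experiment(base)$measurements,
                         simulate_experiment(base)$design)
  m1 <- combine_dye_swap(simulate_experiment(biased)$measurements,
                         simulate_experiment(biased)$design)
  expect_equal(m0, m1, tolerance = 1e-12)
})

test_that("null simulations are null: classes, ANOVA calibration, errors", {
  ex <- simulate_null(simulation_config(n_genes = 10000, seed = 42))
  expect_true(all(ex$truth$class == "null"))
  expect_true(all(ex$truth$true_fc == 1))
  mat <- prep_matrix(ex)
  frac <- mean(anova_p(mat, ex$design, "progression", "regression") < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
})

test_that("causal neighborhood reproduces the prescribed correlations", {
  spec <- causal_neighborhood_spec(n_direct = 2, n_mediated = 2,
                                   n_remote = 2, direct_strength = 0.8,
                                   mediation_strength = 0.6)
  set.seed(8)
  target <- rep(c(0, 1), each = 5000)
  cn <- simulate_causal_neighborhood(spec, target)
  t_std <- (target - mean(target)) / sd(target)
  r <- as.vector(cor(t(cn$values), t_std))
  expect_equal(r[cn$classes == "causal_direct"], c(0.8, 0.8),
               tolerance = 0.05)
  expect_equal(r[cn$classes == "causal_mediated"], c(0.48, 0.48),
               tolerance = 0.05)
  expect_lt(max(abs(r[cn$classes == "causal_remote"])), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(n_genes = 100, n_transplant_genes = 90,
                                 n_regression_up = 50),
               "exceed")
  expect_error(causal_neighborhood_spec(direct_strength = 1), "strictly")
  expect_error(causal_neighborhood_spec(direct_strength = 0), "strictly")
  expect_error(simulate_causal_neighborhood(causal_neighborhood_spec(),
                                            rep(1, 10)),
               "both classes")
})
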