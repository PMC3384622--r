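make_two_group <- function(a, b) {
  design <- toy_design(n_per_group = max(length(a), length(b)))
  sdes <- sample_design(design)
  mat <- matrix(0, 1, nrow(sdes), dimnames = list("g1", sdes$sample_id))
  mat[1, sdes$group == "progression"] <- a
  mat[1, sdes$group == "regression"] <- b
  list(mat = mat, design = design)
}

test_that("two-group ANOVA matches stats::aov and handles degeneracies", {
  # worked example: groups (0.1,0.2,0.3) vs (0.5,0.6,0.7) give F = 24
  tg <- make_two_group(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7))
  p <- anova_p(tg$mat, tg$design, "progression", "regression")
  expect_equal(unname(p), pf(24, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  # agreement with stats::aov on random data
  set.seed(6)
  ex <- small_sim(seed = 6, n_genes = 25)
  mat <- prep_matrix(ex)
  p_vec <- anova_p(mat, ex$design, "progression", "regression")
  sdes <- sample_design(ex$design)
  keep <- sdes$group %in% c("progression", "regression")
  for (g in sample(rownames(mat), 10)) {
    fit <- stats::aov(y ~ grp, data.frame(y = mat[g, keep],
                                          grp = sdes$group[keep]))
    expect_equal(unname(p_vec[g]), summary(fit)[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-10)
  }

  # complete separation with zero within-group variance
  tg <- make_two_group(c(1, 1, 1), c(2, 2, 2))
  expect_equal(unname(anova_p(tg$mat, tg$design, "progression",
                              "regression")), 1e-300)
  # no difference and no variance
  tg <- make_two_group(c(1, 1, 1), c(1, 1, 1))
  expect_equal(unname(anova_p(tg$mat, tg$design, "progression",
                              "regression")), 1)
})

test_that("fold changes are signed linear ratios with inclusive threshold", {
  tg <- make_two_group(rep(0, 3), rep(log10(1.2), 3))
  fc <- fold_change(tg$mat, tg$design, "progression", "regression")
  expect_equal(unname(fc), 1.2, tolerance = 1e-12)
  expect_true(abs(log10(abs(fc))) >= log10(1.2))  # boundary passes

  tg <- make_two_group(rep(0.5, 3), rep(0.5, 3))
  expect_equal(unname(fold_change(tg$mat, tg$design, "progression",
                                  "regression")), 1)

  tg <- make_two_group(rep(0, 3), rep(-0.30103, 3))
  expect_equal(unname(fold_change(tg$mat, tg$design, "progression",
                                  "regression")), -2, tolerance = 1e-4)
})

test_that("profile cascade equals an independent gene-by-gene recheck", {
  for (seed in c(3, 19)) {
    ex <- small_sim(seed = seed, n_genes = 400)
    mat <- prep_matrix(ex)
    ep <- error_model_surrogate(ex$measurements, ex$design)
    cfg <- pipeline_config(seed = seed)
    prof <- build_profile(mat, ex$design, ep, cfg)
    expect_setequal(prof$table$gene, profile_recheck(mat, ex$design, ep,
                                                     cfg))
    expect_equal(prof$n_final, nrow(prof$table))
    # every member satisfies all four criteria
    expect_true(all(prof$table$p_regression < cfg$p_regression))
    expect_true(all(prof$table$p_transplant > cfg$p_transplant))
    expect_true(all(prof$table$p_error < cfg$p_error_model))
    expect_true(all(abs(log10(abs(prof$table$fold_change))) >=
                      log10(cfg$fc_threshold) - 1e-12))
  }
})

test_that("tightening any threshold never grows the profile", {
  ex <- small_sim(seed = 8, n_genes = 300)
  mat <- prep_matrix(ex)
  ep <- error_model_surrogate(ex$measurements, ex$design)
  base <- build_profile(mat, ex$design, ep, pipeline_config())$n_final
  tighter <- list(pipeline_config(p_regression = 0.01),
                  pipeline_config(p_transplant = 0.3),
                  pipeline_config(p_error_model = 0.01),
                  pipeline_config(fc_threshold = 1.5))
  for (cfg in tighter) {
    expect_lte(build_profile(mat, ex$design, ep, cfg)$n_final, base)
  }
})

test_that("profile recovers most planted regression genes", {
  # power at the reference design: 50 up-regulated genes at a 1.5-fold
  # shift, noise_sd 0.1; the error-model filter has ~80% per-gene power
  # here, so median recovery lands near 35-40 of 50
  set.seed(31)
  hits <- sapply(1:7, function(i) {
    s <- sample.int(1e6, 1)
    ex <- simulate_experiment(simulation_config(
      n_genes = 1000, n_transplant_genes = 50, n_regression_up = 50,
      n_regression_down = 0, noise_sd = 0.1, seed = s))
    mat <- prep_matrix(ex)
    ep <- error_model_surrogate(ex$measurements, ex$design)
    prof <- build_profile(mat, ex$design, ep, pipeline_config(seed = s))
    up <- ex$truth$gene[ex$truth$class == "regression_up"]
    length(intersect(prof$table$gene, up))
  })
  expect_gte(median(hits), 30)
})

test_that("K-means split separates up from down transcripts", {
  design <- toy_design(n_per_group = 4)
  sdes <- sample_design(design)
  set.seed(5)
  mat <- matrix(rnorm(4 * nrow(sdes), sd = 0.01), 4, nrow(sdes),
                dimnames = list(paste0("g", 1:4), sdes$sample_id))
  reg <- sdes$group == "regression"
  mat[1:2, reg] <- mat[1:2, reg] + 1
  mat[3:4, reg] <- mat[3:4, reg] - 1
  lab <- split_up_down_kmeans(mat, design, rownames(mat),
                              pipeline_config())
  expect_equal(unname(lab), c("up", "up", "down", "down"))

  # identical vectors: no crash, centroid tie-break applies one label
  mat2 <- matrix(rep(c(rep(0, 4), rep(0, 4), rep(1, 4)), each = 3),
                 nrow = 3, byrow = FALSE,
                 dimnames = list(paste0("g", 1:3), sdes$sample_id))
  lab2 <- split_up_down_kmeans(mat2, design, rownames(mat2),
                               pipeline_config())
  expect_true(all(lab2 == "up"))
})

test_that("K-means labels match planted signs on simulated profiles", {
  ex <- simulate_experiment(simulation_config(
    n_genes = 400, n_transplant_genes = 0, n_regression_up = 40,
    n_regression_down = 40, effect_size_log10 = 0.25, noise_sd = 0.1,
    seed = 13))
  mat <- prep_matrix(ex)
  members <- ex$truth$gene[ex$truth$class %in% c("regression_up",
                                                 "regression_down")]
  lab <- split_up_down_kmeans(mat, ex$design, members, pipeline_config())
  want <- ifelse(ex$truth$class[match(members, ex$truth$gene)] ==
                   "regression_up", "up", "down")
  expect_gte(mean(lab == want), 0.95)
})

test_that("empty and tiny profiles are handled gracefully", {
  ex <- simulate_null(simulation_config(n_genes = 150, seed = 23,
                                        n_transplant_genes = 0,
                                        n_regression_up = 0,
                                        n_regression_down = 0))
  mat <- prep_matrix(ex)
  ep <- error_model_surrogate(ex$measurements, ex$design)
  cfg <- pipeline_config(fc_threshold = 50)
  prof <- build_profile(mat, ex$design, ep, cfg)
  expect_equal(prof$n_final, 0)
  expect_equal(nrow(prof$table), 0)
})

test_that("FDP estimator is reproducible and correct on trivial cases", {
  ex <- small_sim(seed = 16, n_genes = 250)
  mat <- prep_matrix(ex)
  cfg <- pipeline_config(seed = 16, n_fdp_permutations = 30)
  f1 <- estimate_fdp(mat, ex$design, cfg)
  f2 <- estimate_fdp(mat, ex$design, cfg)
  expect_identical(f1$permuted_sizes, f2$permuted_sizes)
  expect_identical(f1$fdp_estimate, f2$fdp_estimate)
  expect_true(f1$fdp_estimate >= 0 && f1$fdp_estimate <= 1)
  expect_equal(f1$fdp_estimate,
               min(1, f1$mean_permuted_size / f1$observed_size))
})

test_that("FDP is near 1 on exchangeable null data", {
  # thresholds relaxed so the null profile is large enough for the ratio
  # estimator to concentrate (the estimator, not the cascade, is under
  # test here)
  cfg <- pipeline_config(p_regression = 0.3, p_error_model = 0.9,
                         fc_threshold = 1.05, n_fdp_permutations = 50,
                         seed = 62)
  fdps <- sapply(1:3, function(i) {
    ex <- simulate_null(simulation_config(n_genes = 2000, seed = 62 + i))
    estimate_fdp(prep_matrix(ex), ex$design, cfg)$fdp_estimate
  })
  expect_true(all(fdps > 0.8))
  expect_gte(median(fdps), 0.85)
})
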