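test_that("partial correlation: identity, closed form, residual method", {
  set.seed(2)
  x <- rnorm(30)
  expect_equal(partial_correlation(x, x), 1)

  # prescribed sample correlations r_xy=0.8, r_xz=r_yz=0.5:
  # r_xy.z = (0.8 - 0.25) / (1 - 0.25) = 0.7333...
  v <- vectors_with_correlations(0.8, 0.5, 0.5)
  expect_equal(cor(v$x, v$y), 0.8, tolerance = 1e-12)
  expect_equal(partial_correlation(v$x, v$y, v$z), 0.55 / 0.75,
               tolerance = 1e-10)

  # closed form (|Z| = 1) agrees with the residual-regression route
  pcor_residual <- function(x, y, z) {
    cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
  }
  set.seed(15)
  for (i in 1:50) {
    z <- rnorm(40)
    x <- 0.6 * z + rnorm(40)
    y <- -0.4 * z + rnorm(40)
    expect_equal(partial_correlation(x, y, z), pcor_residual(x, y, z),
                 tolerance = 1e-10)
  }

  # |Z| = 2 via residual projection
  set.seed(16)
  z1 <- rnorm(50); z2 <- rnorm(50)
  x <- z1 + z2 + rnorm(50); y <- z1 - z2 + rnorm(50)
  d <- cbind(1, z1, z2)
  expect_equal(partial_correlation(x, y, cbind(z1, z2)),
               cor(resid(lm.fit(d, x)), resid(lm.fit(d, y))),
               tolerance = 1e-12)
})

test_that("partial correlation vanishes along a simulated chain", {
  set.seed(77)
  n <- 5000
  x <- rnorm(n)
  z <- 0.8 * x + rnorm(n, sd = 0.6)
  y <- 0.8 * z + rnorm(n, sd = 0.6)
  expect_lt(abs(partial_correlation(x, y, z)), 0.05)
  expect_gt(abs(partial_correlation(x, y)), 0.3)
})

test_that("degenerate and collinear inputs are rejected", {
  x <- rnorm(20); y <- rnorm(20)
  expect_error(partial_correlation(rep(1, 20), y), "degenerate")
  expect_error(partial_correlation(x, y, rep(0, 20)), "degenerate")
  expect_error(partial_correlation(x, y, x), "collinear")
  expect_error(partial_correlation(x[1:4], y[1:4], cbind(x[1:4], y[1:4])),
               "insufficient sample")
})

test_that("Fisher's Z test matches its closed form and boundaries", {
  # r = 0: no evidence
  t0 <- fisher_z_test(0, 30)
  expect_equal(t0$z, 0)
  expect_equal(t0$p, 1)
  expect_equal(t0$decision, "independent")

  # worked case r = 0.5, n = 20, k = 0
  t1 <- fisher_z_test(0.5, 20, 0)
  expect_equal(t1$z, atanh(0.5) * sqrt(17), tolerance = 1e-12)
  expect_equal(t1$z, 2.2648, tolerance = 1e-4)
  expect_equal(t1$p, 2 * pnorm(-atanh(0.5) * sqrt(17)), tolerance = 1e-12)
  expect_equal(t1$p, 0.0235, tolerance = 1e-3)
  expect_equal(t1$decision, "dependent")

  # perfect correlation
  t2 <- fisher_z_test(1, 10)
  expect_equal(t2$p, 0)
  expect_true(is.infinite(t2$z))

  # conditioning exhausts the sample
  expect_error(fisher_z_test(0.3, 5, 2), "insufficient sample")
})

test_that("Fisher's Z test is calibrated under independence", {
  set.seed(29)
  n <- 50; reps <- 2000
  rejected <- sapply(seq_len(reps), function(i) {
    r <- cor(rnorm(n), rnorm(n))
    fisher_z_test(r, n, 0, alpha = 0.05)$decision == "dependent"
  })
  rate <- mean(rejected)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("HITON-PC distinguishes direct from mediated variables", {
  # chain X1 -> X2 -> T: X2 is in the parents-children set, X1 is
  # univariately associated but d-separated by X2
  hits <- sapply(1:5, function(s) {
    inst <- chain_instance(s, n = 2000)
    cs <- hiton_pc(inst$mat, inst$target, pipeline_config(seed = s))
    identical(cs$members, "X2")
  })
  expect_gte(sum(hits), 4)

  # in a recovering run, the trace shows X1 entered the queue
  # (univariately dependent) and was eliminated conditioning on X2
  s_ok <- which(hits)[1]
  inst <- chain_instance(s_ok, n = 2000)
  cs <- hiton_pc(inst$mat, inst$target, pipeline_config(seed = s_ok))
  uni <- cs$trace[cs$trace$phase == "univariate", ]
  expect_equal(uni$decision[uni$x == "X1"], "dependent")
  elim <- cs$trace[cs$trace$x == "X1" & cs$trace$conditioning == "X2", ]
  expect_gte(nrow(elim), 1)
  expect_true(all(elim$decision == "independent"))
})

test_that("HITON-PC output is deterministic and empty when nothing associates", {
  set.seed(41)
  mat <- matrix(rnorm(6 * 60), 6, 60,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:60)))
  target <- rep(c(0, 1), 30)
  a <- hiton_pc(mat, target, pipeline_config())
  b <- hiton_pc(mat, target, pipeline_config())
  expect_identical(a$members, b$members)
  expect_identical(a$trace, b$trace)

  # unrelated noise: typically empty, never an error
  expect_true(length(a$members) <= 2)

  # degenerate gene is rejected
  mat[2, ] <- 5
  expect_error(hiton_pc(mat, target, pipeline_config()), "degenerate")
})

test_that("members at alpha 0.01 are univariate survivors at alpha 0.05", {
  inst <- random_pc_instance(7)
  strict <- hiton_pc(inst$mat, inst$target,
                     pipeline_config(alpha_ci = 0.01))
  loose <- hiton_pc(inst$mat, inst$target,
                    pipeline_config(alpha_ci = 0.05))
  uni_surv <- unique(loose$trace$x[loose$trace$phase == "univariate" &
                                     loose$trace$decision == "dependent"])
  expect_true(all(strict$members %in% uni_surv))
})

test_that("HITON-PC agrees with the brute-force oracle", {
  agree <- 0
  for (s in 1:30) {
    inst <- random_pc_instance(1000 + s)
    cfg <- pipeline_config(seed = s)
    h <- hiton_pc(inst$mat, inst$target, cfg, trace = FALSE)
    bf <- brute_force_pc(inst$mat, inst$target, cfg)
    agree <- agree + setequal(h$members, bf$members)
  }
  expect_gte(agree, 28)
})

test_that("brute force handles singletons, duplicates and size limits", {
  set.seed(3)
  n <- 400
  target <- rep(c(0, 1), n / 2)
  signal <- 0.8 * scale(target)[, 1] + 0.6 * rnorm(n)
  mat <- rbind(g1 = signal)
  colnames(mat) <- paste0("s", 1:n)
  expect_equal(brute_force_pc(mat, target, pipeline_config())$members,
               "g1")

  # near-duplicate copies of one signal eliminate each other
  dup <- rbind(g1 = signal + rnorm(n, sd = 1e-4),
               g2 = signal + rnorm(n, sd = 1e-4),
               g3 = signal + rnorm(n, sd = 1e-4))
  colnames(dup) <- paste0("s", 1:n)
  expect_equal(length(brute_force_pc(dup, target,
                                     pipeline_config())$members), 0)

  big <- matrix(rnorm(16 * 50), 16, 50,
                dimnames = list(paste0("g", 1:16), paste0("s", 1:50)))
  expect_error(brute_force_pc(big, rep(c(0, 1), 25), pipeline_config()),
               "too many")
})

test_that("the trace is sufficient to replay every decision", {
  inst <- random_pc_instance(55)
  cs <- hiton_pc(inst$mat, inst$target, pipeline_config())
  tr <- cs$trace
  expect_true(all((tr$p > cs$alpha_ci) == (tr$decision == "independent")))
  # members never received an 'independent' verdict in elimination phases
  elim <- tr[tr$phase != "univariate" & tr$decision == "independent", ]
  expect_length(intersect(unique(elim$x), cs$members), 0)
})
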