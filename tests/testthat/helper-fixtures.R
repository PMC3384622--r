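# Shared fixture builders; everything is generated in code.

# Small planted experiment for module tests.
small_sim <- function(seed = 1, n_genes = 300, ...) {
  simulate_experiment(simulation_config(
    n_genes = n_genes,
    n_transplant_genes = min(30L, n_genes %/% 10),
    n_regression_up = min(20L, n_genes %/% 10),
    n_regression_down = min(20L, n_genes %/% 10),
    seed = seed, ...))
}

# Combined + batch-centered matrix of an experiment.
prep_matrix <- function(ex) {
  reratio_by_batch(combine_dye_swap(ex$measurements, ex$design), ex$design)
}

# Binary regression indicator aligned with the matrix columns.
regression_target <- function(ex, mat) {
  sdes <- sample_design(ex$design)
  as.numeric(sdes$group[match(colnames(mat), sdes$sample_id)] ==
               "regression")
}

# Hand-built array-level design: n samples per group, one batch unless
# batches given.
toy_design <- function(n_per_group = 2, batches = "B1") {
  rows <- list()
  s <- 0L
  for (b in batches) {
    for (g in c("baseline", "progression", "regression")) {
      for (k in seq_len(n_per_group)) {
        s <- s + 1L
        sid <- sprintf("S%02d", s)
        rows[[length(rows) + 1L]] <- data.frame(
          array_id = paste0(sid, c("_F", "_R")), sample_id = sid,
          group = g, batch = b, dye = c("forward", "reverse"))
      }
    }
  }
  do.call(rbind, rows)
}

# Independent gene-by-gene recheck of the four cascade criteria, written
# against a different code path (stats::t.test per gene) than
# build_profile.
profile_recheck <- function(mat, design, error_p, config) {
  sdes <- sample_design(design)
  ep <- if (is.data.frame(error_p)) {
    stats::setNames(error_p$p, error_p$gene)
  } else error_p
  cols <- function(g) sdes$sample_id[sdes$group == g]
  keep <- vapply(rownames(mat), function(gene) {
    xb <- mat[gene, cols("baseline")]
    xp <- mat[gene, cols("progression")]
    xr <- mat[gene, cols("regression")]
    p_t <- tryCatch(stats::t.test(xb, xp, var.equal = TRUE)$p.value,
                    error = function(e) 1)
    p_r <- tryCatch(stats::t.test(xp, xr, var.equal = TRUE)$p.value,
                    error = function(e) 1)
    d <- mean(xr) - mean(xp)
    p_t > config$p_transplant &&
      p_r < config$p_regression &&
      ep[gene] < config$p_error_model &&
      abs(d) >= log10(config$fc_threshold)
  }, logical(1))
  sort(rownames(mat)[keep])
}

# Three vectors with prescribed *sample* correlations, built from an
# orthonormal basis of the mean-zero subspace.
vectors_with_correlations <- function(r_xy, r_xz, r_yz, n = 50,
                                      seed = 11) {
  set.seed(seed)
  M <- matrix(rnorm(n * 3), n, 3)
  M <- scale(M, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))
  e1 <- Q[, 1]; e2 <- Q[, 2]; e3 <- Q[, 3]
  x <- e1
  z <- r_xz * e1 + sqrt(1 - r_xz^2) * e2
  b <- (r_yz - r_xy * r_xz) / sqrt(1 - r_xz^2)
  cc <- sqrt(1 - r_xy^2 - b^2)
  y <- r_xy * e1 + b * e2 + cc * e3
  list(x = x, y = y, z = z)
}

# Random linear-Gaussian local-neighborhood instance for oracle
# comparisons: <= `max_candidates` genes around a balanced binary target.
random_pc_instance <- function(seed, n = 2000, max_candidates = 8) {
  set.seed(seed)
  n_direct <- sample(1:3, 1)
  n_mediated <- sample(0:3, 1)
  n_remote <- max_candidates - n_direct - n_mediated
  spec <- causal_neighborhood_spec(
    n_direct = n_direct, n_mediated = n_mediated, n_remote = n_remote,
    direct_strength = runif(1, 0.3, 0.8),
    mediation_strength = runif(1, 0.3, 0.8))
  target <- rep(c(0, 1), length.out = n)
  cn <- simulate_causal_neighborhood(spec, target)
  list(mat = cn$values, target = target, classes = cn$classes)
}

# Chain T -> X2 -> X1 (conditional-independence structure of
# X1 -> X2 -> T): X1 is d-separated from T by X2.
chain_instance <- function(seed, n = 1000, strength = 0.7) {
  set.seed(seed)
  spec <- causal_neighborhood_spec(n_direct = 1, n_mediated = 1,
                                   n_remote = 0,
                                   direct_strength = strength,
                                   mediation_strength = strength)
  target <- rep(c(0, 1), length.out = n)
  cn <- simulate_causal_neighborhood(spec, target,
                                     gene_ids = c("X2", "X1"))
  list(mat = cn$values, target = target)
}
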