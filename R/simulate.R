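#' Sample a planted causal neighborhood given a binary target
#'
#' Draws the causal-class gene values from the linear structural-equation
#' model of a \code{\link{causal_neighborhood_spec}}: the binary target is
#' standardized, direct genes are \code{a * T_std} plus standard-Gaussian
#' noise scaled so each has unit variance, mediated genes depend only on
#' their (round-robin assigned) direct parent, and remote genes are
#' independent standard Gaussians. Values are returned on the unit scale;
#' callers apply \code{signal_scale}.
#'
#' @param spec A \code{\link{causal_neighborhood_spec}}.
#' @param target Binary 0/1 vector (must contain both values).
#' @param gene_ids Optional character vector of ids for the causal genes.
#' @return A list with \code{values} (genes x samples matrix),
#'   \code{classes} (per-gene class) and \code{edges} (data frame
#'   \code{from}, \code{to}).
#' @export
simulate_causal_neighborhood <- function(spec, target, gene_ids = NULL) {
  stopifnot(inherits(spec, "causal_neighborhood_spec"))
  if (!all(target %in% c(0, 1)) || length(unique(target)) < 2) {
    stop("target must be a binary 0/1 vector with both classes present")
  }
  n <- length(target)
  p <- n_causal_genes(spec)
  if (is.null(gene_ids)) gene_ids <- sprintf("C%03d", seq_len(p))
  stopifnot(length(gene_ids) == p)
  t_std <- (target - mean(target)) / stats::sd(target)
  a <- spec$direct_strength
  b <- spec$mediation_strength
  vals <- matrix(0, nrow = p, ncol = n)
  classes <- character(p)
  edges <- data.frame(from = character(0), to = character(0))
  idx <- 1L
  direct_ids <- character(0)
  direct_vals <- NULL
  if (spec$n_direct > 0) {
    direct_ids <- gene_ids[seq_len(spec$n_direct)]
    direct_vals <- matrix(0, spec$n_direct, n)
    for (i in seq_len(spec$n_direct)) {
      direct_vals[i, ] <- a * t_std + sqrt(1 - a^2) * stats::rnorm(n)
      vals[idx, ] <- direct_vals[i, ]
      classes[idx] <- "causal_direct"
      idx <- idx + 1L
    }
    edges <- rbind(edges, data.frame(from = "T", to = direct_ids))
  }
  if (spec$n_mediated > 0) {
    parent <- rep(seq_len(spec$n_direct), length.out = spec$n_mediated)
    for (i in seq_len(spec$n_mediated)) {
      vals[idx, ] <- b * direct_vals[parent[i], ] +
        sqrt(1 - b^2) * stats::rnorm(n)
      classes[idx] <- "causal_mediated"
      edges <- rbind(edges, data.frame(from = direct_ids[parent[i]],
                                       to = gene_ids[idx]))
      idx <- idx + 1L
    }
  }
  if (spec$n_remote > 0) {
    for (i in seq_len(spec$n_remote)) {
      vals[idx, ] <- stats::rnorm(n)
      classes[idx] <- "causal_remote"
      idx <- idx + 1L
    }
  }
  dimnames(vals) <- list(gene_ids,
                         if (!is.null(names(target))) names(target)
                         else sprintf("s%04d", seq_len(n)))
  list(values = vals, classes = classes, edges = edges)
}

# Build the array-level design implied by a simulation_config.
build_design <- function(config) {
  n_s <- config$n_per_group_per_batch
  rows <- list()
  s <- 0L
  for (b in seq_len(config$n_batches)) {
    for (g in GROUP_LEVELS) {
      for (k in seq_len(n_s)) {
        s <- s + 1L
        sid <- sprintf("S%02d", s)
        rows[[length(rows) + 1L]] <- data.frame(
          array_id = paste0(sid, c("_F", "_R")),
          sample_id = sid, group = g, batch = paste0("B", b),
          dye = c("forward", "reverse"))
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a reference-design two-color microarray experiment
#'
#' Generates per-array log10 ratios versus the amplified reference pool
#' for the three-group, multi-batch dye-swap design, with planted
#' transplantation and regression effects, per-batch technical offsets,
#' per-gene dye bias, per-array Gaussian measurement noise, and a known
#' linear-Gaussian causal neighborhood of the binary regression indicator
#' (T = 1 for regression samples, 0 otherwise).
#'
#' Storage convention: forward arrays store sample/reference log ratios,
#' reverse arrays store reference/sample (so the biological signal enters
#' the reverse array with flipped sign), while the dye bias attaches to the
#' label and enters both orientations with the same sign.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list of class \code{"simulated_experiment"} with elements
#'   \code{measurements} (genes x arrays matrix), \code{design}
#'   (array-level design data frame), \code{truth} (data frame
#'   \code{gene}, \code{class}, \code{true_fc}), \code{causal_edges} and
#'   \code{config}.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  design <- build_design(config)
  sdesign <- sample_design(design)
  n_samples <- nrow(sdesign)
  n_genes <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  # gene class assignment in deterministic blocks
  cs <- config$causal_spec
  classes <- rep("null", n_genes)
  idx <- 1L
  take <- function(n) {
    if (n == 0) return(integer(0))
    out <- seq.int(idx, idx + n - 1L)
    idx <<- idx + n
    out
  }
  i_trans <- take(config$n_transplant_genes)
  i_up <- take(config$n_regression_up)
  i_down <- take(config$n_regression_down)
  i_causal <- take(n_causal_genes(cs))
  classes[i_trans] <- "transplant"
  classes[i_up] <- "regression_up"
  classes[i_down] <- "regression_down"

  eff <- config$effect_size_log10
  in_reg <- sdesign$group == "regression"
  in_transplanted <- sdesign$group %in% c("progression", "regression")

  # sample-level biological signal
  signal <- matrix(0, n_genes, n_samples,
                   dimnames = list(gene_ids, sdesign$sample_id))
  true_shift <- rep(0, n_genes)  # log10 shift of the affected condition
  if (length(i_trans)) {
    sign_t <- sample(c(-1, 1), length(i_trans), replace = TRUE)
    true_shift[i_trans] <- sign_t * eff
    signal[i_trans, in_transplanted] <- true_shift[i_trans]
  }
  if (length(i_up)) {
    true_shift[i_up] <- eff
    signal[i_up, in_reg] <- eff
  }
  if (length(i_down)) {
    true_shift[i_down] <- -eff
    signal[i_down, in_reg] <- -eff
  }
  causal_edges <- data.frame(from = character(0), to = character(0))
  if (length(i_causal)) {
    target <- as.numeric(in_reg)
    cn <- simulate_causal_neighborhood(cs, target,
                                       gene_ids = gene_ids[i_causal])
    signal[i_causal, ] <- cn$values * cs$signal_scale
    classes[i_causal] <- cn$classes
    causal_edges <- cn$edges
  }

  # per-gene per-batch technical offsets, shared within batch
  # (drawn as standard normals scaled afterwards so the RNG stream is
  # identical whichever sd is configured, including 0)
  batches <- unique(sdesign$batch)
  batch_off <- matrix(stats::rnorm(n_genes * length(batches)) *
                        config$batch_sd,
                      n_genes, length(batches),
                      dimnames = list(gene_ids, batches))
  sample_true <- signal + batch_off[, sdesign$batch, drop = FALSE]

  # arrays: forward stores sample/reference, reverse reference/sample;
  # dye bias d_g rides on the label, same sign in both orientations
  dye_bias <- stats::rnorm(n_genes) * config$dye_bias_sd
  meas <- matrix(0, n_genes, nrow(design),
                 dimnames = list(gene_ids, design$array_id))
  for (j in seq_len(nrow(design))) {
    x <- sample_true[, design$sample_id[j]]
    orient <- if (design$dye[j] == "forward") 1 else -1
    meas[, j] <- orient * x + dye_bias +
      stats::rnorm(n_genes, sd = config$noise_sd)
  }

  truth <- data.frame(gene = gene_ids, class = classes,
                      true_fc = ifelse(true_shift == 0, 1,
                                       sign(true_shift) *
                                         10^abs(true_shift)))
  structure(list(measurements = meas, design = design, truth = truth,
                 causal_edges = causal_edges, config = config),
            class = "simulated_experiment")
}

#' Simulate a pure-null experiment
#'
#' Identical generative process to \code{\link{simulate_experiment}} with
#' every planted effect and causal strength switched off: all genes are
#' class \code{"null"}. Technical structure (batch offsets, dye bias,
#' measurement noise) is retained, since it is removed by preprocessing
#' rather than by the statistics under test.
#'
#' @param config A \code{\link{simulation_config}}; its planted-class
#'   counts and effect size are ignored.
#' @return A \code{"simulated_experiment"} whose truth table marks every
#'   gene null.
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  null_config <- simulation_config(
    n_genes = config$n_genes,
    n_per_group_per_batch = config$n_per_group_per_batch,
    n_batches = config$n_batches,
    n_transplant_genes = 0L, n_regression_up = 0L, n_regression_down = 0L,
    effect_size_log10 = 0,
    batch_sd = config$batch_sd, noise_sd = config$noise_sd,
    dye_bias_sd = config$dye_bias_sd,
    causal_spec = causal_neighborhood_spec(
      n_direct = 0L, n_mediated = 0L, n_remote = 0L,
      direct_strength = config$causal_spec$direct_strength,
      mediation_strength = config$causal_spec$mediation_strength,
      signal_scale = config$causal_spec$signal_scale),
    seed = config$seed)
  simulate_experiment(null_config)
}

#' Write a simulated experiment to disk
#'
#' Writes the ratio matrix, array-level design and truth table as TSV
#' files round-trippable through \code{\link{read_ratio_matrix}},
#' \code{\link{read_design}} and \code{\link{read_truth}}.
#'
#' @param experiment A \code{"simulated_experiment"}.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "simulated_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "ratios.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_ratio_matrix(experiment$measurements, paths["matrix"])
  write_design(experiment$design, paths["design"])
  write_truth(experiment$truth, paths["truth"])
  paths
}
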