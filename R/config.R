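#' Pipeline configuration
#'
#' Collects every tuning constant of the analysis pipeline in one validated
#' list: the conditional-independence test level and conditioning bound used
#' by HITON-PC, the SVM soft-margin constant, the ANOVA / error-model /
#' fold-change thresholds of the differential-profile cascade, and the
#' permutation counts.
#'
#' @param alpha_ci Significance level of the Fisher's Z conditional
#'   independence test (default 0.05).
#' @param max_k Upper bound on the conditioning-set size in HITON-PC
#'   (default 1).
#' @param svm_C Soft-margin constant of the linear SVM (default 1).
#' @param p_regression ANOVA threshold for the progression-vs-regression
#'   comparison; genes with p below it count as regulated by regression
#'   (default 0.05).
#' @param p_transplant ANOVA exclusion threshold for the
#'   baseline-vs-progression comparison; genes with p at or below it are
#'   considered transplantation-regulated and removed (default 0.1).
#' @param p_error_model Threshold on the error-model p-value (default 0.05).
#' @param fc_threshold Linear-scale fold-change threshold, applied
#'   inclusively to the group-mean ratio (default 1.2).
#' @param n_fdp_permutations Number of label permutations used to estimate
#'   the proportion of false positives in the profile (default 100).
#' @param n_signature_permutations Number of label permutations used to
#'   assess signature significance (default 1000).
#' @param bonferroni_alpha Family-wise level for the enrichment correction
#'   (default 0.05).
#' @param permute_all_groups If TRUE (default) label permutations shuffle
#'   all three group labels; if FALSE only progression and regression labels
#'   are exchanged.
#' @param seed Integer seed from which all randomized steps derive.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(alpha_ci = 0.05,
                            max_k = 1L,
                            svm_C = 1,
                            p_regression = 0.05,
                            p_transplant = 0.1,
                            p_error_model = 0.05,
                            fc_threshold = 1.2,
                            n_fdp_permutations = 100L,
                            n_signature_permutations = 1000L,
                            bonferroni_alpha = 0.05,
                            permute_all_groups = TRUE,
                            seed = 1L) {
  probs <- c(alpha_ci = alpha_ci, p_regression = p_regression,
             p_transplant = p_transplant, p_error_model = p_error_model,
             bonferroni_alpha = bonferroni_alpha)
  bad <- probs <= 0 | probs >= 1
  if (any(bad)) {
    stop("probability thresholds must lie strictly in (0, 1): ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  if (max_k < 0) stop("max_k must be >= 0")
  if (svm_C <= 0) stop("svm_C must be positive")
  counts <- c(n_fdp_permutations = n_fdp_permutations,
              n_signature_permutations = n_signature_permutations)
  if (any(counts < 1)) {
    stop("permutation counts must be >= 1: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  structure(list(
    alpha_ci = alpha_ci, max_k = as.integer(max_k), svm_C = svm_C,
    p_regression = p_regression, p_transplant = p_transplant,
    p_error_model = p_error_model, fc_threshold = fc_threshold,
    n_fdp_permutations = as.integer(n_fdp_permutations),
    n_signature_permutations = as.integer(n_signature_permutations),
    bonferroni_alpha = bonferroni_alpha,
    permute_all_groups = isTRUE(permute_all_groups),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Causal-neighborhood specification for the simulator
#'
#' Describes the planted linear-Gaussian neighborhood of the binary
#' regression indicator T: \code{n_direct} genes receive a direct edge from
#' T, \code{n_mediated} genes are connected to T only through one direct
#' gene, and \code{n_remote} genes are independent of T. Strengths are path
#' coefficients on standardized variables, so \code{direct_strength} is the
#' (population) correlation between a direct gene and standardized T, and
#' \code{direct_strength * mediation_strength} the correlation between a
#' mediated gene and T.
#'
#' Defaults are sized for the reference two-batch design with 24 samples
#' by a power analysis of the conditional tests. At n = 24 a Fisher's Z
#' test at alpha = 0.05 only detects correlations above roughly 0.4.
#' More importantly, two direct children of a binary target with strength
#' a are mutually correlated a^2, and the partial correlation of either
#' with the target given the other saturates at a / sqrt(1 + a^2) <=
#' 0.707 -- at 24 samples each such sibling test then carries a >= 2
#' percent chance of a false independence verdict, so several strong
#' direct neighbors cannot be jointly recovered reliably at this design
#' size. The default neighborhood therefore plants a single strong direct
#' neighbor (strength 0.95) for end-to-end recovery checks; multi-neighbor
#' recovery is a large-sample property and is exercised at n of order
#' 1000 in dedicated analyses.
#'
#' @param n_direct Number of direct neighbors of T (default 1).
#' @param n_mediated Number of mediated genes (default 2).
#' @param n_remote Number of remote genes independent of T (default 4).
#' @param direct_strength Path coefficient T -> direct gene, in (0, 1)
#'   (default 0.95).
#' @param mediation_strength Path coefficient direct -> mediated gene, in
#'   (0, 1) (default 0.7).
#' @param signal_scale Standard deviation, on the log10-ratio scale, given
#'   to causal-gene expression values (default 0.5).
#' @return A list of class \code{"causal_neighborhood_spec"}.
#' @export
causal_neighborhood_spec <- function(n_direct = 1L,
                                     n_mediated = 2L,
                                     n_remote = 4L,
                                     direct_strength = 0.95,
                                     mediation_strength = 0.7,
                                     signal_scale = 0.5) {
  counts <- c(n_direct = n_direct, n_mediated = n_mediated,
              n_remote = n_remote)
  if (any(counts < 0)) stop("causal gene counts must be >= 0")
  if (n_mediated > 0 && n_direct == 0) {
    stop("mediated genes require at least one direct gene")
  }
  for (s in c(direct_strength = direct_strength,
              mediation_strength = mediation_strength)) {
    if (s <= 0 || s >= 1) stop("strengths must lie strictly in (0, 1)")
  }
  if (signal_scale <= 0) stop("signal_scale must be positive")
  spec <- structure(list(
    n_direct = as.integer(n_direct), n_mediated = as.integer(n_mediated),
    n_remote = as.integer(n_remote), direct_strength = direct_strength,
    mediation_strength = mediation_strength, signal_scale = signal_scale
  ), class = "causal_neighborhood_spec")
  # construction-time positive-definiteness check of the implied
  # covariance over (T*, direct, mediated, remote)
  cov <- causal_covariance(spec)
  tryCatch(chol(cov), error = function(e) {
    stop("implied causal covariance matrix is not positive definite")
  })
  spec
}

n_causal_genes <- function(spec) {
  spec$n_direct + spec$n_mediated + spec$n_remote
}

# Population covariance over (T_std, directs, mediateds, remotes) implied
# by the structural model; used only for the positive-definiteness check.
causal_covariance <- function(spec) {
  p <- 1L + n_causal_genes(spec)
  a <- spec$direct_strength
  b <- spec$mediation_strength
  idx_t <- 1L
  idx_d <- seq_len(spec$n_direct) + 1L
  idx_m <- seq_len(spec$n_mediated) + 1L + spec$n_direct
  idx_r <- seq_len(spec$n_remote) + 1L + spec$n_direct + spec$n_mediated
  cov <- diag(p)
  for (i in idx_d) {
    cov[idx_t, i] <- cov[i, idx_t] <- a
    for (j in idx_d) if (i != j) cov[i, j] <- a * a
  }
  if (spec$n_mediated > 0) {
    parent_of <- rep(idx_d, length.out = spec$n_mediated)
    for (mi in seq_len(spec$n_mediated)) {
      m <- idx_m[mi]
      pa <- parent_of[mi]
      cov[m, idx_t] <- cov[idx_t, m] <- a * b
      for (j in idx_d) {
        cov[m, j] <- cov[j, m] <- if (j == pa) b else b * a * a
      }
      for (mj in seq_len(spec$n_mediated)) {
        if (mj != mi) {
          m2 <- idx_m[mj]
          r <- if (parent_of[mj] == pa) b * b else b * b * a * a
          cov[m, m2] <- cov[m2, m] <- r
        }
      }
    }
  }
  cov
}

#' Simulation configuration
#'
#' Parameters of the synthetic reference-design experiment: three groups
#' (baseline, progression, regression) times \code{n_batches} batches with
#' \code{n_per_group_per_batch} samples per cell, each sample measured on a
#' fluoro-forward and a fluoro-reverse array. Genes are partitioned into
#' null genes, transplantation-affected genes (shifted in both transplanted
#' groups relative to baseline), regression-regulated genes (shifted only
#' in the regression group, up or down), and the causal neighborhood of
#' \code{\link{causal_neighborhood_spec}}.
#'
#' @param n_genes Total number of reporters (default 2000).
#' @param n_per_group_per_batch Samples per group per batch (default 4).
#' @param n_batches Number of processing batches (default 2).
#' @param n_transplant_genes Genes shifted by the transplantation procedure
#'   (default 100).
#' @param n_regression_up,n_regression_down Genes shifted up / down only in
#'   the regression group (defaults 50 and 50).
#' @param effect_size_log10 Log10-ratio shift planted in affected genes
#'   (default log10(1.5)).
#' @param batch_sd SD of the per-gene, per-batch technical offset shared by
#'   all samples of a batch (default 0.2).
#' @param noise_sd SD of the per-array measurement noise on the log10 scale
#'   (default 0.1); must be positive.
#' @param dye_bias_sd SD of the per-gene dye bias attached to the Cy5
#'   channel (default 0.05).
#' @param causal_spec A \code{\link{causal_neighborhood_spec}}.
#' @param seed Integer seed.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_per_group_per_batch = 4L,
                              n_batches = 2L,
                              n_transplant_genes = 100L,
                              n_regression_up = 50L,
                              n_regression_down = 50L,
                              effect_size_log10 = log10(1.5),
                              batch_sd = 0.2,
                              noise_sd = 0.1,
                              dye_bias_sd = 0.05,
                              causal_spec = causal_neighborhood_spec(),
                              seed = 1L) {
  counts <- c(n_genes = n_genes,
              n_per_group_per_batch = n_per_group_per_batch,
              n_batches = n_batches,
              n_transplant_genes = n_transplant_genes,
              n_regression_up = n_regression_up,
              n_regression_down = n_regression_down)
  if (any(counts < 0)) {
    stop("counts must be >= 0: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (n_per_group_per_batch < 1 || n_batches < 1 || n_genes < 1) {
    stop("n_genes, n_per_group_per_batch and n_batches must be >= 1")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (batch_sd < 0 || dye_bias_sd < 0) {
    stop("batch_sd and dye_bias_sd must be non-negative")
  }
  if (effect_size_log10 < 0) stop("effect_size_log10 must be non-negative")
  stopifnot(inherits(causal_spec, "causal_neighborhood_spec"))
  planted <- n_transplant_genes + n_regression_up + n_regression_down +
    n_causal_genes(causal_spec)
  if (planted > n_genes) {
    stop("planted gene classes (", planted, ") exceed n_genes (",
         n_genes, ")")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_per_group_per_batch = as.integer(n_per_group_per_batch),
    n_batches = as.integer(n_batches),
    n_transplant_genes = as.integer(n_transplant_genes),
    n_regression_up = as.integer(n_regression_up),
    n_regression_down = as.integer(n_regression_down),
    effect_size_log10 = effect_size_log10,
    batch_sd = batch_sd, noise_sd = noise_sd, dye_bias_sd = dye_bias_sd,
    causal_spec = causal_spec, seed = as.integer(seed)
  ), class = "simulation_config")
}
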