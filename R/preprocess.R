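#' Combine fluoro-reverse duplicate arrays into per-sample ratios
#'
#' Each sample was hybridized twice with swapped Cy3/Cy5 assignment.
#' Forward arrays store sample/reference log10 ratios and reverse arrays
#' reference/sample, so the reverse array is sign-flipped on the log scale
#' before averaging:
#' \code{combined = (forward + (-reverse)) / 2}. Gene-specific dye bias,
#' which enters both orientations with the same sign, cancels exactly.
#'
#' @param measurements Genes x arrays numeric matrix of per-array log10
#'   ratios, columns named by array id.
#' @param design Array-level design data frame (see
#'   \code{\link{read_design}}).
#' @return Genes x samples matrix of combined log10 ratios, one column per
#'   sample in design order.
#' @export
combine_dye_swap <- function(measurements, design) {
  check_expression_matrix(measurements, "measurements")
  sdesign <- sample_design(design)
  out <- matrix(NA_real_, nrow(measurements), nrow(sdesign),
                dimnames = list(rownames(measurements), sdesign$sample_id))
  for (i in seq_len(nrow(sdesign))) {
    s <- sdesign$sample_id[i]
    rows <- design[design$sample_id == s, ]
    fwd <- rows$array_id[rows$dye == "forward"]
    rev <- rows$array_id[rows$dye == "reverse"]
    if (length(fwd) != 1 || length(rev) != 1) {
      stop("sample ", s, " must have exactly one forward and one reverse ",
           "array")
    }
    missing <- setdiff(c(fwd, rev), colnames(measurements))
    if (length(missing)) {
      stop("array(s) missing from measurements for sample ", s, ": ",
           paste(missing, collapse = ", "))
    }
    out[, i] <- (measurements[, fwd] - measurements[, rev]) / 2
  }
  out
}

#' Re-ratio each sample against the pool of its batch
#'
#' Normalizes batch-to-batch variation by re-expressing each sample
#' relative to the pooled behavior of its batch: for every gene, the
#' arithmetic mean across all samples of a batch is subtracted, so the
#' per-gene per-batch mean of the output is exactly zero. The operation is
#' idempotent.
#'
#' @param mat Genes x samples matrix of combined log10 ratios.
#' @param design Array- or sample-level design.
#' @return Matrix of the same shape, batch-centered per gene.
#' @export
reratio_by_batch <- function(mat, design) {
  check_expression_matrix(mat)
  sdesign <- sample_design(design)
  sdesign <- sdesign[match(colnames(mat), sdesign$sample_id), ]
  if (anyNA(sdesign$sample_id)) {
    stop("matrix columns missing from design: ",
         paste(setdiff(colnames(mat), sdesign$sample_id), collapse = ", "))
  }
  out <- mat
  for (b in unique(sdesign$batch)) {
    cols <- which(sdesign$batch == b)
    if (length(cols) < 2) {
      stop("batch ", b, " has fewer than 2 samples; cannot re-ratio")
    }
    out[, cols] <- mat[, cols] - rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

#' Surrogate error-model p-value
#'
#' A stand-in for a per-gene measurement-error model: it asks whether a
#' gene's signal in the contrast groups exceeds what its replicate scatter
#' supports. After dye-swap combination and per-batch re-ratio, the
#' statistic is the mean of the batch-centered ratios over the contrast
#' samples, divided by a moderated standard error. The per-gene residual
#' variance (within group-by-batch cells) is shrunk halfway toward the
#' genome-wide median, and the variance of the contrast mean uses the
#' exact linear weights induced by batch centering, so the test is
#' approximately calibrated under the null by construction. Its contract
#' is: p in [0, 1], approximate null calibration, monotone in
#' signal-to-noise.
#'
#' @param measurements Genes x arrays matrix of per-array log10 ratios.
#' @param design Array-level design.
#' @param contrast_groups Groups whose signal is tested (default
#'   progression and regression, the groups compared by the profile
#'   cascade).
#' @return A data frame of class \code{"error_model_result"} with columns
#'   \code{gene} and \code{p}.
#' @export
error_model_surrogate <- function(measurements, design,
                                  contrast_groups = c("progression",
                                                      "regression")) {
  combined <- combine_dye_swap(measurements, design)
  centered <- reratio_by_batch(combined, design)
  error_model_from_matrix(centered, sample_design(design), contrast_groups)
}

# Core of the surrogate, operating on a batch-centered genes x samples
# matrix. Exposed internally so label permutations can recompute it
# without redoing the dye-swap combination.
error_model_from_matrix <- function(mat, sdesign,
                                    contrast_groups = c("progression",
                                                        "regression")) {
  sdesign <- sdesign[match(colnames(mat), sdesign$sample_id), ]
  in_contrast <- sdesign$group %in% contrast_groups
  if (sum(in_contrast) < 2) {
    stop("need >= 2 samples in the contrast groups")
  }
  n <- ncol(mat)
  n_c <- sum(in_contrast)

  # linear weights of the contrast mean on the *uncentered* data:
  # w_j = (1/n_c) (1[j in C] - n_{C,b(j)} / n_{b(j)})
  w <- numeric(n)
  for (b in unique(sdesign$batch)) {
    in_b <- sdesign$batch == b
    ncb <- sum(in_b & in_contrast)
    w[in_b] <- (as.numeric(in_contrast[in_b]) - ncb / sum(in_b)) / n_c
  }
  c_design <- sum(w^2)

  m <- rowMeans(mat[, in_contrast, drop = FALSE])

  # residual variance within group x batch cells
  cell <- interaction(sdesign$group, sdesign$batch, drop = TRUE)
  df <- n - nlevels(cell)
  resid_ss <- rep(0, nrow(mat))
  for (lv in levels(cell)) {
    cols <- which(cell == lv)
    block <- mat[, cols, drop = FALSE]
    resid_ss <- resid_ss + rowSums((block - rowMeans(block))^2)
  }
  if (df <= 0) stop("not enough replication to estimate residual variance")
  s2 <- resid_ss / df
  s2_0 <- stats::median(s2)
  s2_mod <- (s2 + s2_0) / 2
  if (all(s2_mod == 0)) {
    warning("zero pooled variance; error-model p set to 1 for all genes")
    p <- rep(1, nrow(mat))
  } else {
    se <- sqrt(s2_mod * c_design)
    t_stat <- ifelse(se == 0, 0, m / se)
    zero_var <- s2_mod == 0
    if (any(zero_var & m != 0)) {
      warning(sum(zero_var & m != 0),
              " gene(s) with zero pooled variance; p set to 1")
    }
    p <- 2 * stats::pt(-abs(t_stat), df = df)
    p[zero_var] <- 1
  }
  structure(data.frame(gene = rownames(mat), p = p,
                       row.names = NULL),
            class = c("error_model_result", "data.frame"))
}
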