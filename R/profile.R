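#' Per-gene two-group one-way ANOVA p-values
#'
#' One-way ANOVA F-test across two groups, computed row-wise; with two
#' groups it is algebraically identical to the two-sided equal-variance
#' t-test. Degenerate rows are handled explicitly: zero between-group
#' difference with zero within-group variance gives p = 1; a nonzero
#' difference with zero within-group variance gives the smallest
#' representable p (1e-300), keeping downstream log-scale displays finite.
#'
#' @param mat Genes x samples matrix.
#' @param design Array- or sample-level design.
#' @param group_a,group_b Group labels to compare.
#' @return Named vector of p-values, one per gene.
#' @export
anova_p <- function(mat, design, group_a, group_b) {
  check_expression_matrix(mat)
  sdesign <- sample_design(design)
  ids_a <- group_columns(mat, sdesign, group_a)
  ids_b <- group_columns(mat, sdesign, group_b)
  n1 <- length(ids_a); n2 <- length(ids_b)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 samples")
  xa <- mat[, ids_a, drop = FALSE]
  xb <- mat[, ids_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssw <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  n <- n1 + n2
  grand <- (n1 * ma + n2 * mb) / n
  ssb <- n1 * (ma - grand)^2 + n2 * (mb - grand)^2
  df2 <- n - 2
  msw <- ssw / df2
  p <- ifelse(msw > 0,
              stats::pf(ssb / msw, 1, df2, lower.tail = FALSE),
              ifelse(ssb > 0, 1e-300, 1))
  names(p) <- rownames(mat)
  p
}

#' Per-gene signed fold changes between two groups
#'
#' For each gene, \code{d = mean log10 ratio in group_b - mean in group_a};
#' the reported fold change is \code{10^|d|} carrying the sign of
#' \code{d} (with \code{d = 0} mapping to +1). The threshold test used by
#' the cascade compares on the log scale, \code{|d| >= log10(threshold)},
#' so a gene sitting exactly on the threshold passes.
#'
#' @inheritParams anova_p
#' @return Named vector of signed linear-scale fold changes.
#' @export
fold_change <- function(mat, design, group_a, group_b) {
  check_expression_matrix(mat)
  sdesign <- sample_design(design)
  ids_a <- group_columns(mat, sdesign, group_a)
  ids_b <- group_columns(mat, sdesign, group_b)
  if (!length(ids_a) || !length(ids_b)) stop("groups must be non-empty")
  d <- rowMeans(mat[, ids_b, drop = FALSE]) -
    rowMeans(mat[, ids_a, drop = FALSE])
  fc <- ifelse(d < 0, -1, 1) * 10^abs(d)
  names(fc) <- rownames(mat)
  fc
}

#' Build the plaque-regression differential profile
#'
#' Applies the conjunctive filter cascade, in order: (1) remove genes
#' regulated by the transplantation procedure
#' (baseline-vs-progression ANOVA p <= \code{p_transplant}); (2) keep genes
#' regulated by regression (progression-vs-regression ANOVA
#' p < \code{p_regression}) — the count surviving (1)+(2) is recorded as
#' \code{n_after_anova}; (3) keep genes whose error-model p-value is below
#' \code{p_error_model}; (4) keep genes whose progression-to-regression
#' group-mean fold change reaches \code{fc_threshold} (inclusive).
#' Surviving genes are split into up- and down-regulated clusters by
#' K-means (K = 2).
#'
#' The filters are conjunctive, so the order does not change membership,
#' only the intermediate counts reported.
#'
#' @param mat Batch-centered genes x samples matrix.
#' @param design Array- or sample-level design containing all three groups.
#' @param error_p An \code{"error_model_result"} (or named vector of
#'   per-gene p-values).
#' @param config A \code{\link{pipeline_config}}.
#' @return A list of class \code{"differential_profile"}: \code{table}
#'   (data frame with columns \code{gene}, \code{p_regression},
#'   \code{p_transplant}, \code{p_error}, \code{fold_change},
#'   \code{cluster}), \code{n_after_anova}, \code{n_final},
#'   \code{fdp_estimate} (NA until \code{\link{estimate_fdp}} is run) and
#'   a config echo.
#' @export
build_profile <- function(mat, design, error_p, config = pipeline_config()) {
  check_expression_matrix(mat)
  sdesign <- sample_design(design)
  missing_groups <- setdiff(GROUP_LEVELS, unique(sdesign$group))
  if (length(missing_groups)) {
    stop("design is missing group(s): ",
         paste(missing_groups, collapse = ", "))
  }
  if (inherits(error_p, "error_model_result") || is.data.frame(error_p)) {
    ep <- stats::setNames(error_p$p, error_p$gene)
  } else {
    ep <- error_p
  }
  if (!all(rownames(mat) %in% names(ep))) {
    stop("error_p is missing genes present in the matrix")
  }
  ep <- ep[rownames(mat)]

  p_trans <- anova_p(mat, sdesign, "baseline", "progression")
  p_reg <- anova_p(mat, sdesign, "progression", "regression")
  fc <- fold_change(mat, sdesign, "progression", "regression")
  log_fc <- abs(log10(abs(fc)))

  keep1 <- p_trans > config$p_transplant
  keep2 <- keep1 & p_reg < config$p_regression
  n_after_anova <- sum(keep2)
  keep3 <- keep2 & ep < config$p_error_model
  keep4 <- keep3 & log_fc >= log10(config$fc_threshold)
  members <- rownames(mat)[keep4]

  cluster <- rep(NA_character_, length(members))
  if (length(members) >= 2) {
    cluster <- split_up_down_kmeans(mat, sdesign, members, config)
  } else if (length(members) == 1) {
    warning("single-gene profile; cluster assigned by fold-change sign")
    cluster <- if (fc[members] >= 0) "up" else "down"
  }
  tab <- data.frame(gene = members,
                    p_regression = unname(p_reg[members]),
                    p_transplant = unname(p_trans[members]),
                    p_error = unname(ep[members]),
                    fold_change = unname(fc[members]),
                    cluster = unname(cluster),
                    row.names = NULL)
  structure(list(table = tab, n_after_anova = n_after_anova,
                 n_final = length(members), fdp_estimate = NA_real_,
                 config = config),
            class = "differential_profile")
}

#' @export
print.differential_profile <- function(x, ...) {
  cat("Differential profile\n")
  cat("  genes passing ANOVA criteria: ", x$n_after_anova, "\n", sep = "")
  cat("  final profile size:           ", x$n_final, "\n", sep = "")
  if (x$n_final > 0) {
    cat("  up / down:                    ",
        sum(x$table$cluster == "up", na.rm = TRUE), " / ",
        sum(x$table$cluster == "down", na.rm = TRUE), "\n", sep = "")
  }
  cat("  estimated false-positive proportion: ",
      ifelse(is.na(x$fdp_estimate), "not computed",
             format(x$fdp_estimate, digits = 3)), "\n", sep = "")
  invisible(x)
}

#' Split profile members into up- and down-regulated clusters
#'
#' K-means with K = 2 on each member gene's vector of per-sample
#' batch-centered log10 ratios over the progression and regression
#' samples. The cluster whose centroid shows the larger mean over
#' regression samples minus mean over progression samples is labeled
#' \code{"up"}. Deterministic given \code{config$seed}; 10 restarts, the
#' solution with the best within-cluster sum of squares kept. If the
#' member vectors admit fewer than two distinct points, all members
#' receive the label given by the sign of their common
#' regression-minus-progression delta.
#'
#' @param mat Batch-centered genes x samples matrix.
#' @param design Array- or sample-level design.
#' @param members Character vector of member genes (>= 2 for a real
#'   split).
#' @param config A \code{\link{pipeline_config}}.
#' @return Named character vector (\code{"up"}/\code{"down"}) over
#'   \code{members}.
#' @export
split_up_down_kmeans <- function(mat, design, members,
                                 config = pipeline_config()) {
  sdesign <- sample_design(design)
  if (length(members) < 2) {
    warning("fewer than 2 members; no K-means split performed")
    return(stats::setNames(rep(NA_character_, length(members)), members))
  }
  ids_p <- samples_in_groups(sdesign, "progression")
  ids_r <- samples_in_groups(sdesign, "regression")
  feats <- mat[members, c(ids_p, ids_r), drop = FALSE]
  delta <- rowMeans(mat[members, ids_r, drop = FALSE]) -
    rowMeans(mat[members, ids_p, drop = FALSE])
  n_distinct <- nrow(unique(feats))
  if (n_distinct < 2) {
    lab <- ifelse(delta >= 0, "up", "down")
    return(stats::setNames(lab, members))
  }
  set.seed(derive_seed(config$seed, 104729L))
  km <- stats::kmeans(feats, centers = 2, nstart = 10)
  cent_delta <- rowMeans(km$centers[, seq_along(ids_r) + length(ids_p),
                                    drop = FALSE]) -
    rowMeans(km$centers[, seq_along(ids_p), drop = FALSE])
  up_cluster <- which.max(cent_delta)  # ties: first cluster is "up"
  lab <- ifelse(km$cluster == up_cluster, "up", "down")
  stats::setNames(lab, members)
}

#' Estimate the proportion of false positives by label permutation
#'
#' Group labels are permuted (within batch, preserving the normalization
#' geometry of the per-batch re-ratio) prior to any gene filtering; the
#' entire cascade — including recomputation of the label-dependent
#' error-model surrogate — is re-run on each permuted labeling and the
#' profile size recorded. The estimate is the mean permuted size divided
#' by the observed size, clipped to [0, 1].
#'
#' @param mat Batch-centered genes x samples matrix.
#' @param design Array- or sample-level design.
#' @param config A \code{\link{pipeline_config}}; uses
#'   \code{n_fdp_permutations}, \code{permute_all_groups} and \code{seed}.
#' @return A list of class \code{"fdp_estimate"}: \code{fdp_estimate}
#'   (NA with a warning if the observed size is zero),
#'   \code{observed_size}, \code{permuted_sizes},
#'   \code{mean_permuted_size}.
#' @export
estimate_fdp <- function(mat, design, config = pipeline_config()) {
  check_expression_matrix(mat)
  sdesign <- sample_design(design)
  sdesign <- sdesign[match(colnames(mat), sdesign$sample_id), ]
  observed <- profile_size(mat, sdesign, config)
  B <- config$n_fdp_permutations
  set.seed(derive_seed(config$seed, 7919L))
  sizes <- integer(B)
  for (b in seq_len(B)) {
    perm <- sdesign
    perm$group <- permute_groups(sdesign, config$permute_all_groups)
    sizes[b] <- profile_size(mat, perm, config)
  }
  mean_size <- mean(sizes)
  if (observed == 0) {
    warning("observed profile is empty; FDP estimate undefined")
    fdp <- NA_real_
  } else {
    fdp <- min(1, max(0, mean_size / observed))
  }
  structure(list(fdp_estimate = fdp, observed_size = observed,
                 permuted_sizes = sizes, mean_permuted_size = mean_size),
            class = "fdp_estimate")
}

# Permute group labels within each batch. With permute_all_groups = FALSE
# only progression/regression labels are exchanged.
permute_groups <- function(sdesign, all_groups = TRUE) {
  g <- sdesign$group
  for (b in unique(sdesign$batch)) {
    idx <- which(sdesign$batch == b)
    if (all_groups) {
      g[idx] <- sample(g[idx])
    } else {
      pr <- idx[g[idx] %in% c("progression", "regression")]
      g[pr] <- sample(g[pr])
    }
  }
  g
}

# Size of the cascade-surviving profile under a given labeling, without
# the K-means split. Mirrors build_profile's membership rule exactly.
profile_size <- function(mat, sdesign, config) {
  ep <- error_model_from_matrix(mat, sdesign)$p
  p_trans <- anova_p(mat, sdesign, "baseline", "progression")
  p_reg <- anova_p(mat, sdesign, "progression", "regression")
  fc <- fold_change(mat, sdesign, "progression", "regression")
  sum(p_trans > config$p_transplant &
        p_reg < config$p_regression &
        ep < config$p_error_model &
        abs(log10(abs(fc))) >= log10(config$fc_threshold))
}
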