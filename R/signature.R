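#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a uniformly random positive-negative pair is ordered
#' correctly by the decision values, counting ties as 1/2; computed from
#' rank sums.
#'
#' @param decisions Numeric vector of decision values (larger = more
#'   positive).
#' @param labels Binary 0/1 vector of true classes.
#' @return AUC in [0, 1].
#' @export
auc <- function(decisions, labels) {
  if (length(decisions) != length(labels)) {
    stop("decisions and labels must have the same length")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("labels must contain both classes")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(decisions)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Linear SVM decision values oriented so that larger favors class "1".
# The decision value is computed directly from the support-vector
# expansion, f(x) = x w' - rho with w = coefs' SV; equality with
# predict(..., decision.values = TRUE) is asserted in the test suite.
svm_decision <- function(train_x, train_y, test_x, C) {
  fit <- e1071::svm(x = train_x, y = factor(train_y, levels = c(0, 1)),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)
  d <- as.numeric(test_x %*% t(w)) - fit$rho
  # libsvm orients the decision value toward the class it saw first
  if (fit$levels[fit$labels[1]] != "1") d <- -d
  d
}

#' LOOCV evaluation of a molecular signature
#'
#' Leave-one-out cross-validation of a linear soft-margin SVM
#' (\code{C = config$svm_C}): for each sample, the classifier is trained
#' on all other samples restricted to the signature genes, features are
#' standardized with training-fold statistics only, and the held-out
#' signed decision value is recorded. The pooled AUC over the held-out
#' decision values estimates predictive accuracy.
#'
#' In \code{"nested_selection"} mode, gene selection
#' (\code{\link{hiton_pc}}) is re-run inside every training fold and the
#' fold's own selected genes are used; a fold whose selection is empty
#' contributes an uninformative decision value of 0. In
#' \code{"fixed_genes"} mode the supplied gene list is used in every fold.
#'
#' @param mat Genes x samples matrix.
#' @param target Binary 0/1 vector over samples.
#' @param genes Character vector of signature genes (required in
#'   \code{fixed_genes} mode).
#' @param config A \code{\link{pipeline_config}}.
#' @param mode \code{"fixed_genes"} or \code{"nested_selection"}.
#' @return A list of class \code{"signature_evaluation"}: \code{genes},
#'   \code{decisions} (one held-out value per sample), \code{labels},
#'   \code{auc}, \code{mode}, \code{fold_genes} (per-fold selections in
#'   nested mode), \code{p_value} (NA until
#'   \code{\link{permutation_significance}}), \code{n_permutations}.
#' @export
loocv_auc <- function(mat, target, genes = NULL,
                      config = pipeline_config(),
                      mode = c("fixed_genes", "nested_selection")) {
  mode <- match.arg(mode)
  check_expression_matrix(mat)
  n <- ncol(mat)
  if (length(target) != n) stop("target length must match sample count")
  if (!all(target %in% c(0, 1)) || min(table(target)) < 2) {
    stop("need >= 2 samples per class")
  }
  if (mode == "fixed_genes") {
    if (is.null(genes) || !length(genes)) {
      stop("fixed_genes mode requires a non-empty gene list")
    }
    missing <- setdiff(genes, rownames(mat))
    if (length(missing)) {
      stop("signature gene(s) missing from matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  decisions <- numeric(n)
  fold_genes <- vector("list", n)
  X_all <- if (mode == "fixed_genes") t(mat[genes, , drop = FALSE])
  for (i in seq_len(n)) {
    tr_idx <- seq_len(n)[-i]
    y_tr <- target[tr_idx]
    if (length(unique(y_tr)) < 2) stop("training fold has a single class")
    if (mode == "fixed_genes") {
      g <- genes
      x_tr <- X_all[tr_idx, , drop = FALSE]
      x_te <- X_all[i, , drop = FALSE]
    } else {
      g <- hiton_pc(mat[, tr_idx, drop = FALSE], y_tr, config,
                    trace = FALSE)$members
      if (length(g)) {
        x_tr <- t(mat[g, tr_idx, drop = FALSE])
        x_te <- t(mat[g, i, drop = FALSE])
      }
    }
    fold_genes[[i]] <- g
    if (!length(g)) {
      decisions[i] <- 0
      next
    }
    # standardize with training-fold statistics only
    ntr <- nrow(x_tr)
    mu <- colMeans(x_tr)
    sd_tr <- sqrt((colSums(x_tr^2) - ntr * mu^2) / (ntr - 1))
    sd_tr[sd_tr <= 0 | !is.finite(sd_tr)] <- 1
    x_tr <- (x_tr - rep(mu, each = ntr)) / rep(sd_tr, each = ntr)
    x_te <- (x_te - rep(mu, each = 1)) / rep(sd_tr, each = 1)
    decisions[i] <- svm_decision(x_tr, y_tr, x_te, config$svm_C)
  }
  names(decisions) <- colnames(mat)
  structure(list(genes = genes, decisions = decisions, labels = target,
                 auc = auc(decisions, target), mode = mode,
                 fold_genes = if (mode == "nested_selection") fold_genes,
                 p_value = NA_real_, n_permutations = NA_integer_),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat("Signature evaluation (", x$mode, ", LOOCV over ",
      length(x$decisions), " samples)\n", sep = "")
  if (!is.null(x$genes)) {
    cat("  genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  }
  cat("  AUC: ", format(x$auc, digits = 3), "\n", sep = "")
  if (!is.na(x$p_value)) {
    cat("  permutation p: ", format(x$p_value, digits = 3), " (B = ",
        x$n_permutations, ")\n", sep = "")
  }
  invisible(x)
}

#' Permutation significance of a multivariate signature
#'
#' Computes the observed LOOCV AUC of the full procedure (gene selection
#' plus classification, in the configured mode), then repeats the entire
#' procedure on label-permuted data B times. The add-one permutation
#' p-value is
#' \code{p = (1 + #\{AUC_perm >= AUC_obs\}) / (1 + B)}, which is always
#' at least \code{1 / (B + 1)}. A permutation whose folds cannot be
#' evaluated contributes an uninformative AUC of 0.5 (with a warning).
#'
#' @inheritParams loocv_auc
#' @param B Number of permutations (default
#'   \code{config$n_signature_permutations}).
#' @return A \code{"signature_evaluation"} carrying \code{p_value},
#'   \code{n_permutations} and \code{perm_aucs}.
#' @export
permutation_significance <- function(mat, target, genes = NULL,
                                     config = pipeline_config(),
                                     mode = c("nested_selection",
                                              "fixed_genes"),
                                     B = config$n_signature_permutations) {
  mode <- match.arg(mode)
  if (B < 19) stop("need at least 19 permutations")
  observed <- loocv_auc(mat, target, genes = genes, config = config,
                        mode = mode)
  set.seed(derive_seed(config$seed, 15485863L))
  perm_aucs <- numeric(B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    t_perm <- sample(target)
    perm_aucs[b] <- tryCatch(
      loocv_auc(mat, t_perm, genes = genes, config = config,
                mode = mode)$auc,
      error = function(e) {
        n_failed <<- n_failed + 1L
        0.5
      })
  }
  if (n_failed > 0) {
    warning(n_failed, " permutation(s) were un-evaluable; AUC set to 0.5")
  }
  p <- (1 + sum(perm_aucs >= observed$auc)) / (1 + B)
  observed$p_value <- p
  observed$n_permutations <- as.integer(B)
  observed$perm_aucs <- perm_aucs
  observed
}
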