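#' Partial correlation
#'
#' Pearson correlation of \code{x} and \code{y} given a conditioning set
#' \code{Z}. With an empty set this is the plain Pearson correlation; with
#' one conditioning variable the closed form
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' is used; for larger sets the correlation of least-squares residuals
#' after projecting out \code{Z} (with intercept) is returned, which
#' coincides with the closed form when |Z| = 1.
#'
#' @param x,y Numeric vectors of equal length n.
#' @param Z NULL, a numeric vector, a list of numeric vectors, or an
#'   n x k matrix of conditioning variables.
#' @return The partial correlation, a number in [-1, 1].
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  if (is.list(Z)) Z <- if (length(Z)) do.call(cbind, Z) else NULL
  if (!is.null(Z)) Z <- as.matrix(Z)
  n <- length(x)
  if (length(y) != n || (!is.null(Z) && nrow(Z) != n)) {
    stop("all vectors must have the same length")
  }
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n < k + 3) stop("insufficient sample for conditioning size")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 ||
      (k > 0 && any(apply(Z, 2, stats::sd) == 0))) {
    stop("degenerate variable (zero variance)")
  }
  if (k == 0) return(stats::cor(x, y))
  if (k == 1) {
    z <- Z[, 1]
    r_xy <- stats::cor(x, y)
    r_xz <- stats::cor(x, z)
    r_yz <- stats::cor(y, z)
    if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
      stop("collinear conditioning")
    }
    return((r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)))
  }
  D <- cbind(1, Z)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) stop("collinear conditioning")
  rx <- stats::resid(stats::lm.fit(D, x))
  ry <- stats::resid(stats::lm.fit(D, y))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("collinear conditioning")
  }
  stats::cor(rx, ry)
}

#' Fisher's Z conditional-independence test
#'
#' Maps a (partial) correlation to
#' \code{z = atanh(r) * sqrt(n - k - 3)} and compares it to a standard
#' normal, two-sided. The pair is declared independent exactly when
#' \code{p > alpha}; a p-value equal to alpha counts as dependent.
#' A correlation of magnitude 1 yields an infinite z and p = 0.
#'
#' @param r (Partial) correlation in [-1, 1].
#' @param n Sample size.
#' @param k Size of the conditioning set.
#' @param alpha Test level (default 0.05).
#' @return A one-row data frame: \code{r}, \code{z}, \code{p},
#'   \code{decision} (\code{"dependent"} or \code{"independent"}).
#' @export
fisher_z_test <- function(r, n, k = 0L, alpha = 0.05) {
  if (n - k - 3 <= 0) stop("insufficient sample for conditioning size")
  if (abs(r) > 1 + 1e-12) stop("|r| must not exceed 1")
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    z <- sign(r) * Inf
    p <- 0
  } else {
    z <- atanh(r) * sqrt(n - k - 3)
    p <- 2 * stats::pnorm(-abs(z))
  }
  data.frame(r = r, z = z, p = p,
             decision = if (p > alpha) "independent" else "dependent")
}

# Partial correlation of variables i and j given S, from a correlation
# matrix (closed forms for |S| <= 1).
pcor_from_cormat <- function(C, i, j, S) {
  if (length(S) == 0) return(C[i, j])
  if (length(S) == 1) {
    r_ik <- C[i, S]; r_jk <- C[j, S]
    den <- (1 - r_ik^2) * (1 - r_jk^2)
    if (den <= 1e-24) return(NA_real_)  # collinear conditioning
    return((C[i, j] - r_ik * r_jk) / sqrt(den))
  }
  sub <- c(i, j, S)
  P <- tryCatch(solve(C[sub, sub]), error = function(e) NULL)
  if (is.null(P)) return(NA_real_)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Shared CI-test engine over a correlation matrix. Returns the test row
# (list) with r possibly NA when conditioning is collinear; collinear
# conditioning is treated as maximal dependence explained by S, i.e.
# decision "independent" is NOT inferred -- the test is skipped by
# callers.
ci_test <- function(C, n, i, j, S, alpha) {
  r <- pcor_from_cormat(C, i, j, S)
  if (is.na(r)) return(NULL)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    z <- sign(r) * Inf; p <- 0
  } else {
    z <- atanh(r) * sqrt(n - length(S) - 3)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(r = r, z = z, p = p, independent = p > alpha)
}

# Enumerate subsets of `pool` with size 1..max_k (size-ascending, stable
# order). Conditioning sets for admission/elimination tests.
subsets_up_to <- function(pool, max_k) {
  out <- list()
  for (k in seq_len(min(max_k, length(pool)))) {
    cmb <- utils::combn(pool, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

new_local_causal_set <- function(target_name, members, trace, config,
                                 admission_order) {
  structure(list(target = target_name, members = members,
                 admission_order = admission_order,
                 trace = trace,
                 alpha_ci = config$alpha_ci, max_k = config$max_k),
            class = "local_causal_set")
}

#' @export
print.local_causal_set <- function(x, ...) {
  cat("Local causal set for target '", x$target, "' (alpha = ",
      x$alpha_ci, ", max-k = ", x$max_k, ")\n", sep = "")
  cat("  members (", length(x$members), "): ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  cat("  CI tests performed: ", nrow(x$trace), "\n", sep = "")
  invisible(x)
}

#' Semi-Interleaved HITON-PC without symmetry correction
#'
#' Local causal discovery of the parents-and-children set of a binary
#' target over continuous expression data, using the Fisher's Z
#' partial-correlation test (the 0/1 target enters the correlations
#' numerically, i.e. point-biserially). The algorithm:
#' \enumerate{
#'   \item Univariate phase: every gene is tested against the target
#'     unconditionally; independents are discarded and survivors queued by
#'     decreasing |r| (ties broken lexicographically by gene id).
#'   \item Semi-interleaved inclusion: candidates are popped in order; a
#'     candidate is discarded permanently if any subset of the currently
#'     accepted set, of size at most \code{max_k}, renders it independent
#'     of the target; otherwise it is accepted.
#'   \item Backward pass: each accepted gene is re-tested against subsets
#'     of the other accepted genes; eliminations repeat until a fixed
#'     point.
#' }
#' No symmetry correction is applied (the reciprocal test that the target
#' belongs to the candidate's own parents-children set is skipped).
#'
#' @param mat Genes x samples matrix.
#' @param target Binary 0/1 vector over the samples (e.g. 1 for
#'   regression samples).
#' @param config A \code{\link{pipeline_config}} (uses \code{alpha_ci},
#'   \code{max_k}).
#' @param target_name Label used in the trace (default \code{"T"}).
#' @param trace If FALSE, the per-test trace is not materialized (used by
#'   permutation re-runs for speed); results are identical.
#' @return A \code{"local_causal_set"}: members in admission order, the
#'   full conditional-independence test trace, and a config echo.
#' @export
hiton_pc <- function(mat, target, config = pipeline_config(),
                     target_name = "T", trace = TRUE) {
  check_expression_matrix(mat)
  if (length(target) != ncol(mat)) {
    stop("target length must match the number of samples")
  }
  if (!all(target %in% c(0, 1)) || length(unique(target)) < 2) {
    stop("target must be binary 0/1 with both classes present")
  }
  n <- ncol(mat)
  alpha <- config$alpha_ci
  max_k <- config$max_k
  genes <- rownames(mat)
  rm_ <- rowMeans(mat)
  sds <- sqrt(pmax(0, (rowSums(mat^2) - n * rm_^2) / (n - 1)))
  if (any(sds == 0)) {
    stop("degenerate (zero-variance) gene(s): ",
         paste(utils::head(genes[sds == 0], 3), collapse = ", "))
  }

  trace_rows <- list()
  log_test <- function(x, S, tst, phase) {
    if (!trace) return(invisible(NULL))
    trace_rows[[length(trace_rows) + 1L]] <<- data.frame(
      x = x, y = target_name,
      conditioning = paste(S, collapse = ","),
      r = tst$r, z = tst$z, p = tst$p,
      decision = if (tst$independent) "independent" else "dependent",
      phase = phase)
  }

  # univariate phase (k = 0), vectorized over genes
  r_uni <- as.vector(stats::cor(t(mat), target))
  names(r_uni) <- genes
  r_cl <- pmax(-1, pmin(1, r_uni))
  z_uni <- ifelse(abs(r_cl) == 1, sign(r_cl) * Inf,
                  atanh(r_cl) * sqrt(n - 3))
  p_uni <- ifelse(is.infinite(z_uni), 0, 2 * stats::pnorm(-abs(z_uni)))
  if (trace) {
    trace_rows[[1L]] <- data.frame(
      x = genes, y = target_name, conditioning = "",
      r = r_cl, z = z_uni, p = p_uni,
      decision = ifelse(p_uni > alpha, "independent", "dependent"),
      phase = "univariate")
  }
  surv <- genes[p_uni <= alpha]
  if (!length(surv)) {
    tr <- if (trace) do.call(rbind, trace_rows) else empty_trace()
    return(new_local_causal_set(target_name, character(0), tr, config,
                                character(0)))
  }
  ord <- order(-abs(r_uni[surv]), surv)
  queue <- surv[ord]

  # correlation matrix over survivors + target (target is last index)
  C <- stats::cor(cbind(t(mat[queue, , drop = FALSE]), .target. = target))
  t_idx <- length(queue) + 1L
  pos <- stats::setNames(seq_along(queue), queue)

  # semi-interleaved inclusion
  accepted <- character(0)
  for (g in queue) {
    eliminated <- FALSE
    for (S in subsets_up_to(accepted, max_k)) {
      tst <- ci_test(C, n, pos[g], t_idx, pos[S], alpha)
      if (is.null(tst)) next  # collinear conditioning set: skip
      log_test(g, S, tst, "inclusion")
      if (tst$independent) {
        eliminated <- TRUE
        break
      }
    }
    if (!eliminated) accepted <- c(accepted, g)
  }

  # backward elimination to a fixed point
  repeat {
    removed <- FALSE
    for (g in accepted) {
      others <- setdiff(accepted, g)
      for (S in subsets_up_to(others, max_k)) {
        tst <- ci_test(C, n, pos[g], t_idx, pos[S], alpha)
        if (is.null(tst)) next
        log_test(g, S, tst, "backward")
        if (tst$independent) {
          accepted <- setdiff(accepted, g)
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break
  }

  tr <- if (trace) do.call(rbind, trace_rows) else empty_trace()
  new_local_causal_set(target_name, accepted, tr, config,
                       intersect(queue, accepted))
}

empty_trace <- function() {
  data.frame(x = character(0), y = character(0),
             conditioning = character(0), r = numeric(0), z = numeric(0),
             p = numeric(0), decision = character(0), phase = character(0))
}

#' Brute-force parents-children oracle
#'
#' Exhaustive reference implementation for verifying
#' \code{\link{hiton_pc}}: a gene belongs to the output exactly when no
#' subset of the other candidate genes, of size at most \code{max_k}
#' (including the empty set), renders it independent of the target under
#' the same Fisher's Z test. Exponential in the number of candidates;
#' refuses more than 15.
#'
#' @inheritParams hiton_pc
#' @return A \code{"local_causal_set"}.
#' @export
brute_force_pc <- function(mat, target, config = pipeline_config(),
                           target_name = "T") {
  check_expression_matrix(mat)
  if (nrow(mat) > 15) {
    stop("too many candidates for exhaustive search; use hiton_pc")
  }
  if (!all(target %in% c(0, 1)) || length(unique(target)) < 2) {
    stop("target must be binary 0/1 with both classes present")
  }
  n <- ncol(mat)
  genes <- rownames(mat)
  C <- stats::cor(cbind(t(mat), .target. = target))
  t_idx <- nrow(mat) + 1L
  pos <- stats::setNames(seq_along(genes), genes)
  trace_rows <- list()
  members <- character(0)
  for (g in genes) {
    others <- setdiff(genes, g)
    independent <- FALSE
    all_s <- c(list(character(0)), subsets_up_to(others, config$max_k))
    for (S in all_s) {
      tst <- ci_test(C, n, pos[g], t_idx, pos[S], config$alpha_ci)
      if (is.null(tst)) next
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        x = g, y = target_name, conditioning = paste(S, collapse = ","),
        r = tst$r, z = tst$z, p = tst$p,
        decision = if (tst$independent) "independent" else "dependent",
        phase = "exhaustive")
      if (tst$independent) {
        independent <- TRUE
        break
      }
    }
    if (!independent) members <- c(members, g)
  }
  new_local_causal_set(target_name, members,
                       do.call(rbind, trace_rows), config, members)
}
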