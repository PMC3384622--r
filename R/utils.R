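GROUP_LEVELS <- c("baseline", "progression", "regression")
DYE_LEVELS <- c("forward", "reverse")

#' Reduce an array-level design to one row per sample
#'
#' @param design An array-level design data frame (columns \code{array_id},
#'   \code{sample_id}, \code{group}, \code{batch}, \code{dye}) or an
#'   already-reduced sample-level frame (columns \code{sample_id},
#'   \code{group}, \code{batch}).
#' @return A data frame with one row per sample and columns
#'   \code{sample_id}, \code{group}, \code{batch}, in first-appearance
#'   order.
#' @export
sample_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(design))) {
    stop("design must contain columns: ", paste(need, collapse = ", "))
  }
  sd <- unique(design[need])
  if (anyDuplicated(sd$sample_id)) {
    dup <- unique(sd$sample_id[duplicated(sd$sample_id)])
    stop("sample(s) with inconsistent group/batch annotation: ",
         paste(dup, collapse = ", "))
  }
  rownames(sd) <- NULL
  sd$sample_id <- as.character(sd$sample_id)
  sd$group <- as.character(sd$group)
  sd$batch <- as.character(sd$batch)
  sd
}

# Sample ids of a sample-level design belonging to the given groups.
samples_in_groups <- function(sdesign, groups) {
  sdesign$sample_id[sdesign$group %in% groups]
}

# Columns of `mat` for the given groups, in design order.
group_columns <- function(mat, sdesign, group) {
  ids <- samples_in_groups(sdesign, group)
  missing <- setdiff(ids, colnames(mat))
  if (length(missing)) {
    stop("samples missing from matrix: ", paste(missing, collapse = ", "))
  }
  ids
}

# Deterministic sub-seed derivation; keeps results below .Machine's
# 32-bit integer bound so seeds survive set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

check_expression_matrix <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop(what, " must be a numeric matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop(what, " must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene id in ", what, ": ",
         rownames(mat)[duplicated(rownames(mat))][1])
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate column id in ", what, ": ",
         colnames(mat)[duplicated(colnames(mat))][1])
  }
  invisible(mat)
}
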