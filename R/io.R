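#' Read a gene-by-sample log-ratio matrix from TSV
#'
#' Expects a tab-delimited file whose header row names the sample (or
#' array) columns and whose first column holds gene identifiers. Values are
#' log10 ratios. Malformed input is rejected rather than coerced: duplicate
#' identifiers, ragged rows and non-numeric cells are all errors that name
#' the offending location.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene rownames and sample colnames, in file
#'   order.
#' @export
read_ratio_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- unique(utils::count.fields(path, sep = "\t", quote = ""))
  if (length(nf) > 1) {
    stop("ragged rows in ", path, ": rows have ",
         paste(sort(nf), collapse = ", "), " fields")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("matrix file needs a gene column plus >=1 sample")
  gene_ids <- trimws(df[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  }
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1])
  }
  vals <- as.matrix(df[-1])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric value '%s' at gene %s, column %s",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write a gene-by-sample matrix as TSV
#'
#' Inverse of \code{\link{read_ratio_matrix}}; values are written with
#' enough digits to round-trip to at least 12 decimal digits.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ratio_matrix <- function(mat, path) {
  check_expression_matrix(mat)
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format(mat[i, ], digits = 15,
                                     scientific = TRUE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an array-level sample design table
#'
#' Expects tab-delimited columns \code{array_id}, \code{sample_id},
#' \code{group}, \code{batch}, \code{dye}. Group and dye labels are
#' case-normalized. The reference-design invariants are enforced: every
#' sample has exactly two arrays with opposite dye orientation, belongs to
#' one group and one batch, and every group has at least two samples.
#'
#' @param path Path to a TSV file.
#' @return A validated data frame with the five columns above.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c("array_id", "sample_id", "group", "batch", "dye")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("design file missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[need]
  df[] <- lapply(df, trimws)
  df$group <- tolower(df$group)
  df$dye <- tolower(df$dye)
  validate_design(df)
}

#' Validate an array-level design data frame
#'
#' @param design Data frame with columns \code{array_id}, \code{sample_id},
#'   \code{group}, \code{batch}, \code{dye}.
#' @return The design, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  if (anyDuplicated(design$array_id)) {
    stop("duplicate array id: ",
         design$array_id[duplicated(design$array_id)][1])
  }
  bad_group <- setdiff(unique(design$group), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("unknown group label(s) ", paste(bad_group, collapse = ", "),
         "; allowed: ", paste(GROUP_LEVELS, collapse = ", "))
  }
  bad_dye <- setdiff(unique(design$dye), DYE_LEVELS)
  if (length(bad_dye)) {
    stop("unknown dye label(s) ", paste(bad_dye, collapse = ", "),
         "; allowed: ", paste(DYE_LEVELS, collapse = ", "))
  }
  per_sample <- split(design$dye, design$sample_id)
  for (s in names(per_sample)) {
    dyes <- sort(per_sample[[s]])
    if (length(dyes) != 2 || !identical(dyes, DYE_LEVELS)) {
      stop("sample ", s, " must have exactly one forward and one reverse ",
           "array; found: ", paste(per_sample[[s]], collapse = ", "))
    }
  }
  sd <- sample_design(design)  # errors on inconsistent group/batch
  tab <- table(sd$group)
  if (any(tab < 2)) {
    stop("every group needs >= 2 samples; short: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  design
}

#' Write an array-level design table as TSV
#'
#' @param design Validated design data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, fields
#' \code{name TAB description TAB member TAB member ...}. Member fields are
#' whitespace-trimmed and empty members dropped. Lines with fewer than
#' three fields and duplicate set names are errors.
#'
#' @param path Path to a GMT file.
#' @param source_label Label recorded as the collection's origin; defaults
#'   to the file name.
#' @return A list of class \code{"gene_set_collection"} with elements
#'   \code{sets} (named list of character vectors), \code{descriptions}
#'   and \code{source}.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    name <- trimws(fields[1])
    if (name %in% names(sets)) stop("duplicate set name: ", name)
    members <- trimws(fields[-(1:2)])
    members <- unique(members[nzchar(members)])
    if (length(members) == 0) stop("GMT line ", i, " has no members")
    sets[[name]] <- members
    descriptions[name] <- trimws(fields[2])
  }
  structure(list(sets = sets, descriptions = descriptions,
                 source = source_label),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection A \code{"gene_set_collection"}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- collection$descriptions[nm]
    if (is.na(desc) || !nzchar(desc)) desc <- "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the simulation truth table
#'
#' Three tab-delimited columns: \code{gene}, \code{class},
#' \code{true_fc} (signed linear fold change; 1 for unaffected genes).
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns \code{gene}, \code{class},
#'   \code{true_fc}.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "numeric"),
                          check.names = FALSE, quote = "")
  need <- c("gene", "class", "true_fc")
  if (!all(need %in% names(df))) {
    stop("truth file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df[need]
}

#' @rdname read_truth
#' @param truth Truth data frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
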