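#' Serialize pipeline result objects to JSON
#'
#' Writes differential profiles, enrichment tables, local causal sets,
#' signature evaluations and run reports as JSON documents (schema: plain
#' transcription of the object's fields; data frames become arrays of
#' records).
#'
#' @param x A result object (\code{differential_profile},
#'   \code{enrichment_result}, \code{local_causal_set},
#'   \code{signature_evaluation}, \code{fdp_estimate} or
#'   \code{run_report}).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_result_json <- function(x, path) {
  payload <- unclass(x)
  payload$config <- NULL  # config echoed separately in run reports
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a differential profile as TSV plus JSON header
#'
#' The gene table goes to \code{<stem>.tsv} (columns \code{gene},
#' \code{p_regression}, \code{p_transplant}, \code{p_error},
#' \code{fold_change}, \code{cluster}); the counts, FDP estimate and
#' config echo go to \code{<stem>.json}.
#'
#' @param profile A \code{"differential_profile"}.
#' @param stem Output path without extension.
#' @return Character vector of the two paths written.
#' @export
write_profile <- function(profile, stem) {
  stopifnot(inherits(profile, "differential_profile"))
  tsv <- paste0(stem, ".tsv")
  json <- paste0(stem, ".json")
  utils::write.table(profile$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  header <- list(n_after_anova = profile$n_after_anova,
                 n_final = profile$n_final,
                 fdp_estimate = profile$fdp_estimate,
                 config = unclass(profile$config))
  jsonlite::write_json(header, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  c(tsv, json)
}
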