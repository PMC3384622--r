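#' Run the full analysis pipeline
#'
#' Orchestrates every stage end-to-end: simulate (or load) a
#' reference-design experiment, combine dye-swap duplicates, re-ratio by
#' batch, compute the error-model surrogate, build the differential
#' profile with its permutation false-positive estimate, test up/down
#' clusters for gene-set over-representation, discover the local causal
#' neighborhood of the regression indicator with HITON-PC, and evaluate
#' the resulting signature by LOOCV with permutation significance.
#'
#' The run is fully determined by the configuration and seed: every
#' randomized stage derives its own sub-seed from \code{pipeline$seed}.
#'
#' @param config Either a path to a YAML file or a list with (all
#'   optional) entries:
#'   \describe{
#'     \item{simulate}{logical, default TRUE; if FALSE,
#'       \code{matrix_path} and \code{design_path} must point to a ratio
#'       matrix and design TSV.}
#'     \item{sim}{list of \code{\link{simulation_config}} arguments.}
#'     \item{pipeline}{list of \code{\link{pipeline_config}} arguments.}
#'     \item{gmt_path}{optional GMT file for enrichment; when simulating
#'       without one, a collection is built from the planted truth plus
#'       random sets.}
#'     \item{signature_mode}{\code{"nested_selection"} (default) or
#'       \code{"fixed_genes"}.}
#'     \item{run_signature_permutation}{logical, default TRUE.}
#'     \item{out_dir}{optional directory; when set, every intermediate
#'       artifact and the report are written there.}
#'   }
#' @param seed Optional integer overriding both config seeds.
#' @return A list of class \code{"run_report"} with the config echo,
#'   per-stage fingerprints and timings, and the headline numbers
#'   (\code{n_after_anova}, \code{n_final}, \code{fdp_estimate},
#'   enrichment hits, causal members, \code{auc}, \code{signature_p}).
#' @export
run_all <- function(config = list(), seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  sim_args <- config$sim %||% list()
  pipe_args <- config$pipeline %||% list()
  if (!is.null(seed)) {
    sim_args$seed <- as.integer(seed)
    pipe_args$seed <- as.integer(seed)
  }
  pcfg <- do.call(pipeline_config, pipe_args)
  simulate <- config$simulate %||% TRUE
  mode <- config$signature_mode %||% "nested_selection"
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  timings <- c()
  fingerprints <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }
  fp <- function(stage, x) {
    v <- if (is.matrix(x)) x else as.matrix(as.data.frame(
      Filter(is.numeric, as.list(x))))
    fingerprints[[stage]] <<- sprintf("%dx%d:%.8e", NROW(x), NCOL(x),
                                      sum(as.numeric(v), na.rm = TRUE))
  }

  # --- stage: input -------------------------------------------------------
  truth <- NULL
  if (isTRUE(simulate)) {
    scfg <- do.call(simulation_config, sim_args)
    experiment <- clock("simulate", simulate_experiment(scfg))
    measurements <- experiment$measurements
    design <- experiment$design
    truth <- experiment$truth
  } else {
    for (p in c(config$matrix_path, config$design_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("input file not found: ", if (is.null(p)) "(unset)" else p)
      }
    }
    measurements <- clock("load", read_ratio_matrix(config$matrix_path))
    design <- read_design(config$design_path)
  }
  fp("measurements", measurements)

  # --- stage: preprocess --------------------------------------------------
  combined <- clock("combine_dye_swap",
                    combine_dye_swap(measurements, design))
  mat <- clock("reratio_by_batch", reratio_by_batch(combined, design))
  error_p <- clock("error_model",
                   error_model_surrogate(measurements, design))
  fp("expression_matrix", mat)

  # --- stage: differential profile ---------------------------------------
  profile <- clock("build_profile", build_profile(mat, design, error_p,
                                                  pcfg))
  fdp <- clock("estimate_fdp", estimate_fdp(mat, design, pcfg))
  profile$fdp_estimate <- fdp$fdp_estimate
  fp("profile", profile$table)

  # --- stage: enrichment --------------------------------------------------
  universe <- rownames(mat)
  collection <- if (!is.null(config$gmt_path)) {
    read_gmt(config$gmt_path)
  } else if (!is.null(truth)) {
    truth_collection(truth, seed = derive_seed(pcfg$seed, 2714L))
  }
  enrichment <- NULL
  if (!is.null(collection) && profile$n_final > 0) {
    enrichment <- clock("enrichment", {
      lapply(c(up = "up", down = "down"), function(side) {
        members <- profile$table$gene[profile$table$cluster == side]
        if (length(members) == 0) return(NULL)
        enrich(members, universe, collection,
               alpha = pcfg$bonferroni_alpha)
      })
    })
  }

  # --- stage: causal discovery -------------------------------------------
  sdesign <- sample_design(design)
  sdesign <- sdesign[match(colnames(mat), sdesign$sample_id), ]
  target <- as.numeric(sdesign$group == "regression")
  causal <- clock("hiton_pc", hiton_pc(mat, target, pcfg,
                                       target_name = "regression"))

  # --- stage: signature ---------------------------------------------------
  signature <- NULL
  if (length(causal$members) > 0) {
    signature <- clock("signature", {
      if (isTRUE(config$run_signature_permutation %||% TRUE)) {
        permutation_significance(mat, target, genes = causal$members,
                                 config = pcfg, mode = mode)
      } else {
        loocv_auc(mat, target, genes = causal$members, config = pcfg,
                  mode = mode)
      }
    })
  }

  report <- structure(list(
    seed = pcfg$seed,
    pipeline_config = unclass(pcfg),
    simulation_config = if (isTRUE(simulate)) {
      c(unclass(scfg)[setdiff(names(scfg), "causal_spec")],
        list(causal_spec = unclass(scfg$causal_spec)))
    },
    fingerprints = fingerprints,
    headline = list(
      n_after_anova = profile$n_after_anova,
      n_final = profile$n_final,
      fdp_estimate = profile$fdp_estimate,
      enrichment_significant = if (!is.null(enrichment)) {
        vapply(enrichment, function(e) {
          if (is.null(e)) 0L else sum(e$significant)
        }, integer(1))
      },
      causal_members = causal$members,
      auc = if (!is.null(signature)) signature$auc,
      signature_p = if (!is.null(signature)) signature$p_value
    ),
    timings = timings
  ), class = "run_report")
  report$profile <- profile
  report$enrichment <- enrichment
  report$causal <- causal
  report$signature <- signature
  if (!is.null(truth)) report$truth <- truth

  if (!is.null(out_dir)) {
    write_ratio_matrix(mat, file.path(out_dir, "expression_matrix.tsv"))
    write_design(design, file.path(out_dir, "design.tsv"))
    utils::write.table(error_p, file.path(out_dir, "error_model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_profile(profile, file.path(out_dir, "profile"))
    if (!is.null(enrichment)) {
      for (side in names(enrichment)) {
        if (!is.null(enrichment[[side]])) {
          utils::write.table(enrichment[[side]],
                             file.path(out_dir,
                                       paste0("enrichment_", side, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
    write_result_json(causal, file.path(out_dir, "causal_set.json"))
    if (!is.null(signature)) {
      write_result_json(signature, file.path(out_dir, "signature.json"))
    }
    report_for_disk <- report
    report_for_disk$profile <- NULL
    report_for_disk$enrichment <- NULL
    report_for_disk$causal <- NULL
    report_for_disk$signature <- NULL
    report_for_disk$truth <- NULL
    write_result_json(report_for_disk, file.path(out_dir, "report.json"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gene-set collection derived from the simulation truth: one set per
# planted class plus seeded random decoy sets.
truth_collection <- function(truth, n_random = 20L, random_size = 50L,
                             seed = 1L) {
  sets <- list()
  for (cls in c("regression_up", "regression_down", "transplant")) {
    members <- truth$gene[truth$class == cls]
    if (length(members)) sets[[paste0("planted_", cls)]] <- members
  }
  causal <- truth$gene[startsWith(truth$class, "causal")]
  if (length(causal)) sets[["planted_causal"]] <- causal
  set.seed(seed)
  size <- min(random_size, nrow(truth))
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_%02d", i)]] <- sample(truth$gene, size)
  }
  structure(list(sets = sets,
                 descriptions = stats::setNames(rep("synthetic",
                                                    length(sets)),
                                                names(sets)),
                 source = "simulation truth"),
            class = "gene_set_collection")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed ", x$seed, ")\n", sep = "")
  h <- x$headline
  cat("  ANOVA-passing genes:  ", h$n_after_anova, "\n", sep = "")
  cat("  final profile size:   ", h$n_final, "\n", sep = "")
  cat("  FDP estimate:         ",
      ifelse(is.na(h$fdp_estimate), "undefined",
             format(h$fdp_estimate, digits = 3)), "\n", sep = "")
  if (!is.null(h$enrichment_significant)) {
    cat("  enriched sets (up/down): ",
        paste(h$enrichment_significant, collapse = " / "), "\n", sep = "")
  }
  cat("  causal members (", length(h$causal_members), "): ",
      paste(h$causal_members, collapse = ", "), "\n", sep = "")
  if (!is.null(h$auc)) {
    cat("  signature AUC: ", format(h$auc, digits = 3), sep = "")
    if (!is.null(h$signature_p)) {
      cat(", permutation p = ", format(h$signature_p, digits = 3),
          sep = "")
    }
    cat("\n")
  }
  cat("  stage timings (s): ",
      paste(names(x$timings), unlist(x$timings), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
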