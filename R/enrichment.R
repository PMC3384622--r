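#' Gene-set over-representation by Fisher's exact test
#'
#' One-sided (over-representation) Fisher's exact test of each gene set
#' against the profile, from the 2x2 table
#' \code{[profile & set, profile & !set; !profile & set, !profile & !set]}
#' within the universe. The one-sided p equals the hypergeometric upper
#' tail. P-values are Bonferroni-corrected over the number of sets with a
#' nonzero universe intersection; sets with an empty intersection are
#' excluded (and reported via \code{message}). The universe is the set of
#' reporters on the analyzed matrix, the array being the sampling frame.
#'
#' @param profile_genes Character vector of profile members (must be a
#'   subset of \code{universe}).
#' @param universe Character vector of all genes in the sampling frame.
#' @param collection A \code{"gene_set_collection"} from
#'   \code{\link{read_gmt}}, or a named list of character vectors.
#' @param alpha Family-wise level for the significance flag (default
#'   0.05).
#' @return A data frame of class \code{"enrichment_result"} sorted by
#'   adjusted p, with columns \code{set}, \code{overlap},
#'   \code{profile_size}, \code{set_size}, \code{universe_size},
#'   \code{odds_ratio}, \code{p}, \code{p_adjusted},
#'   \code{significant}.
#' @export
enrich <- function(profile_genes, universe, collection, alpha = 0.05) {
  universe <- unique(as.character(universe))
  profile_genes <- unique(as.character(profile_genes))
  if (!all(profile_genes %in% universe)) {
    stop("profile genes absent from the universe: ",
         paste(utils::head(setdiff(profile_genes, universe), 3),
               collapse = ", "))
  }
  sets <- if (inherits(collection, "gene_set_collection")) {
    collection$sets
  } else {
    collection
  }
  if (!length(sets)) stop("empty gene-set collection")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    message(sum(empty), " set(s) with empty universe intersection excluded: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no gene set intersects the universe")
  N <- length(universe)
  n_prof <- length(profile_genes)
  n_tested <- length(sets)
  res <- lapply(names(sets), function(nm) {
    set <- sets[[nm]]
    K <- length(set)
    a <- length(intersect(profile_genes, set))
    b <- n_prof - a
    cc <- K - a
    d <- N - K - b
    # hypergeometric upper tail P(X >= a) = one-sided Fisher p
    p <- stats::phyper(a - 1, K, N - K, n_prof, lower.tail = FALSE)
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(set = nm, overlap = a, profile_size = n_prof,
               set_size = K, universe_size = N, odds_ratio = or, p = p)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p * n_tested)
  res$significant <- res$p_adjusted < alpha
  res <- res[order(res$p_adjusted, res$p, res$set), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
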