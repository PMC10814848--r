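#' Ascending competition ranks from stability values
#'
#' Lower stability value = better = smaller rank. Ties (on the unrounded
#' values) share the smallest applicable rank and the next distinct value
#' skips the absorbed ranks ("min"/competition method), so a tied best pair
#' yields ranks 1, 1, 3, ...
#'
#' @param values non-negative numeric stability values, one per gene.
#' @return integer ranks, same length and names as `values`.
#' @export
assign_ranks <- function(values) {
  if (!length(values)) stop("no values to rank", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("stability values must be finite and non-negative", call. = FALSE)
  r <- as.integer(rank(values, ties.method = "min"))
  names(r) <- names(values)
  r
}

#' Geometric mean of a rank vector
#'
#' The consensus statistic: the geometric mean of one gene's ranks across
#' the stability algorithms. Lies in `[1, G]` by construction.
#'
#' @param ranks integer (or numeric) ranks, all >= 1.
#' @return the unrounded geometric mean (a double). Reports conventionally
#'   print it rounded to 2 decimals.
#' @examples
#' geometric_mean_rank(c(1, 2, 1, 1))  # 1.189...
#' @export
geometric_mean_rank <- function(ranks) {
  if (!length(ranks)) stop("empty rank vector", call. = FALSE)
  if (any(!is.finite(ranks)) || any(ranks < 1))
    stop("ranks must be finite and >= 1", call. = FALSE)
  exp(mean(log(ranks)))
}

# fixed algorithm order used for rank vectors and report columns
CONSENSUS_ALGORITHMS <- c("delta_ct", "bestkeeper", "normfinder", "genorm")

#' Comprehensive geometric-mean consensus ranking
#'
#' Merges one `stability_table` per algorithm into a single ranking: each
#' gene's four competition ranks (order: comparative delta-Ct, BestKeeper,
#' NormFinder, geNorm) are combined by geometric mean and genes sorted
#' ascending. Equal geometric means are broken alphabetically by gene
#' symbol (deterministic) and flagged.
#'
#' @param tables list of four `stability_table`s, one per algorithm in
#'   `delta_ct`, `bestkeeper`, `normfinder`, `genorm` (any list order; matched by their `algorithm`
#'   column). All must cover the same gene set.
#' @param stratum optional label describing the sample stratum the tables
#'   were computed on (e.g. `"FBS"`, `"X1/X2"`, `"ALL"`, a donor id).
#' @return data.frame of class `consensus_ranking`, sorted by consensus:
#'   columns `gene`, `geomean` (unrounded), `rank_delta_ct`,
#'   `rank_bestkeeper`, `rank_normfinder`, `rank_genorm`,
#'   `value_delta_ct`, ..., `final_position`, `tied`. Attribute `stratum`.
#' @export
comprehensive_ranking <- function(tables, stratum = NA_character_) {
  if (inherits(tables, "stability_table")) tables <- list(tables)
  algs <- vapply(tables, function(t) t$algorithm[1], character(1))
  missing_algs <- setdiff(CONSENSUS_ALGORITHMS, algs)
  if (length(missing_algs))
    stop("missing stability table(s) for: ",
         paste(missing_algs, collapse = ", "), call. = FALSE)
  if (anyDuplicated(algs))
    stop("duplicate stability table for an algorithm", call. = FALSE)
  tables <- tables[match(CONSENSUS_ALGORITHMS, algs)]
  genes <- sort(tables[[1]]$gene)
  for (t in tables[-1])
    if (!setequal(t$gene, genes))
      stop("stability tables do not cover the same gene set", call. = FALSE)
  rank_mat <- vapply(tables,
                     function(t) t$rank[match(genes, t$gene)],
                     integer(length(genes)))
  value_mat <- vapply(tables,
                      function(t) t$value[match(genes, t$gene)],
                      numeric(length(genes)))
  geo <- apply(rank_mat, 1, geometric_mean_rank)
  ord <- order(geo, genes)  # alphabetical tie-break, deterministic
  res <- data.frame(gene = genes[ord], geomean = geo[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (k in seq_along(CONSENSUS_ALGORITHMS)) {
    res[[paste0("rank_", CONSENSUS_ALGORITHMS[k])]] <- rank_mat[ord, k]
    res[[paste0("value_", CONSENSUS_ALGORITHMS[k])]] <- value_mat[ord, k]
  }
  res$final_position <- seq_len(nrow(res))
  res$tied <- duplicated(res$geomean) | duplicated(res$geomean, fromLast = TRUE)
  structure(res, class = c("consensus_ranking", "data.frame"),
            stratum = stratum)
}

#' @export
print.consensus_ranking <- function(x, ...) {
  strat <- attr(x, "stratum")
  cat("<consensus_ranking>",
      if (!is.na(strat)) paste0(" stratum: ", strat), "\n", sep = "")
  show <- data.frame(gene = x$gene, geomean = sprintf("%.2f", x$geomean),
                     delta_ct = x$rank_delta_ct, bestkeeper = x$rank_bestkeeper,
                     normfinder = x$rank_normfinder, genorm = x$rank_genorm)
  print(show, row.names = FALSE)
  if (any(x$tied))
    cat("note: tie(s) on the geometric mean broken alphabetically\n")
  invisible(x)
}

#' Run all four algorithms and build the consensus for one stratum
#'
#' Convenience wrapper: computes comparative delta-Ct, BestKeeper,
#' NormFinder and geNorm stability tables on `x` and aggregates them with
#' [comprehensive_ranking()].
#'
#' @param x a [ct_matrix()] (>= 3 genes, >= 2 samples).
#' @param stratum label recorded on the result.
#' @param normfinder_groups passed to [normfinder_stability()]; `NULL`
#'   (ungrouped) by default.
#' @param bestkeeper_dispersion passed to [bestkeeper()].
#' @return list with elements `tables` (named list of the four
#'   `stability_table`s) and `consensus` (a `consensus_ranking`).
#' @export
stability_analysis <- function(x, stratum = NA_character_,
                               normfinder_groups = NULL,
                               bestkeeper_dispersion = c("mad", "sd")) {
  tables <- list(
    delta_ct = delta_ct_stability(x),
    bestkeeper = bestkeeper(x, dispersion = match.arg(bestkeeper_dispersion)),
    normfinder = normfinder_stability(x, groups = normfinder_groups),
    genorm = genorm_rank(x))
  list(tables = tables,
       consensus = comprehensive_ranking(tables, stratum = stratum))
}

#' Consensus ranking from published per-algorithm orderings
#'
#' Builds a `consensus_ranking` from ordered gene lists (best first) rather
#' than from raw stability values — the situation when only the printed
#' per-algorithm orderings of a report are available. List position is
#' taken as the rank; the geNorm stepwise procedure cannot separate its
#' final two genes, so a geNorm ordering lists the tied best pair at
#' position 1 (two genes sharing position 1) and competition ranking then
#' assigns ranks 1, 1, 3, ...
#'
#' @param orderings data.frame with columns `algorithm` (values in
#'   `delta_ct`, `bestkeeper`, `normfinder`, `genorm`), `gene`, and `position` (1 = most stable;
#'   equal positions are ties).
#' @param stratum label recorded on the result.
#' @return a `consensus_ranking` (value columns are `NA`; only ranks are
#'   known).
#' @export
consensus_from_orderings <- function(orderings, stratum = NA_character_) {
  req <- c("algorithm", "gene", "position")
  miss <- setdiff(req, names(orderings))
  if (length(miss))
    stop("orderings lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tables <- lapply(split(orderings, orderings$algorithm), function(d) {
    ranks <- assign_ranks(as.numeric(d$position))
    tab <- stability_table(d$algorithm[1], d$gene,
                           values = rep(0, nrow(d)), ranks = ranks)
    tab$value <- NA_real_
    tab
  })
  comprehensive_ranking(unname(tables), stratum = stratum)
}

#' Per-algorithm stability orderings of the ASC culture-media study design
#'
#' The validation dataset shipped with the package: the per-algorithm
#' stability orderings of five housekeeping genes (ACTB, EF1A, GAPDH,
#' RPLP0, TBP) in adipose stromal cells from four donors cultured in FBS
#' medium and two serum/xeno-free media, as published for seven
#' condition strata (FBS, X1, X2, X1/X2, FBS/X1, FBS/X2, ALL) and four
#' per-donor strata (ASC1-ASC4). Positions encode list order per
#' algorithm; geNorm's structurally tied best pair shares position 1.
#'
#' @param which `"media"` (condition strata), `"donor"` (per-donor strata)
#'   or `"both"`.
#' @return data.frame with columns `stratum`, `algorithm`, `gene`,
#'   `position`, suitable for [consensus_from_orderings()] per stratum.
#' @export
study_orderings <- function(which = c("both", "media", "donor")) {
  which <- match.arg(which)
  read_one <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "hkgstab",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
  }
  out <- switch(which,
                media = read_one("asc_media_orderings.csv"),
                donor = read_one("asc_donor_orderings.csv"),
                both = rbind(read_one("asc_media_orderings.csv"),
                             read_one("asc_donor_orderings.csv")))
  out
}
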