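#' Study stratification preset
#'
#' The stratification scheme of a multi-medium, multi-donor reference-gene
#' study: each single condition, each pair of conditions, all conditions
#' together (`ALL`), and each donor across all conditions. For the default
#' 3-condition x 4-donor design this yields 11 strata (FBS, X1, X2, X1/X2,
#' FBS/X1, FBS/X2, ALL, ASC1-ASC4). Labels for condition pairs join the
#' labels with `/` in first-seen order.
#'
#' @param x a [ct_matrix()].
#' @return named list of stratum definitions, each a list with `label`,
#'   `conditions` (or `NULL`) and `donors` (or `NULL`), consumable by
#'   [run_stability()].
#' @export
study_strata <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  conds <- unique(x$samples$condition)
  donors <- unique(x$samples$donor)
  strata <- list()
  for (cc in conds)
    strata[[cc]] <- list(label = cc, conditions = cc, donors = NULL)
  if (length(conds) >= 2) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    for (p in pairs) {
      lab <- paste(p, collapse = "/")
      strata[[lab]] <- list(label = lab, conditions = p, donors = NULL)
    }
  }
  if (length(conds) >= 3)
    strata[["ALL"]] <- list(label = "ALL", conditions = NULL, donors = NULL)
  for (d in donors)
    strata[[d]] <- list(label = d, conditions = NULL, donors = d)
  strata
}

#' Run the stability pipeline over strata
#'
#' For every stratum: subset the Ct matrix, run the four stability
#' algorithms and build the geometric-mean consensus. A stratum that fails
#' an algorithm's preconditions (too few genes or samples) is logged to
#' stderr and skipped; the run continues. Per-stratum gene and sample
#' counts are logged.
#'
#' @param x a [ct_matrix()].
#' @param strata list of stratum definitions as from [study_strata()]
#'   (default), or a custom list of `list(label, conditions, donors)`.
#' @param genes genes to analyse (the housekeeping candidates); default:
#'   genes with role `"hkg"` if `x` carries generator roles, else all.
#' @param out_dir optional directory; when given, each stratum's consensus
#'   is written as `stability_<label>.csv` and `stability_<label>.json`
#'   (`/` in labels becomes `-`).
#' @param normfinder_groups,bestkeeper_dispersion passed through to the
#'   algorithms.
#' @param quiet suppress progress logging.
#' @return named list of `consensus_ranking` objects (failed strata are
#'   absent); attribute `errors` maps failed stratum labels to condition
#'   messages, attribute `tables` holds the per-stratum stability tables.
#' @export
run_stability <- function(x, strata = study_strata(x), genes = NULL,
                          out_dir = NULL, normfinder_groups = NULL,
                          bestkeeper_dispersion = c("mad", "sd"),
                          quiet = FALSE) {
  stopifnot(inherits(x, "ct_matrix"))
  bestkeeper_dispersion <- match.arg(bestkeeper_dispersion)
  if (is.null(genes)) {
    roles <- attr(x, "roles")
    genes <- if (!is.null(roles)) names(roles)[roles == "hkg"]
             else rownames(x$ct)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log <- function(...) if (!quiet) message(...)
  rankings <- list()
  tables <- list()
  errors <- character(0)
  for (s in strata) {
    res <- tryCatch({
      sub <- subset(x, conditions = s$conditions, donors = s$donors,
                    genes = genes)
      log("stratum ", s$label, ": ", nrow(sub$ct), " genes x ",
          ncol(sub$ct), " samples")
      stability_analysis(sub, stratum = s$label,
                         normfinder_groups = normfinder_groups,
                         bestkeeper_dispersion = bestkeeper_dispersion)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log("stratum ", s$label, " failed: ", conditionMessage(res))
      errors[s$label] <- conditionMessage(res)
      next
    }
    rankings[[s$label]] <- res$consensus
    tables[[s$label]] <- res$tables
    if (!is.null(out_dir)) {
      stem <- file.path(out_dir,
                        paste0("stability_", gsub("/", "-", s$label)))
      write_consensus_csv(res$consensus, paste0(stem, ".csv"))
      write_consensus_json(res$consensus, paste0(stem, ".json"))
    }
  }
  attr(rankings, "errors") <- errors
  attr(rankings, "tables") <- tables
  rankings
}

#' Run the normalizer-impact analysis from consensus rankings
#'
#' For each condition comparison, picks the best (consensus position 1)
#' and worst (last position) housekeeping gene from the ranking of the
#' corresponding condition-pair stratum and produces a
#' [merged_condition_report()] for the target genes.
#'
#' @param x a [ct_matrix()] containing targets and housekeeping genes.
#' @param rankings named list of `consensus_ranking`s as returned by
#'   [run_stability()]; must contain the pair stratum of every comparison
#'   (label `"<ref>/<num>"` or `"<num>/<ref>"`).
#' @param targets target gene symbols; default: genes with role
#'   `"target"` if `x` carries generator roles.
#' @param comparisons list of character(2) `c(numerator, reference)`
#'   condition pairs; default: every condition against the first-seen
#'   condition plus remaining pairs, matching the strata available.
#' @param threshold worst/best flag threshold.
#' @param out_dir optional directory for `normeffect_<num>_vs_<ref>.csv`
#'   (per-donor grid) and `..._merged.csv` reports.
#' @return named list of `norm_effect_report`s, one per comparison
#'   (`"<num>_vs_<ref>"`).
#' @export
run_normeffect <- function(x, rankings, targets = NULL, comparisons = NULL,
                           threshold = 2, out_dir = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (is.null(targets)) {
    roles <- attr(x, "roles")
    if (is.null(roles))
      stop("`targets` must be given when the matrix carries no gene roles",
           call. = FALSE)
    targets <- names(roles)[roles == "target"]
  }
  conds <- unique(x$samples$condition)
  if (is.null(comparisons)) {
    if (length(conds) < 2)
      stop("need at least two conditions for a comparison", call. = FALSE)
    comparisons <- lapply(utils::combn(conds, 2, simplify = FALSE), rev)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  reports <- list()
  for (cmp in comparisons) {
    lab_candidates <- c(paste(cmp[2], cmp[1], sep = "/"),
                        paste(cmp[1], cmp[2], sep = "/"))
    lab <- intersect(lab_candidates, names(rankings))
    if (!length(lab))
      stop("no consensus ranking available for stratum ",
           lab_candidates[1], call. = FALSE)
    cr <- rankings[[lab[1]]]
    best <- cr$gene[1]
    worst <- cr$gene[nrow(cr)]
    rep <- merged_condition_report(x, targets, best_hkg = best,
                                   worst_hkg = worst, comparison = cmp,
                                   threshold = threshold)
    key <- paste0(cmp[1], "_vs_", cmp[2])
    reports[[key]] <- rep
    if (!is.null(out_dir)) {
      utils::write.csv(rep$per_donor,
                       file.path(out_dir, paste0("normeffect_", key, ".csv")),
                       row.names = FALSE)
      utils::write.csv(rep$merged,
                       file.path(out_dir,
                                 paste0("normeffect_", key, "_merged.csv")),
                       row.names = FALSE)
    }
  }
  reports
}

#' Write a consensus ranking as a report-style CSV
#'
#' One row per gene in final order: `gene`, `geomean` (2 decimals, as such
#' tables are conventionally printed), then rank and value per algorithm.
#' Full precision is preserved in the JSON twin ([write_consensus_json()]).
#'
#' @param cr a `consensus_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(cr, path) {
  stopifnot(inherits(cr, "consensus_ranking"))
  out <- as.data.frame(cr)
  out$geomean <- sprintf("%.2f", out$geomean)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a consensus ranking as JSON (full precision)
#'
#' @param cr a `consensus_ranking`.
#' @param path file path.
#' @return `write_consensus_json` returns `path` invisibly;
#'   `read_consensus_json` returns the `consensus_ranking`.
#' @export
write_consensus_json <- function(cr, path) {
  stopifnot(inherits(cr, "consensus_ranking"))
  obj <- list(stratum = attr(cr, "stratum"),
              ranking = as.data.frame(cr))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_consensus_json
#' @export
read_consensus_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(obj$ranking, stringsAsFactors = FALSE)
  int_cols <- c(paste0("rank_", CONSENSUS_ALGORITHMS), "final_position")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  for (cc in paste0("value_", CONSENSUS_ALGORITHMS))
    df[[cc]] <- as.numeric(df[[cc]])
  structure(df, class = c("consensus_ranking", "data.frame"),
            stratum = if (is.null(obj$stratum)) NA_character_ else obj$stratum)
}
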