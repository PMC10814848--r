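#' Delta-delta-Ct fold change for one donor
#'
#' Classic relative quantification: within each condition the target gene's
#' Ct is referenced to the chosen housekeeping gene
#' (\eqn{\Delta Ct = Ct_{target} - Ct_{hkg}}), and the fold change between
#' the numerator and reference condition is
#' \eqn{FC = E^{-(\Delta Ct_{num} - \Delta Ct_{ref})}}. With per-gene
#' efficiencies the target and normalizer contributions use their own `E`
#' (Pfaffl form); under the default `E = 2` everywhere this reduces to
#' \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param x a [ct_matrix()] containing target and normalizer genes.
#' @param target target gene symbol.
#' @param hkg housekeeping (normalizer) gene symbol; must differ from
#'   `target`.
#' @param comparison character(2): `c(numerator_condition,
#'   reference_condition)`.
#' @param donor donor label; the donor must contribute exactly one sample
#'   in each of the two conditions.
#' @return a single positive fold change.
#' @export
fold_change <- function(x, target, hkg, comparison, donor) {
  stopifnot(inherits(x, "ct_matrix"), length(comparison) == 2)
  if (identical(target, hkg))
    stop("target and normalizer must be different genes", call. = FALSE)
  for (g in c(target, hkg))
    if (!g %in% rownames(x$ct))
      stop("unknown gene: ", g, call. = FALSE)
  cell <- function(gene, cond) {
    j <- which(x$samples$donor == donor & x$samples$condition == cond)
    if (length(j) != 1L)
      stop("donor ", donor, " has ", length(j), " sample(s) in condition ",
           cond, " (need exactly 1)", call. = FALSE)
    x$ct[gene, j]
  }
  e_t <- x$efficiency[[target]]
  e_h <- x$efficiency[[hkg]]
  # target and normalizer each amplify with their own efficiency
  num <- e_t^-(cell(target, comparison[1]) - cell(target, comparison[2]))
  den <- e_h^-(cell(hkg, comparison[1]) - cell(hkg, comparison[2]))
  num / den
}

#' Per-donor fold changes of one target under one normalizer
#'
#' @inheritParams fold_change
#' @param donors donors to include; default all donors present in both
#'   conditions.
#' @return data.frame of class `fold_change_set` with columns `donor`,
#'   `fc`; attributes `target`, `hkg`, `comparison`.
#' @export
fold_change_set <- function(x, target, hkg, comparison, donors = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  in_cond <- function(cond) unique(x$samples$donor[x$samples$condition == cond])
  both <- intersect(in_cond(comparison[1]), in_cond(comparison[2]))
  if (is.null(donors)) donors <- both
  missing_d <- setdiff(donors, both)
  if (length(missing_d))
    stop("donor(s) not present in both conditions: ",
         paste(missing_d, collapse = ", "), call. = FALSE)
  if (!length(donors))
    stop("no donor present in both conditions", call. = FALSE)
  fc <- vapply(donors, function(d) fold_change(x, target, hkg, comparison, d),
               numeric(1))
  structure(data.frame(donor = donors, fc = as.numeric(fc),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("fold_change_set", "data.frame"),
            target = target, hkg = hkg, comparison = comparison)
}

#' Worst/best normalizer fold-change ratios
#'
#' The apparent-difference artifact: for each donor, the ratio of the fold
#' change obtained with the worst normalizer to the one obtained with the
#' best. Algebraically the target's own Ct values cancel, so the ratio
#' depends only on how differently the two normalizers moved between the
#' conditions. Ratios at or above `threshold` (default 2) are flagged as
#' liable to change the biological conclusion.
#'
#' @param fc_best,fc_worst two [fold_change_set()]s for the same target and
#'   comparison, covering the same donors.
#' @param threshold flag ratios `>= threshold`.
#' @return data.frame with columns `donor`, `fc_best`, `fc_worst`,
#'   `wb_ratio`, `flagged`.
#' @export
wb_ratio <- function(fc_best, fc_worst, threshold = 2) {
  stopifnot(inherits(fc_best, "fold_change_set"),
            inherits(fc_worst, "fold_change_set"))
  if (!identical(attr(fc_best, "target"), attr(fc_worst, "target")) ||
      !identical(attr(fc_best, "comparison"), attr(fc_worst, "comparison")))
    stop("fold-change sets describe different targets or comparisons",
         call. = FALSE)
  if (!setequal(fc_best$donor, fc_worst$donor))
    stop("fold-change sets cover different donors", call. = FALSE)
  fw <- fc_worst$fc[match(fc_best$donor, fc_worst$donor)]
  ratio <- fw / fc_best$fc
  data.frame(donor = fc_best$donor, fc_best = fc_best$fc, fc_worst = fw,
             wb_ratio = ratio, flagged = ratio >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-sample t-test of fold changes against 1
#'
#' Tests whether fold changes differ from no-change: two-sided one-sample
#' t-test with hypothetical mean 1, i.e. \eqn{t = (\bar{FC} - 1)/(SD/\sqrt
#' n)} on `n - 1` degrees of freedom. Testing raw fold changes against 1 is
#' the convention followed here (fidelity to common qPCR practice); a
#' log2-scale variant testing `mean(log2 FC) = 0`, statistically preferable
#' because fold changes are ratio-scaled, is available via
#' `log_scale = TRUE` and is *not* the default.
#'
#' Degenerate inputs: zero SD with mean equal to the null gives `t = 0, p =
#' 1`; zero SD with mean different from the null is reported as `p = 0`
#' with a warning (the test statistic is unbounded).
#'
#' @param fold_changes positive fold changes, `n >= 2`.
#' @param log_scale test `log2(fold_changes)` against 0 instead.
#' @return list with `t`, `df`, `p_value`, `mean`, `sd`, `n`, `tier`
#'   (significance label from [significance_tier()]).
#' @export
one_sample_t_vs_unity <- function(fold_changes, log_scale = FALSE) {
  fc <- as.numeric(fold_changes)
  if (length(fc) < 2)
    stop("need at least 2 fold changes for a t-test", call. = FALSE)
  if (any(fc <= 0)) stop("fold changes must be positive", call. = FALSE)
  y <- if (log_scale) log2(fc) else fc
  mu <- if (log_scale) 0 else 1
  n <- length(y)
  m <- mean(y)
  s <- stats::sd(y)
  if (s == 0) {
    if (m == mu) {
      t <- 0; p <- 1
    } else {
      warning("zero variance with mean != ", mu,
              ": p-value reported as 0", call. = FALSE)
      t <- sign(m - mu) * Inf; p <- 0
    }
  } else {
    t <- (m - mu) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1, p_value = p, mean = m, sd = s, n = n,
       tier = significance_tier(p))
}

#' Significance tier labels
#'
#' Conventional star notation: `ns` for p > 0.05, then `*`, `**`, `***`,
#' `****` at 0.05, 0.01, 0.001 and 0.0001.
#'
#' @param p p-value(s).
#' @return character vector of tier labels.
#' @export
significance_tier <- function(p) {
  cut_points <- c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf)
  labels <- c("****", "***", "**", "*", "ns")
  as.character(cut(p, breaks = cut_points, labels = labels, right = TRUE))
}

#' Normalizer-choice impact report for one condition comparison
#'
#' For each target gene, computes per-donor fold changes between two
#' conditions under the best and the worst normalizer, their worst/best
#' ratios with flags, and merged-donor statistics: arithmetic and geometric
#' mean fold change and the one-sample t-test against 1 under each
#' normalizer. Also reports the condition-level worst/best ratio (geometric
#' mean of the per-donor ratios across donors, per target and overall).
#'
#' @param x a [ct_matrix()].
#' @param targets character vector of target gene symbols.
#' @param best_hkg,worst_hkg normalizer gene symbols (typically the top and
#'   bottom genes of the consensus ranking for this comparison's stratum).
#' @param comparison character(2): numerator condition, reference condition.
#' @param threshold worst/best flag threshold (default 2).
#' @return list of class `norm_effect_report`: `per_donor` (data.frame
#'   `target`, `donor`, `fc_best`, `fc_worst`, `wb_ratio`, `flagged`),
#'   `merged` (per target: means, t, p, tier under best and worst),
#'   `wb_geomean` (per target) and `wb_geomean_overall`; attributes record
#'   the comparison and normalizer choices.
#' @export
merged_condition_report <- function(x, targets, best_hkg, worst_hkg,
                                    comparison, threshold = 2) {
  stopifnot(inherits(x, "ct_matrix"))
  per_donor <- NULL
  merged <- NULL
  wb_geo <- stats::setNames(numeric(0), character(0))
  for (tg in targets) {
    fb <- fold_change_set(x, tg, best_hkg, comparison)
    fw <- fold_change_set(x, tg, worst_hkg, comparison)
    wb <- wb_ratio(fb, fw, threshold = threshold)
    per_donor <- rbind(per_donor,
                       cbind(data.frame(target = tg, stringsAsFactors = FALSE),
                             wb))
    tb <- one_sample_t_vs_unity(fb$fc)
    tw <- one_sample_t_vs_unity(fw$fc)
    merged <- rbind(merged, data.frame(
      target = tg, n = tb$n,
      mean_fc_best = mean(fb$fc), geomean_fc_best = exp(mean(log(fb$fc))),
      t_best = tb$t, p_best = tb$p_value, tier_best = tb$tier,
      mean_fc_worst = mean(fw$fc), geomean_fc_worst = exp(mean(log(fw$fc))),
      t_worst = tw$t, p_worst = tw$p_value, tier_worst = tw$tier,
      stringsAsFactors = FALSE, row.names = NULL))
    wb_geo[tg] <- exp(mean(log(wb$wb_ratio)))
  }
  structure(list(per_donor = per_donor, merged = merged,
                 wb_geomean = wb_geo,
                 wb_geomean_overall = exp(mean(log(per_donor$wb_ratio)))),
            class = "norm_effect_report",
            comparison = comparison, best_hkg = best_hkg,
            worst_hkg = worst_hkg, threshold = threshold)
}

#' @export
print.norm_effect_report <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat("<norm_effect_report> ", cmp[1], " vs ", cmp[2],
      "  (best: ", attr(x, "best_hkg"), ", worst: ", attr(x, "worst_hkg"),
      ")\n", sep = "")
  cat("per-donor worst/best ratios (flag >= ", attr(x, "threshold"), "):\n",
      sep = "")
  print(x$per_donor, row.names = FALSE, digits = 3)
  cat("merged-donor tests of FC vs 1:\n")
  print(x$merged, row.names = FALSE, digits = 3)
  cat(sprintf("condition-level W/B geometric mean: %.2f\n",
              x$wb_geomean_overall))
  invisible(x)
}
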