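#' @title Stability tables
#' @description Every stability algorithm returns a `stability_table`: a
#'   data.frame with columns `algorithm`, `gene`, `value` (the algorithm's
#'   stability statistic, lower = more stable, always >= 0) and `rank`
#'   (ascending competition rank on the unrounded values; geNorm ranks are
#'   structural, see [genorm_rank()]). Algorithm-specific extras are kept in
#'   attributes.
#' @param algorithm one of `"delta_ct"`, `"bestkeeper"`, `"normfinder"`,
#'   `"genorm"`.
#' @param genes,values,ranks parallel vectors; `ranks` defaults to
#'   [assign_ranks()] on `values`.
#' @return data.frame of class `stability_table`.
#' @keywords internal
stability_table <- function(algorithm, genes, values, ranks = NULL) {
  algorithm <- match.arg(algorithm,
                         c("delta_ct", "bestkeeper", "normfinder", "genorm"))
  if (is.null(ranks)) ranks <- assign_ranks(values)
  stopifnot(length(genes) == length(values), length(genes) == length(ranks))
  if (any(values < 0 & !is.na(values)))
    stop("stability values must be non-negative", call. = FALSE)
  structure(
    data.frame(algorithm = algorithm, gene = as.character(genes),
               value = as.numeric(values), rank = as.integer(ranks),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("stability_table", "data.frame"))
}

check_arity <- function(x, min_genes, min_samples, what) {
  if (nrow(x$ct) < min_genes)
    stop(what, " requires at least ", min_genes, " genes (got ", nrow(x$ct),
         ")", call. = FALSE)
  if (ncol(x$ct) < min_samples)
    stop(what, " requires at least ", min_samples, " samples (got ",
         ncol(x$ct), ")", call. = FALSE)
}

#' geNorm expression-stability measure M
#'
#' For gene *g*, `M_g` is the average over all other candidates *h* of the
#' sample standard deviation of the pairwise log2 expression ratio
#' `log2(q_g / q_h)` across samples (n-1 denominator). A perfectly
#' co-regulated pair has a constant ratio and hence contributes 0. Genes
#' with `M < 1.5` carry a conventional "stable" flag.
#'
#' @param x a [ct_matrix()] with >= 2 genes and >= 2 samples.
#' @return named numeric vector of M-values with a logical attribute
#'   `stable` (`M < 1.5`).
#' @seealso [genorm_rank()] for the stepwise-exclusion ranking.
#' @export
genorm_m <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  check_arity(x, 2, 2, "geNorm")
  a <- log2_quantity(x)
  G <- nrow(a)
  m <- vapply(seq_len(G), function(g) {
    mean(vapply(setdiff(seq_len(G), g),
                function(h) stats::sd(a[g, ] - a[h, ]), numeric(1)))
  }, numeric(1))
  names(m) <- rownames(a)
  attr(m, "stable") <- m < 1.5
  m
}

#' geNorm ranking by stepwise exclusion
#'
#' Repeatedly removes the gene with the highest M-value and recomputes M on
#' the remainder until two genes are left. Those two form the structurally
#' tied most-stable pair (the pairwise ratio cannot separate them) and both
#' receive rank 1; the next gene receives rank 3 and the rest follow the
#' reverse exclusion order. The reported value per gene is its M at the
#' round of its exclusion (for the final pair, their common M in the
#' two-gene round). Exact ties for worst M are broken by excluding the
#' first such gene in matrix order (deterministic).
#'
#' @param x a [ct_matrix()] with >= 3 genes.
#' @return A `stability_table` for algorithm `"genorm"` with attributes
#'   `exclusion_order` (first-excluded first), `final_pair` (character(2)),
#'   and `m_all` (the all-genes-in M vector from [genorm_m()]).
#' @export
genorm_rank <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  check_arity(x, 3, 2, "geNorm stepwise exclusion")
  genes <- rownames(x$ct)
  m_all <- genorm_m(x)
  value <- stats::setNames(rep(NA_real_, length(genes)), genes)
  excluded <- character(0)
  remaining <- genes
  while (length(remaining) > 2) {
    m <- genorm_m(subset(x, genes = remaining))
    worst <- names(m)[which.max(m)]
    value[worst] <- m[[worst]]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  m_final <- genorm_m(subset(x, genes = remaining))
  value[remaining] <- m_final[remaining]
  rank <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  rank[remaining] <- 1L
  # reverse exclusion order: last excluded -> rank 3, first excluded -> rank G
  if (length(excluded))
    rank[rev(excluded)] <- seq(3L, length.out = length(excluded))
  tab <- stability_table("genorm", genes, value[genes], rank[genes])
  attr(tab, "exclusion_order") <- excluded
  attr(tab, "final_pair") <- remaining
  attr(tab, "m_all") <- m_all
  tab
}

#' NormFinder model-based stability value
#'
#' Fits the additive model \eqn{y_{gs} = \alpha_g + \beta_s + \epsilon_{gs}}
#' to log2 relative quantities by double centering and estimates each
#' gene's residual variance with a bias correction that accounts for the
#' other candidates' noise leaking into the row/column means: with
#' \eqn{s_g^2 = \sum_s r_{gs}^2/(n-1)} and
#' \eqn{\hat T = \frac{G}{G-1}\sum_h s_h^2}, the gene variance is
#' \eqn{\hat\sigma_g^2 = \max(0, \frac{G}{G-2}(s_g^2 - \hat T/G^2))} and the
#' stability value is \eqn{\hat\sigma_g}. This ungrouped estimator is the
#' default even when condition labels exist, because strata as small as one
#' condition leave no grouping structure; the grouped variant (intragroup
#' variance plus shrunken absolute intergroup deviation) is explicit opt-in
#' via `groups`.
#'
#' @param x a [ct_matrix()] with >= 3 genes (the variance decomposition
#'   needs G >= 3) and >= 2 samples.
#' @param groups optional character vector naming the metadata column to
#'   group by (`"condition"` or `"donor"`), or a factor/vector of length
#'   `ncol(x$ct)`. `NULL` (default) = ungrouped.
#' @return A `stability_table` for algorithm `"normfinder"`. In grouped
#'   mode, attributes `intergroup` (genes x groups matrix of shrunken group
#'   deviations) and `intragroup_sd` (genes x groups) are attached.
#' @export
normfinder_stability <- function(x, groups = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  check_arity(x, 3, 2, "NormFinder")
  y <- log2_quantity(x)
  if (is.null(groups)) {
    stab <- sqrt(normfinder_var_ungrouped(y))
    return(stability_table("normfinder", rownames(y), stab))
  }
  if (is.character(groups) && length(groups) == 1L &&
      groups %in% c("condition", "donor"))
    groups <- x$samples[[groups]]
  if (length(groups) != ncol(y))
    stop("`groups` must have one label per sample", call. = FALSE)
  g <- factor(groups)
  sizes <- table(g)
  if (any(sizes < 2))
    stop("degenerate group(s) of size < 2: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  G <- nrow(y)
  lev <- levels(g)
  sig2 <- matrix(NA_real_, G, length(lev), dimnames = list(rownames(y), lev))
  dmat <- sig2
  grand_gene <- rowMeans(y)
  grand <- mean(y)
  for (a in seq_along(lev)) {
    ya <- y[, g == lev[a], drop = FALSE]
    sig2[, a] <- normfinder_var_ungrouped(ya)
    # intergroup deviation of gene g in group a (sums to 0 over genes)
    dmat[, a] <- (rowMeans(ya) - grand_gene) - (mean(ya) - grand)
  }
  n_a <- as.numeric(sizes[lev])
  dtil <- dmat
  for (a in seq_along(lev)) {
    gam2 <- max(0, sum(dmat[, a]^2) / (G - 1) - mean(sig2[, a]) / n_a[a])
    denom <- gam2 + sig2[, a] / n_a[a]
    shrink <- ifelse(denom > 0, gam2 / denom, 0)
    dtil[, a] <- dmat[, a] * shrink
  }
  intra_se <- sweep(sqrt(sig2), 2, sqrt(n_a), "/")
  stab <- rowMeans(abs(dtil) + intra_se)
  tab <- stability_table("normfinder", rownames(y), stab)
  attr(tab, "intergroup") <- dtil
  attr(tab, "intragroup_sd") <- sqrt(sig2)
  tab
}

# Bias-corrected per-gene variance of the additive gene + sample model,
# truncated at zero. y: genes x samples log2 quantities.
normfinder_var_ungrouped <- function(y) {
  G <- nrow(y); n <- ncol(y)
  if (G < 3) stop("NormFinder requires at least 3 genes", call. = FALSE)
  if (n < 2) stop("NormFinder requires at least 2 samples", call. = FALSE)
  r <- sweep(y, 1, rowMeans(y))
  r <- sweep(r, 2, colMeans(r))
  s2 <- rowSums(r^2) / (n - 1)
  t_hat <- G / (G - 1) * sum(s2)
  pmax(0, G / (G - 2) * (s2 - t_hat / G^2))
}

#' BestKeeper descriptive stability statistics
#'
#' Per-gene descriptives of raw Ct: geometric mean, arithmetic mean, min,
#' max, the BestKeeper dispersion statistic `SD[+/- Ct]`, and `CV[%]` =
#' 100 * SD / arithmetic mean. The original BestKeeper applet reports the
#' *mean absolute deviation* from the mean Ct as its "SD"; that MAD dialect
#' is the default, with the conventional sample SD available via
#' `dispersion = "sd"` (both are always tabulated). The BestKeeper index is
#' the per-sample geometric mean of Ct across genes; each gene's Pearson
#' correlation with the index is reported. Ranking uses the dispersion
#' statistic only (higher dispersion = less stable).
#'
#' @param x a [ct_matrix()] with >= 2 genes; correlations need >= 3 samples.
#' @param dispersion `"mad"` (applet dialect, default) or `"sd"`.
#' @return A `stability_table` for algorithm `"bestkeeper"` with attributes
#'   `descriptives` (full per-gene table: `geo_mean`, `ar_mean`, `min_ct`,
#'   `max_ct`, `sd_mad`, `sd_sample`, `cv_pct`, `r_index`) and `index`
#'   (per-sample geometric-mean Ct).
#' @export
bestkeeper <- function(x, dispersion = c("mad", "sd")) {
  stopifnot(inherits(x, "ct_matrix"))
  dispersion <- match.arg(dispersion)
  check_arity(x, 2, 2, "BestKeeper")
  ct <- x$ct
  n <- ncol(ct)
  ar_mean <- rowMeans(ct)
  geo_mean <- exp(rowMeans(log(ct)))
  sd_mad <- rowMeans(abs(ct - ar_mean))
  sd_sample <- apply(ct, 1, stats::sd)
  disp <- if (dispersion == "mad") sd_mad else sd_sample
  cv_pct <- 100 * disp / ar_mean
  index <- exp(colMeans(log(ct)))
  r_index <- rep(NA_real_, nrow(ct))
  if (n >= 3) {
    const <- sd_sample == 0 | stats::sd(index) == 0
    if (any(const))
      warning("constant gene or index: BestKeeper correlation undefined for ",
              paste(rownames(ct)[const], collapse = ", "), call. = FALSE)
    r_index[!const] <- vapply(which(!const),
                              function(g) stats::cor(ct[g, ], index),
                              numeric(1))
  } else {
    warning("fewer than 3 samples: BestKeeper index correlations not computed",
            call. = FALSE)
  }
  tab <- stability_table("bestkeeper", rownames(ct), disp)
  attr(tab, "descriptives") <- data.frame(
    gene = rownames(ct), geo_mean = geo_mean, ar_mean = ar_mean,
    min_ct = apply(ct, 1, min), max_ct = apply(ct, 1, max),
    sd_mad = sd_mad, sd_sample = sd_sample, cv_pct = cv_pct,
    r_index = r_index, stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "index") <- index
  attr(tab, "dispersion") <- dispersion
  tab
}

#' Comparative delta-Ct stability
#'
#' For every unordered pair of genes (g, h), the per-sample Ct difference
#' `Ct_g - Ct_h` is formed and its sample SD taken across samples; gene g's
#' stability is the mean of these SDs over all partners h. A gene whose Ct
#' moves in lockstep with every other candidate scores 0.
#'
#' @param x a [ct_matrix()] with >= 2 genes and >= 2 samples.
#' @return A `stability_table` for algorithm `"delta_ct"`.
#' @export
delta_ct_stability <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  check_arity(x, 2, 2, "comparative delta-Ct")
  ct <- x$ct
  G <- nrow(ct)
  s <- vapply(seq_len(G), function(g) {
    mean(vapply(setdiff(seq_len(G), g),
                function(h) stats::sd(ct[g, ] - ct[h, ]), numeric(1)))
  }, numeric(1))
  stability_table("delta_ct", rownames(ct), s)
}

#' Serialize a stability table to CSV
#'
#' Columns: `algorithm`, `gene`, `value`, `rank`, `tied_best_pair` (geNorm
#' structural pair flag, `FALSE` elsewhere).
#'
#' @param tab a `stability_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(tab, path) {
  stopifnot(inherits(tab, "stability_table"))
  out <- as.data.frame(tab)
  pair <- attr(tab, "final_pair")
  out$tied_best_pair <- if (is.null(pair)) FALSE else out$gene %in% pair
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
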