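#' Construct a Ct matrix with per-sample annotations
#'
#' The central container of the package: a genes x samples grid of
#' quantification-cycle (Ct) values plus per-sample metadata (donor and
#' culture condition) and per-gene amplification efficiencies.
#'
#' Ct values are PCR cycle numbers: lower Ct means more transcript, and
#' expression scales as \eqn{E^{-Ct}} where \eqn{E} is the amplification
#' efficiency (2 for perfect doubling). All downstream stability algorithms
#' assume a complete grid, so validation is strict by default; in permissive
#' mode samples carrying any missing Ct are dropped listwise (for every
#' gene), never imputed.
#'
#' @param ct numeric matrix of Ct values, genes in rows (rownames = gene
#'   symbols), samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `donor`, `condition`;
#'   one row per column of `ct`, in the same order.
#' @param efficiency per-gene amplification efficiency, a scalar (recycled)
#'   or a vector named by gene. Must lie in (1, 2]. Default 2 (perfect
#'   doubling, the implicit convention when raw SYBR Ct values are analysed
#'   directly).
#' @param max_ct upper validity bound for Ct values in cycles (common
#'   instrument maximum 45).
#' @param strict if `TRUE` (default) any missing Ct is an error; if `FALSE`
#'   samples with missing values are dropped with a warning.
#' @return An object of class `ct_matrix`: a list with elements `ct`
#'   (numeric matrix), `samples` (data.frame) and `efficiency` (named
#'   numeric vector).
#' @examples
#' ct <- matrix(c(10, 11, 12, 13), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("GAPDH", "TBP"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"),
#'                    donor = c("D1", "D2"), condition = "FBS")
#' ct_matrix(ct, meta)
#' @export
ct_matrix <- function(ct, samples, efficiency = 2, max_ct = 45, strict = TRUE) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must carry gene symbols as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(ct)))
    stop("duplicate gene symbols in `ct`", call. = FALSE)
  if (anyDuplicated(colnames(ct)))
    stop("duplicate sample ids in `ct`", call. = FALSE)

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor", "condition")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  samples <- samples[req]
  samples[] <- lapply(samples, as.character)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if (!identical(colnames(ct), samples$sample_id))
    stop("colnames(ct) and samples$sample_id must match in order",
         call. = FALSE)
  if (any(!nzchar(samples$donor)) || any(is.na(samples$donor)))
    stop("donor labels must be non-empty", call. = FALSE)
  if (any(!nzchar(samples$condition)) || any(is.na(samples$condition)))
    stop("condition labels must be non-empty", call. = FALSE)

  if (anyNA(ct)) {
    if (strict) {
      bad <- which(is.na(ct), arr.ind = TRUE)
      stop("missing Ct value for gene ", rownames(ct)[bad[1, 1]],
           ", sample ", colnames(ct)[bad[1, 2]],
           " (strict mode rejects incomplete grids)", call. = FALSE)
    }
    drop <- unique(which(is.na(ct), arr.ind = TRUE)[, 2])
    warning("dropping ", length(drop), " sample(s) with missing Ct values: ",
            paste(colnames(ct)[drop], collapse = ", "), call. = FALSE)
    keep <- setdiff(seq_len(ncol(ct)), drop)
    if (!length(keep))
      stop("no complete samples remain after listwise deletion", call. = FALSE)
    ct <- ct[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
    rownames(samples) <- NULL
  }

  out_of_range <- which(!(ct > 0 & ct <= max_ct), arr.ind = TRUE)
  if (nrow(out_of_range)) {
    stop("Ct value out of range (0, ", max_ct, "] for gene ",
         rownames(ct)[out_of_range[1, 1]], ", sample ",
         colnames(ct)[out_of_range[1, 2]], ": ",
         ct[out_of_range[1, , drop = FALSE]], call. = FALSE)
  }

  genes <- rownames(ct)
  if (length(efficiency) == 1L && is.null(names(efficiency)))
    efficiency <- stats::setNames(rep(as.numeric(efficiency), length(genes)),
                                  genes)
  if (is.null(names(efficiency)) || !all(genes %in% names(efficiency)))
    stop("`efficiency` must be a scalar or a vector named by gene",
         call. = FALSE)
  efficiency <- efficiency[genes]
  if (any(!(efficiency > 1 & efficiency <= 2)))
    stop("amplification efficiencies must lie in (1, 2]", call. = FALSE)

  structure(list(ct = ct, samples = samples, efficiency = efficiency),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("<ct_matrix> ", nrow(x$ct), " gene(s) x ", ncol(x$ct), " sample(s)\n",
      sep = "")
  cat("  genes:      ", paste(rownames(x$ct), collapse = ", "), "\n", sep = "")
  cat("  conditions: ", paste(unique(x$samples$condition), collapse = ", "),
      "\n", sep = "")
  cat("  donors:     ", paste(unique(x$samples$donor), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Subset a Ct matrix by condition, donor and/or gene
#'
#' Ordering of the retained genes and samples is preserved. Requesting an
#' unknown label is an error (a typo should never silently yield an empty
#' stratum), as is a selection that matches nothing.
#'
#' @param x a [ct_matrix()].
#' @param conditions,donors,genes character vectors of labels to keep;
#'   `NULL` keeps everything.
#' @param ... ignored.
#' @return A `ct_matrix` restricted to the selection.
#' @export
subset.ct_matrix <- function(x, conditions = NULL, donors = NULL,
                             genes = NULL, ...) {
  check_labels <- function(requested, known, what) {
    unknown <- setdiff(requested, known)
    if (length(unknown))
      stop("unknown ", what, " label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  keep <- rep(TRUE, ncol(x$ct))
  if (!is.null(conditions)) {
    check_labels(conditions, unique(x$samples$condition), "condition")
    keep <- keep & x$samples$condition %in% conditions
  }
  if (!is.null(donors)) {
    check_labels(donors, unique(x$samples$donor), "donor")
    keep <- keep & x$samples$donor %in% donors
  }
  gkeep <- rownames(x$ct)
  if (!is.null(genes)) {
    check_labels(genes, rownames(x$ct), "gene")
    gkeep <- rownames(x$ct)[rownames(x$ct) %in% genes]
  }
  if (!any(keep) || !length(gkeep))
    stop("empty selection: no samples/genes match the requested labels",
         call. = FALSE)
  ct_matrix(x$ct[gkeep, keep, drop = FALSE],
            x$samples[keep, , drop = FALSE],
            efficiency = x$efficiency[gkeep])
}

#' Read a Ct table from CSV
#'
#' Two dialects are supported. *Long*: one row per measurement with columns
#' `sample_id`, `donor`, `condition`, `gene`, `ct`. *Wide*: one row per gene
#' (first column `gene`, remaining columns one per sample, headed by sample
#' id) plus a sidecar metadata CSV with `sample_id`, `donor`, `condition` —
#' the layout qPCR instrument exports typically use. Gene and sample order
#' is preserved as first seen.
#'
#' @param path path to the CSV file.
#' @param format `"long"` or `"wide"`.
#' @param meta path to the sample-metadata CSV (wide format only).
#' @inheritParams ct_matrix
#' @return A validated [ct_matrix()].
#' @export
read_ct_table <- function(path, format = c("long", "wide"), meta = NULL,
                          efficiency = 2, max_ct = 45, strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "long") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    req <- c("sample_id", "donor", "condition", "gene", "ct")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("long-format file lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(df[c("gene", "sample_id")]))
      stop("duplicate (gene, sample) pair in ", path, call. = FALSE)
    meta_df <- unique(df[c("sample_id", "donor", "condition")])
    rownames(meta_df) <- NULL
    if (anyDuplicated(meta_df$sample_id))
      stop("sample_id annotated with conflicting donor/condition labels",
           call. = FALSE)
    genes <- unique(df$gene)
    sids <- meta_df$sample_id
    ctv <- parse_ct_values(df$ct, df$gene, df$sample_id, strict)
    m <- matrix(NA_real_, length(genes), length(sids),
                dimnames = list(genes, sids))
    m[cbind(match(df$gene, genes), match(df$sample_id, sids))] <- ctv
    # A (gene, sample) pair absent from the file leaves an NA: incomplete grid.
    absent <- which(is.na(m), arr.ind = TRUE)
    if (nrow(absent) && strict) {
      stop("no Ct row for gene ", genes[absent[1, 1]],
           ", sample ", sids[absent[1, 2]], call. = FALSE)
    }
    ct_matrix(m, meta_df, efficiency = efficiency, max_ct = max_ct,
              strict = strict)
  } else {
    if (is.null(meta))
      stop("wide format requires a `meta` sidecar CSV with sample annotations",
           call. = FALSE)
    if (!file.exists(meta)) stop("file not found: ", meta, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
    if (names(df)[1] != "gene")
      stop("wide-format file must have `gene` as its first column",
           call. = FALSE)
    if (anyDuplicated(df$gene))
      stop("duplicate gene row in ", path, call. = FALSE)
    md <- utils::read.csv(meta, stringsAsFactors = FALSE,
                          colClasses = "character")
    miss <- setdiff(c("sample_id", "donor", "condition"), names(md))
    if (length(miss))
      stop("metadata file lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    sids <- names(df)[-1]
    if (!setequal(sids, md$sample_id))
      stop("wide-table sample columns and metadata sample_id disagree",
           call. = FALSE)
    md <- md[match(sids, md$sample_id), , drop = FALSE]
    rownames(md) <- NULL
    genes <- df$gene
    m <- matrix(NA_real_, length(genes), length(sids),
                dimnames = list(genes, sids))
    for (j in seq_along(sids)) {
      m[, j] <- parse_ct_values(df[[sids[j]]], genes, rep(sids[j], length(genes)),
                                strict)
    }
    ct_matrix(m, md, efficiency = efficiency, max_ct = max_ct, strict = strict)
  }
}

# Coerce character Ct cells to numeric; in strict mode name the first
# offending (gene, sample) cell, whether non-numeric or NA.
parse_ct_values <- function(chr, gene, sample_id, strict) {
  v <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(v))
  if (length(bad) && strict) {
    stop("non-numeric or missing Ct value for gene ", gene[bad[1]],
         ", sample ", sample_id[bad[1]], ": \"", chr[bad[1]], "\"",
         call. = FALSE)
  }
  v
}

#' Write a Ct matrix to CSV
#'
#' Inverse of [read_ct_table()]. Ct values are printed with 17 significant
#' digits so a write/read round trip reproduces every double exactly.
#'
#' @param x a [ct_matrix()].
#' @param path output CSV path.
#' @param format `"long"` or `"wide"`.
#' @param meta output path for the metadata sidecar (wide format only).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, format = c("long", "wide"), meta = NULL) {
  format <- match.arg(format)
  fmt <- function(v) sprintf("%.17g", v)
  if (format == "long") {
    idx <- expand.grid(g = seq_len(nrow(x$ct)), s = seq_len(ncol(x$ct)))
    df <- data.frame(
      sample_id = x$samples$sample_id[idx$s],
      donor = x$samples$donor[idx$s],
      condition = x$samples$condition[idx$s],
      gene = rownames(x$ct)[idx$g],
      ct = fmt(x$ct[cbind(idx$g, idx$s)]),
      stringsAsFactors = FALSE)
    df <- df[order(idx$s, idx$g), ]
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    if (is.null(meta))
      stop("wide format requires a `meta` output path", call. = FALSE)
    df <- data.frame(gene = rownames(x$ct), stringsAsFactors = FALSE,
                     check.names = FALSE)
    for (j in seq_len(ncol(x$ct))) df[[colnames(x$ct)[j]]] <- fmt(x$ct[, j])
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    utils::write.csv(x$samples, meta, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Linear-scale relative quantities from Ct values
#'
#' Converts each gene's Ct values to relative quantities
#' \eqn{q_{gs} = E_g^{\,\mathrm{min}_s Ct_{gs} - Ct_{gs}}}, i.e. expression
#' relative to that gene's most abundant sample in the *current* matrix.
#' By construction every gene's maximum quantity is exactly 1 and all
#' quantities lie in (0, 1]. This is the input scale the NormFinder and
#' geNorm algorithms operate on.
#'
#' @param x a [ct_matrix()].
#' @return numeric matrix of quantities, same dimnames as `x$ct`.
#' @export
relative_quantity <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  mins <- apply(x$ct, 1, min)
  e <- x$efficiency[rownames(x$ct)]
  q <- e ^ (mins - x$ct)   # column-recycling over samples
  dimnames(q) <- dimnames(x$ct)
  q
}

# log2 quantities; equals (minCt - Ct) * log2(E), so exactly minCt - Ct
# under perfect doubling.
log2_quantity <- function(x) log2(relative_quantity(x))

#' Descriptive Ct statistics per gene and stratum
#'
#' Mean, sample SD and SEM (= SD/sqrt(n)) of Ct per gene, either over all
#' samples (`by = NULL`, stratum label `"ALL"`) or within groups defined by
#' one or more metadata columns (`"condition"`, `"donor"`).
#'
#' @param x a [ct_matrix()].
#' @param by `NULL` for a single all-samples stratum, or a character vector
#'   of metadata columns to group by.
#' @return data.frame with columns `gene`, `stratum`, `n`, `mean_ct`,
#'   `sd_ct`, `sem_ct`. Strata of size 1 carry `NA` SD/SEM with a warning.
#' @export
ct_summarize <- function(x, by = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  if (is.null(by)) {
    groups <- stats::setNames(list(seq_len(ncol(x$ct))), "ALL")
  } else {
    bad <- setdiff(by, c("condition", "donor"))
    if (length(bad))
      stop("unknown grouping column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    key <- do.call(paste, c(x$samples[by], sep = "/"))
    groups <- split(seq_len(ncol(x$ct)), factor(key, levels = unique(key)))
  }
  res <- do.call(rbind, lapply(names(groups), function(lab) {
    idx <- groups[[lab]]
    n <- length(idx)
    sub <- x$ct[, idx, drop = FALSE]
    sdv <- if (n > 1) apply(sub, 1, stats::sd) else rep(NA_real_, nrow(sub))
    data.frame(gene = rownames(x$ct), stratum = lab, n = n,
               mean_ct = rowMeans(sub), sd_ct = sdv, sem_ct = sdv / sqrt(n),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (any(res$n == 1))
    warning("stratum of size 1: SD and SEM undefined, reported as NA",
            call. = FALSE)
  res
}
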