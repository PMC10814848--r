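#' Synthetic Ct study configuration
#'
#' Describes a generative model for RT-qPCR Ct data with the structure of
#' a multi-donor, multi-condition reference-gene study:
#' \deqn{Ct_{gs} = baseline_g + shift_{g,c(s)} + donor_{d(s)} +
#'   \epsilon_{gs}, \quad \epsilon_{gs} \sim N(0, \sigma_g^2)}
#' Condition shifts are additive in Ct, i.e. multiplicative in expression,
#' matching delta-delta-Ct algebra; donor offsets are drawn once per donor
#' from \eqn{N(0, donor\_sd^2)} and shared across all of that donor's
#' samples and genes, which induces donor-dominant clustering of samples.
#'
#' @param genes data.frame with columns `gene`, `baseline` (mean Ct in
#'   (0, 45)), `noise_sd` (Ct cycles, >= 0) and `role` (`"hkg"` or
#'   `"target"`).
#' @param condition_shift numeric matrix of additive Ct shifts, genes x
#'   conditions (dimnames required; genes must match `genes$gene`). For a
#'   target gene a log2 fold change `f` relative to the reference condition
#'   corresponds to a Ct shift of `-f`.
#' @param donors character vector of donor labels.
#' @param donor_sd SD of the shared per-donor Ct offset (cycles).
#' @param seed integer seed; mandatory, every stochastic draw in
#'   [generate_ct()] derives from it.
#' @param noise one of `"gaussian"` (default) or `"student_t"`
#'   (heavier-tailed, 3 df, scaled to the configured SD) for robustness
#'   experiments.
#' @return list of class `synth_config`.
#' @seealso [default_study_config()] for the ready-made study emulation.
#' @export
synth_config <- function(genes, condition_shift, donors, donor_sd, seed,
                         noise = c("gaussian", "student_t")) {
  noise <- match.arg(noise)
  stopifnot(is.data.frame(genes),
            all(c("gene", "baseline", "noise_sd", "role") %in% names(genes)))
  if (any(genes$noise_sd < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  if (any(genes$baseline <= 0 | genes$baseline >= 45))
    stop("baseline Ct values must lie in (0, 45)", call. = FALSE)
  if (!all(genes$role %in% c("hkg", "target")))
    stop("gene roles must be \"hkg\" or \"target\"", call. = FALSE)
  if (!is.matrix(condition_shift) || is.null(dimnames(condition_shift)))
    stop("`condition_shift` must be a genes x conditions matrix with dimnames",
         call. = FALSE)
  if (!identical(rownames(condition_shift), genes$gene))
    stop("rownames(condition_shift) must equal genes$gene", call. = FALSE)
  if (donor_sd < 0) stop("donor offset SD must be >= 0", call. = FALSE)
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory for any stochastic draw", call. = FALSE)
  structure(list(genes = genes, condition_shift = condition_shift,
                 donors = as.character(donors), donor_sd = donor_sd,
                 seed = as.integer(seed), noise = noise),
            class = "synth_config")
}

#' Default configuration emulating the ASC culture-media study design
#'
#' Five housekeeping genes (ACTB, EF1A, GAPDH, RPLP0, TBP) with baseline
#' mean Ct values taken from the study's all-samples summary (12.72,
#' 10.19, 11.42, 11.07, 20.51 cycles) and per-condition shifts of a few
#' tenths of a cycle equal to the published per-condition means minus the
#' all-samples means; three culture conditions (FBS and the synthetic
#' media X1, X2); four donors (ASC1-ASC4) with a shared donor offset of SD
#' 0.3 Ct; per-gene Gaussian noise of SD 0.3 Ct. Three target genes (LIF,
#' CCL5, IL6) carry condition-dependent log2 fold shifts relative to FBS
#' (defaults: LIF mildly down, CCL5 mildly up, IL6 strongly down in the
#' synthetic media).
#'
#' @param seed integer seed (mandatory).
#' @param target_log2fc named list of numeric(2) log2 fold changes
#'   `c(X1, X2)` relative to FBS, one entry per target gene; the default
#'   mirrors the qualitative directions above.
#' @return a [synth_config()].
#' @export
default_study_config <- function(seed,
                                 target_log2fc = list(
                                   LIF = c(X1 = -1, X2 = -1.5),
                                   CCL5 = c(X1 = 0.5, X2 = 0.5),
                                   IL6 = c(X1 = -3, X2 = -4))) {
  hkg <- data.frame(
    gene = c("ACTB", "EF1A", "GAPDH", "RPLP0", "TBP"),
    baseline = c(12.72, 10.19, 11.42, 11.07, 20.51),
    noise_sd = 0.3, role = "hkg", stringsAsFactors = FALSE)
  # per-condition mean Ct minus all-samples mean Ct, in cycles
  hkg_shift <- rbind(
    ACTB  = c(FBS = -0.44, X1 = 0.08, X2 = 0.37),
    EF1A  = c(FBS = 0.23, X1 = -0.01, X2 = -0.21),
    GAPDH = c(FBS = 0.17, X1 = -0.07, X2 = -0.08),
    RPLP0 = c(FBS = 0.20, X1 = 0.01, X2 = -0.22),
    TBP   = c(FBS = 0.34, X1 = -0.23, X2 = -0.12))
  tg_names <- names(target_log2fc)
  tg <- data.frame(
    gene = tg_names,
    baseline = c(LIF = 16, CCL5 = 18, IL6 = 14)[tg_names],
    noise_sd = 0.3, role = "target", stringsAsFactors = FALSE)
  tg_shift <- t(vapply(target_log2fc, function(f)
    c(FBS = 0, X1 = -f[["X1"]], X2 = -f[["X2"]]), numeric(3)))
  genes <- rbind(hkg, tg)
  rownames(genes) <- NULL
  synth_config(genes = genes,
               condition_shift = rbind(hkg_shift, tg_shift),
               donors = paste0("ASC", 1:4),
               donor_sd = 0.3, seed = seed)
}

#' Generate a synthetic Ct matrix
#'
#' Draws one dataset from a [synth_config()]: for every donor x condition
#' sample, `Ct = baseline + condition shift + donor offset + noise`.
#' Deterministic given the config's seed (the RNG state of the session is
#' left untouched).
#'
#' @param config a [synth_config()].
#' @return a validated [ct_matrix()] with samples ordered condition-major
#'   (all donors of the first condition, then the second, ...) and sample
#'   ids `<donor>_<condition>`. The gene roles are kept in attribute
#'   `roles`.
#' @export
generate_ct <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- config$genes
  conditions <- colnames(config$condition_shift)
  grid <- expand.grid(donor = config$donors, condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  G <- nrow(genes)
  ct <- withr::with_seed(config$seed, {
    offsets <- stats::rnorm(length(config$donors), 0, config$donor_sd)
    names(offsets) <- config$donors
    eps <- switch(config$noise,
                  gaussian = matrix(stats::rnorm(G * n), G, n),
                  # t(3) rescaled to unit SD, then per-gene SD applied
                  student_t = matrix(stats::rt(G * n, df = 3) / sqrt(3), G, n))
    eps <- eps * genes$noise_sd
    base <- matrix(genes$baseline, G, n)
    shift <- config$condition_shift[, grid$condition, drop = FALSE]
    base + shift + matrix(offsets[grid$donor], G, n, byrow = TRUE) + eps
  })
  dimnames(ct) <- list(genes$gene, paste(grid$donor, grid$condition, sep = "_"))
  meta <- data.frame(sample_id = colnames(ct), donor = grid$donor,
                     condition = grid$condition, stringsAsFactors = FALSE)
  out <- ct_matrix(ct, meta)
  attr(out, "roles") <- stats::setNames(genes$role, genes$gene)
  out
}

#' Scale one gene's noise SD (instability spike-in)
#'
#' Returns a copy of the configuration in which the named gene's residual
#' noise SD is multiplied by `sd_multiplier` (>= 1). Used to plant a known
#' unstable candidate and check that all four algorithms demote it.
#'
#' @param config a [synth_config()].
#' @param gene gene symbol present in the config.
#' @param sd_multiplier multiplier >= 1 (1 leaves the config unchanged).
#' @return the modified [synth_config()].
#' @export
spiked_instability <- function(config, gene, sd_multiplier) {
  stopifnot(inherits(config, "synth_config"))
  if (!gene %in% config$genes$gene)
    stop("unknown gene: ", gene, call. = FALSE)
  if (!is.numeric(sd_multiplier) || sd_multiplier < 1)
    stop("sd_multiplier must be >= 1", call. = FALSE)
  i <- match(gene, config$genes$gene)
  config$genes$noise_sd[i] <- config$genes$noise_sd[i] * sd_multiplier
  config
}

#' Read/write a synthetic study configuration as YAML
#'
#' @param config a [synth_config()].
#' @param path YAML file path.
#' @return `write_synth_config` returns `path` invisibly;
#'   `read_synth_config` returns a [synth_config()].
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  obj <- list(
    genes = config$genes,
    conditions = colnames(config$condition_shift),
    condition_shift = stats::setNames(
      lapply(seq_len(nrow(config$condition_shift)),
             function(i) as.list(config$condition_shift[i, ])),
      rownames(config$condition_shift)),
    donors = config$donors,
    donor_sd = config$donor_sd,
    seed = config$seed,
    noise = config$noise)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  obj <- yaml::read_yaml(path)
  genes <- as.data.frame(obj$genes, stringsAsFactors = FALSE)
  shift <- do.call(rbind, lapply(obj$condition_shift, function(r)
    unlist(r)[obj$conditions]))
  colnames(shift) <- obj$conditions
  shift <- shift[genes$gene, , drop = FALSE]
  synth_config(genes = genes, condition_shift = shift, donors = obj$donors,
               donor_sd = obj$donor_sd, seed = obj$seed, noise = obj$noise)
}
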