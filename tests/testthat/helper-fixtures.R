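# Small programmatic fixtures shared across tests.

make_ct <- function(ct, conditions = NULL, donors = NULL, efficiency = 2) {
  n <- ncol(ct)
  if (is.null(colnames(ct))) colnames(ct) <- paste0("s", seq_len(n))
  if (is.null(rownames(ct))) rownames(ct) <- paste0("G", seq_len(nrow(ct)))
  if (is.null(conditions)) conditions <- rep("C1", n)
  if (is.null(donors)) donors <- paste0("D", seq_len(n))
  ct_matrix(ct, data.frame(sample_id = colnames(ct), donor = donors,
                           condition = conditions,
                           stringsAsFactors = FALSE),
            efficiency = efficiency)
}

rand_ct <- function(G, n, seed) {
  withr::with_seed(seed, {
    base <- runif(G, 8, 30)
    matrix(base + rnorm(G * n, sd = runif(G, 0.1, 1.5)), G, n,
           dimnames = list(paste0("G", seq_len(G)), paste0("s", seq_len(n))))
  })
}

# the worked 3 genes x 4 samples matrix used by several oracle checks
worked_3x4 <- function() {
  rbind(A = c(10, 10, 10, 10),
        B = c(11, 12, 11, 12),
        C = c(15, 14, 15, 16))
}

# standard study-shaped layout: 5 HKGs x (4 donors x 3 conditions)
study_matrix <- function(seed = 42) {
  generate_ct(default_study_config(seed = seed))
}

hkg_genes <- c("ACTB", "EF1A", "GAPDH", "RPLP0", "TBP")
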