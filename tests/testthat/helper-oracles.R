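# Independent brute-force oracles, written with explicit loops and no use
# of package internals. All assume amplification efficiency 2, under which
# log2 relative quantity equals (min Ct - Ct).

o_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))

oracle_genorm_m <- function(ct) {
  G <- nrow(ct)
  out <- numeric(G)
  for (g in seq_len(G)) {
    sds <- numeric(0)
    for (h in seq_len(G)) {
      if (h == g) next
      ratio <- (min(ct[g, ]) - ct[g, ]) - (min(ct[h, ]) - ct[h, ])
      sds <- c(sds, o_sd(ratio))
    }
    out[g] <- mean(sds)
  }
  names(out) <- rownames(ct)
  out
}

oracle_genorm_exclusion <- function(ct) {
  genes <- rownames(ct)
  remaining <- genes
  excluded <- character(0)
  values <- setNames(numeric(length(genes)), genes)
  while (length(remaining) > 2) {
    m <- oracle_genorm_m(ct[remaining, , drop = FALSE])
    worst <- remaining[which.max(m)]
    values[worst] <- m[[worst]]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  m2 <- oracle_genorm_m(ct[remaining, , drop = FALSE])
  values[remaining] <- m2
  ranks <- setNames(integer(length(genes)), genes)
  ranks[remaining] <- 1L
  k <- 3L
  for (g in rev(excluded)) { ranks[g] <- k; k <- k + 1L }
  list(excluded = excluded, final_pair = remaining, values = values,
       ranks = ranks)
}

oracle_delta_ct <- function(ct) {
  G <- nrow(ct)
  out <- numeric(G)
  for (g in seq_len(G)) {
    sds <- numeric(0)
    for (h in seq_len(G)) {
      if (h == g) next
      sds <- c(sds, o_sd(ct[g, ] - ct[h, ]))
    }
    out[g] <- mean(sds)
  }
  names(out) <- rownames(ct)
  out
}

oracle_normfinder <- function(ct) {
  G <- nrow(ct); n <- ncol(ct)
  y <- ct
  for (g in seq_len(G)) y[g, ] <- min(ct[g, ]) - ct[g, ]
  rm_ <- numeric(G); cm_ <- numeric(n)
  for (g in seq_len(G)) rm_[g] <- mean(y[g, ])
  for (s in seq_len(n)) cm_[s] <- mean(y[, s])
  gm <- mean(y)
  s2 <- numeric(G)
  for (g in seq_len(G)) {
    acc <- 0
    for (s in seq_len(n)) acc <- acc + (y[g, s] - rm_[g] - cm_[s] + gm)^2
    s2[g] <- acc / (n - 1)
  }
  t_hat <- G / (G - 1) * sum(s2)
  out <- numeric(G)
  for (g in seq_len(G)) out[g] <- sqrt(max(0, G / (G - 2) * (s2[g] - t_hat / G^2)))
  names(out) <- rownames(ct)
  out
}

oracle_bestkeeper <- function(ct, dialect = "mad") {
  G <- nrow(ct)
  out <- numeric(G)
  for (g in seq_len(G)) {
    m <- mean(ct[g, ])
    out[g] <- if (dialect == "mad") mean(abs(ct[g, ] - m)) else o_sd(ct[g, ])
  }
  names(out) <- rownames(ct)
  out
}

# competition rank by direct counting: 1 + number of strictly better genes
oracle_competition_rank <- function(values) {
  r <- integer(length(values))
  for (i in seq_along(values)) r[i] <- 1L + sum(values < values[i])
  names(r) <- names(values)
  r
}

oracle_consensus_order <- function(rank_mat, genes) {
  geo <- numeric(nrow(rank_mat))
  for (i in seq_len(nrow(rank_mat)))
    geo[i] <- prod(rank_mat[i, ])^(1 / ncol(rank_mat))
  genes[order(geo, genes)]
}
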