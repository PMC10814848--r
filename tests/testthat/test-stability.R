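test_that("geNorm M is zero for perfectly co-regulated genes and flags stability", {
  x <- make_ct(rbind(A = c(10, 12, 11, 13), B = c(13, 15, 14, 16)))
  m <- genorm_m(x)
  expect_equal(as.numeric(m), c(0, 0))
  expect_true(all(attr(m, "stable")))
})

test_that("geNorm M is invariant to per-sample constant shifts", {
  ct <- rand_ct(4, 6, seed = 3)
  shift <- seq(-1, 1.5, length.out = 6)
  m0 <- genorm_m(make_ct(ct))
  m1 <- genorm_m(make_ct(sweep(ct, 2, shift, "+")))
  expect_equal(unname(m0), unname(m1), tolerance = 1e-12)
})

test_that("geNorm M matches the brute-force oracle on the worked matrix", {
  ct <- worked_3x4()
  expect_equal(as.numeric(genorm_m(make_ct(ct))), unname(oracle_genorm_m(ct)),
               tolerance = 1e-12)
})

test_that("geNorm stepwise exclusion has the structural tied pair and matches the oracle", {
  ct <- rand_ct(3, 5, seed = 9)
  tab <- genorm_rank(make_ct(ct))
  expect_equal(sum(tab$rank == 1), 2L)
  expect_equal(sort(tab$rank), c(1L, 1L, 3L))

  for (seed in c(1, 2, 5)) {
    ct <- rand_ct(4, 4, seed)
    tab <- genorm_rank(make_ct(ct))
    orc <- oracle_genorm_exclusion(ct)
    expect_identical(attr(tab, "exclusion_order"), orc$excluded)
    expect_setequal(attr(tab, "final_pair"), orc$final_pair)
    expect_equal(setNames(tab$value, tab$gene), orc$values[tab$gene],
                 tolerance = 1e-12)
    expect_identical(setNames(tab$rank, tab$gene),
                     orc$ranks[tab$gene])
  }
  # final pair shares one identical M value
  tab <- genorm_rank(make_ct(rand_ct(5, 8, seed = 13)))
  pair <- attr(tab, "final_pair")
  expect_equal(tab$value[tab$gene == pair[1]], tab$value[tab$gene == pair[2]])
  expect_error(genorm_rank(make_ct(rand_ct(2, 4, 1))), "at least 3")
})

test_that("NormFinder vanishes on exactly additive data and is exchangeable", {
  alpha <- c(A = 0, B = 2, C = 5, D = 1)
  beta <- c(0, 0.5, -0.3, 1, 0.2)
  ct <- outer(alpha, beta, function(a, b) 15 + a + b)
  tab <- normfinder_stability(make_ct(ct))
  expect_equal(tab$value, rep(0, 4), tolerance = 1e-12)

  ct <- rand_ct(5, 8, seed = 21)
  t1 <- normfinder_stability(make_ct(ct))
  perm <- c(3, 1, 8, 2, 7, 4, 6, 5)
  t2 <- normfinder_stability(make_ct(ct[, perm]))
  expect_equal(t1$value, t2$value, tolerance = 1e-12)
  expect_error(normfinder_stability(make_ct(rand_ct(2, 4, 1))), "at least 3")
})

test_that("grouped NormFinder needs groups of size >= 2 and penalizes group shifts", {
  x <- study_matrix(seed = 5)
  hk <- subset(x, genes = hkg_genes)
  expect_error(normfinder_stability(hk, groups = seq_len(12)), "size < 2")
  tab <- normfinder_stability(hk, groups = "condition")
  expect_true(all(tab$value >= 0))
  expect_equal(sort(tab$gene), sort(hkg_genes))

  # a gene given a strong condition-specific shift must lose stability
  ct <- rand_ct(4, 12, seed = 31)
  ct <- sweep(ct, 2, rep(0, 12), "+")
  conds <- rep(c("A", "B", "C"), each = 4)
  shifted <- ct
  shifted[1, conds == "B"] <- shifted[1, conds == "B"] + 3
  t_plain <- normfinder_stability(make_ct(ct, conditions = conds),
                                  groups = "condition")
  t_shift <- normfinder_stability(make_ct(shifted, conditions = conds),
                                  groups = "condition")
  expect_gt(t_shift$value[t_shift$gene == "G1"],
            t_plain$value[t_plain$gene == "G1"])
  expect_equal(t_shift$rank[t_shift$gene == "G1"], 4L)
})

test_that("BestKeeper descriptives follow both dispersion dialects", {
  x <- make_ct(rbind(A = c(10, 12, 14), B = c(20, 20.5, 20.2)))
  tab <- bestkeeper(x)
  d <- attr(tab, "descriptives")
  expect_equal(d$ar_mean[1], 12)
  expect_equal(d$sd_mad[1], 4 / 3)
  expect_equal(d$sd_sample[1], 2)
  expect_equal(tab$value[tab$gene == "A"], 4 / 3)
  tab_sd <- bestkeeper(x, dispersion = "sd")
  expect_equal(tab_sd$value[tab_sd$gene == "A"], 2)

  # constant gene: dispersion 0, best rank, correlation undefined
  xc <- make_ct(rbind(A = c(20, 20, 20), B = c(10, 12, 14)))
  expect_warning(tabc <- bestkeeper(xc), "correlation undefined")
  expect_equal(tabc$value[tabc$gene == "A"], 0)
  expect_equal(tabc$rank[tabc$gene == "A"], 1L)
  expect_true(is.na(attr(tabc, "descriptives")$r_index[1]))

  # two identical genes: each equals the index, r = 1
  xi <- make_ct(rbind(A = c(10, 12, 14), B = c(10, 12, 14)))
  di <- attr(bestkeeper(xi), "descriptives")
  expect_equal(di$r_index, c(1, 1))
})

test_that("delta-Ct stability is zero for lockstep genes and shift-invariant", {
  x <- make_ct(rbind(A = c(10, 12, 11), B = c(12, 14, 13)))
  expect_equal(delta_ct_stability(x)$value, c(0, 0))

  ct <- rand_ct(4, 6, seed = 17)
  s0 <- delta_ct_stability(make_ct(ct))$value
  ct2 <- ct; ct2[2, ] <- ct2[2, ] + 5
  s1 <- delta_ct_stability(make_ct(ct2))$value
  expect_equal(s0, s1, tolerance = 1e-12)

  ct <- worked_3x4()
  expect_equal(delta_ct_stability(make_ct(ct))$value,
               unname(oracle_delta_ct(ct)), tolerance = 1e-12)
})

test_that("all four algorithms match their brute-force oracles on random matrices", {
  for (seed in 1:25) {
    G <- sample(4:6, 1)
    n <- sample(4:12, 1)
    ct <- rand_ct(G, n, seed = 1000 + seed)
    x <- make_ct(ct)
    expect_equal(as.numeric(genorm_m(x)), unname(oracle_genorm_m(ct)),
                 tolerance = 1e-10)
    expect_equal(delta_ct_stability(x)$value, unname(oracle_delta_ct(ct)),
                 tolerance = 1e-10)
    expect_equal(normfinder_stability(x)$value, unname(oracle_normfinder(ct)),
                 tolerance = 1e-10)
    expect_equal(bestkeeper(x)$value, unname(oracle_bestkeeper(ct, "mad")),
                 tolerance = 1e-10)
    expect_equal(bestkeeper(x, "sd")$value,
                 unname(oracle_bestkeeper(ct, "sd")), tolerance = 1e-10)
  }
})

test_that("gene-wise constant shifts leave all four stability values unchanged", {
  for (seed in 1:5) {
    ct <- rand_ct(5, 8, seed = 300 + seed)
    ct2 <- ct + matrix(c(3, -2, 0, 1, 5), 5, 8)
    x <- make_ct(ct); x2 <- make_ct(ct2)
    expect_equal(as.numeric(genorm_m(x)), as.numeric(genorm_m(x2)), tolerance = 1e-10)
    expect_equal(delta_ct_stability(x)$value, delta_ct_stability(x2)$value,
                 tolerance = 1e-10)
    expect_equal(normfinder_stability(x)$value,
                 normfinder_stability(x2)$value, tolerance = 1e-10)
    expect_equal(bestkeeper(x)$value, bestkeeper(x2)$value, tolerance = 1e-10)
  }
})

test_that("sample-wise constant shifts leave geNorm, delta-Ct and NormFinder unchanged", {
  for (seed in 1:5) {
    ct <- rand_ct(5, 8, seed = 400 + seed)
    shift <- seq(-2, 2, length.out = 8)
    ct2 <- sweep(ct, 2, shift, "+")
    x <- make_ct(ct); x2 <- make_ct(ct2)
    expect_equal(as.numeric(genorm_m(x)), as.numeric(genorm_m(x2)), tolerance = 1e-10)
    expect_equal(delta_ct_stability(x)$value, delta_ct_stability(x2)$value,
                 tolerance = 1e-10)
    expect_equal(normfinder_stability(x)$value,
                 normfinder_stability(x2)$value, tolerance = 1e-10)
    # BestKeeper dispersion of raw Ct is deliberately NOT invariant
    expect_false(isTRUE(all.equal(bestkeeper(x)$value, bestkeeper(x2)$value)))
  }
})
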