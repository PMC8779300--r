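# Drug-range scaling ---------------------------------------------------------

test_that("drug-range scaling maps drug extremes to 0 and 1", {
  vals <- matrix(c(2, 4, 6, 8), 4, 1)
  tab <- make_desc_table(vals, c("drug", "drug", "drug", "np"))
  scaled <- suppressMessages(drug_range_scale(tab))
  expect_equal(unname(scaled$values[1:3, 1]), c(0, 0.5, 1))
  # NP value outside the drug range scales beyond 1 and is flagged
  expect_equal(unname(scaled$values[4, 1]), 1.5)
  expect_equal(attr(scaled, "n_out_of_range"), 1L)
})

test_that("drug-range scaling is deliberately not idempotent", {
  vals <- matrix(c(2, 4, 6), 3, 1)
  tab <- make_desc_table(vals, rep("drug", 3))
  once <- drug_range_scale(tab)
  twice <- drug_range_scale(once)
  expect_equal(unname(once$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(twice$values[, 1]), c(0, 0.5, 1)) # re-scaling the
  # already-[0,1] drug column is a no-op here, but a shifted column is not:
  vals2 <- cbind(vals, c(5, 6, 8))
  tab2 <- make_desc_table(vals2, rep("drug", 3))
  expect_false(isTRUE(all.equal(drug_range_scale(tab2)$values,
                                tab2$values)))
})

test_that("variables constant over drugs error or drop in lenient mode", {
  vals <- cbind(a = c(1, 1, 5), b = c(0, 2, 9))
  tab <- make_desc_table(vals, c("drug", "drug", "np"))
  expect_error(drug_range_scale(tab), "constant over drugs: a")
  expect_warning(lenient <- suppressMessages(drug_range_scale(tab, lenient = TRUE)),
                 "dropping")
  expect_equal(lenient$variables, "b")
})

# PCA -------------------------------------------------------------------------

test_that("PCA recovers closed-form eigenstructure", {
  set.seed(13)
  n <- 2e4
  x <- cbind(rnorm(n, sd = sqrt(2)), rnorm(n, sd = 1))
  tab <- make_desc_table(x, rep("drug", n))
  pc <- run_pca(tab)
  # eigenvalues 2 and 1: PC1 carries 2/3 of the variance
  expect_equal(pc$axis_variance_pct[1], 100 * 2 / 3, tolerance = 0.02)
  expect_equal(sum(pc$axis_variance_pct), 100, tolerance = 1e-6)
})

test_that("isotropic data spreads variance evenly over axes", {
  set.seed(14)
  x <- matrix(rnorm(5000 * 5), ncol = 5)
  pc <- run_pca(make_desc_table(x, rep("np", 1000)))
  expect_true(all(abs(pc$axis_variance_pct - 20) < 3))
})

test_that("variable contributions sum to 100 per axis", {
  set.seed(15)
  x <- matrix(rnorm(300 * 7), ncol = 7)
  pc <- run_pca(make_desc_table(x, rep("np", 300)), n_axes = 3)
  expect_equal(unname(colSums(pc$variable_contributions_pct)),
               rep(100, 3), tolerance = 1e-6)
  expect_error(run_pca(make_desc_table(matrix(c(1, NA, 2, 3), 2, 2),
                                       c("np", "np"))), "non-finite")
})

# PERMANOVA --------------------------------------------------------------------

test_that("pseudo-F and exact p match the exhaustive-permutation oracle", {
  set.seed(21)
  # 4 points, 2 groups of 2
  x4 <- matrix(rnorm(4 * 3), 4, 3)
  l4 <- c("a", "a", "b", "b")
  or4 <- oracle_permanova(x4, l4)
  got4 <- permanova(x4, l4, exact = TRUE)
  expect_equal(got4$F, or4$F, tolerance = 1e-9)
  expect_equal(got4$p, or4$p, tolerance = 1e-9)

  # 8 points, 2 uneven groups
  x8 <- matrix(rnorm(8 * 2), 8, 2)
  l8 <- c(rep("a", 3), rep("b", 5))
  or8 <- oracle_permanova(x8, l8)
  got8 <- permanova(x8, l8, exact = TRUE)
  expect_equal(got8$F, or8$F, tolerance = 1e-9)
  expect_equal(got8$p, or8$p, tolerance = 1e-9)

  # 6 points, 3 groups
  x6 <- matrix(rnorm(6 * 2), 6, 2)
  l6 <- rep(c("a", "b", "c"), each = 2)
  or6 <- oracle_permanova(x6, l6)
  got6 <- permanova(x6, l6, exact = TRUE)
  expect_equal(got6$F, or6$F, tolerance = 1e-9)
  expect_equal(got6$p, or6$p, tolerance = 1e-9)
})

test_that("permanova agrees with vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  set.seed(22)
  x <- matrix(rnorm(30 * 5), 30, 5)
  labs <- rep(c("a", "b", "c"), each = 10)
  got <- permanova(x, labs, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dist(x) ~ labs, permutations = 19)
  expect_equal(got$F, ref$F[1], tolerance = 1e-9)
  expect_equal(got$r2, ref$R2[1], tolerance = 1e-9)
})

test_that("permanova on a distance matrix equals permanova on the table", {
  set.seed(23)
  x <- matrix(rnorm(20 * 4), 20, 4)
  labs <- rep(c("a", "b"), each = 10)
  a <- permanova(x, labs, n_perm = 49, seed = 9)
  b <- permanova(dist(x), labs, n_perm = 49, seed = 9)
  expect_equal(a$F, b$F, tolerance = 1e-9)
  expect_equal(a$r2, b$r2, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("permanova validates groups and respects label exchangeability", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(permanova(x, c("a", "a", "a", "a", "b")), "at least 2 members")
  expect_error(permanova(x, rep("a", 5)), "at least 2 groups")
  # permuting points and labels together leaves F unchanged
  set.seed(24)
  x <- matrix(rnorm(12 * 2), 12, 2)
  labs <- rep(c("a", "b"), each = 6)
  perm <- sample(12)
  f1 <- permanova(x, labs, n_perm = 9, seed = 1)$F
  f2 <- permanova(x[perm, ], labs[perm], n_perm = 9, seed = 1)$F
  expect_equal(f1, f2, tolerance = 1e-9)
})

# Quantitative Jaccard ---------------------------------------------------------

test_that("quantitative Jaccard identities and hand-computed values hold", {
  x <- c(0.2, 0.8, 0.5)
  expect_equal(ruzicka(x, x), 1)
  expect_equal(ruzicka(c(1, 0), c(0, 1)), 0)
  expect_equal(ruzicka(c(1, 0), c(0.5, 0.5)), 1 / 3)
  expect_message(z <- ruzicka(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 1)
  expect_error(ruzicka(c(1, 2), c(1, 2, 3)), "length")
  expect_error(ruzicka(c(-1, 2), c(1, 2)), "non-negative")
  # symmetry
  set.seed(31)
  for (i in 1:20) {
    a <- runif(6); b <- runif(6)
    expect_equal(ruzicka(a, b), ruzicka(b, a))
  }
})

test_that("mean Jaccard to drugs averages pairwise similarities with clipping", {
  vals <- rbind(d1 = c(0.0, 0.0), d2 = c(1, 1), np1 = c(1, 1), np2 = c(1.5, -0.5))
  colnames(vals) <- c("v1", "v2")
  tab <- descriptor_table(vals, c("drug", "drug", "np", "np"))
  res <- suppressMessages(mean_jaccard_to_drugs(tab))
  # np1 vs d1 (all-zero pair -> handled), vs d2 identical -> 1
  np1 <- res$mean_jaccard[res$id == "np1"]
  expect_equal(np1, mean(c(0, 1)))
  # np2 clips to (1, 0): vs d1 -> 0, vs d2 -> ruzicka((1,0),(1,1)) = 1/2
  np2 <- res$mean_jaccard[res$id == "np2"]
  expect_equal(np2, mean(c(0, 0.5)))
  expect_true(all(res$mean_jaccard >= 0 & res$mean_jaccard <= 1))
})

# Fingerprint Tanimoto ---------------------------------------------------------

test_that("fingerprint Tanimoto follows the set-bit formula", {
  expect_equal(fingerprint_tanimoto(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(fingerprint_tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # bits {1,2} vs {2,3} -> 1/3
  expect_equal(fingerprint_tanimoto(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_message(s <- fingerprint_tanimoto(c(0, 0), c(0, 0)), "empty")
  expect_equal(s, 1)
  expect_error(fingerprint_tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("atom-pair fingerprint similarities match ChemmineR::fpSim", {
  ms <- fixture_structures(8, category = "drug")
  fps <- atom_pair_fingerprints(ms)
  conv <- npdrugspace:::mol_sdfset(ms)
  ap <- ChemmineR::sdf2ap(conv$sdf, uniquePairs = TRUE)
  e <- new.env(); utils::data("apfp", package = "ChemmineR", envir = e)
  fpset <- ChemmineR::desc2fp(ap, descnames = as.character(e$apfp$AP)[1:1024],
                              type = "FPset")
  # addone = 0: fpSim's default adds a pseudocount to the Tanimoto ratio
  ref <- ChemmineR::fpSim(fpset[1], fpset, method = "Tanimoto",
                          sorted = FALSE, addone = 0)
  mine <- vapply(seq_len(nrow(fps)), function(i)
    fingerprint_tanimoto(fps[1, ], fps[i, ]), 0)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-9)
})

# MCS Tanimoto -----------------------------------------------------------------

test_that("MCS Tanimoto identities hold", {
  asp <- "CC(=O)Oc1ccccc1C(=O)O"
  s <- mcs_tanimoto(asp, asp)
  expect_equal(as.numeric(s), 1)
  expect_true(attr(s, "exact"))
  # methane vs benzene: single-atom MCS, 1/(1 + 6 - 1)
  expect_equal(as.numeric(mcs_tanimoto("C", "c1ccccc1")), 1 / 6)
  expect_error(mcs_tanimoto("", "C"), "unparseable|empty")
})

test_that("MCS matches brute-force common-subgraph enumeration", {
  pairs <- list(c("CC", "CCO"),          # ethane vs ethanol
                c("CCC", "CCO"),         # propane vs ethanol
                c("CC(=O)O", "CCO"),     # acetic acid vs ethanol
                c("C=O", "CCO"),         # formaldehyde vs ethanol
                c("CC(C)C", "CCCC"))     # isobutane vs butane
  for (p in pairs) {
    got <- mcs_tanimoto(p[1], p[2])
    expect_true(attr(got, "exact"))
    expect_equal(as.numeric(got), oracle_mcs_tanimoto(p[1], p[2]),
                 label = paste(p, collapse = " vs "))
  }
})

test_that("MCS Tanimoto is symmetric and maximal only for isomorphic graphs", {
  pairs <- list(c("CCO", "CC(=O)O"), c("c1ccccc1", "Cc1ccccc1"),
                c("CCN", "CCO"))
  for (p in pairs) {
    a <- as.numeric(mcs_tanimoto(p[1], p[2]))
    b <- as.numeric(mcs_tanimoto(p[2], p[1]))
    expect_equal(a, b)
    expect_lt(a, 1)
  }
  # same graph written differently is isomorphic -> exactly 1
  expect_equal(as.numeric(mcs_tanimoto("OCC", "CCO")), 1)
})

# Combined Tanimoto index ------------------------------------------------------

test_that("combined Tanimoto index arithmetic is as printed", {
  expect_equal(tanimoto_index(0, 0), 0)
  expect_equal(tanimoto_index(0, 0, mode = "euclid"), 0)
  expect_equal(tanimoto_index(0.6, 0.8), 1.0)
  expect_equal(tanimoto_index(1, 1), 2.0)
  expect_equal(tanimoto_index(1, 1, mode = "euclid"), sqrt(2))
  expect_error(tanimoto_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("mean Tanimoto to drugs averages per-drug indices", {
  np <- make_molset(c(q = "CCO"))
  drugs <- make_molset(c(d1 = "CCO", d2 = "CCC", d3 = "c1ccccc1"),
                       category = "drug")
  res <- suppressMessages(mean_tanimoto_to_drugs(np, drugs, time_cap = 2))
  # identical to d1: both components 1 against d1
  self_only <- suppressMessages(
    mean_tanimoto_to_drugs(np, drugs[1, ], time_cap = 2))
  expect_equal(self_only$tanimoto_index, 2.0)
  expect_equal(self_only$mean_fp_tanimoto, 1)
  expect_equal(self_only$mean_mcs_tanimoto, 1)
  # mean over drugs = mean of per-drug indices
  per_drug <- vapply(seq_len(3), function(j) {
    suppressMessages(mean_tanimoto_to_drugs(np, drugs[j, ],
                                            time_cap = 2))$tanimoto_index
  }, 0)
  expect_equal(res$tanimoto_index, mean(per_drug), tolerance = 1e-9)
  # invariance to drug ordering
  res_rev <- suppressMessages(
    mean_tanimoto_to_drugs(np, drugs[3:1, ], time_cap = 2))
  expect_equal(res$tanimoto_index, res_rev$tanimoto_index, tolerance = 1e-9)
  expect_error(mean_tanimoto_to_drugs(np, drugs[0, ]), "empty")
})
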