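# QED desirability models ----------------------------------------------------

test_that("desirability histograms peak-normalise and floor", {
  # degenerate: all drug values identical -> single cell with d = 1,
  # floor elsewhere
  m <- fit_desirability(rep(5, 50), "toy")
  expect_equal(max(m$d), 1)
  expect_equal(eval_desirability(m, 5), 1)
  expect_equal(eval_desirability(m, 100), m$floor)

  # evaluation at the histogram mode is exactly 1
  set.seed(11)
  v <- rnorm(5000, mean = 10)
  m <- fit_desirability(v, "toy")
  expect_equal(max(m$d), 1)
  expect_equal(eval_desirability(m, m$breaks[which.max(m$d)] +
                                   diff(m$breaks)[1] / 2), 1)
  expect_error(fit_desirability(rnorm(10), "toy"), "at least 30")
})

test_that("a large uniform sample yields a near-flat desirability", {
  set.seed(42)
  m <- fit_desirability(runif(1e5), "toy")
  interior <- m$d[3:(length(m$d) - 2)]
  expect_true(all(abs(interior - 1) < 0.15))
})

test_that("QED equals the geometric mean of desirabilities", {
  models <- replicate(8, flat_model(1), simplify = FALSE)
  names(models) <- npdrugspace::QED_PROPERTIES
  pv <- stats::setNames(rep(0.5, 8), names(models))
  expect_equal(qed(pv, models), 1)

  models <- replicate(8, flat_model(0.3), simplify = FALSE)
  names(models) <- npdrugspace::QED_PROPERTIES
  expect_equal(qed(pv, models), 0.3)

  eps <- 1e-4
  d <- c(rep(1, 7), eps)
  models <- lapply(d, flat_model)
  names(models) <- npdrugspace::QED_PROPERTIES
  expect_equal(qed(pv, models), eps^(1 / 8), tolerance = 1e-12)
  expect_equal(qed(pv, models), prod(d)^(1 / 8), tolerance = 1e-12)
})

test_that("QED is monotone in each single desirability component", {
  pv <- stats::setNames(rep(0.5, 8), npdrugspace::QED_PROPERTIES)
  base <- lapply(rep(0.5, 8), flat_model)
  names(base) <- names(pv)
  q0 <- qed(pv, base)
  for (i in seq_len(8)) {
    up <- base
    up[[i]] <- flat_model(0.9)
    expect_gt(qed(pv, up), q0)
  }
})

# RDL -------------------------------------------------------------------------

test_that("RDL relative likelihoods centre on 0.5 when groups coincide", {
  set.seed(7)
  m <- fit_rdl_model(rnorm(1e4), rnorm(1e4), "toy")
  expect_identical(m$breaks, m$breaks) # shared grid by construction
  expect_equal(sum(m$f_drug), 1, tolerance = 1e-12)
  expect_equal(sum(m$f_ref), 1, tolerance = 1e-12)
  dense <- m$f_drug > 0.01 & m$f_ref > 0.01
  rl <- m$f_drug[dense] / (m$f_drug[dense] + m$f_ref[dense])
  expect_true(all(abs(rl - 0.5) < 0.1))
})

test_that("cells empty of reference compounds give likelihood near 1", {
  drug <- c(rep(0.5, 200), 10)           # drugs dense near 0.5
  ref <- rep(10, 200)                    # reference far away
  m <- fit_rdl_model(drug, ref, "toy", bins = c(0, 1, 9, 11))
  rl <- npdrugspace:::relative_likelihood(m, 0.5)
  expect_gt(rl, 1 - 1e-3)
})

test_that("RDL equals the brute-force product of tabulated likelihoods", {
  m1 <- fit_rdl_model(c(rep(1, 100), rep(2, 50)), c(rep(1, 50), rep(2, 100)),
                      "p1", bins = c(0.5, 1.5, 2.5))
  m2 <- fit_rdl_model(rep(5, 100), c(rep(5, 50), rep(7, 50)),
                      "p2", bins = c(4, 6, 8))
  models <- list(p1 = m1, p2 = m2)
  pv <- c(p1 = 1, p2 = 5)
  rl1 <- npdrugspace:::relative_likelihood(m1, 1)
  rl2 <- npdrugspace:::relative_likelihood(m2, 5)
  expect_equal(rdl(pv, models), sqrt(rl1 * rl2), tolerance = 1e-12)
  expect_gt(rdl(pv, models), 0)
  expect_lt(rdl(pv, models), 1)
  expect_error(fit_rdl_model(rnorm(5), rnorm(100)), "at least 30")
})

# Rule of five -----------------------------------------------------------------

test_that("rule-of-five counts thresholds not satisfied, bounded by 0 and 4", {
  expect_equal(ro5_violations(499, 4.9, 4, 9), 0L)
  expect_equal(ro5_violations(600, 6.0, 6, 11), 4L)
  # strict inequalities: boundary values count as violations
  expect_equal(ro5_violations(500, 5.0, 5, 10), 4L)
  expect_error(ro5_violations(NA, 1, 1, 1), "missing")
})

test_that("rule-of-five equals the brute-force predicate count", {
  set.seed(3)
  for (i in 1:200) {
    mw <- sample(c(100, 499, 500, 501, 900), 1)
    lp <- sample(c(-1, 4.9, 5, 5.1, 8), 1)
    hbd <- sample(0:8, 1)
    hba <- sample(0:14, 1)
    oracle <- sum(!c(lp < 5, mw < 500, hbd < 5, hba < 10))
    expect_equal(ro5_violations(mw, lp, hbd, hba), oracle)
  }
})

# ADMET-score ------------------------------------------------------------------

test_that("admet frequency weights are drug beneficial-value frequencies", {
  vals <- matrix(c(1, 1, 1, 1,   1, 0, 1, 0,   0, 0, 0, 0), 4, 3,
                 dimnames = list(paste0("d", 1:4), c("e1", "e2", "e3")))
  w <- suppressMessages(derive_admet_weights(endpoint_table(vals)))
  expect_equal(w$w1, c(1, 0.5, 0))
  expect_equal(w$w2, rep(1, 3))
  # dropping one drug moves w1 by at most 1/n
  w2 <- suppressMessages(derive_admet_weights(endpoint_table(vals[-1, ])))
  expect_true(all(abs(w2$w1 - w$w1) <= 1 / 3 + 1e-12))
  expect_error(derive_admet_weights(endpoint_table(vals[0, , drop = FALSE])),
               "empty")
})

test_that("admet raw scores are weighted sums and additive over endpoints", {
  vals <- matrix(c(1, 0, 1), 1, 3,
                 dimnames = list("m1", c("e1", "e2", "e3")))
  w <- structure(data.frame(endpoint = c("e1", "e2", "e3"),
                            w1 = c(0.5, 1, 0.25), w2 = 1, w3 = 1),
                 class = c("admet_weights", "data.frame"))
  sc <- admet_score(endpoint_table(vals), w)
  expect_equal(sc$admet_raw, 0.75)
  # additivity over disjoint endpoint subsets
  sc_a <- admet_score(endpoint_table(vals[, 1:2, drop = FALSE]), w)
  sc_b <- admet_score(endpoint_table(vals[, 3, drop = FALSE]), w)
  expect_equal(sc_a$admet_raw + sc_b$admet_raw, sc$admet_raw)
  # hand standardization
  sc_std <- admet_score(endpoint_table(vals), w, drug_range = c(0.5, 1.75))
  expect_equal(sc_std$admet_std, (0.75 - 0.5) / 1.25)
  expect_error(admet_score(endpoint_table(vals), w, drug_range = c(1, 1)),
               "min < max")
})

test_that("drug-range standardisation pins extreme drugs to 0 and 1", {
  set.seed(5)
  vals <- matrix(rbinom(40 * 6, 1, 0.6), 40, 6,
                 dimnames = list(sprintf("d%02d", 1:40), paste0("e", 1:6)))
  vals[1, ] <- 1L  # most favourable drug
  vals[2, ] <- 0L  # least favourable drug
  tab <- endpoint_table(vals)
  w <- suppressMessages(derive_admet_weights(tab))
  raw <- admet_score(tab, w)$admet_raw
  std <- admet_score(tab, w, drug_range = range(raw))$admet_std
  expect_equal(std[1], 1)
  expect_equal(std[2], 0)
  expect_true(all(std >= 0 & std <= 1))
})

test_that("likeness profiles cover every compound with scores in range", {
  cfg <- sim_config(n_drug = 60, n_np = 80, n_toxin = 60, seed = 5)
  lib <- simulate_library(cfg)
  eps <- bind_endpoint_tables(lib$endpoints)
  prof <- suppressMessages(likeness_profiles(lib$properties, eps))
  expect_equal(nrow(prof), 200L)
  expect_true(all(prof$qed > 0 & prof$qed <= 1))
  expect_true(all(prof$rdl > 0 & prof$rdl < 1))
  expect_true(all(prof$ro5 %in% 0:4))
  drug_std <- prof$admet_std[prof$category == "drug"]
  expect_true(all(drug_std >= 0 & drug_std <= 1))
})
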