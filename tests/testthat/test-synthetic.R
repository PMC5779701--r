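test_that("true network construction honours requested structure", {
  # single-edge model: partial correlation equals the sampled weight
  m2 <- make_true_network(2, edge_prob = 1, weight_range = c(0.35, 0.35),
                          seed = 3)
  expect_equal(m2$Pcor_true[1, 2], 0.35, tolerance = 1e-12)

  # empty graph: identity partial-correlation matrix
  m0 <- make_true_network(5, edge_prob = 0, seed = 1)
  expect_equal(m0$Pcor_true, diag(5))

  # positive definiteness by direct eigendecomposition
  m4 <- make_true_network(4, edge_prob = 0.8, weight_range = c(0.3, 0.5),
                          seed = 11)
  ev <- eigen(m4$Omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # support of Pcor matches support of Omega off-diagonals
  expect_equal(abs(m4$Pcor_true[upper.tri(diag(4))]) > 0,
               abs(m4$Omega[upper.tri(diag(4))]) > 0)
})

test_that("dense high-weight models trigger diagonal loading, not failure", {
  m <- make_true_network(6, edge_prob = 1, weight_range = c(0.6, 0.8),
                         seed = 5)
  ev <- eigen(m$Omega, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(diag(m$Omega), rep(1, 6))
})

test_that("ordinal sampling reproduces bivariate normal cell probabilities", {
  m <- make_true_network(2, edge_prob = 1, weight_range = c(0.5, 0.5),
                         seed = 1, thresholds = c(-0.5, 0, 0.5))
  d <- sample_ordinal_wave(m, 1e5, seed = 42)
  X <- d$values
  cuts <- c(-Inf, -0.5, 0, 0.5, Inf)
  for (cell in list(c(0, 0), c(1, 2), c(3, 3), c(2, 0))) {
    i <- cell[1]; j <- cell[2]
    p_theo <- pbvnorm(cuts[i + 2], cuts[j + 2], 0.5) -
      pbvnorm(cuts[i + 1], cuts[j + 2], 0.5) -
      pbvnorm(cuts[i + 2], cuts[j + 1], 0.5) +
      pbvnorm(cuts[i + 1], cuts[j + 1], 0.5)
    p_emp <- mean(X[, 1] == i & X[, 2] == j)
    expect_lt(abs(p_emp - p_theo), 0.006,
              label = sprintf("cell (%d, %d) deviation", i, j))
  }
  # marginal calibration: category frequencies match normal-CDF differences
  marg_theo <- diff(pnorm(cuts))
  expect_lt(max(abs(as.numeric(table(X[, 1]) / nrow(X)) - marg_theo)), 0.006)
})

test_that("extreme thresholds collapse an item to a constant column", {
  m <- make_true_network(2, edge_prob = 1, weight_range = c(0.3, 0.3),
                         seed = 1, thresholds = c(8, 9, 10))
  d <- sample_ordinal_wave(m, 500, seed = 1)
  expect_true(all(d$values == 0))
})

test_that("sampling is deterministic given the seed", {
  m <- make_true_network(4, 0.5, seed = 2)
  d1 <- sample_ordinal_wave(m, 100, seed = 9)
  d2 <- sample_ordinal_wave(m, 100, seed = 9)
  expect_identical(d1$values, d2$values)
  des <- longitudinal_design(50, 3, subject_corr = 0.4, missing_rate = 0.1,
                             seed = 7)
  s1 <- sample_longitudinal(m, des)
  s2 <- sample_longitudinal(m, des)
  expect_identical(lapply(s1$waves, `[[`, "values"),
                   lapply(s2$waves, `[[`, "values"))
})

test_that("within-subject dependence behaves as designed", {
  m <- make_true_network(3, 0.5, weight_range = c(0.25, 0.35), seed = 4)
  # independence limit
  s0 <- sample_longitudinal(m, longitudinal_design(4000, 2, subject_corr = 0,
                                                   seed = 5))
  r0 <- cor(s0$waves[[1]]$values[, 1], s0$waves[[2]]$values[, 1])
  expect_lt(abs(r0), 0.05)
  # positive dependence raises the across-wave item correlation
  s5 <- sample_longitudinal(m, longitudinal_design(4000, 2, subject_corr = 0.5,
                                                   seed = 5))
  r5 <- cor(s5$waves[[1]]$values[, 1], s5$waves[[2]]$values[, 1])
  expect_gt(r5, 0.25)
})

test_that("identical wave models give matching wave-level polychoric matrices", {
  m <- make_true_network(4, 0.6, weight_range = c(0.2, 0.35), seed = 8)
  s <- sample_longitudinal(m, longitudinal_design(5000, 2, subject_corr = 0.5,
                                                  seed = 13))
  R1 <- correlation_matrix(s$waves[[1]])$R
  R2 <- correlation_matrix(s$waves[[2]])$R
  expect_lt(max(abs(R1 - R2)), 0.06)
})

test_that("missingness yields the expected complete-case count", {
  m <- make_true_network(3, 0.5, seed = 1)
  des <- longitudinal_design(306, 4, subject_corr = 0.3, missing_rate = 0.15,
                             seed = 21)
  s <- sample_longitudinal(m, des)
  expected <- 306 * 0.85^4      # ~160
  sd_bin <- sqrt(306 * 0.85^4 * (1 - 0.85^4))
  expect_lt(abs(sum(s$complete) - expected), 4 * sd_bin)
  # the complete flag agrees with the observed data
  observed_complete <- Reduce(`&`, lapply(s$waves, function(w)
    rowSums(is.na(w$values)) == 0))
  expect_identical(s$complete, observed_complete)
})

test_that("ground-truth models round-trip through JSON", {
  m <- make_true_network(4, 0.5, seed = 99)
  path <- tempfile(fileext = ".json")
  write_true_network(m, path)
  m2 <- read_true_network(path)
  expect_equal(m2$Omega, m$Omega, tolerance = 1e-12)
  expect_equal(m2$Pcor_true, m$Pcor_true, tolerance = 1e-12)
  expect_equal(m2$thresholds, m$thresholds, tolerance = 1e-12)
})

test_that("estimation recovers the generating network at large n", {
  # EBIC-selected graphical lasso networks retain a few spurious edges whose
  # count fluctuates run to run, but those edges are negligible in magnitude:
  # recovery is checked on the weights (high correlation with truth, and no
  # false edge anywhere near the generated weight range).
  m <- make_true_network(10, 0.25, weight_range = c(0.2, 0.4), seed = 31)
  d <- sample_ordinal_wave(m, 5000, seed = 32)
  net <- estimate_network(d)
  up <- upper.tri(net$W)
  expect_gt(cor(net$W[up], m$Pcor_true[up]), 0.9)
  true_zero <- abs(m$Pcor_true[up]) < 1e-12
  expect_lt(max(abs(net$W[up][true_zero])), 0.05)
  # every true edge is found
  expect_true(all(abs(net$W[up][!true_zero]) > 1e-10))
})
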