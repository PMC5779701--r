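test_that("bootstrap runs are reproducible from the seed", {
  d <- make_test_wave(p = 4, n = 150, seed = 40)
  spec <- bootstrap_spec(n_boot = 15, seed = 5)
  b1 <- nonparametric_boot(d, spec)
  b2 <- nonparametric_boot(d, spec)
  expect_identical(b1$table, b2$table)
  expect_identical(b1$edge_replicates, b2$edge_replicates)
})

test_that("a single replicate yields a flagged degenerate interval", {
  d <- make_test_wave(p = 4, n = 150, seed = 41)
  expect_warning(b <- nonparametric_boot(d, bootstrap_spec(n_boot = 1)),
                 "degenerate")
  expect_equal(b$table$lower, b$table$upper)
})

test_that("bootstrap intervals cover a true zero edge", {
  # chain 1-2-3-4: the (1,3) partial correlation is exactly zero
  m <- make_true_network(4, 0, seed = 1)
  for (e in list(c(1, 2), c(2, 3), c(3, 4)))
    m$Omega[e[1], e[2]] <- m$Omega[e[2], e[1]] <- -0.35
  covered <- 0
  for (run in 1:10) {
    d <- sample_ordinal_wave(m, 600, seed = 100 + run)
    b <- nonparametric_boot(d, bootstrap_spec(n_boot = 60, seed = run))
    row <- b$table[b$table$node_i == "item1" & b$table$node_j == "item3", ]
    covered <- covered + (row$lower <= 0 && row$upper >= 0)
  }
  expect_gte(covered, 9)
})

test_that("interval width shrinks with the sample size", {
  m <- make_true_network(5, 0.5, weight_range = c(0.2, 0.35), seed = 42)
  width <- function(n) {
    d <- sample_ordinal_wave(m, n, seed = n)
    b <- nonparametric_boot(d, bootstrap_spec(n_boot = 40, seed = 2))
    median(b$table$upper - b$table$lower)
  }
  expect_lt(width(2000), width(300))
})

test_that("difference tests are symmetric and never flag self-comparisons", {
  d <- make_test_wave(p = 4, n = 250, seed = 43)
  b <- nonparametric_boot(d, bootstrap_spec(n_boot = 50, seed = 3))
  dt <- difference_tests(b)
  expect_false(any(diag(dt$edges)))
  expect_false(any(diag(dt$strength)))
  expect_identical(dt$edges, t(dt$edges))
  expect_identical(dt$strength, t(dt$strength))
})

test_that("difference tests separate a strong edge from a true zero edge", {
  m <- make_true_network(4, 0, seed = 1)
  m$Omega[1, 2] <- m$Omega[2, 1] <- -0.5
  m$Omega[3, 4] <- m$Omega[4, 3] <- -0.05
  hits <- 0
  for (run in 1:5) {
    d <- sample_ordinal_wave(m, 1200, seed = 200 + run)
    b <- nonparametric_boot(d, bootstrap_spec(n_boot = 60, seed = run))
    dt <- difference_tests(b)
    hits <- hits + dt$edges["item1--item2", "item3--item4"]
  }
  expect_gte(hits, 4)
})

test_that("CS coefficient follows its definition and skips tiny subsets", {
  cors <- cbind(rep(0.9, 20), rep(0.75, 20), c(rep(0.75, 18), 0.2, 0.1),
                rep(0.3, 20))
  props <- c(0.1, 0.2, 0.3, 0.4)
  # col 3 has 18/20 = 90% of replicates above 0.7, short of the 95% rule
  expect_equal(cs_coefficient(cors, props, threshold = 0.7, prob = 0.95), 0.2)
  expect_equal(cs_coefficient(cors, props, threshold = 0.7, prob = 0.9), 0.3)
  expect_equal(cs_coefficient(cors, props, threshold = 0.8, prob = 0.95), 0.1)
  expect_equal(cs_coefficient(cors, props, threshold = 0.95, prob = 0.95), 0)
  # monotone in the correlation threshold
  for (th in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    expect_gte(cs_coefficient(cors, props, threshold = 0.5, prob = 0.95),
               cs_coefficient(cors, props, threshold = th, prob = 0.95))
  }
  # a drop proportion leaving fewer than p + 5 subjects is skipped
  d <- make_test_wave(p = 5, n = 40, seed = 44)
  spec <- bootstrap_spec(n_boot = 5, kind = "case_dropping",
                         drop_proportions = c(0.1, 0.8), seed = 1)
  expect_warning(res <- case_dropping_boot(d, spec), "skipped")
  expect_equal(res$proportions, 0.1)
})

test_that("case-dropping stability reflects the information in the data", {
  # strong structure, large n: stable at every proportion
  m <- make_true_network(6, 0.5, weight_range = c(0.25, 0.4), seed = 45)
  d <- sample_ordinal_wave(m, 2500, seed = 46)
  spec <- bootstrap_spec(n_boot = 30, kind = "case_dropping",
                         drop_proportions = seq(0.1, 0.7, 0.2), seed = 7)
  res <- case_dropping_boot(d, spec)
  expect_equal(res$cs_coefficient, 0.7)
  expect_true(all(res$correlations > 0.9, na.rm = TRUE))
})
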