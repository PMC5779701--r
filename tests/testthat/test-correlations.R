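test_that("threshold estimation inverts cumulative proportions", {
  expect_equal(estimate_thresholds(rep(0:1, c(50, 50))), 0)
  th <- estimate_thresholds(rep(0:2, c(25, 50, 25)))
  expect_equal(th, c(qnorm(0.25), qnorm(0.75)))
  expect_equal(th[1], -th[2])
  expect_equal(estimate_thresholds(rep(0:1, c(1587, 8413))), -1,
               tolerance = 1e-3)
  expect_error(estimate_thresholds(rep(2, 30), item = "cesd3"), "cesd3")
  # zero-mass interior category merges without producing duplicate cuts
  th2 <- estimate_thresholds(rep(c(0, 3), c(40, 60)))
  expect_equal(th2, qnorm(0.4))
})

test_that("polychoric estimate agrees with a dense grid search", {
  tab <- matrix(c(40, 10, 10, 40), 2, 2, byrow = TRUE)
  rho <- as.numeric(polychoric_table(tab))
  expect_equal(rho, polychoric_grid_oracle(tab), tolerance = 1e-4)

  tab2 <- matrix(c(30, 25, 5, 10, 40, 20, 5, 10, 35), 3, 3, byrow = TRUE)
  expect_equal(as.numeric(polychoric_table(tab2)),
               polychoric_grid_oracle(tab2), tolerance = 1e-4)
})

test_that("polychoric degenerate tables behave as specified", {
  # independence table -> rho ~ 0
  ind <- outer(c(3, 7), c(2, 5, 3)) * 10
  expect_lt(abs(as.numeric(polychoric_table(ind))), 1e-4)
  # perfect association -> boundary with warning
  expect_warning(r <- polychoric_table(matrix(c(50, 0, 0, 50), 2, 2)),
                 "boundary")
  expect_equal(as.numeric(r), 0.999)
  expect_true(attr(r, "boundary"))
})

test_that("polychoric is symmetric and invariant to order-preserving relabeling", {
  set.seed(10)
  d <- make_test_wave(p = 3, n = 400, seed = 10)
  x <- d$values[, 1]; y <- d$values[, 2]
  r_xy <- as.numeric(polychoric_pair(x, y))
  expect_equal(as.numeric(polychoric_pair(y, x)), r_xy, tolerance = 1e-9)
  relabel <- c(0, 5, 6, 9)
  expect_equal(as.numeric(polychoric_pair(relabel[x + 1], relabel[y + 1])),
               r_xy, tolerance = 1e-9)
})

test_that("binary items reduce to the tetrachoric special case", {
  set.seed(11)
  x <- as.integer(runif(500) < 0.4)
  y <- as.integer(runif(500) < 0.3 + 0.3 * x)
  tab <- table(x, y)
  expect_equal(as.numeric(polychoric_pair(x, y)),
               as.numeric(polychoric_table(unclass(tab))), tolerance = 1e-8)
})

test_that("polyserial estimation recovers latent correlations", {
  set.seed(12)
  n <- 20000
  z <- rnorm(n)
  # deterministic link: thresholding x itself drives rho to the boundary
  y_det <- as.integer(z > median(z))
  expect_warning(r_det <- polyserial_pair(z, y_det), "boundary")
  expect_equal(as.numeric(r_det), 0.999)
  # independence
  y_ind <- findInterval(rnorm(n), c(-0.6, 0.6))
  expect_lt(abs(as.numeric(polyserial_pair(z, y_ind))), 0.05)
  # latent rho 0.6, 3 categories
  latent <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  y3 <- findInterval(latent, c(-0.5, 0.7))
  expect_equal(as.numeric(polyserial_pair(z, y3)), 0.6, tolerance = 0.03)
  expect_error(polyserial_pair(rep(1, 100), y3[1:100]), "zero variance")
})

test_that("correlation_matrix dispatches by item kind", {
  set.seed(13)
  n <- 300
  Z <- matrix(rnorm(n * 3), n, 3) %*% chol(matrix(c(1, .5, .2, .5, 1, .3,
                                                    .2, .3, 1), 3, 3))
  d_cont <- ordinal_dataset(Z, item_codes = c("a", "b", "c"),
                            item_kind = rep("continuous", 3))
  cm <- correlation_matrix(d_cont)
  expect_equal(unname(cm$R), cor(Z), tolerance = 1e-12)
  expect_false(cm$pd_repaired)

  # contract: symmetric, unit diagonal, thresholds only for ordinal items
  d_ord <- make_test_wave(p = 4, n = 250, seed = 14)
  cm2 <- correlation_matrix(d_ord)
  expect_true(isSymmetric(cm2$R))
  expect_equal(unname(diag(cm2$R)), rep(1, 4))
  expect_length(cm2$thresholds, 4)
})

test_that("mixed continuous/ordinal/binary matrices are estimated coherently", {
  set.seed(15)
  n <- 800
  R_lat <- matrix(c(1, .5, .3, .5, 1, .4, .3, .4, 1), 3, 3)
  Z <- matrix(rnorm(n * 3), n, 3) %*% chol(R_lat)
  V <- cbind(Z[, 1],
             findInterval(Z[, 2], c(-0.5, 0.5)),
             as.integer(Z[, 3] > 0.2))
  d <- ordinal_dataset(V, item_codes = c("cont", "ord", "bin"),
                       item_kind = c("continuous", "ordinal", "binary"))
  cm <- correlation_matrix(d)
  expect_lt(max(abs(cm$R - R_lat)), 0.12)
})

test_that("latent correlations round-trip through the generator", {
  m <- make_true_network(4, edge_prob = 1, weight_range = c(0.2, 0.3),
                         seed = 16)
  Sigma <- cov2cor(solve(m$Omega))
  d <- sample_ordinal_wave(m, 20000, seed = 17)
  cm <- correlation_matrix(d)
  expect_lte(max(abs(unname(cm$R) - Sigma)), 0.03)
})

test_that("pairwise-complete estimation uses per-pair samples and errors below the floor", {
  d <- make_test_wave(p = 4, n = 120, seed = 18)
  V <- d$values
  V[1:40, 2] <- NA
  d2 <- ordinal_dataset(V, item_codes = d$item_codes,
                        item_kind = d$item_kind)
  cm <- correlation_matrix(d2)
  expect_equal(cm$n_pairwise[1, 2], 80L)
  expect_equal(cm$n_pairwise[1, 3], 120L)
  # push a pair below the pairwise minimum
  V[5:120, 3] <- NA
  d3 <- ordinal_dataset(V, item_codes = d$item_codes, item_kind = d$item_kind)
  expect_error(correlation_matrix(d3), "item2-item3")
})

test_that("positive-definite repair clips eigenvalues and is idempotent", {
  R_bad <- matrix(0.9, 3, 3)
  R_bad[1, 2] <- R_bad[2, 1] <- -0.9
  diag(R_bad) <- 1
  expect_lt(min(eigen(R_bad, symmetric = TRUE)$values), 0)   # indefinite
  R_fix <- nearest_pd_repair(R_bad)
  expect_gt(min(eigen(R_fix, symmetric = TRUE)$values), 0)
  expect_equal(unname(diag(R_fix)), rep(1, 3))
  expect_equal(nearest_pd_repair(R_fix), R_fix, tolerance = 1e-12)
  expect_equal(nearest_pd_repair(diag(4)), diag(4))
  R_ok <- matrix(c(1, .3, .3, 1), 2, 2)
  expect_identical(nearest_pd_repair(R_ok), R_ok)
})
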