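# Restrained least squares, Tukey IRLS, prediction, effective weights.

test_that("tukey weights follow the (1 - d^2/W^2)^2 profile", {
  expect_identical(tukey_weight(0, 10), 1)
  expect_identical(tukey_weight(10, 10), 0)
  expect_identical(tukey_weight(10.0001, 10), 0)
  expect_equal(tukey_weight(5, 10), 0.5625)
  # symmetric in the sign of the residual
  expect_identical(tukey_weight(-3, 10), tukey_weight(3, 10))
  # non-increasing in |d| on [0, W]
  d <- seq(0, 10, length.out = 50)
  expect_true(all(diff(tukey_weight(d, 10)) <= 0))
  # Inf disables weighting
  expect_identical(tukey_weight(c(-1e6, 0, 1e6), Inf), c(1, 1, 1))
  expect_error(tukey_weight(1, 0), "positive")
  expect_error(tukey_weight(1, -5), "positive")
})

test_that("fit_restrained solves the stated objective in closed form", {
  P <- matrix(c(1, -1), 2, 1)
  y <- c(1, -1)
  # exact interpolation at lambda = 0
  f0 <- fit_restrained(P, y, lambda = 0)
  expect_equal(f0$coefficients, 1, tolerance = 1e-12)
  expect_equal(f0$beta, 0, tolerance = 1e-12)
  # lambda = 1 shrinks the slope to 2/3 (hand/brute-force value)
  f1 <- fit_restrained(P, y, lambda = 1)
  expect_equal(f1$coefficients, 2 / 3, tolerance = 1e-10)
  expect_equal(f1$beta, 0, tolerance = 1e-10)
  # heavy shrinkage pulls c to c_ideal and beta to the weighted mean
  fL <- fit_restrained(P, y, lambda = 1e10)
  expect_equal(fL$coefficients, 0, tolerance = 1e-8)
  expect_equal(fL$beta, mean(y), tolerance = 1e-8)
  # shrinkage toward a nonzero ideal value
  fI <- fit_restrained(P, y, lambda = 1e10, c_ideal = 2)
  expect_equal(fI$coefficients, 2, tolerance = 1e-6)
  # collinear axes at lambda = 0 are rejected with advice
  Pc <- cbind(1:4, 2 * (1:4))
  expect_error(fit_restrained(Pc, rnorm(4), lambda = 0), "lambda")
})

test_that("closed form matches the brute-force minimiser, with weights", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(8:30, 1); k <- sample(1:4, 1)
    P <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n, sd = 2)
    w <- runif(n, 0.2, 1)
    lam <- sample(c(0, 1e-3, 0.1, 1), 1)
    f <- fit_restrained(P, y, lam, c_ideal = 0.5, weights = w)
    bf <- brute_force_restrained(P, y, lam, c_ideal = 0.5, weights = w)
    expect_equal(f$objective, bf$value, tolerance = 1e-6)
    expect_equal(c(f$coefficients, f$beta), bf$par, tolerance = 1e-4)
  }
})

test_that("IRLS matches the plain fit on clean data and with W disabled", {
  set.seed(5)
  P <- matrix(rnorm(60), 30, 2)
  y <- drop(P %*% c(1.5, -0.8)) + rnorm(30, sd = 0.1)
  plain <- fit_restrained(P, y, lambda = 1e-4)
  # W far above the residual scale: same answer
  rob <- dsqsar:::irls_restrained(P, y, lambda = 1e-4, W = 1e4)
  expect_equal(rob$fit$coefficients, plain$coefficients, tolerance = 1e-8)
  expect_equal(rob$fit$beta, plain$beta, tolerance = 1e-8)
  expect_true(rob$diagnostics$converged)
  # diagnostics weight support: zero exactly beyond W
  expect_true(all(rob$diagnostics$weights > 0))
})

test_that("a gross outlier with zero converged weight is effectively deleted", {
  set.seed(8)
  P <- matrix(rnorm(50), 25, 2)
  y <- drop(P %*% c(2, -1)) + rnorm(25, sd = 0.2)
  y[7] <- y[7] + 12            # gross outlier
  rob <- dsqsar:::irls_restrained(P, y, lambda = 1e-4, W = 5)
  expect_identical(rob$diagnostics$weights[7], 0)
  # refit-without-point oracle: a fresh robust fit on the remaining data
  # lands on the same solution
  ref <- dsqsar:::irls_restrained(P[-7, ], y[-7], lambda = 1e-4, W = 5)
  expect_equal(rob$fit$coefficients, ref$fit$coefficients, tolerance = 1e-6)
  expect_equal(rob$fit$beta, ref$fit$beta, tolerance = 1e-6)
  # and the objective trace never increases
  expect_true(all(diff(rob$diagnostics$objective_trace) <=
                    1e-9 * abs(rob$diagnostics$objective_trace[-1])))
})

test_that("every observation beyond W aborts with advice", {
  # no line through these three points leaves any residual below W = 1
  P <- matrix(c(-1, 0, 1), 3, 1)
  expect_error(dsqsar:::irls_restrained(P, c(100, -100, 100), 0, W = 1),
               "increase W")
})

test_that("dsq_fit with W = Inf is bit-identical to the plain fit", {
  sim <- generate_synthetic(synthetic_spec(n_compounds = 50, n_proteins = 10,
                                           latent_rank = 3, seed = 4))
  y <- consolidate(sim$observations)$dataset
  dg <- setNames(y$delta_g, y$compound_id)
  fitI <- dsq_fit(sim$scores, dg, lambda = 1e-4, W = Inf)
  pca <- score_pca(sim$scores)
  plain <- fit_restrained(pca$scores[, fitI$axes, drop = FALSE],
                          dg[rownames(sim$scores)], lambda = 1e-4)
  expect_identical(fitI$coefficients, plain$coefficients)
  expect_identical(fitI$beta, plain$beta)
})

test_that("prediction reproduces training data under exact interpolation", {
  sim <- generate_synthetic(synthetic_spec(
    n_compounds = 40, n_proteins = 8, latent_rank = 3, score_noise_sd = 0,
    dg_noise_sd = 0, replicates_per_pair = 1, seed = 6))
  y <- consolidate(sim$observations)$dataset
  dg <- setNames(y$delta_g, y$compound_id)
  fit <- dsq_fit(sim$scores, dg, lambda = 0, W = Inf, max_axes = 7)
  expect_equal(unname(predict(fit, sim$scores)),
               unname(dg[rownames(sim$scores)]), tolerance = 1e-8)
  # a compound at the column means predicts the offset
  at_mean <- matrix(colMeans(sim$scores), 1,
                    dimnames = list("x", colnames(sim$scores)))
  expect_equal(unname(predict(fit, at_mean)), fit$beta, tolerance = 1e-10)
  # id mismatch is rejected
  bad <- sim$scores; colnames(bad)[1] <- "nope"
  expect_error(predict(fit, bad), "missing")
})

test_that("effective protein weights satisfy the fold-back identity", {
  sim <- generate_synthetic(synthetic_spec(n_compounds = 40, n_proteins = 9,
                                           latent_rank = 3, seed = 12))
  y <- consolidate(sim$observations)$dataset
  fit <- dsq_fit(sim$scores, setNames(y$delta_g, y$compound_id))
  R <- effective_protein_weights(fit)
  expect_length(R, 9L)
  set.seed(3)
  x <- matrix(rnorm(9), 1, dimnames = list("z", colnames(sim$scores)))
  lhs <- unname(predict(fit, x)) - fit$beta
  rhs <- sum(R * (x[1, names(R)] - fit$basis$center[names(R)]))
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # single-axis model: weights are that axis's loadings scaled by c
  f1 <- dsq_fit(sim$scores, setNames(y$delta_g, y$compound_id),
                axes = 1L, W = Inf)
  expect_equal(unname(effective_protein_weights(f1)),
               unname(f1$basis$loadings[, 1] * f1$coefficients),
               tolerance = 1e-12)
})

test_that("model serialisation round-trips and predicts identically", {
  sim <- generate_synthetic(synthetic_spec(n_compounds = 30, n_proteins = 8,
                                           latent_rank = 3, seed = 9))
  y <- consolidate(sim$observations)$dataset
  fit <- dsq_fit(sim$scores, setNames(y$delta_g, y$compound_id),
                 lambda = 2e-4, W = 20, target_id = "SYN1")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_dsqsar(fit, path)
  back <- read_dsqsar(path)
  expect_identical(back$axes, fit$axes)
  expect_identical(back$W, fit$W)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 0)
  expect_identical(predict(back, sim$scores), predict(fit, sim$scores))
  # the disabled sentinel survives the round trip
  fitI <- dsq_fit(sim$scores, setNames(y$delta_g, y$compound_id), W = Inf)
  write_dsqsar(fitI, path)
  expect_identical(read_dsqsar(path)$W, Inf)
})
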