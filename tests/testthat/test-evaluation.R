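# Q2/RMSE metrics, cross-validation protocols, grid search.

test_that("Q2 and RMSE reproduce hand values and their identities", {
  expect_identical(q_squared(c(-9, -8, -7), c(-9, -8, -7)), 1)
  expect_identical(rmse(c(-9, -8, -7), c(-9, -8, -7)), 0)
  e <- c(0, 1, 2)
  expect_identical(q_squared(rep(mean(e), 3), e), 0)
  expect_equal(q_squared(c(0, 1, 3), e), 0.5)
  expect_equal(rmse(c(0, 1, 3), e), sqrt(1 / 3))
  # shift invariance of Q2; RMSE of a constant offset is the offset
  expect_equal(q_squared(c(0, 1, 3) - 5, e - 5), 0.5)
  expect_equal(rmse(e + 0.7, e), 0.7)
  expect_identical(rmse(e, e + 0.7), rmse(e + 0.7, e))  # symmetry
  expect_error(q_squared(c(1, 2), c(3, 3)), "constant")
  expect_error(q_squared(1, 1), "length")
})

# signal-rich small fixture so protocol mechanics are visible above noise
make_cv_data <- function(n = 24, p = 6, seed = 2, reps = 1, dg_noise = 0.3) {
  generate_synthetic(synthetic_spec(
    n_compounds = n, n_proteins = p, latent_rank = 3,
    n_informative_proteins = 4, true_weight_scale = 1,
    dg_noise_sd = dg_noise, replicates_per_pair = reps, seed = seed))
}

test_that("LOO pools one exact-protocol prediction per pair", {
  sim <- make_cv_data()
  cv <- loo_cv(sim$scores, sim$observations, lambda = 1e-4, W = Inf,
               max_axes = 4)
  expect_identical(cv$n, 24L)
  expect_identical(nrow(cv$predictions), 24L)
  expect_false(any(is.na(cv$predictions$dg_pred)))
  # stored scalars recompute exactly from the stored prediction pairs
  expect_identical(cv$q2, q_squared(cv$predictions$dg_pred,
                                    cv$predictions$dg_exp))
  expect_identical(cv$rmse, rmse(cv$predictions$dg_pred,
                                 cv$predictions$dg_exp))
  # 3-point minimal dataset runs
  tiny <- make_cv_data(n = 3, p = 4)
  expect_s3_class(loo_cv(tiny$scores, tiny$observations, max_axes = 1,
                         W = Inf), "dsq_cv")
  expect_error(loo_cv(tiny$scores, tiny$observations[1:2, ], W = Inf),
               "at least 3")
})

test_that("noise-free linear data cross-validates almost perfectly", {
  sim <- generate_synthetic(synthetic_spec(
    n_compounds = 30, n_proteins = 8, latent_rank = 3, score_noise_sd = 0,
    dg_noise_sd = 0, replicates_per_pair = 1, seed = 14))
  cv <- loo_cv(sim$scores, sim$observations, lambda = 0, W = Inf,
               max_axes = 6)
  expect_gte(cv$q2, 0.99)
})

test_that("shuffled labels carry no cross-validated signal", {
  q2s <- vapply(1:3, function(s) {
    sim <- make_cv_data(n = 50, p = 8, seed = s)
    obs <- sim$observations
    set.seed(s)
    obs$delta_g <- sample(obs$delta_g)
    loo_cv(sim$scores, obs, W = Inf, max_axes = 4)$q2
  }, numeric(1))
  expect_lte(mean(q2s), 0.2)
})

test_that("k-fold partitions are seeded, balanced and reduce to LOO at k = n", {
  sim <- make_cv_data()
  cv1 <- kfold_cv(sim$scores, sim$observations, k = 4, seed = 7, W = Inf,
                  max_axes = 4)
  cv2 <- kfold_cv(sim$scores, sim$observations, k = 4, seed = 7, W = Inf,
                  max_axes = 4)
  expect_identical(cv1$predictions, cv2$predictions)   # determinism
  expect_identical(cv1$q2, cv2$q2)
  sizes <- table(cv1$predictions$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(sum(sizes), 24L)
  # k = n is leave-one-out
  cvn <- kfold_cv(sim$scores, sim$observations, k = 24, seed = 1, W = Inf,
                  max_axes = 4)
  loo <- loo_cv(sim$scores, sim$observations, W = Inf, max_axes = 4)
  o1 <- cvn$predictions[order(cvn$predictions$compound_id), ]
  o2 <- loo$predictions[order(loo$predictions$compound_id), ]
  expect_equal(o1$dg_pred, o2$dg_pred, tolerance = 1e-12)
  expect_error(kfold_cv(sim$scores, sim$observations, k = 25, W = Inf),
               "exceeds")
  expect_error(kfold_cv(sim$scores, sim$observations, k = 1, W = Inf),
               "at least 2")
})

test_that("multiple targets are stratified and reported per target", {
  s1 <- make_cv_data(n = 12, p = 5, seed = 3)
  obs2 <- s1$observations
  obs2$target_id <- "SYN2"
  set.seed(1); obs2$delta_g <- obs2$delta_g + rnorm(nrow(obs2), sd = 0.2)
  both <- rbind(s1$observations, obs2)
  cv <- kfold_cv(s1$scores, both, k = 3, seed = 2, W = Inf, max_axes = 3)
  expect_identical(nrow(cv$per_target), 2L)
  expect_identical(cv$n, 24L)
  # every target appears in every fold (stratification)
  tab <- table(cv$predictions$target_id, cv$predictions$fold)
  expect_true(all(tab > 0))
  # pooled and averaged aggregations both reported
  expect_true(is.finite(cv$q2_avg) && is.finite(cv$rmse_avg))
})

test_that("replicate consolidation inside CV respects the N-sigma rule", {
  sim <- make_cv_data(n = 15, p = 5, seed = 8, reps = 3)
  cv <- loo_cv(sim$scores, sim$observations, n_sigma = 3, W = Inf,
               max_axes = 3)
  expect_identical(cv$filter_report$n_observations, 45L)
  expect_identical(cv$n, 15L)
  expect_lte(cv$filter_report$removal_fraction, 0.05)
})

test_that("grid search evaluates every cell and orders the best sanely", {
  sim <- make_cv_data(n = 20, p = 5, seed = 10)
  g <- grid_search(sim$scores, sim$observations,
                   lambda_grid = c(1e-4, 1e8), w_grid = c(Inf, 20),
                   n_sigma_grid = NA, protocol = "kfold", k = 4, seed = 3,
                   max_axes = 3)
  expect_identical(nrow(g$table), 4L)
  expect_identical(names(g$table),
                   c("lambda", "W", "N", "Q2", "RMSE_kcal_mol", "n_points"))
  expect_identical(g$best$Q2, max(g$table$Q2))
  # single-cell grid works
  g1 <- grid_search(sim$scores, sim$observations, lambda_grid = 1e-4,
                    w_grid = Inf, n_sigma_grid = NA, protocol = "kfold",
                    k = 4, seed = 3, max_axes = 3)
  expect_identical(nrow(g1$table), 1L)
  # over-regularisation hurts: crushing the coefficients to the ideal value
  # leaves only the offset, which cannot track the signal
  tab <- g$table[is.infinite(g$table$W), ]
  expect_gt(tab$RMSE_kcal_mol[tab$lambda == 1e8],
            tab$RMSE_kcal_mol[tab$lambda == 1e-4])
  expect_error(grid_search(sim$scores, sim$observations,
                           lambda_grid = numeric()), "non-empty")
})

test_that("held-out labels cannot influence the training-fold models", {
  sim <- make_cv_data(n = 20, p = 5, seed = 5)
  cv1 <- kfold_cv(sim$scores, sim$observations, k = 4, seed = 9, W = Inf,
                  max_axes = 3)
  # poison the labels of fold 1's test pairs only
  fold1 <- cv1$predictions$compound_id[cv1$predictions$fold == 1]
  obs <- sim$observations
  poisoned <- obs$compound_id %in% fold1
  obs$delta_g[poisoned] <- obs$delta_g[poisoned] + 50
  # poisoned folds fit wild labels and may warn about coefficient size
  cv2 <- suppressWarnings(kfold_cv(sim$scores, obs, k = 4, seed = 9,
                                   W = Inf, max_axes = 3))
  expect_identical(cv1$fold_models$SYN1[[1]], cv2$fold_models$SYN1[[1]])
  # the other folds' models MUST change (they train on the poisoned pairs)
  expect_false(identical(cv1$fold_models$SYN1[[2]],
                         cv2$fold_models$SYN1[[2]]))
})
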