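## Cross-validated Q2 and RMSE, and grid search over the restraint strength
## lambda, the robust cutoff W and the outlier-elimination multiplier N.

#' Cross-validated coefficient of determination
#'
#' `Q2 = 1 - sum((pred - exp)^2) / sum((exp - mean(exp))^2)`.  At most 1;
#' invariant to a common shift of both vectors.
#'
#' @param pred predicted free energies, kcal/mol.
#' @param exp experimental free energies, kcal/mol.
#' @return a single number `<= 1`.
#' @export
q_squared <- function(pred, exp) {
  if (length(pred) != length(exp) || length(exp) < 2L)
    stop("pred and exp must have equal length >= 2", call. = FALSE)
  den <- sum((exp - mean(exp))^2)
  if (den == 0)
    stop("exp is constant; Q2 is undefined", call. = FALSE)
  1 - sum((pred - exp)^2) / den
}

#' Root-mean-square error
#'
#' @inheritParams q_squared
#' @return RMSE in kcal/mol.
#' @export
rmse <- function(pred, exp) {
  if (length(pred) != length(exp) || length(exp) < 1L)
    stop("pred and exp must have equal, positive length", call. = FALSE)
  sqrt(mean((pred - exp)^2))
}

## Shared CV engine.  `observations` are replicate-level records; replicate
## consolidation (with optional N-sigma elimination) is a per-pair operation,
## so it is computed once up front — training statistics never see held-out
## pairs, and held-out consolidation uses only the pair's own replicates.
run_cv <- function(scores, observations, protocol, k = 4L, seed = 1L,
                   lambda = 1e-4, W = 20, n_sigma = NULL, max_axes = 15,
                   iterative = FALSE) {
  assert_score_matrix(scores)
  cons <- consolidate(observations, n_sigma, iterative)
  ds <- cons$dataset
  if (nrow(ds) == 0L) stop("no observations to cross-validate", call. = FALSE)
  miss <- setdiff(ds$compound_id, rownames(scores))
  if (length(miss) > 0L)
    stop("score matrix is missing compounds: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)

  targets <- sort(unique(ds$target_id))
  ## seeded fold assignment, stratified by target, sizes differing by <= 1
  fold_ids <- vector("list", length(targets))
  names(fold_ids) <- targets
  if (protocol == "kfold") {
    if (k < 2L) stop("k must be at least 2", call. = FALSE)
    with_seed(seed, {
      for (t in targets) {
        n_t <- sum(ds$target_id == t)
        if (k > n_t)
          stop(sprintf("k = %d exceeds the %d pairs for target %s",
                       k, n_t, t), call. = FALSE)
        fold_ids[[t]] <- sample(rep(seq_len(k), length.out = n_t))
      }
    })
  }

  pred_rows <- list()
  fold_models <- list()
  for (t in targets) {
    dt <- ds[ds$target_id == t, , drop = FALSE]
    n_t <- nrow(dt)
    if (protocol == "loo" && n_t < 3L)
      stop(sprintf("need at least 3 pairs for target %s (have %d)", t, n_t),
           call. = FALSE)
    folds <- if (protocol == "loo") as.list(seq_len(n_t))
             else split(seq_len(n_t), fold_ids[[t]])
    fm <- vector("list", length(folds))
    dg_pred <- rep(NA_real_, n_t)
    fold_of <- rep(NA_integer_, n_t)
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n_t), test)
      fit <- dsq_fit(scores[dt$compound_id[train], , drop = FALSE],
                     dt$delta_g[train], lambda = lambda, W = W,
                     max_axes = max_axes, target_id = t)
      dg_pred[test] <- predict(fit,
                               scores[dt$compound_id[test], , drop = FALSE])
      fold_of[test] <- f
      fm[[f]] <- list(axes = fit$axes, coefficients = fit$coefficients,
                      beta = fit$beta)
    }
    fold_models[[t]] <- fm
    pred_rows[[t]] <- data.frame(target_id = t,
                                 compound_id = dt$compound_id,
                                 fold = fold_of,
                                 dg_exp = dt$delta_g,
                                 dg_pred = dg_pred,
                                 stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, c(pred_rows, list(make.row.names = FALSE)))

  per_target <- do.call(rbind, lapply(split(predictions,
                                            predictions$target_id),
    function(d) data.frame(
      target_id = d$target_id[1L], n = nrow(d),
      q2 = if (nrow(d) >= 2L && stats::sd(d$dg_exp) > 0)
        q_squared(d$dg_pred, d$dg_exp) else NA_real_,
      rmse = rmse(d$dg_pred, d$dg_exp), stringsAsFactors = FALSE)))
  rownames(per_target) <- NULL

  structure(list(
    protocol = protocol, k = if (protocol == "kfold") k else NA_integer_,
    seed = if (protocol == "kfold") seed else NA_integer_,
    hyper = list(lambda = lambda, W = W, n_sigma = n_sigma %||% NA_real_,
                 max_axes = max_axes),
    predictions = predictions,
    q2 = q_squared(predictions$dg_pred, predictions$dg_exp),
    rmse = rmse(predictions$dg_pred, predictions$dg_exp),
    per_target = per_target,
    q2_avg = mean(per_target$q2, na.rm = TRUE),
    rmse_avg = mean(per_target$rmse),
    n = nrow(predictions),
    fold_models = fold_models,
    filter_report = cons$report), class = "dsq_cv")
}

#' Leave-one-out cross-validation of the docking-score QSAR model
#'
#' For every held-out pair the full pipeline is rerun on the remainder:
#' column centring, PCA, axis selection and the (robust) restrained fit —
#' held-out data never leak into any training statistic.  Replicates are
#' consolidated per pair (with N-sigma elimination when `n_sigma` is given),
#' for training and held-out pairs alike.  With several targets each target
#' is modelled separately; the report carries pooled and per-target metrics
#' as well as their across-target averages.
#'
#' @param scores docking-score matrix covering all referenced compounds.
#' @param observations replicate-level data frame with columns `target_id`
#'   (optional), `compound_id`, `delta_g` (kcal/mol).
#' @param lambda,W,max_axes model hyperparameters, as in [dsq_fit()].
#' @param n_sigma replicate outlier-elimination multiplier, or `NULL`.
#' @param iterative passed to [consolidate()].
#' @return object of class `dsq_cv`: per-pair predictions, pooled `q2` and
#'   `rmse`, `per_target` breakdown, per-fold model coefficients, and the
#'   consolidation report.
#' @export
loo_cv <- function(scores, observations, lambda = 1e-4, W = 20,
                   n_sigma = NULL, max_axes = 15, iterative = FALSE) {
  run_cv(scores, observations, "loo", lambda = lambda, W = W,
         n_sigma = n_sigma, max_axes = max_axes, iterative = iterative)
}

#' k-fold cross-validation of the docking-score QSAR model
#'
#' Folds are a seeded random partition with sizes differing by at most one,
#' drawn separately within each target (stratification), and the per-fold
#' protocol is identical to [loo_cv()].  `k = n` reproduces leave-one-out.
#'
#' @inheritParams loo_cv
#' @param k number of folds (`>= 2`, at most the number of pairs).
#' @param seed partition seed; fixed seed gives an identical report.
#' @export
kfold_cv <- function(scores, observations, k = 4L, seed = 1L,
                     lambda = 1e-4, W = 20, n_sigma = NULL, max_axes = 15,
                     iterative = FALSE) {
  run_cv(scores, observations, "kfold", k = k, seed = seed, lambda = lambda,
         W = W, n_sigma = n_sigma, max_axes = max_axes,
         iterative = iterative)
}

#' @export
print.dsq_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation (%d predictions", toupper(x$protocol), x$n))
  if (x$protocol == "kfold") cat(sprintf(", k = %d, seed = %d", x$k, x$seed))
  cat(")\n")
  cat(sprintf("  lambda = %g, W = %s, N = %s\n", x$hyper$lambda,
              if (is.infinite(x$hyper$W)) "disabled" else format(x$hyper$W),
              if (is.na(x$hyper$n_sigma)) "none" else format(x$hyper$n_sigma)))
  cat(sprintf("  pooled Q2 = %.3f, RMSE = %.3f kcal/mol\n", x$q2, x$rmse))
  if (nrow(x$per_target) > 1L)
    cat(sprintf("  per-target averages: Q2 = %.3f, RMSE = %.3f kcal/mol\n",
                x$q2_avg, x$rmse_avg))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' The restraint grid spans 0 to 0.1; the robust cutoff grid spans 5 to 100
#' kcal/mol plus the disabled sentinel (`Inf`); the elimination grid spans
#' 0.2 to 3 standard deviations.
#'
#' @return numeric vector.
#' @export
dsq_lambda_grid <- function()
  c(0, 1e-5, 2e-5, 5e-5, 1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3, 1e-2, 0.1)

#' @rdname dsq_lambda_grid
#' @export
dsq_w_grid <- function() c(Inf, 5, 10, 15, 20, 50, 100)

#' @rdname dsq_lambda_grid
#' @export
dsq_n_grid <- function() c(0.2, 0.4, 0.5, 0.6, 0.8, 1, 2, 3)

#' Hyperparameter grid search
#'
#' Evaluates every (lambda, W, N) cell with the requested cross-validation
#' protocol and reports Q2 and RMSE per cell.  The best cell maximises Q2;
#' ties break to the smaller RMSE, then the smaller lambda, then the smaller
#' W (the disabled sentinel `Inf` sorts last).  Use `NA` in `n_sigma_grid`
#' for "no elimination".
#'
#' @inheritParams kfold_cv
#' @param lambda_grid,w_grid,n_sigma_grid non-empty grids; defaults are the
#'   default grids [dsq_lambda_grid()], [dsq_w_grid()], [dsq_n_grid()].
#' @param protocol `"loo"` or `"kfold"`.
#' @return object of class `dsq_grid` with `table` (columns `lambda`, `W`,
#'   `N`, `Q2`, `RMSE_kcal_mol`, `n_points`) and `best` (the winning row).
#' @export
grid_search <- function(scores, observations,
                        lambda_grid = dsq_lambda_grid(),
                        w_grid = dsq_w_grid(),
                        n_sigma_grid = NA,
                        protocol = c("loo", "kfold"), k = 4L, seed = 1L,
                        max_axes = 15, iterative = FALSE) {
  protocol <- match.arg(protocol)
  if (length(lambda_grid) == 0L || length(w_grid) == 0L ||
      length(n_sigma_grid) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  cells <- expand.grid(lambda = lambda_grid, W = w_grid, N = n_sigma_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    n_sigma <- if (is.na(cells$N[i])) NULL else cells$N[i]
    cv <- run_cv(scores, observations, protocol, k = k, seed = seed,
                 lambda = cells$lambda[i], W = cells$W[i],
                 n_sigma = n_sigma, max_axes = max_axes,
                 iterative = iterative)
    rows[[i]] <- data.frame(lambda = cells$lambda[i], W = cells$W[i],
                            N = cells$N[i], Q2 = cv$q2,
                            RMSE_kcal_mol = cv$rmse, n_points = cv$n)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ord <- order(-tab$Q2, tab$RMSE_kcal_mol, tab$lambda, tab$W)
  structure(list(table = tab, best = tab[ord[1L], , drop = FALSE],
                 protocol = protocol, k = k, seed = seed),
            class = "dsq_grid")
}

#' @export
print.dsq_grid <- function(x, ...) {
  cat(sprintf("Hyperparameter grid search (%s CV, %d cells)\n",
              toupper(x$protocol), nrow(x$table)))
  cat("best cell:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Write a grid-search table as delimited text
#'
#' Tab-separated with columns `lambda`, `W`, `N`, `Q2`, `RMSE_kcal_mol`,
#' `n_points`; a disabled robust cutoff is written as `disabled`.
#'
#' @param grid a [grid_search()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(grid, path) {
  tab <- grid$table
  tab$W <- ifelse(is.infinite(tab$W), "disabled", format(tab$W))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
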