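## Restrained (Tikhonov) regression on PC coordinates and its Tukey-type
## M-estimation variant.  Coefficients live on the kcal/mol scale, and the
## restraint pulls them toward an ideal value (0 when the probe panel does
## not contain the target protein itself).

#' Tukey-type M-estimation weight
#'
#' `w(d) = (1 - d^2/W^2)^2` for `|d| <= W`, and 0 beyond the cutoff, applied
#' to the absolute residual so negative and positive errors weight
#' symmetrically.  `W = Inf` disables robust weighting (all weights 1).
#'
#' @param d residual(s), kcal/mol.
#' @param W upper limit of allowed error, kcal/mol; positive (or `Inf`).
#' @return weight(s) in `[0, 1]`.
#' @examples
#' tukey_weight(0, 10)          # 1
#' tukey_weight(5, 10)          # 0.5625
#' tukey_weight(c(-11, 11), 10) # 0 0
#' @export
tukey_weight <- function(d, W) {
  if (!is.numeric(W) || length(W) != 1L || is.na(W) || W <= 0)
    stop("W must be a single positive value (Inf disables weighting)",
         call. = FALSE)
  a <- abs(d)
  r <- a / W                      # 0 when W = Inf
  ifelse(a > W, 0, (1 - r^2)^2)
}

#' Fit the restrained least-squares objective
#'
#' Exact minimiser of
#' `sum_i w_i (y_i - sum_j c_j p_ij - beta)^2 + lambda * sum_j (c_j - c_ideal_j)^2`
#' over `(c, beta)`; the offset `beta` is never penalised.  Solved in closed
#' form through the penalised normal equations.
#'
#' @param P coordinate matrix (compounds x axes).
#' @param y experimental free energies, kcal/mol.
#' @param lambda restraint strength, `>= 0`.
#' @param c_ideal restraint target for the coefficients (recycled; default 0).
#' @param weights optional non-negative per-observation weights.
#' @return list with `coefficients` (c, kcal/mol scale), `beta`, `fitted`,
#'   and the achieved `objective` value.
#' @export
fit_restrained <- function(P, y, lambda = 0, c_ideal = 0, weights = NULL) {
  P <- as.matrix(P)
  n <- nrow(P); k <- ncol(P)
  if (length(y) != n) stop("length(y) must equal nrow(P)", call. = FALSE)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("lambda must be a single non-negative number", call. = FALSE)
  c_ideal <- rep_len(c_ideal, k)
  w <- if (is.null(weights)) rep(1, n) else rep_len(weights, n)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  X <- cbind(P, 1)
  pen <- diag(c(rep(lambda, k), 0), k + 1L)
  A <- crossprod(X, X * w) + pen
  b <- crossprod(X, w * y) + pen %*% c(c_ideal, 0)
  theta <- tryCatch(drop(solve(A, b)), error = function(e)
    stop("singular normal equations (collinear axes or degenerate weights); ",
         "use lambda > 0", call. = FALSE))
  cc <- theta[seq_len(k)]
  beta <- theta[k + 1L]
  fitted <- drop(X %*% theta)
  list(coefficients = unname(cc), beta = unname(beta), fitted = fitted,
       objective = sum(w * (y - fitted)^2) + lambda * sum((cc - c_ideal)^2))
}

## Tukey robust loss with cutoff W, scaled so that rho_W(d) -> d^2 as
## W -> Inf.  The weighted least-squares form of the objective (weights
## (1 - d^2/W^2)^2) is exactly the quadratic majorisation of this loss at
## the current residuals, so IRLS descends it monotonically.
tukey_rho <- function(d, W) {
  if (is.infinite(W)) return(d^2)
  a <- pmin(abs(d), W)
  (W^2 / 3) * (1 - (1 - (a / W)^2)^3)
}

## Iteratively reweighted least squares for the M-estimation objective.
## Starts from unit weights (d = 0), alternates weighted restrained fits,
## residual updates and Tukey weight updates until the coefficients move by
## less than `tol` (relative max change) or `max_iter` is reached.  The
## recorded objective is the robust loss sum(rho_W(d)) + restraint, which
## each exact weighted fit can only decrease.
irls_restrained <- function(P, y, lambda, W, c_ideal = 0,
                            tol = 1e-8, max_iter = 100L) {
  n <- length(y)
  w <- rep(1, n)
  theta_old <- NULL
  objective_trace <- numeric()
  iterations <- 0L
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- fit_restrained(P, y, lambda, c_ideal, weights = w)
    d <- y - fit$fitted
    w_new <- tukey_weight(d, W)
    if (all(w_new == 0))
      stop("all observations received zero weight; increase W", call. = FALSE)
    obj <- sum(tukey_rho(d, W)) +
      lambda * sum((fit$coefficients - rep_len(c_ideal, ncol(P)))^2)
    objective_trace <- c(objective_trace, obj)
    theta <- c(fit$coefficients, fit$beta)
    iterations <- it
    if (!is.null(theta_old)) {
      delta <- max(abs(theta - theta_old)) / max(1, max(abs(theta_old)))
      if (delta < tol) { converged <- TRUE; break }
    }
    theta_old <- theta
    w <- w_new
  }
  d <- y - fit$fitted
  list(fit = fit,
       diagnostics = list(residuals = d, weights = tukey_weight(d, W),
                          iterations = iterations, converged = converged,
                          objective = objective_trace[length(objective_trace)],
                          objective_trace = objective_trace))
}

#' Fit a docking-score QSAR model
#'
#' The main modelling entry point.  The score matrix is centred and
#' decomposed by PCA ([score_pca()]), predictive axes are selected by greedy
#' forward search against leave-one-out correlation ([select_axes()]) unless
#' given explicitly, and coefficients are fitted by the Tikhonov-restrained
#' objective — robustly, through Tukey-type iteratively reweighted least
#' squares, when `W` is finite.
#'
#' Coefficients are on the kcal/mol scale and are restrained toward
#' `c_ideal` (default 0, appropriate when the probe panel does not include
#' the target protein); fits with `|c| >= 18` kcal/mol trigger a warning,
#' since realistic binding free energies are below that magnitude.
#'
#' @param scores compounds x probe-proteins docking-score matrix (finite,
#'   with compound/protein ids as dimnames).
#' @param dg experimental binding free energies, kcal/mol: either an unnamed
#'   vector aligned with `rownames(scores)` or a named vector that is
#'   reordered by name.
#' @param lambda restraint strength (default 1e-4, the centre of the well-
#'   behaved range of the default restraint grid).
#' @param W M-estimation error cutoff, kcal/mol; `Inf` disables robust
#'   reweighting and yields exactly the plain restrained fit.
#' @param max_axes cap on the number of selected PC axes.
#' @param axes explicit axis indices, bypassing selection.
#' @param c_ideal restraint target for the coefficients.
#' @param target_id optional label carried into the model and its
#'   serialisation.
#' @param tol,max_iter IRLS convergence controls.
#' @return an object of class `dsqsar`; see [predict.dsqsar()],
#'   [effective_protein_weights()], [write_dsqsar()].
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_compounds = 60, n_proteins = 12,
#'                                          latent_rank = 3, seed = 7))
#' y <- consolidate(sim$observations)$dataset
#' fit <- dsq_fit(sim$scores, stats::setNames(y$delta_g, y$compound_id))
#' fit
#' @export
dsq_fit <- function(scores, dg, lambda = 1e-4, W = 20, max_axes = 15,
                    axes = NULL, c_ideal = 0, target_id = NULL,
                    tol = 1e-8, max_iter = 100L) {
  assert_score_matrix(scores)
  if (ncol(scores) < 2L)
    stop("need at least 2 probe proteins", call. = FALSE)
  if (!is.null(names(dg))) {
    miss <- setdiff(rownames(scores), names(dg))
    if (length(miss) > 0L)
      stop("dg is missing compounds: ", paste(utils::head(miss, 5L),
                                              collapse = ", "), call. = FALSE)
    dg <- dg[rownames(scores)]
  }
  if (length(dg) != nrow(scores))
    stop("length(dg) must equal nrow(scores)", call. = FALSE)
  if (any(!is.finite(dg))) stop("dg must be finite", call. = FALSE)
  if (!is.numeric(W) || length(W) != 1L || is.na(W) || W <= 0)
    stop("W must be positive (Inf disables robust weighting)", call. = FALSE)

  pca <- score_pca(scores)
  proj <- pca$scores
  cap <- min(max_axes, ncol(proj), length(pca$protein_ids) - 1L)
  if (is.null(axes)) {
    if (nrow(scores) < 3L) {
      ## too few compounds to cross-validate a selection: fall back to the
      ## leading-variance axis
      axes <- 1L
      trace <- NULL
    } else {
      sel <- select_axes(proj, dg, lambda = lambda, max_axes = cap)
      axes <- sel$axes
      trace <- sel$trace
    }
  } else {
    if (anyDuplicated(axes) || any(axes < 1L) || any(axes > ncol(proj)))
      stop("axes must be unique indices into the PC basis", call. = FALSE)
    trace <- NULL
  }
  P <- proj[, axes, drop = FALSE]
  k <- length(axes)

  if (is.infinite(W)) {
    fit <- fit_restrained(P, dg, lambda, c_ideal)
    d <- dg - fit$fitted
    diagnostics <- list(residuals = d, weights = rep(1, length(dg)),
                        iterations = 0L, converged = TRUE,
                        objective = fit$objective,
                        objective_trace = fit$objective)
  } else {
    res <- irls_restrained(P, dg, lambda, W, c_ideal, tol, max_iter)
    fit <- res$fit
    diagnostics <- res$diagnostics
  }
  if (any(abs(fit$coefficients) >= 18))
    warning("fitted |c| >= 18 kcal/mol; consider a larger lambda",
            call. = FALSE)

  structure(list(
    call = match.call(),
    target_id = target_id,
    basis = list(center = pca$center, loadings = pca$loadings,
                 explained_variance = pca$explained_variance,
                 protein_ids = pca$protein_ids),
    axes = axes,
    selection_trace = trace,
    coefficients = fit$coefficients,
    beta = fit$beta,
    lambda = lambda,
    W = W,
    c_ideal = rep_len(c_ideal, k),
    diagnostics = diagnostics,
    fitted.values = fit$fitted,
    residuals = dg - fit$fitted,
    y = dg,
    compound_ids = rownames(scores)), class = "dsqsar")
}

#' Predict binding free energies from a fitted model
#'
#' `dG_i = beta + sum_j c_j p_ij`, with the projection `p_ij` computed from
#' the model's stored column means and loadings.  Columns of `newdata` are
#' matched to the model's probe proteins by id.
#'
#' @param object a [dsq_fit()] model.
#' @param newdata score matrix (or single named score vector); defaults to
#'   the training fitted values.
#' @param ... unused.
#' @return named vector of predicted free energies, kcal/mol.
#' @export
predict.dsqsar <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  basis <- structure(list(center = object$basis$center,
                          loadings = object$basis$loadings,
                          protein_ids = object$basis$protein_ids),
                     class = "dsq_pca")
  P <- project_scores(newdata, basis, axes = object$axes)
  stats::setNames(drop(P %*% object$coefficients) + object$beta,
                  rownames(newdata))
}

#' Effective per-protein regression weights
#'
#' Folds the PC-space coefficients back onto the probe proteins:
#' `R_b = sum_j c_j d_bj`, so that `predict(model, s) - beta` equals
#' `sum_b R_b (s_b - mean_b)`.  Large magnitudes flag an unrealistic fit.
#'
#' @param model a [dsq_fit()] model.
#' @return named vector, one weight per probe protein.
#' @export
effective_protein_weights <- function(model) {
  stopifnot(inherits(model, "dsqsar"))
  drop(model$basis$loadings[, model$axes, drop = FALSE] %*%
         model$coefficients)
}

#' @export
print.dsqsar <- function(x, ...) {
  cat("Docking-score QSAR model")
  if (!is.null(x$target_id)) cat(" for target ", x$target_id, sep = "")
  cat("\n")
  cat(sprintf("  %d probe proteins, %d compounds, %d selected axes (%s)\n",
              length(x$basis$protein_ids), length(x$y), length(x$axes),
              paste(x$axes, collapse = ", ")))
  cat(sprintf("  lambda = %g, W = %s kcal/mol\n", x$lambda,
              if (is.infinite(x$W)) "disabled" else format(x$W)))
  cat(sprintf("  training RMSE = %.3f kcal/mol\n",
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.dsqsar <- function(object, ...) {
  stats::setNames(c(object$beta, object$coefficients),
                  c("(offset)", paste0("PC", object$axes)))
}

#' @export
residuals.dsqsar <- function(object, ...) object$residuals

#' @export
fitted.dsqsar <- function(object, ...) object$fitted.values

#' @export
summary.dsqsar <- function(object, ...) {
  R <- effective_protein_weights(object)
  out <- list(model = object,
              coefficients = coef(object),
              rmse_train = sqrt(mean(object$residuals^2)),
              r2_train = 1 - sum(object$residuals^2) /
                sum((object$y - mean(object$y))^2),
              weight_range = range(R),
              weight_sd = stats::sd(R),
              iterations = object$diagnostics$iterations,
              converged = object$diagnostics$converged,
              n_zero_weight = sum(object$diagnostics$weights == 0))
  class(out) <- "summary.dsqsar"
  out
}

#' @export
print.summary.dsqsar <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training R^2 = %.3f\n", x$r2_train))
  cat(sprintf("  effective protein weights R_b in [%.3g, %.3g], sd %.3g\n",
              x$weight_range[1L], x$weight_range[2L], x$weight_sd))
  if (is.finite(x$model$W))
    cat(sprintf("  IRLS: %d iterations, converged: %s, %d zero-weight points\n",
                x$iterations, x$converged, x$n_zero_weight))
  cat("  coefficients (kcal/mol):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
plot.dsqsar <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values,
                 xlab = expression(paste("experimental ", Delta, "G (kcal/mol)")),
                 ylab = expression(paste("fitted ", Delta, "G (kcal/mol)")),
                 main = "Docking-score QSAR fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialise a fitted model to JSON
#'
#' Stores everything prediction needs (ids, axes, coefficients, offset,
#' column means, selected loading columns, hyperparameters) at full numeric
#' precision, so a round-trip through [read_dsqsar()] predicts identically.
#'
#' @param model a [dsq_fit()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dsqsar <- function(model, path) {
  stopifnot(inherits(model, "dsqsar"))
  L <- model$basis$loadings[, model$axes, drop = FALSE]
  num <- function(x) sprintf("%.17g", x)  # decimal-exact double round trip
  doc <- list(
    format = "dsqsar-model",
    version = as.character(utils::packageVersion("dsqsar")),
    target_id = model$target_id,
    protein_ids = model$basis$protein_ids,
    axes = model$axes,
    coefficients = num(model$coefficients),
    beta = num(model$beta),
    lambda = num(model$lambda),
    W = if (is.infinite(model$W)) "disabled" else num(model$W),
    c_ideal = num(model$c_ideal),
    center = num(unname(model$basis$center)),
    loadings = num(as.vector(L)))  # column-major, proteins x selected axes
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialised model
#'
#' @param path a file written by [write_dsqsar()].
#' @return a `dsqsar` model usable with [predict.dsqsar()] and
#'   [effective_protein_weights()].
#' @export
read_dsqsar <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "dsqsar-model"))
    stop("not a dsqsar model file: ", path, call. = FALSE)
  k <- length(doc$axes)
  L <- matrix(as.numeric(doc$loadings), nrow = length(doc$protein_ids),
              ncol = k,
              dimnames = list(doc$protein_ids, paste0("PC", doc$axes)))
  full <- matrix(0, length(doc$protein_ids), max(doc$axes),
                 dimnames = list(doc$protein_ids,
                                 paste0("PC", seq_len(max(doc$axes)))))
  full[, doc$axes] <- L
  structure(list(
    target_id = doc$target_id,
    basis = list(center = stats::setNames(as.numeric(doc$center),
                                          doc$protein_ids),
                 loadings = full, explained_variance = NULL,
                 protein_ids = doc$protein_ids),
    axes = as.integer(doc$axes),
    coefficients = as.numeric(doc$coefficients),
    beta = as.numeric(doc$beta),
    lambda = as.numeric(doc$lambda),
    W = if (identical(doc$W, "disabled")) Inf else as.numeric(doc$W),
    c_ideal = as.numeric(doc$c_ideal),
    diagnostics = NULL, fitted.values = NULL, residuals = NULL,
    y = NULL, compound_ids = NULL, call = NULL), class = "dsqsar")
}
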