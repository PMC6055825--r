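## Synthetic docking-score and affinity data with the statistical structure
## the method assumes: a low-rank score matrix (compounds share latent
## pharmacophore-like responses across probe proteins) and free energies that
## are a sparse linear combination of the noiseless scores, observed through
## replicated noisy measurements with an optional planted fraction of gross
## outliers.  Every module's ground-truth tests are driven from here.

#' Specification of a synthetic docking-score QSAR dataset
#'
#' Defaults describe a realistic desk-scale study: 500 compounds docked
#' against 60 probe proteins, 8 latent factors, a sparse true weight vector
#' over 10 probes with magnitudes well below the few-kcal/mol effective
#' weights seen in real fits, per-replicate free-energy noise of 0.7 kcal/mol
#' (the typical spread of repeated database measurements of one pair), and
#' 3 replicates per pair.  Scores carry a small 0.2 kcal/mol jitter on top of
#' their low-rank structure.  True free energies are centred at -9 kcal/mol,
#' the middle of the usual binder range.
#'
#' @param n_compounds,n_proteins matrix dimensions.
#' @param latent_rank number of shared latent factors;
#'   `<= min(n_compounds, n_proteins)`.
#' @param n_informative_proteins sparsity of the true weight vector.
#' @param true_weight_scale magnitude scale of nonzero true weights
#'   (kcal/mol per score unit).
#' @param score_noise_sd sd of the score jitter around the low-rank part.
#' @param dg_noise_sd sd of per-replicate free-energy noise, kcal/mol.
#' @param replicates_per_pair replicate measurements per (target, compound)
#'   pair, `>= 1`.
#' @param outlier_fraction probability that a replicate is replaced by a
#'   grossly shifted value; in `[0, 1)`.
#' @param outlier_shift shift of planted outliers, kcal/mol.
#' @param dg_offset centre of the true free energies, kcal/mol.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return object of class `dsq_spec`.
#' @export
synthetic_spec <- function(n_compounds = 500, n_proteins = 60,
                           latent_rank = 8,
                           n_informative_proteins = min(10, n_proteins),
                           true_weight_scale = 0.3, score_noise_sd = 0.2,
                           dg_noise_sd = 0.7, replicates_per_pair = 3,
                           outlier_fraction = 0, outlier_shift = 5,
                           dg_offset = -9, seed = 1) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop(sprintf("invalid synthetic spec: %s %s", field,
                                  what), call. = FALSE)
  }
  chk(is.numeric(n_compounds) && n_compounds >= 2, "n_compounds",
      "must be >= 2")
  chk(is.numeric(n_proteins) && n_proteins >= 2, "n_proteins", "must be >= 2")
  chk(is.numeric(latent_rank) && latent_rank >= 1 &&
        latent_rank <= min(n_compounds, n_proteins), "latent_rank",
      "must be in [1, min(n_compounds, n_proteins)]")
  chk(is.numeric(n_informative_proteins) && n_informative_proteins >= 1 &&
        n_informative_proteins <= n_proteins, "n_informative_proteins",
      "must be in [1, n_proteins]")
  chk(is.numeric(true_weight_scale) && true_weight_scale > 0,
      "true_weight_scale", "must be positive")
  chk(is.numeric(score_noise_sd) && score_noise_sd >= 0, "score_noise_sd",
      "must be >= 0")
  chk(is.numeric(dg_noise_sd) && dg_noise_sd >= 0, "dg_noise_sd",
      "must be >= 0")
  chk(is.numeric(replicates_per_pair) && replicates_per_pair >= 1,
      "replicates_per_pair", "must be >= 1")
  chk(is.numeric(outlier_fraction) && outlier_fraction >= 0 &&
        outlier_fraction < 1, "outlier_fraction", "must be in [0, 1)")
  chk(is.numeric(outlier_shift) && is.finite(outlier_shift), "outlier_shift",
      "must be finite")
  chk(is.numeric(seed) && is.finite(seed), "seed", "must be finite")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_proteins = as.integer(n_proteins),
                 latent_rank = as.integer(latent_rank),
                 n_informative_proteins = as.integer(n_informative_proteins),
                 true_weight_scale = true_weight_scale,
                 score_noise_sd = score_noise_sd,
                 dg_noise_sd = dg_noise_sd,
                 replicates_per_pair = as.integer(replicates_per_pair),
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift,
                 dg_offset = dg_offset,
                 seed = seed), class = "dsq_spec")
}

#' Generate a synthetic docking-score QSAR dataset
#'
#' Scores are `F L' + noise` with Gaussian latent factors `F` (compounds x
#' rank) and loadings `L` (proteins x rank).  True free energies are a sparse
#' linear combination of the noiseless scores plus an offset.  Each pair
#' yields `replicates_per_pair` observations `truth + N(0, dg_noise_sd)`,
#' each independently replaced by `truth + outlier_shift` with probability
#' `outlier_fraction`.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `dsq_sim` with `scores` (matrix), `observations`
#'   (replicate-level data frame: `target_id`, `compound_id`, `replicate`,
#'   `delta_g`), `truth` (`weights` per protein, `dg_true` per compound,
#'   `outlier_flags` aligned with `observations`), and the `spec`.
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "dsq_spec"))
    stop("spec must be a synthetic_spec()", call. = FALSE)
  n <- spec$n_compounds; p <- spec$n_proteins; r <- spec$latent_rank
  with_seed(spec$seed, {
    compound_ids <- sprintf("CMP%04d", seq_len(n))
    protein_ids <- sprintf("PRB%03d", seq_len(p))
    F <- matrix(stats::rnorm(n * r), n, r)
    L <- matrix(stats::rnorm(p * r), p, r)
    S0 <- tcrossprod(F, L)
    scores <- S0 + matrix(stats::rnorm(n * p, sd = spec$score_noise_sd), n, p)
    dimnames(scores) <- list(compound_ids, protein_ids)

    w <- numeric(p)
    informative <- sort(sample.int(p, spec$n_informative_proteins))
    w[informative] <- stats::runif(spec$n_informative_proteins, 0.5, 1) *
      spec$true_weight_scale *
      sample(c(-1, 1), spec$n_informative_proteins, replace = TRUE)
    dg_true <- drop(S0 %*% w) + spec$dg_offset

    reps <- spec$replicates_per_pair
    truth_rep <- rep(dg_true, each = reps)
    noisy <- truth_rep + stats::rnorm(n * reps, sd = spec$dg_noise_sd)
    flags <- stats::runif(n * reps) < spec$outlier_fraction
    noisy[flags] <- truth_rep[flags] + spec$outlier_shift
    observations <- data.frame(
      target_id = "SYN1",
      compound_id = rep(compound_ids, each = reps),
      replicate = rep(seq_len(reps), times = n),
      delta_g = noisy, stringsAsFactors = FALSE)

    structure(list(scores = scores, observations = observations,
                   truth = list(weights = stats::setNames(w, protein_ids),
                                dg_true = stats::setNames(dg_true,
                                                          compound_ids),
                                outlier_flags = flags),
                   spec = spec), class = "dsq_sim")
  })
}

#' @export
print.dsq_sim <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("Synthetic docking-score QSAR dataset: %d compounds x ",
                     "%d proteins (rank %d), %d replicates/pair, seed %g\n"),
              s$n_compounds, s$n_proteins, s$latent_rank,
              s$replicates_per_pair, s$seed))
  cat(sprintf("  %d observations, %d planted outliers\n",
              nrow(x$observations), sum(x$truth$outlier_flags)))
  invisible(x)
}

#' Best-achievable RMSE implied by a synthetic spec
#'
#' The replicate mean of a pair carries noise `dg_noise_sd / sqrt(replicates)`;
#' no predictor of the consolidated value can beat that floor in expectation.
#'
#' @param spec a [synthetic_spec()].
#' @return expected noise floor, kcal/mol.
#' @export
noise_floor <- function(spec) {
  if (!inherits(spec, "dsq_spec"))
    stop("spec must be a synthetic_spec()", call. = FALSE)
  spec$dg_noise_sd / sqrt(spec$replicates_per_pair)
}
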