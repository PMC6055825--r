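# Small in-code fixtures shared across the suite.

# random score matrix with proper dimnames
make_scores <- function(n, p, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n * p, sd = sd), n, p,
         dimnames = list(sprintf("c%03d", seq_len(n)),
                         sprintf("p%03d", seq_len(p))))
}

# independent brute-force minimiser of the restrained objective
# (derivative-free Nelder-Mead with restarts, started from zero)
brute_force_restrained <- function(P, y, lambda, c_ideal = 0,
                                   weights = NULL) {
  k <- ncol(P)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  ci <- rep_len(c_ideal, k)
  obj <- function(theta) {
    fit <- drop(cbind(P, 1) %*% theta)
    sum(w * (y - fit)^2) + lambda * sum((theta[seq_len(k)] - ci)^2)
  }
  theta <- rep(0, k + 1)
  res <- NULL
  for (r in 1:4) {
    res <- stats::optim(theta, obj, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-15))
    theta <- res$par
  }
  list(par = res$par, value = res$value)
}

# replicate-level observations for a single synthetic target
toy_observations <- function(pairs) {
  do.call(rbind, lapply(names(pairs), function(cid)
    data.frame(target_id = "T1", compound_id = cid,
               delta_g = pairs[[cid]], stringsAsFactors = FALSE)))
}
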