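#' dsqsar: docking-score QSAR models of binding free energy
#'
#' Binding free energies are regressed on a compound's docking scores against a
#' panel of probe proteins.  See `vignette("docking-score-qsar")` for the model
#' and its assumptions, and [dsq_fit()] for the main fitting entry point.
#'
#' @keywords internal
"_PACKAGE"

## gas constant, kcal mol^-1 K^-1
R_KCAL <- 1.987e-3

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state.  All randomness in the package funnels through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Validate a compounds x probe-proteins score matrix: numeric, finite,
## duplicate-free row/column ids.  Offending entries are named in errors.
assert_score_matrix <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("scores must be a numeric matrix (compounds x probe proteins)",
         call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must carry compound ids as rownames and protein ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(scores)))
    stop("duplicate compound ids in score matrix: ",
         paste(unique(rownames(scores)[duplicated(rownames(scores))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(scores)))
    stop("duplicate protein ids in score matrix: ",
         paste(unique(colnames(scores)[duplicated(colnames(scores))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(scores), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite score for compound '%s', protein '%s'",
                 rownames(scores)[bad[1L, 1L]], colnames(scores)[bad[1L, 2L]]),
         call. = FALSE)
  invisible(scores)
}

assert_observations <- function(observations) {
  if (!is.data.frame(observations))
    stop("observations must be a data frame", call. = FALSE)
  need <- c("compound_id", "delta_g")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0L)
    stop("observations is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"target_id" %in% names(observations))
    observations$target_id <- "target"
  if (nrow(observations) > 0L && any(!is.finite(observations$delta_g)))
    stop("observations contain non-finite delta_g values", call. = FALSE)
  observations
}
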