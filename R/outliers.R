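## N-sigma elimination of replicate outliers.  Databases often hold several
## affinity measurements for one (target, compound) pair, taken under
## different (unrecorded) assay conditions; a replicate is discarded when it
## deviates from the pair mean by more than N sample standard deviations.

#' Group affinity observations by (target, compound) pair
#'
#' @param observations data frame with columns `target_id` (optional, a single
#'   target is assumed when absent), `compound_id` and `delta_g` (kcal/mol).
#' @return list of measurement groups, one per distinct pair, ordered by
#'   (target_id, compound_id).  Each group holds `values`, their count `n`,
#'   `mean` and sample `sd` (`NA` for singletons).  Grouping is
#'   order-independent: permuting the input rows gives the same groups.
#' @export
group_measurements <- function(observations) {
  observations <- assert_observations(observations)
  if (nrow(observations) == 0L) return(list())
  key <- paste(observations$target_id, observations$compound_id, sep = "\r")
  idx <- split(seq_len(nrow(observations)), key)
  idx <- unname(idx[order(names(idx))])
  lapply(idx, function(i) {
    v <- sort(observations$delta_g[i])  # multiset; input order is irrelevant
    list(target_id = observations$target_id[i[1L]],
         compound_id = observations$compound_id[i[1L]],
         values = v, n = length(v), mean = mean(v),
         sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  })
}

#' Eliminate replicate outliers from a measurement group
#'
#' A value is an outlier when `|E(k) - mean| > N * sigma`, with the mean and
#' sample standard deviation (denominator M - 1) computed over the full group
#' in a single pass — statistics are not recomputed after removals, so the
#' rule is idempotent on its retained set.  Singletons (sigma undefined) are
#' always retained.  An iterative variant that recomputes the statistics
#' until no further value is flagged is available; it never empties a group
#' (removal stops if all remaining values would be flagged).
#'
#' @param values numeric vector of replicate free energies (kcal/mol) for one
#'   (target, compound) pair, or a group as returned by
#'   [group_measurements()].
#' @param n_sigma positive multiplier N.
#' @param iterative recompute statistics after each removal pass.
#' @return list with `retained`, `removed`, and the full-group `mean` and
#'   `sd` the decision was based on.
#' @export
eliminate_outliers <- function(values, n_sigma, iterative = FALSE) {
  if (is.list(values)) values <- values$values
  if (!is.numeric(values) || length(values) < 1L)
    stop("values must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(n_sigma) || length(n_sigma) != 1L || n_sigma <= 0)
    stop("n_sigma must be a single positive number", call. = FALSE)
  m <- mean(values)
  s <- if (length(values) >= 2L) stats::sd(values) else NA_real_
  flag_once <- function(v) {
    if (length(v) < 2L) return(rep(FALSE, length(v)))
    mv <- mean(v); sv <- stats::sd(v)
    if (!is.finite(sv) || sv == 0) return(rep(FALSE, length(v)))
    abs(v - mv) > n_sigma * sv
  }
  if (!iterative) {
    out <- if (length(values) >= 2L && is.finite(s) && s > 0)
      abs(values - m) > n_sigma * s else rep(FALSE, length(values))
    return(list(retained = values[!out], removed = values[out],
                mean = m, sd = s))
  }
  retained <- values
  removed <- numeric()
  repeat {
    out <- flag_once(retained)
    if (!any(out) || all(out)) break
    removed <- c(removed, retained[out])
    retained <- retained[!out]
  }
  list(retained = retained, removed = removed, mean = m, sd = s)
}

#' Consolidate replicate observations into one free energy per pair
#'
#' Applies [eliminate_outliers()] to every (target, compound) group and takes
#' the arithmetic mean of the retained replicates as the pair's free energy.
#' With `n_sigma = NULL` no elimination is performed and the plain replicate
#' mean is used.
#'
#' The single-pass rule can flag every value of a group when `n_sigma` is
#' small (e.g. both values of a duplicate pair once `N < 1/sqrt(2)`); this is
#' asserted and reported as an error rather than silently producing an empty
#' group.
#'
#' @inheritParams group_measurements
#' @inheritParams eliminate_outliers
#' @param n_sigma positive multiplier N, or `NULL` to skip elimination.
#' @return list with `dataset` (data frame: `target_id`, `compound_id`,
#'   `delta_g`, `n_obs`, `n_removed`) and `report` (total/removed counts,
#'   removal fraction, per-target breakdown).
#' @seealso [write_filter_report()]
#' @export
consolidate <- function(observations, n_sigma = NULL, iterative = FALSE) {
  groups <- group_measurements(observations)
  empty <- data.frame(target_id = character(), compound_id = character(),
                      delta_g = numeric(), n_obs = integer(),
                      n_removed = integer(), stringsAsFactors = FALSE)
  if (length(groups) == 0L)
    return(list(dataset = empty,
                report = list(n_observations = 0L, n_removed = 0L,
                              removal_fraction = 0,
                              n_sigma = n_sigma %||% NA_real_,
                              by_target = data.frame())))
  rows <- lapply(groups, function(g) {
    kept <- if (is.null(n_sigma)) g$values
            else {
      res <- eliminate_outliers(g$values, n_sigma, iterative)
      if (length(res$retained) == 0L)
        stop(sprintf(paste0("all %d replicate values removed for pair ",
                            "(%s, %s) at N = %g; use a larger n_sigma"),
                     g$n, g$target_id, g$compound_id, n_sigma), call. = FALSE)
      res$retained
    }
    data.frame(target_id = g$target_id, compound_id = g$compound_id,
               delta_g = mean(kept), n_obs = g$n,
               n_removed = g$n - length(kept), stringsAsFactors = FALSE)
  })
  dataset <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  by_target <- do.call(rbind, lapply(split(dataset, dataset$target_id),
    function(d) data.frame(target_id = d$target_id[1L],
                           n_pairs = nrow(d), n_observations = sum(d$n_obs),
                           n_removed = sum(d$n_removed),
                           stringsAsFactors = FALSE)))
  rownames(by_target) <- NULL
  n_total <- sum(dataset$n_obs)
  n_rm <- sum(dataset$n_removed)
  list(dataset = dataset,
       report = list(n_observations = n_total, n_removed = n_rm,
                     removal_fraction = if (n_total > 0L) n_rm / n_total else 0,
                     n_sigma = n_sigma %||% NA_real_,
                     by_target = by_target))
}

#' Write a consolidation/filter report as JSON
#'
#' @param report the `report` element returned by [consolidate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
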