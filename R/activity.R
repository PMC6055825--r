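## Conversion of heterogeneous assay records into binding free energies
## (kcal/mol), the regression target.  Stronger binder => more negative
## delta G; standard state 1 M, delta G = RT ln(K).

ASSAY_TYPES <- c("KI", "IC50", "PCT_INHIBITION", "PCT_RESIDUAL")

molar_factor <- function(unit) {
  factors <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  unit <- sub("µ", "u", unit)  # micro sign
  out <- factors[unit]
  if (any(is.na(out)))
    stop("unknown concentration unit: ",
         paste(unique(unit[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Convert an inhibition constant to a binding free energy
#'
#' `delta_g = R T ln(Ki / 1 M)` with `R = 1.987e-3` kcal/(mol K).  A Ki below
#' 1 M therefore gives a negative free energy; tighter binders are more
#' negative.
#'
#' @param value positive Ki (vectorised).
#' @param unit concentration unit, one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @param temperature_K assay temperature in kelvin (default 300 K, i.e. RT
#'   about 0.6 kcal/mol).
#' @return binding free energy in kcal/mol.
#' @examples
#' ki_to_delta_g(1e-9, "M")   # 1 nM, about -12.35 kcal/mol
#' ki_to_delta_g(1, "uM")     # same as ki_to_delta_g(1e-6, "M")
#' @export
ki_to_delta_g <- function(value, unit = "M", temperature_K = 300) {
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be positive", call. = FALSE)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("Ki/IC50 value must be positive and finite; record is unconvertible",
         call. = FALSE)
  R_KCAL * temperature_K * log(value * molar_factor(unit))
}

#' Convert an IC50 to a binding free energy
#'
#' IC50 is treated as Ki (Cheng-Prusoff correction factor 1), i.e. assay
#' conditions are assumed uniform across records; see the methods vignette.
#'
#' @inheritParams ki_to_delta_g
#' @return binding free energy in kcal/mol.
#' @export
ic50_to_delta_g <- function(value, unit = "M", temperature_K = 300) {
  ki_to_delta_g(value, unit, temperature_K)
}

#' Convert a percent-inhibition / percent-residual-activity record
#'
#' Residual activity is first mapped to inhibition (`p = 100 - value`).  A
#' non-informative record (0% inhibition, equivalently 100% residual activity)
#' is mapped to the weak-binder floor of -4 kcal/mol.  Otherwise the assay
#' concentration `C` is required and the implied IC50 is `C (100 - p) / p`;
#' complete inhibition is treated as 99% to avoid a zero IC50.  Any result
#' weaker than the floor is set to the floor, so percent-derived free energies
#' never exceed -4 kcal/mol.
#'
#' @param value percent in `[0, 100]`; slightly out-of-range values are
#'   clipped (assay noise).
#' @param kind `"PCT_INHIBITION"` or `"PCT_RESIDUAL"`.
#' @param assay_concentration compound concentration in molar at which the
#'   percent effect was measured; required unless the record is
#'   non-informative.
#' @param temperature_K assay temperature in kelvin.
#' @param floor weak-binder floor in kcal/mol.
#' @return binding free energy in kcal/mol, always `<= floor`.
#' @export
percent_to_delta_g <- function(value, kind = c("PCT_INHIBITION", "PCT_RESIDUAL"),
                               assay_concentration = NULL,
                               temperature_K = 300, floor = -4) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("percent value must be a single finite number", call. = FALSE)
  value <- min(max(value, 0), 100)
  p <- if (kind == "PCT_RESIDUAL") 100 - value else value
  if (p <= 0) return(floor)
  if (is.null(assay_concentration) || is.na(assay_concentration))
    stop("percent record without assay concentration is unconvertible",
         call. = FALSE)
  if (assay_concentration <= 0)
    stop("assay_concentration must be positive molar", call. = FALSE)
  if (p >= 100) p <- 99  # complete inhibition: IC50 capped at C/99
  ic50 <- assay_concentration * (100 - p) / p
  min(ic50_to_delta_g(ic50, "M", temperature_K), floor)
}

#' Convert a table of assay records to binding free energy observations
#'
#' Each convertible record yields one observation; unconvertible records
#' (non-positive concentrations, percent records without an assay
#' concentration, unknown assay types) are skipped and counted by reason.
#' Conversion is record-local, so the result is order-independent.
#'
#' @param records data frame with columns `compound_id`, `target_id`,
#'   `assay_type` (one of `"KI"`, `"IC50"`, `"PCT_INHIBITION"`,
#'   `"PCT_RESIDUAL"`), `value`, `unit` and optionally `assay_concentration`
#'   (molar), as returned by [read_activity_table()].
#' @param temperature_K assay temperature in kelvin.
#' @param floor weak-binder floor for percent records, kcal/mol.
#' @return list with `observations` (data frame: `compound_id`, `target_id`,
#'   `delta_g` in kcal/mol, `source_type`) and `report` (counts of converted
#'   and skipped records by reason).
#' @export
convert_records <- function(records, temperature_K = 300, floor = -4) {
  empty <- data.frame(compound_id = character(), target_id = character(),
                      delta_g = numeric(), source_type = character(),
                      stringsAsFactors = FALSE)
  report <- list(n_input = 0L, n_converted = 0L, n_skipped = 0L,
                 skipped_by_reason = integer())
  if (is.null(records) || nrow(records) == 0L)
    return(list(observations = empty, report = report))
  need <- c("compound_id", "target_id", "assay_type", "value", "unit")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_conc <- "assay_concentration" %in% names(records)
  n <- nrow(records)
  dg <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    type <- records$assay_type[i]
    val <- records$value[i]
    conc <- if (has_conc) records$assay_concentration[i] else NULL
    if (!type %in% ASSAY_TYPES) { reason[i] <- "unknown_type"; next }
    if (is.na(val)) { reason[i] <- "missing_value"; next }
    res <- tryCatch({
      switch(type,
        KI = ki_to_delta_g(val, records$unit[i], temperature_K),
        IC50 = ic50_to_delta_g(val, records$unit[i], temperature_K),
        PCT_INHIBITION = percent_to_delta_g(val, "PCT_INHIBITION", conc,
                                            temperature_K, floor),
        PCT_RESIDUAL = percent_to_delta_g(val, "PCT_RESIDUAL", conc,
                                          temperature_K, floor))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reason[i] <- if (grepl("concentration", conditionMessage(res)))
        "missing_concentration" else "nonpositive_value"
    } else dg[i] <- res
  }
  keep <- is.na(reason)
  obs <- data.frame(compound_id = as.character(records$compound_id[keep]),
                    target_id = as.character(records$target_id[keep]),
                    delta_g = dg[keep],
                    source_type = as.character(records$assay_type[keep]),
                    stringsAsFactors = FALSE)
  rownames(obs) <- NULL
  report$n_input <- n
  report$n_converted <- sum(keep)
  report$n_skipped <- sum(!keep)
  report$skipped_by_reason <-
    if (any(!keep)) table(reason[!keep]) else integer()
  list(observations = obs, report = report)
}
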