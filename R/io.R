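## Delimited-text readers and writers.  Inputs are small matrices and
## tables; everything is plain text (TSV/CSV) or JSON, full precision on
## round trips.

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a docking-score matrix from delimited text
#'
#' Expects a header row `compound_id<sep>protein ids...` followed by one row
#' per compound.  The separator (tab or comma) is detected from the header,
#' and lines starting with `#` are ignored.  Ragged rows, non-numeric cells
#' and duplicate ids are rejected with the offending line named.
#'
#' @param path input file.
#' @return numeric matrix with compound ids as rownames and protein ids as
#'   colnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L)
    stop("score matrix file needs a header and at least one row",
         call. = FALSE)
  sep <- detect_sep(lines[1L])
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  proteins <- header[-1L]
  if (length(proteins) < 1L)
    stop("score matrix header has no protein columns", call. = FALSE)
  if (anyDuplicated(proteins))
    stop("duplicate protein ids in header: ",
         paste(unique(proteins[duplicated(proteins)]), collapse = ", "),
         call. = FALSE)
  body <- strsplit(lines[-1L], sep, fixed = TRUE)
  n_fields <- lengths(body)
  bad <- which(n_fields != length(header))
  if (length(bad) > 0L)
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 lineno[-1L][bad[1L]], n_fields[bad[1L]], length(header)),
         call. = FALSE)
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(proteins))))
  vals <- matrix(vals, nrow = length(proteins))  # proteins x compounds
  nav <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nav) > 0L)
    stop(sprintf("non-numeric score at line %d (compound '%s', protein '%s')",
                 lineno[-1L][nav[1L, 2L]], ids[nav[1L, 2L]],
                 proteins[nav[1L, 1L]]), call. = FALSE)
  out <- t(vals)
  dimnames(out) <- list(ids, proteins)
  assert_score_matrix(out)
}

#' Write a docking-score matrix as tab-separated text
#'
#' Values are written with 17 significant digits so a read/write round trip
#' is bit-exact.
#'
#' @param scores score matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  assert_score_matrix(scores)
  header <- paste(c("compound_id", colnames(scores)), collapse = "\t")
  rows <- vapply(seq_len(nrow(scores)), function(i)
    paste(c(rownames(scores)[i], sprintf("%.17g", scores[i, ])),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

normalize_assay_type <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  map <- c(KI = "KI", IC50 = "IC50",
           INHIBITION = "PCT_INHIBITION",
           PCTINHIBITION = "PCT_INHIBITION",
           PERCENTINHIBITION = "PCT_INHIBITION",
           RESIDUALACTIVITY = "PCT_RESIDUAL",
           PCTRESIDUAL = "PCT_RESIDUAL",
           PERCENTRESIDUALACTIVITY = "PCT_RESIDUAL")
  out <- map[key]
  ifelse(is.na(out), NA_character_, out)
}

normalize_unit <- function(x) {
  x <- sub("µ", "u", trimws(x))
  key <- c(M = "M", mM = "mM", uM = "uM", nM = "nM", pM = "pM",
           "%" = "PERCENT", PERCENT = "PERCENT")
  out <- key[x]
  ifelse(is.na(out), NA_character_, out)
}

#' Read an activity table (ChEMBL-export-like delimited text)
#'
#' Requires header columns `compound_id`, `target_id`, `standard_type`,
#' `standard_value`, `standard_units`; `assay_concentration` (molar) is
#' optional.  Rows with an unrecognised assay type or unit are skipped and
#' counted, never fatal; a missing required column is an error naming it.
#'
#' @param path input TSV/CSV file.
#' @return list with `records` (data frame ready for [convert_records()]:
#'   `compound_id`, `target_id`, `assay_type`, `value`, `unit`,
#'   `assay_concentration`) and `report` (row counts, skip counts by reason).
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("empty activity table: ", path, call. = FALSE)
  sep <- detect_sep(first)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "\"", check.names = TRUE)
  need <- c("compound_id", "target_id", "standard_type", "standard_value",
            "standard_units")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("activity table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(tab)
  type <- normalize_assay_type(tab$standard_type)
  unit <- normalize_unit(tab$standard_units)
  value <- suppressWarnings(as.numeric(tab$standard_value))
  conc <- if ("assay_concentration" %in% names(tab))
    suppressWarnings(as.numeric(tab$assay_concentration)) else
      rep(NA_real_, n)
  ok_type <- !is.na(type)
  ## percent types must carry a percent unit and vice versa
  pct <- type %in% c("PCT_INHIBITION", "PCT_RESIDUAL")
  ok_unit <- !is.na(unit) & ((pct & unit == "PERCENT") |
                               (!pct & unit != "PERCENT"))
  ok_val <- !is.na(value)
  keep <- ok_type & ok_unit & ok_val
  reason <- ifelse(!ok_type, "unknown_type",
                   ifelse(!ok_val, "bad_value", "bad_unit"))
  records <- data.frame(compound_id = as.character(tab$compound_id[keep]),
                        target_id = as.character(tab$target_id[keep]),
                        assay_type = type[keep],
                        value = value[keep],
                        unit = ifelse(pct[keep], "PERCENT", unit[keep]),
                        assay_concentration = conc[keep],
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records,
       report = list(n_rows = n, n_parsed = sum(keep),
                     n_skipped = sum(!keep),
                     skipped_by_reason = if (any(!keep))
                       table(reason[!keep]) else integer()))
}

#' Write free-energy observations as an activity table
#'
#' The inverse of the conversion pipeline, used by the synthetic generator's
#' self-consistency path: each free energy is written as a Ki record in molar
#' (`Ki = exp(dG / RT)`), so read-and-convert recovers the input to full
#' precision.
#'
#' @param observations data frame with `target_id`, `compound_id`, `delta_g`.
#' @param path output TSV path.
#' @param temperature_K temperature used for the inverse transform.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(observations, path, temperature_K = 300) {
  observations <- assert_observations(observations)
  ki <- exp(observations$delta_g / (R_KCAL * temperature_K))
  out <- data.frame(compound_id = observations$compound_id,
                    target_id = observations$target_id,
                    standard_type = "Ki",
                    standard_value = sprintf("%.17g", ki),
                    standard_units = "M", stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write consolidated free energies as tab-separated text
#'
#' @param dataset data frame with `target_id`, `compound_id`, `delta_g`
#'   (e.g. the `dataset` element of [consolidate()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dg_table <- function(dataset, path) {
  dataset <- assert_observations(dataset)
  out <- data.frame(target_id = dataset$target_id,
                    compound_id = dataset$compound_id,
                    delta_g_kcal_mol = sprintf("%.17g", dataset$delta_g),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consolidated free-energy table written by [write_dg_table()]
#'
#' @param path input path.
#' @return data frame with `target_id`, `compound_id`, `delta_g`.
#' @export
read_dg_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("target_id", "compound_id", "delta_g_kcal_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("free-energy table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(target_id = as.character(tab$target_id),
             compound_id = as.character(tab$compound_id),
             delta_g = as.numeric(tab$delta_g_kcal_mol),
             stringsAsFactors = FALSE)
}
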