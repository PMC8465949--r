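#' Validate a paired cohort table against a schema
#'
#' A cohort table holds one row per patient and occasion (`"baseline"` or
#' `"post"`) plus one column per schema variable. Values must lie within the
#' schema support or be missing; each (patient, occasion) pair may occur at
#' most once.
#'
#' @param table a data frame with columns `patient_id`, `occasion` and the
#'   schema variables.
#' @param schema a [crs_schema].
#' @return `table`, invisibly, after checks.
#' @export
validate_cohort <- function(table, schema) {
  stopifnot(is.data.frame(table))
  if (!all(c("patient_id", "occasion") %in% names(table)))
    stop("cohort table needs 'patient_id' and 'occasion' columns")
  if (!all(table$occasion %in% c("baseline", "post")))
    stop("occasion must be coded 'baseline' or 'post'")
  extra <- setdiff(names(table), c("patient_id", "occasion", schema$name))
  if (length(extra)) stop("unknown variable(s) not in schema: ", paste(extra, collapse = ", "))
  miss <- setdiff(schema$name, names(table))
  if (length(miss)) stop("schema variable(s) missing from table: ", paste(miss, collapse = ", "))
  key <- paste(table$patient_id, table$occasion)
  if (anyDuplicated(key))
    stop("duplicated (patient, occasion) row(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    x <- table[[v]]
    if (!is.numeric(x)) stop("variable '", v, "' is not numeric")
    bad <- !is.na(x) & (x < schema$lo[i] | x > schema$hi[i])
    if (any(bad)) stop("variable '", v, "' has value(s) outside schema support [",
                       schema$lo[i], ", ", schema$hi[i], "]")
  }
  invisible(table)
}

#' Read or write a cohort CSV
#'
#' The on-disk format is comma-separated UTF-8 with a header row; empty
#' cells encode missing values. `read_cohort` validates the result against
#' the schema, so write-then-read is an identity (up to row order).
#'
#' @param path CSV file path.
#' @param schema a [crs_schema].
#' @param table a cohort data frame.
#' @return `read_cohort` returns a validated cohort data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path, schema) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  for (v in intersect(schema$name, names(tab))) {
    x <- tab[[v]]
    if (is.character(x)) {
      conv <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & is.na(conv)
      if (any(bad)) stop("unparseable value(s) in variable '", v, "': ",
                         paste(unique(x[bad]), collapse = ", "))
      x <- conv
    }
    tab[[v]] <- as.numeric(x)
  }
  validate_cohort(tab, schema)
  tab
}

#' @rdname read_cohort
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a cohort to patients observed at both occasions
#'
#' Paired analyses use only completers, i.e. patients with both a baseline
#' and a post-surgery record.
#'
#' @param table a cohort data frame.
#' @return The subset of `table` for complete pairs, ordered by patient and
#'   occasion (baseline first).
#' @export
paired_cohort <- function(table) {
  ids <- intersect(table$patient_id[table$occasion == "baseline"],
                   table$patient_id[table$occasion == "post"])
  out <- table[table$patient_id %in% ids, , drop = FALSE]
  out[order(match(out$patient_id, ids), match(out$occasion, c("baseline", "post"))), ,
      drop = FALSE]
}
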