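#' Variable schema for the paired CRS cohort
#'
#' A schema declares, for every variable in a cohort table, its clinical
#' category, measurement scale, support and the direction in which a change
#' counts as an improvement. The default schema describes the d = 37
#' variables of the study design: 3 nasal anatomy/pathology variables, 8
#' olfactory variables, 14 quality-of-life variables and 12
#' demographic/concomitant-disease variables.
#'
#' @param name,category,scale,lo,hi,improves_when vectors defining one row
#'   per variable. `category` is one of `"anatomy"`, `"olfactory"`, `"qol"`,
#'   `"demographic"`; `scale` one of `"interval"`, `"ordinal"`, `"binary"`,
#'   `"nominal"`; `lo`/`hi` bound the support; `improves_when` is
#'   `"decreases"`, `"increases"` or `"none"`.
#' @return A data frame of class `crs_schema`.
#' @export
crs_schema <- function(name, category, scale, lo, hi, improves_when) {
  category <- match.arg(category, c("anatomy", "olfactory", "qol", "demographic"),
                        several.ok = TRUE)
  scale <- match.arg(scale, c("interval", "ordinal", "binary", "nominal"),
                     several.ok = TRUE)
  improves_when <- match.arg(improves_when, c("decreases", "increases", "none"),
                             several.ok = TRUE)
  s <- data.frame(name = as.character(name), category = category, scale = scale,
                  lo = as.numeric(lo), hi = as.numeric(hi),
                  improves_when = improves_when, stringsAsFactors = FALSE)
  if (anyDuplicated(s$name)) stop("duplicated variable names in schema")
  if (any(s$lo > s$hi)) stop("schema support bounds must satisfy lo <= hi")
  class(s) <- c("crs_schema", "data.frame")
  s
}

#' @rdname crs_schema
#' @export
default_schema <- function() {
  v <- list(
    # name,                category,      scale,      lo,    hi,     improves
    c("lildholdt",         "anatomy",     "ordinal",  0,     6,      "decreases"),
    c("lund_kennedy",      "anatomy",     "ordinal",  0,     20,     "decreases"),
    c("eosinophilia",      "anatomy",     "ordinal",  0,     3,      "none"),
    c("tdi",               "olfactory",   "interval", 0,     48,     "increases"),
    c("olf_threshold",     "olfactory",   "interval", 0,     16,     "increases"),
    c("olf_discrimination","olfactory",   "interval", 0,     16,     "increases"),
    c("olf_identification","olfactory",   "interval", 0,     16,     "increases"),
    c("olf_rating_1",      "olfactory",   "ordinal",  0,     7,      "increases"),
    c("olf_rating_2",      "olfactory",   "ordinal",  1,     10,     "increases"),
    c("parosmia",          "olfactory",   "binary",   0,     1,      "decreases"),
    c("phantosmia",        "olfactory",   "binary",   0,     1,      "decreases"),
    c("snot_primary",      "qol",         "interval", 0,     100,    "decreases"),
    c("snot_secondary",    "qol",         "interval", 0,     100,    "decreases"),
    c("snot_general",      "qol",         "interval", 0,     100,    "decreases"),
    c("snot_total",        "qol",         "interval", 0,     100,    "decreases"),
    c("sf36_pf",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_rp",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_bp",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_gh",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_vt",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_sf",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_re",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_mh",           "qol",         "interval", 0,     100,    "increases"),
    c("sf36_pcs",          "qol",         "interval", -20,   120,    "increases"),
    c("sf36_mcs",          "qol",         "interval", -20,   120,    "increases"),
    c("age",               "demographic", "interval", 0,     110,    "none"),
    c("bmi",               "demographic", "interval", 10,    70,     "none"),
    c("sex",               "demographic", "binary",   0,     1,      "none"),
    c("steroid_use",       "demographic", "binary",   0,     1,      "none"),
    c("allergy_house_dust","demographic", "binary",   0,     1,      "none"),
    c("allergy_early_bloomers","demographic","binary",0,     1,      "none"),
    c("allergy_hay_fever", "demographic", "binary",   0,     1,      "none"),
    c("allergy_grasses",   "demographic", "binary",   0,     1,      "none"),
    c("allergy_cat",       "demographic", "binary",   0,     1,      "none"),
    c("asa_triad",         "demographic", "binary",   0,     1,      "none"),
    c("asa_pseudoallergy", "demographic", "binary",   0,     1,      "none"),
    c("asthma",            "demographic", "binary",   0,     1,      "none")
  )
  m <- do.call(rbind, v)
  crs_schema(m[, 1], m[, 2], m[, 3], as.numeric(m[, 4]), as.numeric(m[, 5]), m[, 6])
}

#' Read or write a variable schema
#'
#' Schemas are serialized as YAML or JSON (by file extension), one record per
#' variable.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param schema a `crs_schema`.
#' @return `read_schema` returns a `crs_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path)
  rows <- lapply(x, function(r) data.frame(name = r$name, category = r$category,
    scale = r$scale, lo = r$lo, hi = r$hi, improves_when = r$improves_when,
    stringsAsFactors = FALSE))
  s <- do.call(rbind, rows)
  crs_schema(s$name, s$category, s$scale, s$lo, s$hi, s$improves_when)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "crs_schema"))
  recs <- lapply(seq_len(nrow(schema)), function(i) as.list(schema[i, , drop = FALSE]))
  recs <- lapply(recs, function(r) lapply(r, function(z) if (is.factor(z)) as.character(z) else z))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(recs, path)
  else jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
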