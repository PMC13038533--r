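# Ingestion of FAERS-dialect quarterly ASCII tables (DEMO/DRUG/REAC/OUTC/INDI)
# and round-trip storage of the cleaned analysis dataset.

# Mandatory columns per table; extra columns are ignored with a warning
# because the public quarterly schema drifts across years.
.faers_required <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

.outcome_codes <- c(DE = "death", LT = "life_threatening", HO = "hospitalization",
                    DS = "disability", OT = "other_serious")

.age_units <- c(YR = "years", YEAR = "years", MON = "months", MONTH = "months",
                DY = "days", DAY = "days")

#' Container for one quarter's report tables
#'
#' Bundles the five parsed report tables into a single object. Normally
#' produced by [read_quarterly_tables()] or [generate_reports()], but can be
#' assembled directly from data frames (useful in tests).
#'
#' @param demo,drug,reac,outc,indi Data frames with the parsed columns
#'   documented in [read_quarterly_tables()].
#' @param quarter_label Free-text label for the quarter(s) covered.
#' @param provenance Named numeric vector of per-step record counts,
#'   accumulated by the cleaning steps.
#' @return An object of class `quarterly_tables`.
#' @export
quarterly_tables <- function(demo, drug, reac, outc, indi, quarter_label = "",
                             provenance = c(raw_reports = nrow(demo))) {
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi)
  for (nm in names(tabs)) {
    stopifnot(is.data.frame(tabs[[nm]]))
    miss <- setdiff(.parsed_cols(nm), names(tabs[[nm]]))
    if (length(miss))
      stop(sprintf("table '%s' lacks column(s): %s", nm, paste(miss, collapse = ", ")))
  }
  # referential check: child rows should point at a demo report
  known <- unique(demo$primaryid)
  for (nm in c("drug", "reac", "outc", "indi")) {
    orphan <- sum(!(tabs[[nm]]$primaryid %in% known))
    if (orphan > 0)
      warning(sprintf("%d %s row(s) reference a primaryid absent from demo", orphan, nm))
  }
  structure(c(tabs, list(quarter_label = quarter_label, provenance = provenance)),
            class = "quarterly_tables")
}

.parsed_cols <- function(table) {
  switch(table,
    demo = c("primaryid", "caseid", "caseversion", "fda_dt", "sex",
             "age_value", "age_unit", "country", "event_dt"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai", "route"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outcome"),
    indi = c("primaryid", "drug_seq", "indi_pt"))
}

#' @export
print.quarterly_tables <- function(x, ...) {
  cat("FAERS-style quarterly tables", if (nzchar(x$quarter_label))
    sprintf("[%s]", x$quarter_label) else "", "\n")
  for (nm in c("demo", "drug", "reac", "outc", "indi"))
    cat(sprintf("  %-4s %7d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Read FAERS-dialect quarterly tables
#'
#' Parses the five `$`-delimited quarterly ASCII tables into typed data
#' frames. Column names are matched case-insensitively after trimming;
#' columns beyond the expected schema are dropped with a warning. Values
#' that fail to parse (malformed dates, non-numeric ages) become missing
#' rather than aborting the run.
#'
#' @param paths Named character vector or list with elements `demo`, `drug`,
#'   `reac`, `outc`, `indi` giving one file path per table.
#' @param delim Field delimiter; `"$"` as in the public FAERS extracts, or
#'   `","`/`"\t"` for human-readable fixtures.
#' @param quarter_label Label stored on the returned object.
#' @return A [quarterly_tables] object. Demographic dates (`fda_dt`,
#'   `event_dt`) are YYYYMMDD integers; `sex` is `"male"`/`"female"`/`NA`;
#'   `age_unit` is `"years"`/`"months"`/`"days"`/`NA`; outcome codes are
#'   mapped to `death`, `life_threatening`, `hospitalization`, `disability`,
#'   `other_serious` (anything else is missing).
#' @export
read_quarterly_tables <- function(paths, delim = "$", quarter_label = "") {
  need <- c("demo", "drug", "reac", "outc", "indi")
  if (!all(need %in% names(paths)))
    stop("'paths' must name all of: ", paste(need, collapse = ", "))
  raw <- lapply(need, function(nm)
    .read_faers_file(paths[[nm]], table = nm, delim = delim))
  names(raw) <- need

  demo <- raw$demo
  demo$caseversion <- suppressWarnings(as.integer(demo$caseversion))
  fda <- parse_yyyymmdd(demo$fda_dt)
  bad <- sum(!is.na(demo$fda_dt) & demo$fda_dt != "" & is.na(fda))
  if (bad > 0) warning(sprintf("%d demo fda_dt value(s) unparseable, set to missing", bad))
  demo$fda_dt <- fda
  demo$event_dt <- parse_yyyymmdd(demo$event_dt)
  sex <- toupper(squish(demo$sex))
  demo$sex <- unname(c(M = "male", F = "female")[sex])
  demo$age_value <- suppressWarnings(as.numeric(demo$age_value))
  demo$age_value[!is.na(demo$age_value) & demo$age_value < 0] <- NA_real_
  demo$age_unit <- unname(.age_units[toupper(squish(demo$age_unit))])
  demo$country <- .blank_na(squish(demo$country))
  demo <- demo[, .parsed_cols("demo")]

  drug <- raw$drug
  drug$drug_seq <- suppressWarnings(as.integer(drug$drug_seq))
  drug$role_cod <- toupper(squish(drug$role_cod))
  drug$role_cod[drug$role_cod == ""] <- NA_character_
  drug$drugname <- .blank_na(squish(drug$drugname))
  drug$prod_ai <- .blank_na(squish(drug$prod_ai))
  drug$route <- .blank_na(squish(drug$route))
  drug <- drug[, .parsed_cols("drug")]

  reac <- raw$reac
  reac$pt <- norm_pt(reac$pt)
  reac <- reac[!is.na(reac$pt), c("primaryid", "pt")]

  outc <- raw$outc
  outc$outcome <- unname(.outcome_codes[toupper(squish(outc$outc_cod))])
  outc <- unique(outc[, c("primaryid", "outcome")])

  indi <- raw$indi
  indi$drug_seq <- suppressWarnings(as.integer(indi$indi_drug_seq))
  indi$indi_pt <- norm_pt(indi$indi_pt)
  indi <- indi[, .parsed_cols("indi")]

  for (nm in need) message(sprintf("read %d %s row(s) from %s",
                                   nrow(raw[[nm]]), nm, paths[[nm]]))
  quarterly_tables(demo, drug, reac, outc, indi, quarter_label = quarter_label)
}

.blank_na <- function(x) {
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

.read_faers_file <- function(path, table, delim) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- .faers_required[[table]]
  if (file.size(path) == 0L) {
    warning(sprintf("empty %s file: %s", table, path))
    out <- as.data.frame(setNames(rep(list(character()), length(required)), required))
    return(.pad_optional(out, table))
  }
  quote <- if (identical(delim, "$")) "" else "\""
  dat <- utils::read.table(path, sep = delim, quote = quote, header = TRUE,
                           colClasses = "character", comment.char = "",
                           fill = TRUE, check.names = FALSE,
                           fileEncoding = "UTF-8", na.strings = NULL)
  names(dat) <- tolower(squish(names(dat)))
  miss <- setdiff(required, names(dat))
  if (length(miss))
    stop(sprintf("%s file %s lacks mandatory column(s): %s",
                 table, path, paste(miss, collapse = ", ")))
  known <- unique(c(required, .raw_optional(table)))
  extra <- setdiff(names(dat), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s) in %s: %s",
                    table, paste(extra, collapse = ", ")))
    dat <- dat[, setdiff(names(dat), extra), drop = FALSE]
  }
  .pad_optional(dat, table)
}

.raw_optional <- function(table) {
  switch(table,
    demo = c("sex", "age", "age_cod", "reporter_country", "event_dt"),
    drug = c("prod_ai", "route"),
    character())
}

.pad_optional <- function(dat, table) {
  for (col in .raw_optional(table))
    if (!col %in% names(dat)) dat[[col]] <- NA_character_
  # align raw FAERS names with parsed names
  if (table == "demo") {
    names(dat)[names(dat) == "age"] <- "age_value"
    names(dat)[names(dat) == "age_cod"] <- "age_unit"
    names(dat)[names(dat) == "reporter_country"] <- "country"
  }
  dat
}

#' Write quarterly tables in the FAERS dialect
#'
#' Serializes a [quarterly_tables] object back to the five delimited files,
#' using the raw coding conventions ([read_quarterly_tables()] reverses the
#' mapping). Mainly used to exercise the reader against generated data.
#'
#' @param tables A [quarterly_tables] object.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_quarterly_tables <- function(tables, dir, delim = "$") {
  stopifnot(inherits(tables, "quarterly_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sex_code <- c(male = "M", female = "F")
  unit_code <- c(years = "YR", months = "MON", days = "DY")
  out_code <- setNames(names(.outcome_codes), .outcome_codes)
  raw <- list(
    demo = data.frame(primaryid = tables$demo$primaryid,
                      caseid = tables$demo$caseid,
                      caseversion = tables$demo$caseversion,
                      fda_dt = tables$demo$fda_dt,
                      sex = sex_code[tables$demo$sex],
                      age = tables$demo$age_value,
                      age_cod = unit_code[tables$demo$age_unit],
                      reporter_country = tables$demo$country,
                      event_dt = tables$demo$event_dt,
                      check.names = FALSE),
    drug = tables$drug,
    reac = tables$reac,
    outc = data.frame(primaryid = tables$outc$primaryid,
                      outc_cod = out_code[tables$outc$outcome]),
    indi = data.frame(primaryid = tables$indi$primaryid,
                      indi_drug_seq = tables$indi$drug_seq,
                      indi_pt = tables$indi$indi_pt))
  paths <- character()
  for (nm in names(raw)) {
    p <- file.path(dir, paste0(nm, ".txt"))
    df <- raw[[nm]]
    df[] <- lapply(df, function(col) ifelse(is.na(col), "", as.character(col)))
    utils::write.table(df, p, sep = delim, quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths[nm] <- p
  }
  invisible(paths)
}

# ---- cleaned dataset round trip ------------------------------------------

# Within-field separator for set-valued columns of the cleaned CSV. MedDRA
# preferred terms never contain "|".
.set_sep <- "|"

#' Write the cleaned analysis dataset
#'
#' Serializes a [clean_case_set] to a single CSV (one row per case,
#' set-valued fields joined with `"|"`) plus a sidecar JSON schema carrying
#' the missing-value convention (`""` means missing) and the provenance
#' counters. `read_clean_dataset()` restores the object field-for-field.
#'
#' @param cases A [clean_case_set].
#' @param path Output CSV path; the schema is written to `<path>.schema.json`.
#' @return Invisibly, `path`.
#' @export
write_clean_dataset <- function(cases, path) {
  stopifnot(inherits(cases, "clean_case_set"))
  flat <- .flatten_cases(cases)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  utils::write.csv(flat, con, row.names = FALSE, na = "")
  schema <- list(
    format = "faersignal-clean-case-set",
    version = 1L,
    missing_token = "",
    set_separator = .set_sep,
    columns = names(flat),
    provenance = as.list(cases$provenance))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cleaned analysis dataset written by [write_clean_dataset()]
#'
#' @param path CSV path written by [write_clean_dataset()].
#' @return A [clean_case_set].
#' @export
read_clean_dataset <- function(path) {
  flat <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  schema_path <- paste0(path, ".schema.json")
  prov <- numeric()
  if (file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    prov <- unlist(schema$provenance) %||% numeric()
  }
  split_set <- function(x) lapply(strsplit(x, .set_sep, fixed = TRUE),
                                  function(v) sort(v[v != ""]))
  long <- function(col, name) {
    sets <- split_set(flat[[col]])
    n <- lengths(sets)
    vals <- unlist(sets, use.names = FALSE) %||% character()
    setNames(data.frame(caseid = rep(flat$caseid, n), val = vals,
                        stringsAsFactors = FALSE), c("caseid", name))
  }
  cases <- data.frame(caseid = flat$caseid,
                      sex = .blank_na(flat$sex),
                      age_group = .blank_na(flat$age_group),
                      country = .blank_na(flat$country),
                      target_drug = flat$target_drug == "TRUE",
                      stringsAsFactors = FALSE)
  clean_case_set(cases, pts = long("pts", "pt"),
                 indications = long("indications", "indi_pt"),
                 outcomes = long("outcomes", "outcome"),
                 provenance = prov)
}

.flatten_cases <- function(x) {
  paste_set <- function(df) {
    sets <- split(df[[2L]], factor(df$caseid, levels = x$cases$caseid))
    vapply(sets, function(v) paste(sort(unique(v)), collapse = .set_sep), "")
  }
  data.frame(caseid = x$cases$caseid,
             sex = x$cases$sex,
             age_group = x$cases$age_group,
             country = x$cases$country,
             target_drug = x$cases$target_drug,
             pts = paste_set(x$pts),
             indications = paste_set(x$indications),
             outcomes = paste_set(x$outcomes),
             stringsAsFactors = FALSE)
}
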