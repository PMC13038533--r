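# MedDRA-style terminology support: preferred-term to System Organ Class
# lookup and annotation against the EMA Important/Designated Medical Event
# lists. The full MedDRA dictionary is licensed, so mappings are runtime CSV
# inputs; a small mapping covering the packaged signal fixture ships with
# the package for tests and examples.

#' Preferred-term to System Organ Class map
#'
#' @param pt Character vector of preferred terms.
#' @param soc Character vector of the corresponding (primary) SOC names.
#' @return An object of class `term_map`. Lookups are case-insensitive and
#'   whitespace-insensitive; unmapped terms resolve to the sentinel
#'   `"Missing or unknown"`.
#' @export
term_map <- function(pt, soc) {
  stopifnot(length(pt) == length(soc))
  key <- norm_key(pt)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    first <- !duplicated(key)
    warning(sprintf("%d preferred term(s) mapped more than once; keeping first mapping", length(dup)))
    key <- key[first]; soc <- soc[first]
  }
  structure(list(map = setNames(as.character(soc), key)), class = "term_map")
}

#' Load a PT to SOC map from CSV
#'
#' Expects columns `pt` and `soc` (case-insensitive header).
#'
#' @param path CSV file path.
#' @return A [term_map].
#' @export
load_term_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(df) <- tolower(squish(names(df)))
  if (!all(c("pt", "soc") %in% names(df)))
    stop("term map CSV must have columns 'pt' and 'soc'")
  term_map(df$pt, df$soc)
}

#' System Organ Class of a preferred term
#'
#' @param pt Character vector of preferred terms.
#' @param map A [term_map].
#' @return Character vector of SOC names; `"Missing or unknown"` for
#'   unmapped terms.
#' @export
soc_of <- function(pt, map) {
  stopifnot(inherits(map, "term_map"))
  out <- unname(map$map[norm_key(pt)])
  out[is.na(out)] <- "Missing or unknown"
  out
}

#' Important / Designated Medical Event lists
#'
#' @param ime_pts,dme_pts Character vectors of preferred terms on the EMA
#'   IME and DME lists. A term on both lists is classified as DME (the more
#'   severe designation takes precedence for scoring).
#' @return An object of class `medical_event_list`.
#' @export
medical_event_list <- function(ime_pts, dme_pts) {
  structure(list(ime = unique(norm_key(ime_pts)), dme = unique(norm_key(dme_pts))),
            class = "medical_event_list")
}

#' Load IME/DME lists from CSV
#'
#' Each file needs a `pt` column.
#'
#' @param ime_path,dme_path CSV file paths.
#' @return A [medical_event_list].
#' @export
load_medical_event_list <- function(ime_path, dme_path) {
  read_pts <- function(p) {
    df <- utils::read.csv(p, colClasses = "character", check.names = FALSE)
    names(df) <- tolower(squish(names(df)))
    if (!"pt" %in% names(df)) stop("event list CSV must have a 'pt' column: ", p)
    df$pt
  }
  medical_event_list(read_pts(ime_path), read_pts(dme_path))
}

#' IME/DME designation of a preferred term
#'
#' @param pt Character vector of preferred terms.
#' @param lists A [medical_event_list].
#' @return Character vector with values `"DME"`, `"IME"` or `"none"`; DME
#'   takes precedence when a term appears on both lists.
#' @export
ime_dme_status <- function(pt, lists) {
  stopifnot(inherits(lists, "medical_event_list"))
  key <- norm_key(pt)
  ifelse(key %in% lists$dme, "DME", ifelse(key %in% lists$ime, "IME", "none"))
}

#' Packaged signal-table fixture
#'
#' Loads the packaged table of 83 published ophthalmic-atropine signals:
#' preferred term, SOC, case count, classical ROR with 95% CI, death count,
#' IME/DME designation, evidence grade, and the published priority score and
#' tier. Used as the reference surface for the terminology and priority
#' modules.
#'
#' @return A data frame with 83 rows.
#' @export
load_table4_fixture <- function() {
  path <- system.file("extdata", "table4_signals.csv", package = "faersignal",
                      mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(soc = "character", pt = "character",
                                       cases = "integer", ror = "numeric",
                                       ror_l95 = "numeric", ror_u95 = "numeric",
                                       deaths = "integer", event_status = "character",
                                       evidence = "character",
                                       printed_score = "integer",
                                       printed_tier = "character"))
  df
}

#' Term map covering the packaged signal fixture
#'
#' @return A [term_map] built from the packaged fixture's PT/SOC columns.
#' @export
fixture_term_map <- function() {
  t4 <- load_table4_fixture()
  keep <- t4$soc != "Missing or unknown"
  term_map(t4$pt[keep], t4$soc[keep])
}

#' IME/DME lists covering the packaged signal fixture
#'
#' @return A [medical_event_list] built from the packaged fixture's
#'   designation column.
#' @export
fixture_event_list <- function() {
  t4 <- load_table4_fixture()
  medical_event_list(ime_pts = t4$pt[t4$event_status == "IME"],
                     dme_pts = t4$pt[t4$event_status == "DME"])
}
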