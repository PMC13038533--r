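# Report cleaning: duplicate removal by the regulatory variable-matching
# rule, suspect-role restriction, target-drug identification with route
# restriction, and extraction of an analysis-ready case set.

#' Remove duplicate reports
#'
#' Applies the exact variable-matching rule used by regulatory agencies on
#' the keys PRIMARYID / CASEID / CASEVERSION / FDA_DT: among records sharing
#' a PRIMARYID the latest FDA_DT wins (ties broken by the largest CASEID and
#' CASEVERSION); among records sharing a CASEID only the most recent version
#' (largest CASEVERSION, then latest FDA_DT) is retained. Remaining full-key
#' ties keep the last record in file order so output is deterministic.
#' Records with missing keys are kept and counted. Child-table rows of
#' dropped reports are removed as well.
#'
#' The operation is idempotent and never increases any table's row count.
#'
#' @param tables A [quarterly_tables] object.
#' @return The deduplicated [quarterly_tables]; the `provenance` element
#'   gains a `dropped_duplicates` count.
#' @export
deduplicate <- function(tables) {
  stopifnot(inherits(tables, "quarterly_tables"))
  demo <- tables$demo
  n0 <- nrow(demo)
  demo <- .keep_last(demo, key = demo$primaryid,
                     ord = list(na_low(demo$fda_dt),
                                na_low(suppressWarnings(as.numeric(demo$caseid))),
                                na_low(demo$caseversion)))
  demo <- .keep_last(demo, key = demo$caseid,
                     ord = list(na_low(demo$caseversion), na_low(demo$fda_dt)))
  dropped <- n0 - nrow(demo)
  if (dropped > 0) message(sprintf("deduplicate: removed %d duplicate report(s)", dropped))
  keep_ids <- demo$primaryid
  out <- tables
  out$demo <- demo
  for (nm in c("drug", "reac", "outc", "indi"))
    out[[nm]] <- out[[nm]][out[[nm]]$primaryid %in% keep_ids, , drop = FALSE]
  prov <- out$provenance
  prov["dropped_duplicates"] <- unname(prov["dropped_duplicates"] %|na|% 0) + dropped
  out$provenance <- prov
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# Keep, per key group, the record ranking last under the ordering columns
# (ties: last in file order). Rows with a missing key are kept untouched.
.keep_last <- function(df, key, ord) {
  miss <- is.na(key) | key == ""
  if (all(miss)) return(df)
  sub <- df[!miss, , drop = FALSE]
  k <- key[!miss]
  o <- do.call(order, c(list(k), lapply(ord, function(v) v[!miss]),
                        list(seq_len(nrow(sub)))))
  sub <- sub[o, , drop = FALSE]
  sub <- sub[!duplicated(k[o], fromLast = TRUE), , drop = FALSE]
  out <- rbind(df[miss, , drop = FALSE], sub)
  out[order(match(out$primaryid, df$primaryid)), , drop = FALSE]
}

#' Restrict drug records to suspect roles
#'
#' Drops drug rows whose role code is Concomitant (`C`), Interacting (`I`)
#' or unrecognised, so that target-drug identification sees only Primary and
#' Secondary Suspect rows. Reports whose only link to the target drug was a
#' concomitant/interacting row therefore never become target cases.
#'
#' @param tables A [quarterly_tables] object (normally deduplicated first).
#' @return The filtered [quarterly_tables]; `provenance` gains
#'   `dropped_nonsuspect_drug_rows`.
#' @export
filter_suspect_roles <- function(tables) {
  stopifnot(inherits(tables, "quarterly_tables"))
  role <- tables$drug$role_cod
  keep <- !is.na(role) & role %in% c("PS", "SS")
  unknown <- sum(!is.na(role) & !(role %in% c("PS", "SS", "C", "I")))
  if (unknown > 0)
    message(sprintf("filter_suspect_roles: %d row(s) with unknown role code treated as non-suspect", unknown))
  out <- tables
  out$drug <- tables$drug[keep, , drop = FALSE]
  prov <- out$provenance
  prov["dropped_nonsuspect_drug_rows"] <-
    unname(prov["dropped_nonsuspect_drug_rows"] %|na|% 0) + sum(!keep)
  out$provenance <- prov
  out
}

#' Target-drug dictionary
#'
#' Defines the target medication by its generic and brand names and the
#' administration routes accepted as ocular use. Matching is performed on
#' normalized names (uppercase, punctuation stripped, whitespace collapsed),
#' by substring containment by default, since FAERS free-text drug names
#' carry salts and strengths ("ATROPINE SULFATE 1%").
#'
#' @param generic_names,brand_names Character vectors of names; together
#'   they must be non-empty.
#' @param accepted_routes Character vector of route strings counted as
#'   ocular administration.
#' @param match `"substring"` (default) or `"token"` for exact-token
#'   matching of the dictionary term within the name.
#' @return An object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(generic_names, brand_names = character(),
                            accepted_routes = c("OPHTHALMIC", "OCULAR",
                                                "INTRAOCULAR", "TOPICAL OCULAR"),
                            match = c("substring", "token")) {
  match <- match.arg(match)
  names <- unique(norm_drug(c(generic_names, brand_names)))
  names <- names[!is.na(names) & names != ""]
  routes <- unique(norm_key(accepted_routes))
  routes <- routes[!is.na(routes) & routes != ""]
  if (length(names) == 0) stop("drug dictionary has no usable names")
  if (length(routes) == 0) stop("drug dictionary has no accepted routes")
  structure(list(names = names, accepted_routes = routes, match = match),
            class = "drug_dictionary")
}

#' Load a drug dictionary from JSON
#'
#' Expects keys `generic_names`, `brand_names`, `accepted_routes` and
#' optionally `match`.
#'
#' @param path JSON file path.
#' @return A [drug_dictionary].
#' @export
load_drug_dictionary <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  drug_dictionary(cfg$generic_names %||% character(),
                  cfg$brand_names %||% character(),
                  cfg$accepted_routes %||% c("OPHTHALMIC", "OCULAR",
                                             "INTRAOCULAR", "TOPICAL OCULAR"),
                  match = cfg$match %||% "substring")
}

#' Flag reports exposed to the target drug
#'
#' A report is a target case iff at least one of its (suspect-role) drug
#' rows matches a dictionary name in DRUGNAME or PROD_AI *and* carries an
#' accepted route. Rows that match on name but have a missing or
#' unaccepted route never flag the report: only confirmed ocular
#' administrations count.
#'
#' @param tables A [quarterly_tables] object, deduplicated and
#'   suspect-filtered.
#' @param dict A [drug_dictionary].
#' @return Named logical vector over all demo `primaryid`s.
#' @export
match_target_drug <- function(tables, dict) {
  stopifnot(inherits(tables, "quarterly_tables"), inherits(dict, "drug_dictionary"))
  drug <- tables$drug
  name_hit <- .match_name(drug$drugname, dict) | .match_name(drug$prod_ai, dict)
  route_ok <- !is.na(drug$route) & norm_key(drug$route) %in% dict$accepted_routes
  hit_ids <- unique(drug$primaryid[name_hit & route_ok])
  flags <- tables$demo$primaryid %in% hit_ids
  names(flags) <- tables$demo$primaryid
  flags
}

.match_name <- function(x, dict) {
  xn <- norm_drug(x)
  hit <- rep(FALSE, length(xn))
  ok <- !is.na(xn) & xn != ""
  for (term in dict$names) {
    if (dict$match == "substring") {
      hit[ok] <- hit[ok] | grepl(term, xn[ok], fixed = TRUE)
    } else {
      hit[ok] <- hit[ok] | grepl(paste0("(^| )", term, "( |$)"), xn[ok])
    }
  }
  hit
}

#' Cleaned case set
#'
#' One row per retained case plus long tables of its reaction preferred
#' terms, indications and outcomes, and the per-step provenance counters.
#' Usually produced by [extract_events()].
#'
#' @param cases Data frame with columns `caseid`, `sex`, `age_group`,
#'   `country`, `target_drug`.
#' @param pts Data frame `(caseid, pt)`; every case must have at least one.
#' @param indications Data frame `(caseid, indi_pt)`.
#' @param outcomes Data frame `(caseid, outcome)`.
#' @param provenance Named numeric vector of per-step drop counts.
#' @return An object of class `clean_case_set`.
#' @export
clean_case_set <- function(cases, pts, indications, outcomes,
                           provenance = numeric()) {
  stopifnot(!anyDuplicated(cases$caseid))
  stopifnot(all(pts$caseid %in% cases$caseid))
  structure(list(cases = cases, pts = unique(pts),
                 indications = unique(indications), outcomes = unique(outcomes),
                 provenance = provenance),
            class = "clean_case_set")
}

#' @export
print.clean_case_set <- function(x, ...) {
  cat(sprintf("Clean case set: %d case(s), %d target case(s), %d case-PT pair(s)\n",
              nrow(x$cases), sum(x$cases$target_drug), nrow(x$pts)))
  if (length(x$provenance))
    cat("provenance:", paste(sprintf("%s=%d", names(x$provenance),
                                     round(x$provenance)), collapse = ", "), "\n")
  invisible(x)
}

#' Convert an age to the analysis age group
#'
#' Ages in months or days are converted to years (months/12, days/365.25)
#' before binning into the strata `<=3`, `4-18`, `19-64`, `>=65`; the bins
#' are `[0,3]`, `(3,18]`, `(18,64]`, `(64,Inf)` in years. Missing values or
#' unknown units yield `NA`.
#'
#' @param age_value Numeric vector of ages.
#' @param age_unit Character vector: `"years"`, `"months"`, `"days"` or `NA`.
#' @return Character vector of group labels.
#' @export
age_group <- function(age_value, age_unit) {
  factor_per_unit <- c(years = 1, months = 1 / 12, days = 1 / 365.25)
  yrs <- age_value * unname(factor_per_unit[age_unit])
  out <- rep(NA_character_, length(yrs))
  ok <- !is.na(yrs)
  out[ok & yrs <= 3] <- "<=3"
  out[ok & yrs > 3 & yrs <= 18] <- "4-18"
  out[ok & yrs > 18 & yrs <= 64] <- "19-64"
  out[ok & yrs > 64] <- ">=65"
  out
}

#' Extract the analysis-ready case set
#'
#' Collapses the deduplicated tables to one record per case: demographics
#' with explicit missing categories, the set of reaction preferred terms
#' (whitespace/case-normalized), indication and outcome sets, and the
#' target-drug flag. Cases with no reaction rows are dropped and counted in
#' provenance. Where CASEID is missing the PRIMARYID stands in as the case
#' identifier.
#'
#' @param tables A deduplicated [quarterly_tables] object.
#' @param flags Named logical vector from [match_target_drug()].
#' @return A [clean_case_set].
#' @export
extract_events <- function(tables, flags) {
  stopifnot(inherits(tables, "quarterly_tables"))
  # normalization is idempotent, so pre-normalized input is unaffected
  tables$reac$pt <- norm_pt(tables$reac$pt)
  tables$indi$indi_pt <- norm_pt(tables$indi$indi_pt)
  demo <- tables$demo
  caseid <- ifelse(is.na(demo$caseid) | demo$caseid == "",
                   demo$primaryid, demo$caseid)
  has_reac <- demo$primaryid %in% tables$reac$primaryid
  dropped_noreac <- sum(!has_reac)
  cases <- data.frame(caseid = caseid[has_reac],
                      sex = demo$sex[has_reac],
                      age_group = age_group(demo$age_value, demo$age_unit)[has_reac],
                      country = demo$country[has_reac],
                      target_drug = unname(flags[demo$primaryid[has_reac]]),
                      stringsAsFactors = FALSE)
  id2case <- setNames(caseid, demo$primaryid)
  long <- function(df, col) {
    out <- data.frame(caseid = unname(id2case[df$primaryid]),
                      val = df[[col]], stringsAsFactors = FALSE)
    out <- out[!is.na(out$caseid) & out$caseid %in% cases$caseid & !is.na(out$val), ]
    names(out) <- c("caseid", col)
    unique(out)
  }
  prov <- tables$provenance
  prov["dropped_no_reactions"] <- unname(prov["dropped_no_reactions"] %|na|% 0) +
    dropped_noreac
  prov["retained_cases"] <- nrow(cases)
  clean_case_set(cases,
                 pts = long(tables$reac, "pt"),
                 indications = long(tables$indi, "indi_pt"),
                 outcomes = long(tables$outc, "outcome"),
                 provenance = prov)
}

#' Clean raw tables end to end
#'
#' Convenience wrapper chaining [deduplicate()], [filter_suspect_roles()],
#' [match_target_drug()] and [extract_events()].
#'
#' @param tables A [quarterly_tables] object.
#' @param dict A [drug_dictionary].
#' @return A [clean_case_set].
#' @export
clean_reports <- function(tables, dict) {
  tables <- deduplicate(tables)
  tables <- filter_suspect_roles(tables)
  flags <- match_target_drug(tables, dict)
  extract_events(tables, flags)
}

#' Descriptive frequency tables for target cases
#'
#' Counts and percentages (denominator: all target-drug cases) for sex, age
#' group, reporting country, indications and clinical outcomes, each with an
#' explicit "Missing or unknown" row. Percentages are rounded to two
#' decimals. Both counting conventions are reported: the number of target
#' cases and the number of target case-PT pairs.
#'
#' @param cases A [clean_case_set].
#' @return An object of class `descriptive_summary`: a list of data frames
#'   (`sex`, `age`, `country`, `indications`, `outcome`) plus `n_cases` and
#'   `n_case_pt_pairs`.
#' @export
descriptive_summary <- function(cases) {
  stopifnot(inherits(cases, "clean_case_set"))
  tgt <- cases$cases[cases$cases$target_drug, , drop = FALSE]
  n <- nrow(tgt)
  if (n == 0) stop("no target cases to summarise")
  freq_frame <- function(tab) {
    out <- data.frame(level = as.character(names(tab) %||% character()),
                      n = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(-out$n, out$level), , drop = FALSE]
    out$pct <- round(100 * out$n / n, 2)
    rownames(out) <- NULL
    out
  }
  freq <- function(x) {
    x[is.na(x)] <- "Missing or unknown"
    freq_frame(table(x))
  }
  freq_set <- function(df, col) {
    df <- df[df$caseid %in% tgt$caseid, , drop = FALSE]
    out <- freq_frame(table(df[[col]]))
    miss <- n - length(unique(df$caseid))
    rbind(out, data.frame(level = "Missing or unknown", n = miss,
                          pct = round(100 * miss / n, 2)))
  }
  structure(list(sex = freq(tgt$sex),
                 age = freq(tgt$age_group),
                 country = freq(tgt$country),
                 indications = freq_set(cases$indications, "indi_pt"),
                 outcome = freq_set(cases$outcomes, "outcome"),
                 n_cases = n,
                 n_case_pt_pairs = nrow(cases$pts[cases$pts$caseid %in% tgt$caseid, ])),
            class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(sprintf("Target cases: %d (case-PT pairs: %d)\n",
              x$n_cases, x$n_case_pt_pairs))
  for (nm in c("sex", "age", "country", "indications", "outcome")) {
    cat("\n--", nm, "--\n")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}
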