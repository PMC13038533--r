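# Builders for tiny in-code report tables used across the tests.

demo_row <- function(primaryid, caseid = primaryid, caseversion = 1L,
                     fda_dt = 20240101L, sex = NA_character_,
                     age_value = NA_real_, age_unit = NA_character_,
                     country = NA_character_, event_dt = NA_integer_) {
  data.frame(primaryid = primaryid, caseid = caseid,
             caseversion = as.integer(caseversion),
             fda_dt = as.integer(fda_dt), sex = sex, age_value = age_value,
             age_unit = age_unit, country = country,
             event_dt = as.integer(event_dt), stringsAsFactors = FALSE)
}

drug_row <- function(primaryid, drug_seq = 1L, role_cod = "PS",
                     drugname = "ATROPINE", prod_ai = NA_character_,
                     route = "OPHTHALMIC") {
  data.frame(primaryid = primaryid, drug_seq = as.integer(drug_seq),
             role_cod = role_cod, drugname = drugname, prod_ai = prod_ai,
             route = route, stringsAsFactors = FALSE)
}

reac_row <- function(primaryid, pt) {
  data.frame(primaryid = primaryid, pt = pt, stringsAsFactors = FALSE)
}

empty_tab <- function(what) {
  cols <- switch(what,
    demo = c("primaryid", "caseid", "caseversion", "fda_dt", "sex",
             "age_value", "age_unit", "country", "event_dt"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai", "route"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outcome"),
    indi = c("primaryid", "drug_seq", "indi_pt"))
  as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
}

make_tables <- function(demo, drug = empty_tab("drug"), reac = empty_tab("reac"),
                        outc = empty_tab("outc"), indi = empty_tab("indi")) {
  suppressWarnings(quarterly_tables(demo, drug, reac, outc, indi))
}

# clean_case_set with one PT list per case, for contingency-table tests
make_cases <- function(caseid, target, pts) {
  stopifnot(length(caseid) == length(target), length(caseid) == length(pts))
  clean_case_set(
    cases = data.frame(caseid = caseid, sex = NA_character_,
                       age_group = NA_character_, country = NA_character_,
                       target_drug = target, stringsAsFactors = FALSE),
    pts = data.frame(caseid = rep(caseid, lengths(pts)),
                     pt = unlist(pts, use.names = FALSE),
                     stringsAsFactors = FALSE),
    indications = data.frame(caseid = character(), indi_pt = character()),
    outcomes = data.frame(caseid = character(), outcome = character()))
}

atropine_dict <- function(...) drug_dictionary("ATROPINE", c("ISOPTO ATROPINE"), ...)
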