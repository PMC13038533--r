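# Deduplication, suspect-role filtering, target matching, case extraction
# and the descriptive summary.

test_that("deduplication keeps the latest FDA_DT for a shared PRIMARYID", {
  tabs <- make_tables(rbind(demo_row("1", fda_dt = 20240101),
                            demo_row("1", fda_dt = 20240301)))
  out <- suppressMessages(deduplicate(tabs))
  expect_equal(nrow(out$demo), 1L)
  expect_equal(out$demo$fda_dt, 20240301L)
})

test_that("deduplication keeps the largest version when PRIMARYID and FDA_DT tie", {
  tabs <- make_tables(rbind(demo_row("1", caseversion = 1),
                            demo_row("1", caseversion = 2)))
  out <- suppressMessages(deduplicate(tabs))
  expect_equal(out$demo$caseversion, 2L)
})

test_that("only the most recent version of a case survives across PRIMARYIDs", {
  tabs <- make_tables(rbind(demo_row("11", caseid = "9", caseversion = 1),
                            demo_row("13", caseid = "9", caseversion = 3)),
                      reac = rbind(reac_row("11", "Eye pain"),
                                   reac_row("13", "Mydriasis")))
  out <- suppressMessages(deduplicate(tabs))
  expect_equal(out$demo$primaryid, "13")
  expect_equal(out$reac$primaryid, "13")  # child rows of dropped report removed
})

test_that("a single record passes deduplication unchanged", {
  tabs <- make_tables(demo_row("1"))
  out <- suppressMessages(deduplicate(tabs))
  expect_equal(out$demo, tabs$demo)
})

test_that("deduplication is idempotent and never grows any table", {
  sim <- generate_reports(synthetic_config(n_reports = 300, seed = 5,
                                           duplicate_rate = 0.25))
  once <- suppressMessages(deduplicate(sim$tables))
  twice <- suppressMessages(deduplicate(once))
  for (nm in c("demo", "drug", "reac", "outc", "indi")) {
    expect_lte(nrow(once[[nm]]), nrow(sim$tables[[nm]]))
    expect_equal(twice[[nm]], once[[nm]])
  }
})

test_that("suspect-role filtering keeps PS/SS rows and drops C/I per row", {
  tabs <- make_tables(rbind(demo_row("1"), demo_row("2"), demo_row("3")),
                      drug = rbind(drug_row("1", role_cod = "PS"),
                                   drug_row("2", role_cod = "C"),
                                   drug_row("3", 1, role_cod = "SS"),
                                   drug_row("3", 2, role_cod = "I")))
  out <- suppressMessages(filter_suspect_roles(tabs))
  expect_equal(out$drug$primaryid, c("1", "3"))
  expect_equal(out$drug$role_cod, c("PS", "SS"))
})

test_that("unknown role codes are treated as non-suspect", {
  tabs <- make_tables(demo_row("1"), drug = drug_row("1", role_cod = "XX"))
  out <- suppressMessages(filter_suspect_roles(tabs))
  expect_equal(nrow(out$drug), 0L)
})

test_that("target matching needs a name hit in DRUGNAME or PROD_AI plus an accepted route", {
  tabs <- make_tables(rbind(demo_row("1"), demo_row("2"), demo_row("3"), demo_row("4")),
                      drug = rbind(
                        drug_row("1", drugname = "ATROPINE SULFATE", route = "OPHTHALMIC"),
                        drug_row("2", drugname = "ATROPINE", route = NA),
                        drug_row("3", drugname = "ISOPTO", prod_ai = "atropine",
                                 route = "Ophthalmic"),
                        drug_row("4", drugname = "TIMOLOL", route = "OPHTHALMIC")))
  flags <- match_target_drug(tabs, atropine_dict())
  expect_equal(unname(flags), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("matching is monotone in the dictionary", {
  sim <- generate_reports(synthetic_config(n_reports = 200, seed = 11))
  tabs <- suppressMessages(filter_suspect_roles(deduplicate(sim$tables)))
  small <- drug_dictionary("ATROPINE", accepted_routes = "OPHTHALMIC")
  big <- drug_dictionary(c("ATROPINE", "TIMOLOL"),
                         brand_names = "ISOPTO ATROPINE",
                         accepted_routes = c("OPHTHALMIC", "OCULAR", "ORAL"))
  f1 <- match_target_drug(tabs, small)
  f2 <- match_target_drug(tabs, big)
  expect_true(all(f2[f1]))  # adding names/routes never unflags
})

test_that("exact-token matching is stricter than substring matching", {
  tabs <- make_tables(demo_row("1"),
                      drug = drug_row("1", drugname = "ATROPINESQUE", route = "OPHTHALMIC"))
  expect_true(match_target_drug(tabs, drug_dictionary("ATROPINE")) [["1"]])
  expect_false(match_target_drug(tabs, drug_dictionary("ATROPINE", match = "token"))[["1"]])
})

test_that("an empty dictionary is a hard error", {
  expect_error(drug_dictionary(character()), "names")
  expect_error(drug_dictionary("ATROPINE", accepted_routes = character()), "routes")
})

test_that("age groups convert units before binning at <=3 / 4-18 / 19-64 / >=65", {
  expect_equal(age_group(30, "months"), "<=3")   # 2.5 years
  expect_equal(age_group(c(3, 3.5, 18, 19, 64, 64.5, 90), rep("years", 7)),
               c("<=3", "4-18", "4-18", "19-64", "19-64", ">=65", ">=65"))
  expect_equal(age_group(400, "days"), "<=3")
  expect_true(is.na(age_group(40, NA_character_)))
})

test_that("extracted cases collapse reactions to PT sets and keep explicit missing", {
  tabs <- make_tables(rbind(demo_row("1", sex = NA),
                            demo_row("2", sex = "female")),
                      drug = rbind(drug_row("1"), drug_row("2", drugname = "TIMOLOL")),
                      reac = rbind(reac_row("1", "Eye pain"),
                                   reac_row("1", "eye  pain"),
                                   reac_row("1", "Mydriasis"),
                                   reac_row("2", "Headache")))
  flags <- match_target_drug(tabs, atropine_dict())
  cases <- extract_events(tabs, flags)
  expect_equal(sort(cases$pts$pt[cases$pts$caseid == "1"]),
               c("Eye pain", "Mydriasis"))  # 3 rows, 2 distinct PTs
  expect_true(is.na(cases$cases$sex[cases$cases$caseid == "1"]))
  expect_equal(cases$cases$target_drug, c(TRUE, FALSE))
})

test_that("cases without reactions are dropped and provenance counts conserve", {
  sim <- generate_reports(synthetic_config(n_reports = 400, seed = 3,
                                           duplicate_rate = 0.2))
  tabs <- suppressMessages(deduplicate(sim$tables))
  tabs <- suppressMessages(filter_suspect_roles(tabs))
  # strip the reactions of ten reports to force drops
  drop_ids <- tabs$demo$primaryid[1:10]
  tabs$reac <- tabs$reac[!(tabs$reac$primaryid %in% drop_ids), ]
  cases <- extract_events(tabs, match_target_drug(tabs, atropine_dict()))
  prov <- cases$provenance
  expect_equal(unname(prov["raw_reports"]),
               unname(prov["dropped_duplicates"] + prov["dropped_no_reactions"] +
                        prov["retained_cases"]))
  expect_equal(unname(prov["dropped_no_reactions"]), 10)
})

test_that("descriptive summary reproduces the percentage convention", {
  n <- 60
  cases <- make_cases(as.character(1:n),
                      target = rep(TRUE, n),
                      pts = as.list(rep("Eye pain", n)))
  cases$cases$sex <- c(rep("male", 30), rep("female", 20), rep(NA, 10))
  s <- descriptive_summary(cases)
  expect_equal(s$sex$pct[s$sex$level == "male"], 50.00)
  expect_equal(s$sex$pct[s$sex$level == "Missing or unknown"], 16.67)
  expect_equal(sum(s$sex$n), n)
  # all-missing column collapses to a single 100% missing row
  cases$cases$country <- NA_character_
  s2 <- descriptive_summary(cases)
  expect_equal(s2$country$level, "Missing or unknown")
  expect_equal(s2$country$pct, 100.00)
})
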