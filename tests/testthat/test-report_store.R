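# Reading the FAERS-dialect quarterly files and round-tripping the cleaned
# dataset.

write_dialect_files <- function(dir, demo_lines, drug_lines = NULL,
                                reac_lines = NULL, outc_lines = NULL,
                                indi_lines = NULL) {
  defaults <- list(
    demo = "primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$reporter_country$event_dt",
    drug = "primaryid$drug_seq$role_cod$drugname$prod_ai$route",
    reac = "primaryid$pt",
    outc = "primaryid$outc_cod",
    indi = "primaryid$indi_drug_seq$indi_pt")
  paths <- list()
  lines <- list(demo = demo_lines, drug = drug_lines, reac = reac_lines,
                outc = outc_lines, indi = indi_lines)
  for (nm in names(defaults)) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(lines[[nm]] %||% defaults[[nm]], p)
    paths[[nm]] <- p
  }
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("header row is excluded and fields are normalized while parsing", {
  dir <- withr::local_tempdir()
  paths <- write_dialect_files(dir,
    demo_lines = c("PRIMARYID$CASEID$CASEVERSION$FDA_DT$SEX$AGE$AGE_COD$REPORTER_COUNTRY$EVENT_DT",
                   "101$1$1$20240105$M$42$YR$CA$",
                   "102$2$1$20240106$$30$MON$$"),
    drug_lines = c("primaryid$drug_seq$role_cod$drugname$prod_ai$route",
                   "101$1$C $ATROPINE SULFATE$atropine$OPHTHALMIC",
                   "102$1$ps$TIMOLOL$$ORAL"),
    reac_lines = c("primaryid$pt", "101$  EYE   PAIN ", "102$Headache"))
  tabs <- suppressMessages(read_quarterly_tables(paths))
  expect_equal(nrow(tabs$demo), 2L)           # 3-line file, header excluded
  expect_equal(tabs$drug$role_cod, c("C", "PS"))  # trimmed + uppercased
  expect_equal(tabs$demo$sex, c("male", NA))
  expect_equal(tabs$demo$age_unit, c("years", "months"))
  expect_equal(tabs$reac$pt[1], "Eye pain")   # whitespace/case normalized
})

test_that("unparseable dates become missing with a warning", {
  dir <- withr::local_tempdir()
  paths <- write_dialect_files(dir,
    demo_lines = c("primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$reporter_country$event_dt",
                   "101$1$1$2024130$$$$$",       # 7 digits
                   "102$2$1$20241301$$$$$"))     # month 13
  expect_warning(tabs <- suppressMessages(read_quarterly_tables(paths)),
                 "unparseable")
  expect_true(all(is.na(tabs$demo$fda_dt)))
})

test_that("missing mandatory columns are a hard error naming the column", {
  dir <- withr::local_tempdir()
  paths <- write_dialect_files(dir,
    demo_lines = c("primaryid$caseid$caseversion$sex", "101$1$1$M"))
  expect_error(suppressMessages(read_quarterly_tables(paths)), "fda_dt")
})

test_that("empty files give empty tables with a warning; unknown columns warn", {
  dir <- withr::local_tempdir()
  paths <- write_dialect_files(dir,
    demo_lines = c("primaryid$caseid$caseversion$fda_dt$mystery_col",
                   "101$1$1$20240101$zzz"))
  file.create(file.path(dir, "reac.txt"))  # truncate to zero bytes
  warns <- capture_warnings(tabs <- suppressMessages(read_quarterly_tables(paths)))
  expect_true(any(grepl("mystery_col", warns)))
  expect_true(any(grepl("empty", warns)))
  expect_equal(nrow(tabs$reac), 0L)
  expect_false("mystery_col" %in% names(tabs$demo))
})

test_that("parsing is order-insensitive: permuted rows give the same records", {
  dir <- withr::local_tempdir()
  rows <- c("101$1$1$20240105$F$5$YR$FR$", "102$2$1$20240106$M$7$YR$CA$",
            "103$3$2$20240107$$$$$")
  hdr <- "primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$reporter_country$event_dt"
  p1 <- write_dialect_files(dir, demo_lines = c(hdr, rows))
  t1 <- suppressMessages(read_quarterly_tables(p1))
  dir2 <- withr::local_tempdir()
  p2 <- write_dialect_files(dir2, demo_lines = c(hdr, rev(rows)))
  t2 <- suppressMessages(read_quarterly_tables(p2))
  o1 <- t1$demo[order(t1$demo$primaryid), ]
  o2 <- t2$demo[order(t2$demo$primaryid), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("generated tables survive a write/read cycle in the FAERS dialect", {
  sim <- generate_reports(synthetic_config(n_reports = 40, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_quarterly_tables(sim$tables, dir)
  back <- suppressMessages(suppressWarnings(read_quarterly_tables(paths)))
  expect_equal(back$demo$primaryid, sim$tables$demo$primaryid)
  expect_equal(back$demo$fda_dt, sim$tables$demo$fda_dt)
  expect_equal(back$demo$sex, sim$tables$demo$sex)
  expect_equal(back$drug$role_cod, sim$tables$drug$role_cod)
  expect_equal(sort(back$reac$pt), sort(sim$tables$reac$pt))
})

test_that("clean dataset round-trips field-for-field, missing kept explicit", {
  cases <- clean_case_set(
    cases = data.frame(caseid = c("1", "2", "3"),
                       sex = c("male", NA, "female"),
                       age_group = c("<=3", NA, ">=65"),
                       country = c("CA", "FR", NA),
                       target_drug = c(TRUE, FALSE, TRUE),
                       stringsAsFactors = FALSE),
    pts = data.frame(caseid = c("1", "1", "2", "3"),
                     pt = c("Eye pain", "Mydriasis", "Headache", "Eye pain")),
    indications = data.frame(caseid = "1", indi_pt = "Myopia"),
    outcomes = data.frame(caseid = c("1", "3"),
                          outcome = c("death", "hospitalization")),
    provenance = c(raw_reports = 5, dropped_duplicates = 2, retained_cases = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clean_dataset(cases, path)
  back <- read_clean_dataset(path)
  expect_equal(back$cases, cases$cases)
  expect_true(is.na(back$cases$sex[2]))  # missing sex survives, not collapsed
  sort_df <- function(d) {
    d <- d[do.call(order, d), , drop = FALSE]; rownames(d) <- NULL; d
  }
  expect_equal(sort_df(back$pts), sort_df(cases$pts))
  expect_equal(sort_df(back$indications), sort_df(cases$indications))
  expect_equal(sort_df(back$outcomes), sort_df(cases$outcomes))
  expect_equal(back$provenance[sort(names(back$provenance))],
               cases$provenance[sort(names(cases$provenance))])
})

test_that("an empty clean case set writes a header-only file", {
  empty <- clean_case_set(
    cases = data.frame(caseid = character(), sex = character(),
                       age_group = character(), country = character(),
                       target_drug = logical()),
    pts = data.frame(caseid = character(), pt = character()),
    indications = data.frame(caseid = character(), indi_pt = character()),
    outcomes = data.frame(caseid = character(), outcome = character()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clean_dataset(empty, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_clean_dataset(path)$cases), 0L)
})
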