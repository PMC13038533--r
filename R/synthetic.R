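# Synthetic spontaneous-report generator with known ground truth: injected
# duplicate clusters, suspect/concomitant role codes, route missingness and
# planted drug-event reporting-rate multipliers, so that every cleaning and
# signal-detection step can be validated offline.

.default_event_vocab <- function() {
  data.frame(
    pt = c("Endophthalmitis", "Eye pain", "Mydriasis", "Vision blurred",
           "Eye irritation", "Intraocular pressure increased",
           "Visual acuity reduced", "Photophobia", "Tachycardia",
           "Bradycardia", "Nausea", "Vomiting", "Diarrhoea", "Headache",
           "Dizziness", "Somnolence", "Rash", "Pruritus",
           "Urinary retention", "Dry mouth", "Fatigue", "Pyrexia",
           "Insomnia", "Anxiety"),
    soc = c("Infections and infestations", "Eye disorders", "Eye disorders",
            "Eye disorders", "Eye disorders", "Investigations",
            "Eye disorders", "Eye disorders", "Cardiac disorders",
            "Cardiac disorders", "Gastrointestinal disorders",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "Nervous system disorders", "Nervous system disorders",
            "Nervous system disorders",
            "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Renal and urinary disorders", "Gastrointestinal disorders",
            "General disorders and administration site conditions",
            "General disorders and administration site conditions",
            "Psychiatric disorders", "Psychiatric disorders"),
    weight = c(0.05, 0.06, 0.04, 0.05, 0.03, 0.04, 0.03, 0.03, 0.05, 0.03,
               0.08, 0.06, 0.05, 0.09, 0.06, 0.04, 0.05, 0.04, 0.02, 0.03,
               0.05, 0.04, 0.04, 0.04),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic report generator
#'
#' Defaults emulate a mid-sized spontaneous-report corpus: 5000 reports, 15%
#' carrying the target ophthalmic drug, a PS/SS/C/I role mix of
#' 0.5/0.2/0.2/0.1, an accepted (ocular) route on 80% of target rows with
#' 10% missing routes, a 10% near-duplicate rate, and independent
#' demographic missingness. Planted effects multiply the event-selection
#' probability of chosen preferred terms for exposed reports and renormalize,
#' making the planted log-ratio the recoverable estimand.
#'
#' @param n_reports Number of base reports (duplicates come on top).
#' @param seed Integer seed; identical seeds give byte-identical tables.
#' @param target_generic Generic name of the target drug.
#' @param target_brands Brand-name synonyms of the target drug.
#' @param background_drugs Names of non-target drugs (>= 2).
#' @param event_vocab Data frame `pt`/`soc`/`weight` (>= 2 rows); weights
#'   are normalized internally.
#' @param target_report_frac Fraction of reports carrying the target drug.
#' @param role_mix Named probabilities over the role codes PS/SS/C/I.
#' @param target_route_prob Probability that a target drug row carries an
#'   accepted ocular route.
#' @param missing_route_prob Probability of a missing route on a target
#'   drug row (the remainder gets a non-ocular route).
#' @param duplicate_rate Fraction of reports re-emitted as near-duplicates
#'   (same CASEID, incremented CASEVERSION, later FDA_DT, new PRIMARYID).
#' @param planted_effects Named numeric vector: relative reporting-rate
#'   multiplier (>= 0) per preferred term, applied to exposed reports.
#' @param missing_sex,missing_age,missing_country Missingness probabilities.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 5000, seed = 1,
                             target_generic = "ATROPINE",
                             target_brands = c("ISOPTO ATROPINE", "ATROPEN",
                                               "MINIMS ATROPINE SULPHATE"),
                             background_drugs = c("TIMOLOL", "LATANOPROST",
                               "BRIMONIDINE", "DORZOLAMIDE",
                               "PREDNISOLONE ACETATE", "CICLOSPORIN",
                               "KETOROLAC", "OLOPATADINE", "IBUPROFEN",
                               "METFORMIN", "LISINOPRIL", "OMEPRAZOLE"),
                             event_vocab = .default_event_vocab(),
                             target_report_frac = 0.15,
                             role_mix = c(PS = 0.5, SS = 0.2, C = 0.2, I = 0.1),
                             target_route_prob = 0.8,
                             missing_route_prob = 0.1,
                             duplicate_rate = 0.1,
                             planted_effects = numeric(),
                             missing_sex = 0.1, missing_age = 0.25,
                             missing_country = 0.05) {
  probs <- c(target_report_frac, target_route_prob, missing_route_prob,
             duplicate_rate, missing_sex, missing_age, missing_country)
  stopifnot(all(probs >= 0 & probs <= 1),
            target_route_prob + missing_route_prob <= 1,
            n_reports >= 0, all(planted_effects >= 0),
            length(background_drugs) >= 2, nrow(event_vocab) >= 2,
            all(c("pt", "soc", "weight") %in% names(event_vocab)),
            setequal(names(role_mix), c("PS", "SS", "C", "I")))
  if (length(planted_effects) &&
      !all(names(planted_effects) %in% event_vocab$pt))
    stop("planted_effects names must be preferred terms of the event vocabulary")
  event_vocab$weight <- event_vocab$weight / sum(event_vocab$weight)
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 target_generic = target_generic, target_brands = target_brands,
                 background_drugs = background_drugs, event_vocab = event_vocab,
                 target_report_frac = target_report_frac,
                 role_mix = role_mix / sum(role_mix),
                 target_route_prob = target_route_prob,
                 missing_route_prob = missing_route_prob,
                 duplicate_rate = duplicate_rate,
                 planted_effects = planted_effects,
                 missing_sex = missing_sex, missing_age = missing_age,
                 missing_country = missing_country),
            class = "synthetic_config")
}

#' Drug dictionary matching a generator configuration
#'
#' @param config A [synthetic_config].
#' @return A [drug_dictionary] for the configured target drug.
#' @export
default_drug_dictionary <- function(config = synthetic_config()) {
  drug_dictionary(generic_names = config$target_generic,
                  brand_names = config$target_brands)
}

#' Term map matching a generator configuration
#'
#' @param config A [synthetic_config].
#' @return A [term_map] over the configured event vocabulary.
#' @export
default_term_map <- function(config = synthetic_config()) {
  term_map(config$event_vocab$pt, config$event_vocab$soc)
}

#' Generate synthetic quarterly tables with ground truth
#'
#' Emits the same parsed table layout that [read_quarterly_tables()]
#' produces (use [write_quarterly_tables()] to serialize in the FAERS
#' dialect) together with a ground-truth ledger: the per-report exposure
#' flag, the planted relative reporting rates and the injected duplicate
#' clusters. Every injected duplicate cluster is collapsible by
#' [deduplicate()] to exactly one survivor.
#'
#' @param config A [synthetic_config].
#' @return A list with elements `tables` (a [quarterly_tables]) and `truth`
#'   (list: `reports` data frame with `primaryid`, `caseid`, `carries_target`,
#'   `exposed`; `rr`; `duplicates` data frame).
#' @export
generate_reports <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  if (n == 0) {
    empty <- function(t) as.data.frame(setNames(
      rep(list(character(0)), length(.parsed_cols(t))), .parsed_cols(t)))
    tabs <- quarterly_tables(empty("demo"), empty("drug"), empty("reac"),
                             empty("outc"), empty("indi"),
                             quarter_label = "synthetic",
                             provenance = c(raw_reports = 0))
    return(list(tables = tabs,
                truth = list(reports = data.frame(), rr = config$planted_effects,
                             duplicates = data.frame())))
  }
  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "1")
  date0 <- as.Date("2020-01-01")
  fda_date <- date0 + sample.int(2000, n, replace = TRUE) - 1
  sex <- sample(c("male", "female", NA), n, replace = TRUE,
                prob = c((1 - config$missing_sex) * 0.5,
                         (1 - config$missing_sex) * 0.5, config$missing_sex))
  age_years <- round(runif(n, 0.5, 90), 1)
  in_months <- runif(n) < 0.1
  age_value <- ifelse(in_months, round(age_years * 12), age_years)
  age_unit <- ifelse(in_months, "months", "years")
  age_miss <- runif(n) < config$missing_age
  age_value[age_miss] <- NA_real_
  age_unit[age_miss] <- NA_character_
  country <- sample(c("CA", "FR", "US", "GB", "DE", "BR", NA), n, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.1, 0.08, 0.07,
                             config$missing_country) /
                           (0.95 + config$missing_country))
  demo <- data.frame(primaryid = primaryid, caseid = caseid, caseversion = 1L,
                     fda_dt = as.integer(format(fda_date, "%Y%m%d")),
                     sex = sex, age_value = age_value, age_unit = age_unit,
                     country = country, event_dt = NA_integer_,
                     stringsAsFactors = FALSE)

  # drug rows ---------------------------------------------------------------
  carries <- runif(n) < config$target_report_frac
  roles <- names(config$role_mix)
  target_names <- c(config$target_generic, config$target_brands,
                    paste(config$target_generic, "SULFATE 1%"))
  t_idx <- which(carries)
  t_role <- sample(roles, length(t_idx), replace = TRUE, prob = config$role_mix)
  u <- runif(length(t_idx))
  t_route <- ifelse(u < config$target_route_prob,
                    sample(c("OPHTHALMIC", "Ocular"), length(t_idx), replace = TRUE),
                    ifelse(u < config$target_route_prob + config$missing_route_prob,
                           NA_character_, "ORAL"))
  t_drug <- data.frame(primaryid = primaryid[t_idx], drug_seq = 1L,
                       role_cod = t_role,
                       drugname = sample(target_names, length(t_idx), replace = TRUE),
                       prod_ai = ifelse(runif(length(t_idx)) < 0.7,
                                        config$target_generic, NA_character_),
                       route = t_route, stringsAsFactors = FALSE)
  n_bg <- sample(0:3, n, replace = TRUE, prob = c(0.40, 0.35, 0.17, 0.08))
  n_bg[!carries] <- n_bg[!carries] + 1L  # every report lists at least one drug
  b_rid <- rep(seq_len(n), n_bg)
  b_drug <- data.frame(primaryid = primaryid[b_rid],
                       drug_seq = unlist(lapply(n_bg, seq_len), use.names = FALSE) +
                         ifelse(carries[b_rid], 1L, 0L),
                       role_cod = sample(roles, length(b_rid), replace = TRUE,
                                         prob = config$role_mix),
                       drugname = sample(config$background_drugs, length(b_rid),
                                         replace = TRUE),
                       prod_ai = NA_character_,
                       route = sample(c("ORAL", "INTRAVENOUS", "TOPICAL",
                                        NA_character_), length(b_rid),
                                      replace = TRUE),
                       stringsAsFactors = FALSE)
  b_drug$prod_ai <- b_drug$drugname
  drug <- rbind(t_drug, b_drug)
  drug <- drug[order(match(drug$primaryid, primaryid), drug$drug_seq), ]

  exposed <- rep(FALSE, n)
  exposed[t_idx] <- t_role %in% c("PS", "SS") & !is.na(t_route) &
    norm_key(t_route) %in% c("OPHTHALMIC", "OCULAR")

  # reaction rows: planted effects multiply the event probability for
  # exposed reports and renormalize
  vocab <- config$event_vocab
  k <- nrow(vocab)
  p0 <- vocab$weight
  rr <- rep(1, k)
  if (length(config$planted_effects))
    rr[match(names(config$planted_effects), vocab$pt)] <- config$planted_effects
  p1 <- p0 * rr / sum(p0 * rr)
  n_ev <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  rid <- rep(seq_len(n), n_ev)
  idx <- integer(length(rid))
  is_exp_row <- exposed[rid]
  idx[!is_exp_row] <- sample.int(k, sum(!is_exp_row), replace = TRUE, prob = p0)
  if (any(is_exp_row))
    idx[is_exp_row] <- sample.int(k, sum(is_exp_row), replace = TRUE, prob = p1)
  reac <- data.frame(primaryid = primaryid[rid], pt = vocab$pt[idx],
                     stringsAsFactors = FALSE)

  # indications for target rows; outcomes per report
  ind_has <- carries & runif(n) < 0.5
  indi <- data.frame(primaryid = primaryid[ind_has], drug_seq = 1L,
                     indi_pt = sample(c("Iridocyclitis", "Myopia", "Uveitis",
                                        "Ophthalmological examination",
                                        NA_character_),
                                      sum(ind_has), replace = TRUE),
                     stringsAsFactors = FALSE)
  out_has <- runif(n) < 0.55
  outc <- data.frame(primaryid = primaryid[out_has],
                     outcome = sample(c("other_serious", "hospitalization",
                                        "disability", "death", "life_threatening"),
                                      sum(out_has), replace = TRUE,
                                      prob = c(0.55, 0.27, 0.06, 0.05, 0.07)),
                     stringsAsFactors = FALSE)
  extra <- which(out_has & runif(n) < 0.15)
  if (length(extra)) {
    outc <- rbind(outc, data.frame(primaryid = primaryid[extra],
                                   outcome = sample(c("other_serious",
                                                      "hospitalization"),
                                                    length(extra), replace = TRUE)))
    outc <- unique(outc)
  }

  # near-duplicate clusters: same CASEID, version 2, later FDA_DT, new
  # PRIMARYID; child rows cloned under the new id
  n_dup <- floor(config$duplicate_rate * n)
  duplicates <- data.frame(caseid = character(), primaryid_base = character(),
                           primaryid_dup = character(), stringsAsFactors = FALSE)
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    dup_id <- paste0(caseid[di], "2")
    dup_demo <- demo[di, ]
    dup_demo$primaryid <- dup_id
    dup_demo$caseversion <- 2L
    dup_demo$fda_dt <- as.integer(format(fda_date[di] +
                                           sample(30:90, n_dup, replace = TRUE),
                                         "%Y%m%d"))
    clone <- function(df) {
      sub <- df[df$primaryid %in% primaryid[di], , drop = FALSE]
      sub$primaryid <- dup_id[match(sub$primaryid, primaryid[di])]
      sub
    }
    demo <- rbind(demo, dup_demo)
    drug <- rbind(drug, clone(drug))
    reac <- rbind(reac, clone(reac))
    outc <- rbind(outc, clone(outc))
    indi <- rbind(indi, clone(indi))
    duplicates <- data.frame(caseid = caseid[di], primaryid_base = primaryid[di],
                             primaryid_dup = dup_id, stringsAsFactors = FALSE)
  }
  rownames(demo) <- rownames(drug) <- rownames(reac) <- NULL
  rownames(outc) <- rownames(indi) <- NULL
  tabs <- quarterly_tables(demo, drug, reac, outc, indi,
                           quarter_label = "synthetic",
                           provenance = c(raw_reports = nrow(demo)))
  truth <- list(reports = data.frame(primaryid = primaryid, caseid = caseid,
                                     carries_target = carries, exposed = exposed,
                                     stringsAsFactors = FALSE),
                rr = setNames(rr, vocab$pt),
                duplicates = duplicates)
  list(tables = tabs, truth = truth)
}

#' Large-sample value of the planted information component
#'
#' With a planted multiplier RR on one preferred term, the scan's shrunk
#' ratio converges not to RR itself but to the effective relative reporting
#' rate after renormalization and dilution by the exposed margin:
#' `p1 / (f * p1 + (1 - f) * p0)`, where `p0`/`p1` are the term's selection
#' probabilities in unexposed/exposed reports and `f` is the designed
#' exposed fraction. This is the estimand the recovery experiment targets.
#'
#' @param config A [synthetic_config].
#' @param target_pt Preferred term carrying the planted effect.
#' @param rr Planted relative reporting rate.
#' @return The asymptotic IC in bits.
#' @export
planted_ic_limit <- function(config, target_pt, rr) {
  vocab <- config$event_vocab
  stopifnot(target_pt %in% vocab$pt)
  p0 <- vocab$weight / sum(vocab$weight)
  mult <- rep(1, nrow(vocab))
  mult[vocab$pt == target_pt] <- rr
  p1 <- p0 * mult / sum(p0 * mult)
  i <- which(vocab$pt == target_pt)
  f <- config$target_report_frac * sum(config$role_mix[c("PS", "SS")]) *
    config$target_route_prob
  log2(p1[i] / (f * p1[i] + (1 - f) * p0[i]))
}

#' Parameter-recovery experiment
#'
#' For each relative reporting rate in `rr_grid`, generates `n_reps`
#' independent corpora with that RR planted on one preferred term, runs the
#' full cleaning and scanning pipeline, and summarises recovery: the mean
#' estimated IC (log2 shrunk ratio) for the planted term, its bias against
#' `log2(RR)`, and the detection rate (fraction of replicates with
#' `ic_025 > 0`).
#'
#' @param config Base [synthetic_config]; its seed anchors the replicate
#'   seeds.
#' @param rr_grid Numeric vector of relative reporting rates (>= 1).
#' @param n_reps Replicates per grid point (>= 1).
#' @param target_pt Preferred term carrying the planted effect.
#' @return A data frame with one row per grid point: `rr`, `n_reps`,
#'   `detection_rate`, `mean_ic`, `bias_log2` (against `log2(rr)`) and
#'   `bias_vs_limit` (against [planted_ic_limit()], the estimand).
#' @export
recovery_experiment <- function(config = synthetic_config(), rr_grid = c(1, 5, 20),
                                n_reps = 5, target_pt = "Endophthalmitis") {
  stopifnot(all(rr_grid >= 1), n_reps >= 1,
            target_pt %in% config$event_vocab$pt)
  dict <- default_drug_dictionary(config)
  out <- lapply(seq_along(rr_grid), function(g) {
    ic <- det <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- config
      cfg$planted_effects <- setNames(rr_grid[g], target_pt)
      cfg$seed <- (config$seed + 7919L * g + r) %% .Machine$integer.max
      sim <- generate_reports(cfg)
      cases <- suppressMessages(clean_reports(sim$tables, dict))
      scan <- signal_scan(cases)
      row <- scan$results[scan$results$term == target_pt, ]
      ic[r] <- row$ic
      det[r] <- row$ic_025 > 0
    }
    data.frame(rr = rr_grid[g], n_reps = n_reps, detection_rate = mean(det),
               mean_ic = mean(ic), bias_log2 = mean(ic) - log2(rr_grid[g]),
               bias_vs_limit = mean(ic) -
                 planted_ic_limit(config, target_pt, rr_grid[g]))
  })
  do.call(rbind, out)
}
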