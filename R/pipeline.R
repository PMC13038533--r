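# End-to-end orchestration: clean -> describe -> scan -> prioritize ->
# report, with a provenance manifest. Two entry modes: full pipeline from
# raw (or generated) tables, and annotation-only mode that scores a
# pre-computed signal table.

#' Run the full analysis pipeline
#'
#' Executes cleaning, descriptive summaries, PT- and SOC-level signal scans
#' and clinical prioritization, writing every product as CSV/JSON under
#' `out_dir` together with a provenance manifest (seed, config hash,
#' per-step drop counts). Reruns with the same configuration and seed are
#' byte-identical. Any stage failure aborts with the stage name.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{input}{named list of the five table paths for
#'       [read_quarterly_tables()]; omit when `synthetic` is given.}
#'     \item{synthetic}{named list of [synthetic_config()] arguments; used
#'       when no `input` is given.}
#'     \item{signal_table}{data frame or CSV path with pre-computed signals
#'       (columns `pt`, `cases`, `ror`, `ror_l95`, optionally `deaths`,
#'       `event_status`, `evidence`); switches to annotation-only mode.}
#'     \item{drug_dict}{[drug_dictionary()], JSON path, or omitted for the
#'       generator default.}
#'     \item{term_map}{[term_map()], CSV path, or omitted.}
#'     \item{event_lists}{[medical_event_list()], or list with `ime`/`dme`
#'       CSV paths.}
#'     \item{evidence}{data frame or CSV path `(pt, evidence)` with
#'       optional `event_status` override.}
#'     \item{rule, ror_mode}{signal rule and rubric ROR mode.}
#'     \item{out_dir}{output directory (required).}
#'     \item{seed}{integer seed recorded in the manifest and forwarded to
#'       the generator.}
#'   }
#' @return Invisibly, a list with the in-memory products (`cases`,
#'   `descriptive`, `scan_pt`, `scan_soc`, `priority`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- config$seed %||% 1L
  map <- .resolve_term_map(config$term_map)
  events <- .resolve_events(config$event_lists)
  evidence <- .resolve_table(config$evidence)
  rule <- config$rule %||% "either"
  ror_mode <- config$ror_mode %||% "point"

  if (!is.null(config$signal_table)) {
    sig <- .resolve_table(config$signal_table)
    priority <- stage("prioritize", prioritize_all(sig, annotations = evidence,
                                                   events = events,
                                                   ror_mode = ror_mode))
    utils::write.csv(priority, file.path(out_dir, "priority.csv"), row.names = FALSE)
    manifest <- .write_manifest(out_dir, config, seed,
                                counts = c(signals_scored = nrow(priority)))
    return(invisible(list(priority = priority, manifest = manifest)))
  }

  if (!is.null(config$input)) {
    tables <- stage("read", read_quarterly_tables(config$input,
                                                  delim = config$delim %||% "$"))
    dict <- .resolve_dict(config$drug_dict, default = NULL)
    if (is.null(dict)) stop("pipeline stage 'read' failed: drug_dict required with raw input")
  } else {
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- syn_args$seed %||% seed
    syn <- do.call(synthetic_config, syn_args)
    tables <- stage("simulate", generate_reports(syn)$tables)
    dict <- .resolve_dict(config$drug_dict, default = default_drug_dictionary(syn))
    if (is.null(map)) map <- default_term_map(syn)
  }

  tables <- stage("deduplicate", suppressMessages(deduplicate(tables)))
  tables <- stage("filter_roles", suppressMessages(filter_suspect_roles(tables)))
  flags <- stage("match_target", match_target_drug(tables, dict))
  cases <- stage("extract", extract_events(tables, flags))
  write_clean_dataset(cases, file.path(out_dir, "clean_cases.csv"))

  descr <- stage("describe", descriptive_summary(cases))
  for (nm in c("sex", "age", "country", "indications", "outcome"))
    utils::write.csv(descr[[nm]],
                     file.path(out_dir, paste0("descriptive_", nm, ".csv")),
                     row.names = FALSE)

  scan_pt <- stage("signal_pt", signal_scan(cases, map = map, level = "pt",
                                            rule = rule))
  utils::write.csv(scan_pt$results, file.path(out_dir, "signals_pt.csv"),
                   row.names = FALSE)
  scan_soc <- NULL
  if (!is.null(map)) {
    scan_soc <- stage("signal_soc", signal_scan(cases, map = map, level = "soc",
                                                rule = rule))
    utils::write.csv(scan_soc$results, file.path(out_dir, "signals_soc.csv"),
                     row.names = FALSE)
  }
  priority <- stage("prioritize", prioritize_all(scan_pt, annotations = evidence,
                                                 events = events,
                                                 ror_mode = ror_mode))
  utils::write.csv(priority, file.path(out_dir, "priority.csv"), row.names = FALSE)

  prov <- cases$provenance
  manifest <- .write_manifest(out_dir, config, seed, counts = c(
    as.list(prov),
    list(target_cases = sum(cases$cases$target_drug),
         case_pt_pairs = nrow(cases$pts),
         terms_scanned = nrow(scan_pt$results),
         significant_signals = sum(scan_pt$results$significant),
         signals_scored = nrow(priority))))
  invisible(list(cases = cases, descriptive = descr, scan_pt = scan_pt,
                 scan_soc = scan_soc, priority = priority, manifest = manifest))
}

.write_manifest <- function(out_dir, config, seed, counts) {
  config$out_dir <- NULL  # hash the analysis config, not the output location
  cfg_json <- jsonlite::toJSON(.serializable(config), auto_unbox = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(package = "faersignal",
                   version = as.character(utils::packageVersion("faersignal")),
                   seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

# drop non-serializable members (S3 objects become their underlying lists)
.serializable <- function(x) {
  rapply(x, function(v) if (is.data.frame(v)) v else unclass(v),
         classes = "ANY", how = "replace")
}

.resolve_dict <- function(x, default) {
  if (is.null(x)) return(default)
  if (inherits(x, "drug_dictionary")) return(x)
  load_drug_dictionary(x)
}

.resolve_term_map <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "term_map")) return(x)
  load_term_map(x)
}

.resolve_events <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "medical_event_list")) return(x)
  load_medical_event_list(x$ime, x$dme)
}

.resolve_table <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  utils::read.csv(x, check.names = FALSE, stringsAsFactors = FALSE)
}
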