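# Clinical prioritization of significant signals: a semiquantitative
# five-dimension rubric (0/1/2 points each, 0-10 total) and weak/moderate/
# strong tiers.
#
# Bin closures, resolved against the published scoring examples where the
# printed ranges are open: a case count of exactly 50 scores 1; an ROR of
# exactly 5 or exactly 2 scores 1; a mortality proportion of exactly 25% or
# 50% scores 1.

#' Score one signal on the clinical-priority rubric
#'
#' Five dimensions, each 0-2 points:
#' \itemize{
#'   \item target events: >50 cases = 2, 10-50 = 1, <10 = 0;
#'   \item ROR: >5 = 2, 2-5 = 1, 1-2 = 0 (values below 1 score 0 with a
#'     warning - a flagged signal should exceed 1);
#'   \item mortality proportion (deaths / cases): >50% = 2, 25-50% = 1,
#'     <25% = 0;
#'   \item medical-event designation: DME = 2, IME = 1, none = 0;
#'   \item supporting-evidence grade: `++` = 2, `+` = 1, `-` = 0.
#' }
#'
#' @param n_cases Number of target events (>= 1).
#' @param ror_value The ROR used for binning; the point estimate under the
#'   default configuration, the lower CI bound under `ror_mode = "lower"`
#'   of [prioritize_all()].
#' @param death_count Number of fatal reports.
#' @param event_status `"DME"`, `"IME"` or `"none"`.
#' @param evidence `"++"`, `"+"` or `"-"`.
#' @return A list with `components` (named integer vector of the five
#'   scores), `total` (0-10) and `tier`.
#' @export
score_priority <- function(n_cases, ror_value, death_count = 0,
                           event_status = "none", evidence = "-") {
  stopifnot(n_cases >= 1, death_count >= 0, death_count <= n_cases)
  cases_pts <- if (n_cases > 50) 2L else if (n_cases >= 10) 1L else 0L
  if (!is.na(ror_value) && ror_value < 1)
    warning("ror_value below 1 for a scored signal; ROR dimension scored 0")
  ror_pts <- if (is.na(ror_value) || ror_value < 2) 0L
             else if (ror_value > 5) 2L else 1L
  mort <- death_count / n_cases
  mort_pts <- if (mort > 0.5) 2L else if (mort >= 0.25) 1L else 0L
  event_pts <- switch(match.arg(event_status, c("none", "IME", "DME")),
                      DME = 2L, IME = 1L, none = 0L)
  evid_pts <- switch(match.arg(evidence, c("-", "+", "++")),
                     "++" = 2L, "+" = 1L, "-" = 0L)
  components <- c(cases = cases_pts, ror = ror_pts, mortality = mort_pts,
                  event = event_pts, evidence = evid_pts)
  total <- sum(components)
  list(components = components, total = total, tier = classify_tier(total))
}

#' Priority tier from a total score
#'
#' @param total Integer total score(s) in 0-10.
#' @return `"weak"` (0-4), `"moderate"` (5-7) or `"strong"` (8-10).
#' @export
classify_tier <- function(total) {
  stopifnot(all(total >= 0), all(total <= 10), all(total == round(total)))
  ifelse(total >= 8, "strong", ifelse(total >= 5, "moderate", "weak"))
}

#' Score a table of signals
#'
#' Applies [score_priority()] row-wise to an annotated signal table. The
#' input can be a `signal_scan` (its significant rows are taken, joined to
#' the annotation table) or a plain data frame with columns `pt` (or
#' `term`), `cases` (or `a`), `ror`, `ror_l95`, and optionally `deaths`,
#' `event_status`, `evidence`.
#'
#' @param signals A `signal_scan` object or data frame as described.
#' @param annotations Optional data frame keyed by `pt` supplying
#'   `evidence` and/or `event_status` where the signal table lacks them.
#' @param events Optional [medical_event_list] used to derive
#'   `event_status` when absent.
#' @param ror_mode `"point"` (default) bins on the ROR point estimate;
#'   `"lower"` bins on the lower 95% bound.
#' @return An object of class `priority_table`: a data frame with the five
#'   component scores, `total` and `tier` per signal, plus a `tier_counts`
#'   attribute.
#' @export
prioritize_all <- function(signals, annotations = NULL, events = NULL,
                           ror_mode = c("point", "lower")) {
  ror_mode <- match.arg(ror_mode)
  if (inherits(signals, "signal_scan")) {
    r <- signals$results
    r <- r[r$significant, , drop = FALSE]
    df <- data.frame(pt = r$term, cases = r$a, ror = r$ror,
                     ror_l95 = r$ror_l95, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(signals)
    if (!"pt" %in% names(df) && "term" %in% names(df)) df$pt <- df$term
    if (!"cases" %in% names(df) && "a" %in% names(df)) df$cases <- df$a
  }
  stopifnot(all(c("pt", "cases", "ror") %in% names(df)))
  if (!"deaths" %in% names(df)) df$deaths <- rep(0L, nrow(df))
  if (!"event_status" %in% names(df)) df$event_status <- rep(NA_character_, nrow(df))
  if (!"evidence" %in% names(df)) df$evidence <- rep(NA_character_, nrow(df))
  if (!is.null(annotations)) {
    i <- match(norm_key(df$pt), norm_key(annotations$pt))
    if ("evidence" %in% names(annotations))
      df$evidence <- ifelse(is.na(df$evidence), annotations$evidence[i], df$evidence)
    if ("event_status" %in% names(annotations))
      df$event_status <- ifelse(is.na(df$event_status),
                                annotations$event_status[i], df$event_status)
  }
  if (!is.null(events))
    df$event_status[is.na(df$event_status)] <-
      ime_dme_status(df$pt[is.na(df$event_status)], events)
  df$event_status[is.na(df$event_status)] <- "none"
  # unannotated evidence defaults to "-": no documented support is the
  # conservative grade
  df$evidence[is.na(df$evidence)] <- "-"
  ror_used <- if (ror_mode == "point") df$ror else df$ror_l95
  scored <- lapply(seq_len(nrow(df)), function(i)
    score_priority(df$cases[i], ror_used[i], df$deaths[i],
                   df$event_status[i], df$evidence[i]))
  comp <- do.call(rbind, lapply(scored, function(s) s$components))
  out <- data.frame(pt = df$pt, cases = df$cases, ror_used = ror_used,
                    deaths = df$deaths, event_status = df$event_status,
                    evidence = df$evidence, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    colnames(comp) <- paste0("score_", colnames(comp))
    out <- cbind(out, comp)
    out$total <- vapply(scored, `[[`, 0, "total")
    out$tier <- vapply(scored, `[[`, "", "tier")
  } else {
    for (nm in c("score_cases", "score_ror", "score_mortality", "score_event",
                 "score_evidence", "total")) out[[nm]] <- numeric()
    out$tier <- character()
  }
  tiers <- c(weak = sum(out$tier == "weak"),
             moderate = sum(out$tier == "moderate"),
             strong = sum(out$tier == "strong"))
  structure(out, tier_counts = tiers, ror_mode = ror_mode,
            class = c("priority_table", "data.frame"))
}

#' @export
print.priority_table <- function(x, ...) {
  tc <- attr(x, "tier_counts")
  cat(sprintf("Clinical priority of %d signal(s) [ROR dimension: %s estimate]\n",
              nrow(x), attr(x, "ror_mode")))
  cat(sprintf("  weak %d | moderate %d | strong %d\n",
              tc["weak"], tc["moderate"], tc["strong"]))
  NextMethod()
  invisible(x)
}
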