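# Disproportionality statistics on 2x2 contingency tables of case-term
# pairs: classical reporting odds ratio with the Woolf interval, the
# shrinkage-stabilized observed/expected ratio and its information
# component with closed-form credible bounds, and the signal rule.
#
# The counting unit throughout is the unique (case, term) pair: one case
# contributes a given preferred term (or SOC) at most once.

#' Expected count under independence
#'
#' `n_drug * n_event / n_total`: the number of target-drug records carrying
#' the target event expected if drug and event were reported independently.
#'
#' @param n_drug Total records of the target drug.
#' @param n_event Total records of the target event.
#' @param n_total Total records in the database.
#' @return Real-valued expected count.
#' @export
expected_count <- function(n_drug, n_event, n_total) {
  stopifnot(all(n_total > 0))
  n_drug * n_event / n_total
}

#' Shrinkage-stabilized ratio and information component
#'
#' Adds 0.5 to both the observed and the expected count before taking the
#' ratio, stabilizing it for rare events; the information component is the
#' base-2 log of the same shrunk ratio, so `ic == log2(ror_shrunk)` by
#' construction.
#'
#' @param n_observed Observed count(s), >= 0.
#' @param n_expected Expected count(s), >= 0.
#' @return A data frame with columns `ror_shrunk` and `ic` (bits).
#' @export
shrunk_ratio_and_ic <- function(n_observed, n_expected) {
  stopifnot(all(n_observed >= 0), all(n_expected >= 0))
  ratio <- (n_observed + 0.5) / (n_expected + 0.5)
  data.frame(ror_shrunk = ratio, ic = log2(ratio))
}

#' Credible bounds for the information component
#'
#' Closed-form approximations to the 2.5% and 97.5% bounds of the IC
#' posterior, as functions of the observed count:
#' \deqn{IC_{025} = IC - 3.3 (N+0.5)^{-1/2} - 2 (N+0.5)^{-3/2}}
#' \deqn{IC_{975} = IC + 2.4 (N+0.5)^{-1/2} - 0.5 (N+0.5)^{-3/2}}
#' with `N` the observed count. The interval tightens monotonically as the
#' count grows.
#'
#' @param ic Information component (bits).
#' @param n_observed Observed count(s), >= 0.
#' @return A data frame with columns `ic_025` and `ic_975`.
#' @export
ic_interval <- function(ic, n_observed) {
  stopifnot(all(n_observed >= 0))
  m <- n_observed + 0.5
  data.frame(ic_025 = ic - 3.3 * m^-0.5 - 2 * m^-1.5,
             ic_975 = ic + 2.4 * m^-0.5 - 0.5 * m^-1.5)
}

#' Contingency table for one drug-event pair
#'
#' Builds the 2x2 table over unique case-term pairs: `a` pairs with both the
#' target drug and the term, `b` target-drug pairs with other terms, `c`
#' other-drug pairs with the term, `d` the remainder. At a fixed level the
#' four cells always sum to the full case-term universe, whatever the term.
#'
#' @param cases A [clean_case_set].
#' @param term The preferred term (or SOC name for `level = "soc"`).
#' @param level `"pt"` or `"soc"`.
#' @param map A [term_map]; required for `level = "soc"`.
#' @return An object of class `contingency_table`: list with `a`, `b`, `c`,
#'   `d`, `n_drug`, `n_event`, `n_total`, `term`, `level`.
#' @export
build_contingency <- function(cases, term, level = c("pt", "soc"), map = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(cases, "clean_case_set"))
  u <- .case_term_universe(cases, level, map)
  key <- norm_key(term)
  is_term <- norm_key(u$term) == key
  a <- sum(u$target & is_term)
  b <- sum(u$target & !is_term)
  c_ <- sum(!u$target & is_term)
  d <- sum(!u$target & !is_term)
  structure(list(a = a, b = b, c = c_, d = d,
                 n_drug = a + b, n_event = a + c_, n_total = a + b + c_ + d,
                 term = term, level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table for %s '%s' (case-%s pairs)\n", x$level, x$term, x$level))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs"),
                              c("term", "other terms")))
  print(m)
  invisible(x)
}

# Unique (caseid, term) pairs with target flag, at PT or SOC level.
.case_term_universe <- function(cases, level, map) {
  pts <- cases$pts
  if (level == "soc") {
    if (is.null(map)) stop("a term_map is required at SOC level")
    pts <- unique(data.frame(caseid = pts$caseid, pt = soc_of(pts$pt, map),
                             stringsAsFactors = FALSE))
  }
  tgt <- setNames(cases$cases$target_drug, cases$cases$caseid)
  data.frame(caseid = pts$caseid, term = pts$pt,
             target = unname(tgt[pts$caseid]), stringsAsFactors = FALSE)
}

#' Classical reporting odds ratio with Woolf interval
#'
#' `ROR = ad / bc`, with the 95% CI `exp(ln ROR +- 1.96 sqrt(1/a + 1/b +
#' 1/c + 1/d))`. If any cell is zero the Haldane-Anscombe correction (+0.5
#' to every cell) is applied and flagged instead of failing.
#'
#' @param ct A [contingency_table], or a numeric vector/list with elements
#'   `a`, `b`, `c`, `d`.
#' @return A data frame with columns `ror`, `ror_l95`, `ror_u95`,
#'   `zero_cell_corrected`.
#' @export
classical_ror <- function(ct) {
  cells <- c(a = ct[["a"]], b = ct[["b"]], c = ct[["c"]], d = ct[["d"]])
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  ror <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  data.frame(ror = unname(ror),
             ror_l95 = unname(exp(log(ror) - 1.96 * se)),
             ror_u95 = unname(exp(log(ror) + 1.96 * se)),
             zero_cell_corrected = corrected)
}

#' Statistical significance of a signal
#'
#' Default rule (`"either"`): the signal is significant when the lower ROR
#' bound exceeds one *or* the lower IC bound exceeds zero, with at least
#' three records. The stricter `"both"` variant requires both bounds.
#'
#' @param n_observed Observed count(s).
#' @param ror_l95 Lower 95% bound(s) of the classical ROR.
#' @param ic_025 Lower credible bound(s) of the IC.
#' @param rule `"either"` (default) or `"both"`.
#' @param min_count Minimum record count (default 3).
#' @return Logical vector.
#' @export
flag_signal <- function(n_observed, ror_l95, ic_025,
                        rule = c("either", "both"), min_count = 3) {
  rule <- match.arg(rule)
  stat <- if (rule == "either") (ror_l95 > 1) | (ic_025 > 0)
          else (ror_l95 > 1) & (ic_025 > 0)
  stat & (n_observed >= min_count)
}

#' Scan all terms for disproportionality signals
#'
#' Computes, for every distinct term reported by at least one target-drug
#' case, the 2x2 counts, expected count, classical ROR with Woolf CI, the
#' shrunk ratio, the IC with credible bounds, and the significance flag.
#' This is the package's central estimator; the result prints, summarises
#' and plots like a fitted object.
#'
#' @param cases A [clean_case_set].
#' @param map Optional [term_map] (required for `level = "soc"`; at PT level
#'   it only annotates each PT with its SOC).
#' @param level `"pt"` or `"soc"`.
#' @param rule Signal rule passed to [flag_signal()].
#' @param min_count Minimum record count for significance.
#' @return An object of class `signal_scan`: a list with `results` (one row
#'   per term, sorted by `ror_l95` descending with ties broken by term
#'   name), `level`, `rule`, `n_total` and the matched call.
#' @export
signal_scan <- function(cases, map = NULL, level = c("pt", "soc"),
                        rule = c("either", "both"), min_count = 3) {
  level <- match.arg(level)
  rule <- match.arg(rule)
  stopifnot(inherits(cases, "clean_case_set"))
  u <- .case_term_universe(cases, level, map)
  n_total <- nrow(u)
  terms <- sort(unique(u$term[u$target]))
  res <- if (length(terms) == 0) {
    .empty_scan_results()
  } else {
    n_drug <- sum(u$target)
    a <- as.integer(table(factor(u$term[u$target], levels = terms)))
    n_event <- as.integer(table(factor(u$term, levels = terms)))
    b <- n_drug - a
    c_ <- n_event - a
    d <- n_total - n_drug - c_
    ror <- do.call(rbind, lapply(seq_along(terms), function(i)
      classical_ror(list(a = a[i], b = b[i], c = c_[i], d = d[i]))))
    n_exp <- expected_count(n_drug, n_event, n_total)
    shr <- shrunk_ratio_and_ic(a, n_exp)
    ici <- ic_interval(shr$ic, a)
    soc <- if (!is.null(map)) {
      if (level == "soc") terms else soc_of(terms, map)
    } else NA_character_
    data.frame(term = terms, level = level, soc = soc,
               a = a, b = b, c = c_, d = d, n_expected = n_exp,
               ror, shr, ici,
               significant = flag_signal(a, ror$ror_l95, ici$ic_025,
                                         rule = rule, min_count = min_count),
               stringsAsFactors = FALSE)
  }
  res <- res[order(-res$ror_l95, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, level = level, rule = rule,
                 min_count = min_count, n_total = n_total,
                 call = match.call()),
            class = "signal_scan")
}

.empty_scan_results <- function() {
  data.frame(term = character(), level = character(), soc = character(),
             a = integer(), b = integer(), c = integer(), d = integer(),
             n_expected = numeric(), ror = numeric(), ror_l95 = numeric(),
             ror_u95 = numeric(), zero_cell_corrected = logical(),
             ror_shrunk = numeric(), ic = numeric(), ic_025 = numeric(),
             ic_975 = numeric(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.signal_scan <- function(x, n = 10, ...) {
  cat(sprintf("Disproportionality scan at %s level (%d term(s), %d case-term pair(s))\n",
              toupper(x$level), nrow(x$results), x$n_total))
  cat(sprintf("Signal rule: lower ROR bound > 1 %s IC025 > 0, >= %d records; %d significant\n",
              if (x$rule == "either") "OR" else "AND", x$min_count,
              sum(x$results$significant)))
  if (nrow(x$results)) {
    show <- utils::head(x$results[, c("term", "a", "n_expected", "ror",
                                      "ror_l95", "ror_u95", "ic", "ic_025",
                                      "significant")], n)
    show[, sapply(show, is.numeric)] <- round(show[, sapply(show, is.numeric)], 3)
    print(show, row.names = FALSE)
    if (nrow(x$results) > n) cat(sprintf("... and %d more term(s)\n",
                                         nrow(x$results) - n))
  }
  invisible(x)
}

#' @export
summary.signal_scan <- function(object, ...) {
  r <- object$results
  structure(list(level = object$level, rule = object$rule,
                 n_terms = nrow(r), n_significant = sum(r$significant),
                 n_total = object$n_total,
                 top = utils::head(r[r$significant, , drop = FALSE], 10)),
            class = "summary.signal_scan")
}

#' @export
print.summary.signal_scan <- function(x, ...) {
  cat(sprintf("%d of %d term(s) significant at %s level (%d case-term pairs)\n",
              x$n_significant, x$n_terms, toupper(x$level), x$n_total))
  if (nrow(x$top)) {
    cat("Strongest signals (by lower ROR bound):\n")
    show <- x$top[, c("term", "a", "ror", "ror_l95", "ic", "ic_025")]
    show[, -1] <- round(show[, -1], 3)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.signal_scan <- function(x, ...) x$results

#' Forest plot of scanned signals
#'
#' Draws the classical ROR and its 95% CI on a log axis, one row per term,
#' significant signals filled.
#'
#' @param x A `signal_scan` object.
#' @param n Maximum number of terms to draw (strongest first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.signal_scan <- function(x, n = 30, ...) {
  r <- utils::head(x$results, n)
  if (nrow(r) == 0) stop("nothing to plot")
  r <- r[rev(seq_len(nrow(r))), ]
  y <- seq_len(nrow(r))
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(r$ror, y, log = "x", pch = ifelse(r$significant, 16, 1),
                 xlim = range(c(r$ror_l95, r$ror_u95, 1), finite = TRUE),
                 yaxt = "n", ylab = "", xlab = "Reporting odds ratio (log scale)",
                 ...)
  graphics::segments(r$ror_l95, y, r$ror_u95, y)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = y, labels = r$term, las = 1, cex.axis = 0.7)
  invisible(x)
}
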