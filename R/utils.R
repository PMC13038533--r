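# Internal string / date helpers shared across modules.

#' @noRd
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

# Canonical key for term lookups: case-insensitive, whitespace-collapsed.
#' @noRd
norm_key <- function(x) toupper(squish(as.character(x)))

# Display form for MedDRA preferred terms: whitespace-collapsed sentence case.
#' @noRd
norm_pt <- function(x) {
  x <- squish(as.character(x))
  out <- tolower(x)
  substr(out, 1, 1) <- toupper(substr(out, 1, 1))
  out[is.na(x) | x == ""] <- NA_character_
  out
}

# Drug-name normalisation: uppercase, punctuation stripped, whitespace
# collapsed. FAERS free-text names carry salts, strengths and stray marks
# ("ATROPINE SULFATE 1%"), so matching happens on this canonical form.
#' @noRd
norm_drug <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9 ]", " ", x)
  squish(x)
}

# Parse YYYYMMDD integers; anything that is not a valid 8-digit calendar
# date becomes NA. Dates are kept as integers: ordering is all that the
# deduplication rule needs.
#' @noRd
parse_yyyymmdd <- function(x) {
  x <- squish(as.character(x))
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out <- rep(NA_integer_, length(x))
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y%m%d")
    val <- !is.na(d)
    out[ok][val] <- as.integer(x[ok][val])
  }
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# NA-safe numeric ordering key: missing sorts first (i.e. loses ties).
#' @noRd
na_low <- function(x) {
  x <- as.numeric(x)
  x[is.na(x)] <- -Inf
  x
}
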