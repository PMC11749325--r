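#' Round half away from zero
#'
#' Commercial ("round half up" in magnitude) rounding, as used by most
#' clinical statistics software, in contrast to the IEC 60559 banker's
#' rounding of [base::round()]. A guard of 1e-9 is added to the scaled
#' magnitude before truncation so that values that are exact decimal ties
#' (e.g. 96.25) but sit just below the tie in binary round upward as a
#' decimal calculator would.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_away(96.25, 1) # 96.3
#' round_half_away(-0.125, 2) # -0.13
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# Parse a flag column from {0,1,true,false,yes,no,t,f} (case-insensitive).
# NA and "" stay NA. Anything else is an error naming the offending rows.
parse_flag <- function(x, column = "flag") {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[v %in% c("0", "false", "no", "f", "n")] <- FALSE
  bad <- which(!is.na(v) & v != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable flag value(s) '%s' at row(s) %s",
                 column, paste(unique(v[bad]), collapse = "', '"),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

# Parse a numeric column; empty cells become NA (absent, never zero).
parse_num <- function(x, column = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  v <- trimws(as.character(x))
  v[v == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable numeric value(s) '%s' at row(s) %s",
                 column, paste(unique(v[bad]), collapse = "', '"),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
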