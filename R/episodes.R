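#' @title Episode-level data: schema, I/O and validation
#' @description
#' One row of the episode table describes a single suspected
#' healthcare-associated infection (HAI) episode in a hospitalised neonate:
#' the clinical signs assessed at the bedside, central-line exposure,
#' point-of-care C-reactive protein (CRP) at presentation (t0) and 24 h later
#' (t24), the blood-culture result, and the antibiotic course actually given.
#' CSV with the fixed header below is the canonical interchange format;
#' missing CRP measurements are empty cells, never zeroes.
#' @name episodes
NULL

# Canonical column set. lab_crp (laboratory/serum CRP used by the case
# definitions) and hai_class_sampled (generator truth) are optional.
.episode_cols_required <- c(
  "episode_id", "subject_id", "postnatal_age_days",
  "crt_gt_3s", "lethargy", "abdominal_distention", "cvc_in_situ_or_48h",
  "crp_t0", "crp_t24",
  "organism_class", "n_positive_cultures", "paired_cultures_24_48h_apart",
  "collected_after_72h_admission", "clinical_signs_present",
  "observed_lot_days", "antibiotics_continued_ge_5d",
  "symptoms_short_lived", "abx_stopped_within_72h"
)
.episode_cols_optional <- c("lab_crp", "hai_class_sampled")

.flag_cols <- c(
  "crt_gt_3s", "lethargy", "abdominal_distention", "cvc_in_situ_or_48h",
  "paired_cultures_24_48h_apart", "collected_after_72h_admission",
  "clinical_signs_present", "antibiotics_continued_ge_5d",
  "symptoms_short_lived", "abx_stopped_within_72h"
)
.num_cols <- c("postnatal_age_days", "crp_t0", "crp_t24", "lab_crp",
               "n_positive_cultures", "observed_lot_days")

.organism_levels <- c("pathogen", "cons", "negative", "contaminant_other")

#' Canonical episode-table column names
#'
#' @param optional include the optional columns (`lab_crp`, the laboratory
#'   CRP used by the case definitions, and `hai_class_sampled`, the
#'   generator's ground-truth label).
#' @return character vector of column names.
#' @export
episode_columns <- function(optional = FALSE) {
  if (optional) c(.episode_cols_required, .episode_cols_optional)
  else .episode_cols_required
}

#' Read an episode table from CSV
#'
#' Empty CRP cells are read as missing (`NA`), never as zero. Flags accept
#' `0/1`, `true/false`, `yes/no` case-insensitively. Extra columns are kept
#' as-is.
#'
#' @param path path to a delimited text file with a header row.
#' @param delim field delimiter, default comma.
#' @return a `data.frame`, one row per episode.
#' @seealso [write_episodes()], [validate_episodes()]
#' @export
read_episodes <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = NULL,
                           quote = "\"", comment.char = "")
  missing_cols <- setdiff(.episode_cols_required, names(raw))
  if (length(missing_cols)) {
    stop("episode table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- raw
  for (cl in intersect(.flag_cols, names(df))) {
    df[[cl]] <- parse_flag(df[[cl]], cl)
  }
  for (cl in intersect(.num_cols, names(df))) {
    df[[cl]] <- parse_num(df[[cl]], cl)
  }
  df$organism_class <- tolower(trimws(df$organism_class))
  bad <- which(!df$organism_class %in% .organism_levels)
  if (length(bad)) {
    stop(sprintf("column 'organism_class': unknown value(s) '%s' at row(s) %s",
                 paste(unique(df$organism_class[bad]), collapse = "', '"),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write an episode table to CSV
#'
#' Missing values are written as empty cells so that
#' `read_episodes(write_episodes(x))` reproduces `x` field-for-field.
#'
#' @param episodes episode `data.frame`.
#' @param path output path.
#' @param delim field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path, delim = ",") {
  stopifnot(is.data.frame(episodes))
  out <- episodes
  for (cl in intersect(.flag_cols, names(out))) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), "", ifelse(out[[cl]], "1", "0"))
  }
  # character fields are quoted: free-text columns (e.g. classification
  # rationale) may contain the delimiter
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Validate episode records against the schema invariants
#'
#' Checks, per row: CRP values (when present) are non-negative; observed
#' antibiotic length of therapy (LOT) is non-negative; a course continued
#' for >= 5 days implies LOT >= 5; a negative culture has zero positive
#' bottles and vice versa; paired cultures imply >= 2 positive bottles.
#' Violations are data, not errors.
#'
#' @param episodes episode `data.frame`.
#' @return a `data.frame` with columns `row`, `episode_id`, `field`,
#'   `message`; zero rows means every record is valid. The result carries
#'   attribute `ok` (logical).
#' @export
validate_episodes <- function(episodes) {
  stopifnot(is.data.frame(episodes))
  v <- list()
  add <- function(rows, field, message) {
    if (length(rows)) {
      v[[length(v) + 1L]] <<- data.frame(
        row = rows,
        episode_id = as.character(episodes$episode_id[rows]),
        field = field, message = message, stringsAsFactors = FALSE)
    }
  }
  num_nonneg <- function(col) {
    if (col %in% names(episodes))
      add(which(!is.na(episodes[[col]]) & episodes[[col]] < 0),
          col, paste0(col, " must be >= 0"))
  }
  for (col in c("crp_t0", "crp_t24", "lab_crp", "observed_lot_days",
                "postnatal_age_days", "n_positive_cultures")) num_nonneg(col)
  add(which(episodes$antibiotics_continued_ge_5d %in% TRUE &
              episodes$observed_lot_days < 5),
      "antibiotics_continued_ge_5d",
      "course continued >= 5 days but observed_lot_days < 5")
  add(which(episodes$organism_class == "negative" &
              episodes$n_positive_cultures != 0),
      "n_positive_cultures",
      "negative culture must have n_positive_cultures = 0")
  add(which(episodes$organism_class != "negative" &
              episodes$n_positive_cultures == 0),
      "n_positive_cultures",
      "non-negative culture class requires n_positive_cultures >= 1")
  add(which(episodes$paired_cultures_24_48h_apart %in% TRUE &
              episodes$n_positive_cultures < 2),
      "paired_cultures_24_48h_apart",
      "paired positive cultures imply n_positive_cultures >= 2")
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(row = integer(), episode_id = character(),
               field = character(), message = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$row), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ok") <- nrow(out) == 0L
  out
}

#' Validate a single episode record
#'
#' @param record a one-row `data.frame` or a named list coercible to one.
#' @return as [validate_episodes()], for the single record.
#' @export
validate_episode <- function(record) {
  if (!is.data.frame(record)) record <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(record) == 1L)
  validate_episodes(record)
}

#' Export a validation report as JSON
#'
#' @param report result of [validate_episodes()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
validation_report_json <- function(report, path = NULL) {
  obj <- list(ok = isTRUE(attr(report, "ok")),
              n_violations = nrow(report),
              violations = report)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
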