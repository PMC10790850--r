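EVENT_CATEGORIES <- c("alarm", "beep", "irrelevant1", "irrelevant2", "instruction")
CONDITIONS <- c("narrow", "wide")

#' Event tables
#'
#' An event table is a data.frame with one row per discrete stimulus, with
#' columns `onset_s` (seconds from recording start, non-decreasing),
#' `category` (alarm / beep / irrelevant1 / irrelevant2 / instruction),
#' `condition` (narrow / wide, constant within a recording), `direction_deg`
#' (azimuth), `overlap` (TRUE when the event is co-onset with another
#' stimulus), `is_target` (alarm in narrow, beep in wide), and the optional
#' response columns `response_onset_s` and `is_hit`.
#'
#' `validate_events()` checks the invariants and the target rule and returns
#' the table invisibly.
#'
#' @param events data.frame.
#' @export
validate_events <- function(events) {
  req <- c("onset_s", "category", "condition", "direction_deg",
           "overlap", "is_target")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop_fmt("event table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(events) == 0) return(invisible(events))
  if (!is.numeric(events$onset_s))
    stop_fmt("event onsets must be numeric")
  if (is.unsorted(events$onset_s))
    stop_fmt("event onsets must be non-decreasing")
  if (length(unique(events$condition)) > 1)
    stop_fmt("condition must be constant within one recording")
  bad_cat <- setdiff(unique(events$category), EVENT_CATEGORIES)
  if (length(bad_cat))
    stop_fmt("unknown stimulus category: %s", paste(bad_cat, collapse = ", "))
  expect_target <- (events$category == "alarm" & events$condition == "narrow") |
    (events$category == "beep" & events$condition == "wide")
  if (!identical(as.logical(events$is_target), expect_target))
    stop_fmt("is_target must hold exactly for the condition's target category")
  invisible(events)
}

#' Read / write event tables as TSV
#'
#' Required columns are validated; unknown columns are preserved untouched.
#' Booleans are written as TRUE/FALSE and read case-insensitively.
#'
#' @param path TSV path.
#' @return `read_event_table` returns a validated event data.frame.
#' @export
read_event_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "n/a", ""))
  events <- as.data.frame(dt)
  req <- c("onset_s", "category", "condition", "direction_deg",
           "overlap", "is_target")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop_fmt("event file '%s' is missing column(s): %s", path,
             paste(miss, collapse = ", "))
  if (nrow(events)) {
    suppressWarnings(on <- as.numeric(events$onset_s))
    if (anyNA(on) & !anyNA(events$onset_s))
      stop_fmt("non-numeric onset at row %d", which(is.na(on))[1])
    events$onset_s <- on
    for (cc in c("overlap", "is_target", "is_hit"))
      if (cc %in% names(events) && !is.logical(events[[cc]]))
        events[[cc]] <- toupper(as.character(events[[cc]])) %in% c("TRUE", "1", "T")
  }
  validate_events(events)
  events
}

#' @rdname read_event_table
#' @param events event data.frame.
#' @export
write_event_table <- function(events, path) {
  validate_events(events)
  data.table::fwrite(data.table::as.data.table(events), path, sep = "\t")
  invisible(path)
}

# Empty event table skeleton.
empty_events <- function() {
  data.frame(onset_s = numeric(0), category = character(0),
             condition = character(0), direction_deg = numeric(0),
             overlap = logical(0), is_target = logical(0),
             response_onset_s = numeric(0), is_hit = logical(0),
             stringsAsFactors = FALSE)
}
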