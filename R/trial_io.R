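# Trial-table I/O and validation.
#
# CSV schema (exact header):
#   subject,experiment,block,trial,prospective,stimulus,response,correct,awareness,confidence

trial_csv_columns <- c("subject", "experiment", "block", "trial", "prospective",
                       "stimulus", "response", "correct", "awareness",
                       "confidence")

#' Coerce and validate a trial table
#'
#' Checks the schema, coerces column types, recomputes the correctness
#' invariant (`correct == (response == stimulus)`), verifies that binary
#' columns are 0/1, that every table carries a single experiment label, and
#' that `(block, trial)` pairs are unique within subject; rows are sorted by
#' `(subject, block, trial)`.
#'
#' @param x a data frame with the trial-table columns.
#' @return a `trial_table` (a tibble with an extra S3 class).
#' @export
as_trial_table <- function(x) {
  if (inherits(x, "trial_table")) return(x)
  x <- tibble::as_tibble(x)
  missing <- setdiff(trial_csv_columns, names(x))
  if (length(missing) > 0)
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- x[trial_csv_columns]
  x$subject <- as.character(x$subject)
  x$experiment <- as.character(x$experiment)
  x$block <- as.integer(x$block)
  x$trial <- as.integer(x$trial)
  for (col in c("prospective", "correct", "awareness", "confidence")) {
    v <- x[[col]]
    if (!all(v %in% c(0, 1)))
      stop(sprintf("column '%s' must be binary 0/1 (row %d)",
                   col, which(!v %in% c(0, 1))[1]), call. = FALSE)
    x[[col]] <- as.integer(v)
  }
  for (col in c("stimulus", "response")) {
    if (!all(x[[col]] %in% c("left", "right")))
      stop(sprintf("column '%s' must be 'left' or 'right' (row %d)",
                   col, which(!x[[col]] %in% c("left", "right"))[1]),
           call. = FALSE)
  }
  bad <- which(x$correct != as.integer(x$response == x$stimulus))
  if (length(bad) > 0)
    stop(sprintf("correctness invariant violated at row %d: correct=%d but response %s stimulus",
                 bad[1], x$correct[bad[1]],
                 if (x$response[bad[1]] == x$stimulus[bad[1]]) "==" else "!="),
         call. = FALSE)
  if (dplyr::n_distinct(x$experiment) > 1)
    stop("a trial table must carry a single experiment label; found: ",
         paste(unique(x$experiment), collapse = ", "), call. = FALSE)
  x <- dplyr::arrange(x, .data$subject, .data$block, .data$trial)
  dup <- duplicated(x[c("subject", "block", "trial")])
  if (any(dup))
    stop(sprintf("duplicate (subject, block, trial) at row %d", which(dup)[1]),
         call. = FALSE)
  class(x) <- c("trial_table", class(x))
  x
}

# string dialects accepted on read, per binary column
.binary_dialects <- list(
  prospective = c(low = 0, high = 1),
  awareness = c(unaware = 0, aware = 1, low = 0, high = 1),
  confidence = c(low = 0, high = 1),
  correct = c(incorrect = 0, correct = 1))

coerce_binary <- function(v, col) {
  out <- suppressWarnings(as.integer(v))
  chr <- is.na(out) & !is.na(v)
  if (any(chr)) {
    map <- .binary_dialects[[col]]
    key <- tolower(trimws(as.character(v[chr])))
    unknown <- which(!key %in% names(map))
    if (length(unknown) > 0)
      stop(sprintf("column '%s': cannot coerce value '%s' (row %d)",
                   col, v[chr][unknown[1]], which(chr)[unknown[1]]),
           call. = FALSE)
    out[chr] <- map[key]
  }
  out
}

#' Read a trial table from CSV
#'
#' Reads the canonical trial CSV schema. Binary columns accept either 0/1
#' or the enumerated string dialects (`low`/`high`, `unaware`/`aware`,
#' `incorrect`/`correct`); `stimulus` and `response` must be
#' `left`/`right`. Anything else is an error naming the column and row.
#' The returned table is fully validated (see [as_trial_table()]).
#'
#' @param path CSV file path.
#' @return a `trial_table`.
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(trial_csv_columns, names(raw))
  if (length(missing) > 0)
    stop("'", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("prospective", "correct", "awareness", "confidence"))
    raw[[col]] <- coerce_binary(raw[[col]], col)
  for (col in c("stimulus", "response"))
    raw[[col]] <- tolower(trimws(raw[[col]]))
  as_trial_table(raw)
}

#' Write a trial table to CSV
#'
#' Writes the canonical schema; [read_trials()] on the result reproduces
#' the table exactly.
#'
#' @param table a `trial_table` (or coercible data frame).
#' @param path output CSV path.
#' @export
write_trials <- function(table, path) {
  table <- as_trial_table(table)
  readr::write_csv(tibble::as_tibble(table)[trial_csv_columns], path,
                   progress = FALSE)
  invisible(path)
}

#' Apply participant-exclusion rules
#'
#' Flags subjects that could not be analysed in the original paradigm:
#' (a) any empty cell of the awareness x confidence 2 x 2 over the session
#' (such subjects lack whole response conditions), and (b) an awareness
#' rate below `p_aware_floor` (default 0.05, motivated by the exclusion of
#' an observer reporting only 3% aware trials).
#'
#' @param table a `trial_table`.
#' @param p_aware_floor minimum admissible P(aware) per subject.
#' @return a list of class `exclusion_report`: `retained` (trial table of
#'   retained subjects) and `report` (tibble: subject, empty_cells,
#'   p_aware, retained).
#' @export
validate_subjects <- function(table, p_aware_floor = 0.05) {
  table <- as_trial_table(table)
  report <- table |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      empty_cells = 4L - dplyr::n_distinct(paste(.data$awareness, .data$confidence)),
      p_aware = mean(.data$awareness),
      .groups = "drop") |>
    dplyr::mutate(retained = .data$empty_cells == 0L &
                    .data$p_aware >= p_aware_floor)
  retained <- table[table$subject %in% report$subject[report$retained], ]
  class(retained) <- class(table)
  structure(list(retained = retained, report = report,
                 p_aware_floor = p_aware_floor),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  n_excl <- sum(!x$report$retained)
  cat(sprintf("<exclusion_report> %d/%d subject(s) excluded (P(aware) floor %.2f)\n",
              n_excl, nrow(x$report), x$p_aware_floor))
  print(as.data.frame(x$report), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write an exclusion report as JSON
#'
#' @param report an `exclusion_report` from [validate_subjects()].
#' @param path output JSON path.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  out <- lapply(seq_len(nrow(report$report)), function(i) {
    r <- report$report[i, ]
    list(empty_cells = r$empty_cells, p_aware = r$p_aware,
         retained = r$retained)
  })
  names(out) <- report$report$subject
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
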