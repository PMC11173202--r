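#' Validate a cascade event log
#'
#' A cascade event log is a data frame with one reshare event per row and the
#' columns `piece_id` (information item), `user_id` (the resharing user),
#' `parent_id` (the user the content was reshared from; `NA` for roots) and
#' `timestamp` (non-negative numeric time). `validate_event_log()` checks the
#' structural invariants of such a log and returns it as a tibble:
#'
#' * `parent_id != user_id` for every event;
#' * at most one event per `(piece_id, user_id)` pair (a user reshares a given
#'   piece once);
#' * every non-root event's parent has an event for the same piece with a
#'   *strictly earlier* timestamp (ties are rejected);
#' * the earliest event of every piece is parentless.
#'
#' Several parentless events per piece are permitted: they arise legitimately
#' when events are subsampled ([subsample_events()]) or windowed
#' ([split_by_window()]), where a reshare whose parent event is unobserved (or
#' falls in an earlier window) becomes a local root.
#'
#' @param events A data frame of reshare events.
#' @return The validated log as a tibble (invisibly usable in pipes). Empty
#'   `parent_id` strings are normalised to `NA`.
#' @examples
#' log <- tibble::tibble(
#'   piece_id = c("p1", "p1", "p1"),
#'   user_id = c("u1", "u2", "u3"),
#'   parent_id = c(NA, "u1", "u1"),
#'   timestamp = c(0, 5, 7)
#' )
#' validate_event_log(log)
#' @export
validate_event_log <- function(events) {
  events <- tibble::as_tibble(events)
  required <- c("piece_id", "user_id", "parent_id", "timestamp")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("Event log is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  events <- events[required]
  if (nrow(events) == 0) {
    events$timestamp <- as.numeric(events$timestamp)
    return(events)
  }

  if (is.character(events$parent_id)) {
    events$parent_id[!is.na(events$parent_id) & events$parent_id == ""] <- NA
  }
  events$timestamp <- as.numeric(events$timestamp)

  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort(sprintf("Invalid event log: %s (row%s %s).", what,
                    if (length(rows) > 1) "s" else "",
                    paste(head(rows, 10L), collapse = ", ")))
    }
  }

  bad_rows(!is.finite(events$timestamp) | events$timestamp < 0,
           "timestamps must be finite, non-negative numbers")
  bad_rows(is.na(events$piece_id) | is.na(events$user_id),
           "piece_id and user_id must be present")
  bad_rows(!is.na(events$parent_id) & events$parent_id == events$user_id,
           "an event's parent_id equals its user_id")
  bad_rows(duplicated(events[c("piece_id", "user_id")]),
           "duplicate (piece_id, user_id) event")

  # Parent resolution: every non-root event needs an event for (piece, parent)
  # at a strictly earlier timestamp. (piece, user) pairs are unique, so the
  # join is at most one-to-one.
  kids <- events |>
    mutate(.row = dplyr::row_number()) |>
    filter(!is.na(.data$parent_id))
  if (nrow(kids) > 0) {
    parents <- events |>
      select("piece_id", .parent_user = "user_id", .parent_time = "timestamp")
    joined <- left_join(kids, parents,
                        by = c("piece_id", "parent_id" = ".parent_user"))
    orphan <- is.na(joined$.parent_time)
    if (any(orphan)) {
      abort(sprintf(
        "Invalid event log: parent event not found for row%s %s.",
        if (sum(orphan) > 1) "s" else "",
        paste(head(joined$.row[orphan], 10L), collapse = ", ")))
    }
    late <- joined$.parent_time >= joined$timestamp
    if (any(late)) {
      abort(sprintf(
        "Invalid event log: parent event not strictly earlier for row%s %s.",
        if (sum(late) > 1) "s" else "",
        paste(head(joined$.row[late], 10L), collapse = ", ")))
    }
  }

  # The earliest event of each piece must be parentless (implied by the parent
  # checks, but asserted directly for clear errors on pathological inputs).
  first_ev <- events |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$piece_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  bad_first <- !is.na(first_ev$parent_id)
  if (any(bad_first)) {
    abort(sprintf("Invalid event log: earliest event of piece %s has a parent.",
                  paste(head(first_ev$piece_id[bad_first], 10L), collapse = ", ")))
  }

  events
}

#' Read a cascade event log from TSV or JSON-lines
#'
#' The TSV dialect has a header line
#' `piece_id<TAB>user_id<TAB>parent_id<TAB>timestamp` with an empty
#' `parent_id` field for cascade roots. The JSON-lines dialect has one JSON
#' object per line with the same keys (`parent_id` may be `null` or absent for
#' roots). The parsed log is validated with [validate_event_log()]; violations
#' raise errors naming the offending rows.
#'
#' @param path Path to the log file.
#' @param format `"tsv"` (default) or `"jsonl"`.
#' @return A validated event-log tibble. An empty file yields an empty log.
#' @seealso [write_event_log()]
#' @export
read_event_log <- function(path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Event log file not found: %s", path))
  }
  empty <- tibble::tibble(piece_id = character(), user_id = character(),
                          parent_id = character(), timestamp = numeric())
  if (file.size(path) == 0) {
    return(empty)
  }
  if (format == "tsv") {
    events <- readr::read_tsv(
      path,
      col_types = readr::cols(
        piece_id = readr::col_character(),
        user_id = readr::col_character(),
        parent_id = readr::col_character(),
        timestamp = readr::col_double()
      ),
      na = c("", "NA"),
      progress = FALSE
    )
    probs <- readr::problems(events)
    if (nrow(probs) > 0) {
      abort(sprintf("Malformed event log %s: parse problem at line %d (%s).",
                    path, probs$row[1] + 1L, probs$expected[1]))
    }
  } else {
    con <- file(path, open = "r")
    on.exit(close(con), add = TRUE)
    events <- tibble::as_tibble(jsonlite::stream_in(con, verbose = FALSE))
    if (nrow(events) == 0) {
      return(empty)
    }
    if (!"parent_id" %in% names(events)) {
      events$parent_id <- NA_character_
    }
    events$parent_id <- as.character(events$parent_id)
    events$piece_id <- as.character(events$piece_id)
    events$user_id <- as.character(events$user_id)
  }
  validate_event_log(events)
}

#' Write a cascade event log to TSV or JSON-lines
#'
#' @param events An event-log data frame (validated before writing).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  events <- validate_event_log(events)
  if (format == "tsv") {
    readr::write_tsv(events, path, na = "", progress = FALSE)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con), add = TRUE)
    jsonlite::stream_out(as.data.frame(events), con, verbose = FALSE)
  }
  invisible(path)
}

# Per-piece summary used for past success and superspreader labels: the root
# is the user of the earliest parentless event; size counts all events
# including the root.
cascade_summary <- function(events) {
  events <- validate_event_log(events)
  if (nrow(events) == 0) {
    return(tibble::tibble(piece_id = character(), root_user = character(),
                          size = integer(), start_time = numeric()))
  }
  events |>
    group_by(.data$piece_id) |>
    summarise(
      root_user = {
        roots <- which(is.na(.data$parent_id))
        r <- roots[order(.data$timestamp[roots], .data$user_id[roots])][1L]
        .data$user_id[r]
      },
      size = dplyr::n(),
      start_time = min(.data$timestamp),
      .groups = "drop"
    )
}
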