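#' Split a cascade log into consecutive time windows
#'
#' Partitions the events by timestamp into the consecutive non-overlapping
#' periods defined by strictly increasing cut-points: window 1 is
#' `timestamp <= boundaries[1]`, window k is
#' `boundaries[k-1] < timestamp <= boundaries[k]`, and the last window is
#' everything after the final boundary. A reshare whose parent event falls in
#' an earlier window becomes a window-local root (its `parent_id` is cleared),
#' so every window is a self-contained, valid log. The concatenation of the
#' window logs recovers the original event multiset (with cleared parents on
#' cross-window events).
#'
#' @param events An event-log data frame.
#' @param boundaries Strictly increasing numeric cut-points; `K` boundaries
#'   produce `K + 1` windows.
#' @return A list of validated event-log tibbles, one per window.
#' @export
split_by_window <- function(events, boundaries) {
  events <- validate_event_log(events)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) == 0 || any(!is.finite(boundaries)) ||
      is.unsorted(boundaries, strictly = TRUE)) {
    abort("`boundaries` must be a strictly increasing numeric vector.")
  }
  win <- findInterval(events$timestamp, boundaries,
                      left.open = TRUE) + 1L
  n_windows <- length(boundaries) + 1L
  lapply(seq_len(n_windows), function(k) {
    w <- events[win == k, , drop = FALSE]
    clear_dangling_parents(w)
  })
}

# Clear parent_id on events whose parent event is absent from this log, then
# revalidate. Used by windowing and subsampling.
clear_dangling_parents <- function(events) {
  if (nrow(events) > 0) {
    key <- paste(events$piece_id, events$user_id, sep = "\r")
    parent_key <- paste(events$piece_id, events$parent_id, sep = "\r")
    dangling <- !is.na(events$parent_id) & !(parent_key %in% key)
    events$parent_id[dangling] <- NA
  }
  validate_event_log(events)
}

#' Randomly subsample reshare events from a cascade log
#'
#' Emulates incomplete observation of spreading events: every non-root event
#' is kept independently with probability `keep_fraction`; root events are
#' always kept so no cascade disappears. Kept events whose parent event was
#' dropped are re-rooted (their `parent_id` is cleared), leaving a consistent
#' log.
#'
#' @param events An event-log data frame.
#' @param keep_fraction Probability in (0, 1] of keeping each non-root event.
#' @param seed Optional integer seed for reproducible subsampling.
#' @return A validated event-log tibble.
#' @export
subsample_events <- function(events, keep_fraction, seed = NULL) {
  events <- validate_event_log(events)
  stopifnot_scalar_prob(keep_fraction, "keep_fraction", open_left = TRUE)
  if (keep_fraction == 1 || nrow(events) == 0) {
    return(events)
  }
  with_seed_if(seed, {
    non_root <- !is.na(events$parent_id)
    drop <- non_root & (runif(nrow(events)) >= keep_fraction)
    clear_dangling_parents(events[!drop, , drop = FALSE])
  })
}
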