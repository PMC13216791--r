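#' @title Zone-entry event engine
#' @description Per-track hysteresis state machine converting frame-level
#'   containment flags into de-duplicated entry events. An entry is counted
#'   only after a person has been consistently tracked moving from outside
#'   the zone to inside; detection flicker inside the zone produces no
#'   additional counts. A legacy mode reproduces the naive behaviour
#'   (no track persistence, no debouncing) whose double counting motivated
#'   the fix.
#' @name event-engine
NULL

#' Event-engine configuration
#'
#' Debounce windows, in frames. `confirm_in_frames` consecutive contained
#' frames are required to confirm an entry; `confirm_out_frames`
#' consecutive non-contained frames confirm an exit and re-arm the entry
#' detector. Defaults (3 and 15 at 30 fps: 0.1 s in, 0.5 s out) are sized
#' so a single-frame detector flicker neither triggers a spurious entry
#' nor re-arms the machine inside the zone.
#'
#' @param confirm_in_frames integer >= 1.
#' @param confirm_out_frames integer >= 1.
#' @return a list of class `event_config`.
#' @export
event_config <- function(confirm_in_frames = 3, confirm_out_frames = 15) {
  stopifnot(confirm_in_frames >= 1, confirm_out_frames >= 1)
  structure(list(confirm_in_frames = as.integer(confirm_in_frames),
                 confirm_out_frames = as.integer(confirm_out_frames)),
            class = "event_config")
}

#' Fresh zone state for a track
#'
#' State starts `UNKNOWN`: a person first seen inside the zone resolves to
#' `INSIDE` without an entry event, because an entry requires having
#' previously been seen outside. Legacy mode instead starts tracks at
#' `OUTSIDE`, replicating implementations that assume a default
#' prior-outside state — the root of the double-counting failure when
#' occlusion respawns a track mid-zone.
#'
#' @param initial one of `"UNKNOWN"`, `"OUTSIDE"`, `"INSIDE"`.
#' @return a list of class `zone_state`.
#' @export
new_zone_state <- function(initial = c("UNKNOWN", "OUTSIDE", "INSIDE")) {
  initial <- match.arg(initial)
  structure(list(state = initial, run_flag = NA, run_length = 0L,
                 run_start_frame = NA_integer_, run_start_t = NA_real_,
                 last_frame = -Inf),
            class = "zone_state")
}

#' Advance a track's zone state by one frame
#'
#' Semantics: `UNKNOWN` resolves to `OUTSIDE` after `confirm_out_frames`
#' consecutive non-contained frames, or to `INSIDE` after
#' `confirm_in_frames` contained frames (no event — first seen inside is
#' never an entry). `OUTSIDE` transitions to `INSIDE` after
#' `confirm_in_frames` contained frames, emitting exactly one entry event
#' timestamped at the *first* frame of the contained run (so reported
#' entry times are not delayed by debouncing). `INSIDE` returns to
#' `OUTSIDE` after `confirm_out_frames` clear frames, with no event.
#' Shorter runs change nothing.
#'
#' @param zs a [new_zone_state()].
#' @param contained logical: any monitored landmark inside the zone this
#'   frame.
#' @param frame_index current frame; must advance strictly per track.
#' @param config an [event_config()].
#' @param timestamp seconds for this frame (stored so events carry times).
#' @return list with `state` (updated `zone_state`) and `event` (`NULL`,
#'   or a list with `frame_index` and `timestamp` of the confirmed entry).
#' @export
update_zone_state <- function(zs, contained, frame_index, config,
                              timestamp = NA_real_) {
  stopifnot(inherits(zs, "zone_state"), is.logical(contained),
            length(contained) == 1L)
  if (frame_index <= zs$last_frame) {
    stop("frame regression for track: frame ", frame_index,
         " after frame ", zs$last_frame)
  }
  zs$last_frame <- frame_index
  if (is.na(zs$run_flag) || zs$run_flag != contained) {
    zs$run_flag <- contained
    zs$run_length <- 1L
    zs$run_start_frame <- as.integer(frame_index)
    zs$run_start_t <- timestamp
  } else {
    zs$run_length <- zs$run_length + 1L
  }
  event <- NULL
  if (zs$state == "UNKNOWN") {
    if (contained && zs$run_length >= config$confirm_in_frames) {
      zs$state <- "INSIDE"           # no event: never seen outside first
    } else if (!contained && zs$run_length >= config$confirm_out_frames) {
      zs$state <- "OUTSIDE"
    }
  } else if (zs$state == "OUTSIDE") {
    if (contained && zs$run_length >= config$confirm_in_frames) {
      zs$state <- "INSIDE"
      event <- list(frame_index = zs$run_start_frame,
                    timestamp = zs$run_start_t)
    }
  } else if (zs$state == "INSIDE") {
    if (!contained && zs$run_length >= config$confirm_out_frames) {
      zs$state <- "OUTSIDE"
    }
  }
  list(state = zs, event = event)
}

#' Count confirmed zone entries in a detection stream
#'
#' Full pipeline composition: per frame, detections are associated with
#' persistent tracks ([associate()]), each tracked detection is tested for
#' any-landmark containment ([landmarks_in_zone()]), and the track's zone
#' state machine ([update_zone_state()]) emits at most one entry event per
#' confirmed outside-to-inside transition. Deterministic given its inputs;
#' events are returned ordered by entry frame.
#'
#' With `legacy = TRUE` the engine reproduces the pre-fix behaviour:
#' tracks are retired after a single missed frame, confirmation windows
#' collapse to one frame, and a fresh track starts in state `OUTSIDE` —
#' so an occlusion gap mid-zone yields a spurious extra entry.
#'
#' @param stream a `detection_stream`.
#' @param zone a `zone_polygon`.
#' @param tracker_cfg a [tracker_config()].
#' @param event_cfg an [event_config()].
#' @param min_confidence keypoint confidence threshold for containment and
#'   centroids.
#' @param landmarks landmark names tested for containment.
#' @param legacy logical: disable track persistence and debouncing.
#' @return data frame of entry events with columns `zone_label`,
#'   `track_id`, `frame_index`, `timestamp_s`, ordered by `frame_index`.
#' @export
count_entries <- function(stream, zone, tracker_cfg = tracker_config(),
                          event_cfg = event_config(), min_confidence = 0.5,
                          landmarks = monitored_landmarks(), legacy = FALSE) {
  stopifnot(inherits(stream, "detection_stream"), inherits(zone, "zone_polygon"))
  if (legacy) {
    tracker_cfg <- tracker_config(gate_radius = tracker_cfg$gate_radius,
                                  max_missed_frames = 0)
    event_cfg <- event_config(1, 1)
  }
  initial_state <- if (legacy) "OUTSIDE" else "UNKNOWN"
  trk <- new_tracker(tracker_cfg)
  states <- list()
  events <- list()
  for (f in stream$frames) {
    res <- associate(trk, f$detections, f$frame, min_confidence = min_confidence)
    trk <- res$tracker
    asg <- res$assignments
    for (j in seq_len(nrow(asg))) {
      tid <- asg$track_id[j]
      if (is.na(tid)) next
      key <- as.character(tid)
      zs <- states[[key]]
      if (is.null(zs)) zs <- new_zone_state(initial_state)
      verdict <- landmarks_in_zone(f$detections[[j]], zone,
                                   min_confidence = min_confidence,
                                   landmarks = landmarks)
      upd <- update_zone_state(zs, verdict$contained, f$frame, event_cfg,
                               timestamp = f$t)
      states[[key]] <- upd$state
      if (!is.null(upd$event)) {
        events[[length(events) + 1L]] <-
          data.frame(zone_label = zone$label, track_id = tid,
                     frame_index = upd$event$frame_index,
                     timestamp_s = upd$event$timestamp)
      }
    }
    # drop state machines of retired tracks; their ids never return
    live <- as.character(active_tracks(trk))
    states <- states[names(states) %in% live]
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(zone_label = character(0), track_id = integer(0),
               frame_index = integer(0), timestamp_s = double(0))
  out[order(out$frame_index, out$track_id), , drop = FALSE]
}

#' Write an entry-event log as CSV
#'
#' Append-only audit log: one row per confirmed entry with columns
#' `zone_label`, `track_id`, `frame_index`, `timestamp_s`.
#'
#' @param events data frame from [count_entries()].
#' @param path output CSV path.
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read an entry-event log written by [write_event_log()]
#' @param path CSV path.
#' @export
read_event_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
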