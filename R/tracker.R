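#' @title Multi-person centroid tracking
#' @description Persistent per-person identities across frames, so the
#'   event engine can require a consistently tracked outside-to-inside
#'   trajectory before counting an entry. Association is globally greedy
#'   nearest-centroid with distance gating — the simplest mechanism that
#'   keeps an identity stable through short detection gaps.
#' @name tracker
NULL

#' Tracker configuration
#'
#' @param gate_radius maximum centroid distance (pixels) at which a
#'   detection may be associated with an existing track. Default 120 px at
#'   640x480, roughly one body width.
#' @param max_missed_frames frames a track may go unseen before it is
#'   retired. Default 15 (0.5 s at 30 fps), sized so occlusions shorter
#'   than half a second do not split a track.
#' @return a list of class `tracker_config`.
#' @export
tracker_config <- function(gate_radius = 120, max_missed_frames = 15) {
  stopifnot(gate_radius > 0, max_missed_frames >= 0)
  structure(list(gate_radius = as.double(gate_radius),
                 max_missed_frames = as.integer(max_missed_frames)),
            class = "tracker_config")
}

#' Create an empty tracker
#'
#' @param config a [tracker_config()].
#' @param history_limit per-track history rows retained (bounded for
#'   memory).
#' @return a `tracker` object holding the active/retired track set.
#' @export
new_tracker <- function(config = tracker_config(), history_limit = 256L) {
  structure(list(config = config, tracks = list(), next_id = 1L,
                 last_frame = -1L, history_limit = as.integer(history_limit)),
            class = "tracker")
}

#' Centroid of a pose detection
#'
#' Arithmetic mean of the coordinates of all keypoints at or above
#' `min_confidence`. A detection with no qualifying keypoint cannot be
#' tracked and raises an error of class `zonewatch_untrackable`; callers
#' that prefer to skip such detections should catch it (as
#' [count_entries()] does).
#'
#' @param detection a [pose_detection()].
#' @param min_confidence minimum keypoint confidence.
#' @return numeric `c(x, y)`.
#' @export
detection_centroid <- function(detection, min_confidence = 0.5) {
  kp <- detection$keypoints
  use <- kp$confidence >= min_confidence
  if (!any(use)) {
    stop(errorCondition(
      "untrackable detection: no keypoint at or above the confidence threshold",
      class = c("zonewatch_untrackable", "error", "condition")))
  }
  c(x = mean(kp$x[use]), y = mean(kp$y[use]))
}

#' Associate one frame of detections with existing tracks
#'
#' Globally greedy nearest-centroid assignment: all track–detection pairs
#' within `gate_radius` are sorted by distance and accepted greedily, each
#' track and each detection used at most once. Ties are broken by matching
#' upstream `provisional_id` (a hint only, never trusted as identity),
#' then by lower `track_id`, then lower detection index. Unmatched
#' detections spawn new tracks; unmatched tracks accrue `frames_since_seen`
#' and are retired once it exceeds `max_missed_frames`. Untrackable
#' detections (no qualifying keypoint) receive an `NA` assignment.
#'
#' @param tracker a `tracker` from [new_tracker()].
#' @param detections list of [pose_detection()]s, all from `frame_index`.
#' @param frame_index current frame; must exceed every previously
#'   processed frame (duplicate submission is an error).
#' @param min_confidence keypoint confidence threshold for centroids.
#' @return list with `tracker` (updated) and `assignments`, a data frame
#'   with one row per detection: `detection_index`, `track_id` (`NA` for
#'   untrackable), `new_track`, `cx`, `cy`.
#' @export
associate <- function(tracker, detections, frame_index, min_confidence = 0.5) {
  stopifnot(inherits(tracker, "tracker"))
  frame_index <- as.integer(frame_index)
  if (frame_index <= tracker$last_frame) {
    stop("frame ", frame_index, " submitted out of order (last processed: ",
         tracker$last_frame, ")")
  }
  cfg <- tracker$config
  nd <- length(detections)
  cent <- matrix(NA_real_, nrow = nd, ncol = 2)
  prov <- vector("list", nd)
  for (j in seq_len(nd)) {
    c_j <- tryCatch(detection_centroid(detections[[j]], min_confidence),
                    zonewatch_untrackable = function(e) NULL)
    if (!is.null(c_j)) cent[j, ] <- c_j
    prov[j] <- list(detections[[j]]$provisional_id)
  }
  active_ids <- names(tracker$tracks)[vapply(tracker$tracks, `[[`, TRUE, "active")]

  # candidate pairs within the gate, ordered by (distance, provisional-id
  # mismatch, track_id, detection index)
  pairs <- NULL
  if (length(active_ids) && nd) {
    tc <- do.call(rbind, lapply(tracker$tracks[active_ids], `[[`, "last_centroid"))
    for (j in which(!is.na(cent[, 1]))) {
      d <- sqrt((tc[, 1] - cent[j, 1])^2 + (tc[, 2] - cent[j, 2])^2)
      ok <- which(d <= cfg$gate_radius)
      if (length(ok)) {
        tids <- as.integer(active_ids[ok])
        prov_match <- vapply(active_ids[ok], function(id) {
          tp <- tracker$tracks[[id]]$provisional_id
          !is.null(tp) && !is.null(prov[[j]]) && identical(tp, prov[[j]])
        }, logical(1))
        pairs <- rbind(pairs, data.frame(track = active_ids[ok], det = j,
                                         dist = d[ok], tid = tids,
                                         prov = !prov_match))
      }
    }
  }
  assigned_track <- rep(NA_integer_, nd)
  used_tracks <- character(0)
  if (!is.null(pairs) && nrow(pairs)) {
    ord <- order(pairs$dist, pairs$prov, pairs$tid, pairs$det)
    for (k in ord) {
      tr <- pairs$track[k]; j <- pairs$det[k]
      if (tr %in% used_tracks || !is.na(assigned_track[j])) next
      used_tracks <- c(used_tracks, tr)
      assigned_track[j] <- pairs$tid[k]
    }
  }

  new_flag <- rep(FALSE, nd)
  for (j in seq_len(nd)) {
    if (is.na(cent[j, 1])) next
    if (is.na(assigned_track[j])) {
      id <- tracker$next_id
      tracker$next_id <- id + 1L
      tracker$tracks[[as.character(id)]] <-
        list(track_id = id, last_centroid = cent[j, ], frames_since_seen = 0L,
             active = TRUE, provisional_id = prov[[j]],
             history = data.frame(frame_index = frame_index,
                                  cx = cent[j, 1], cy = cent[j, 2]))
      assigned_track[j] <- id
      new_flag[j] <- TRUE
    } else {
      id <- as.character(assigned_track[j])
      tr <- tracker$tracks[[id]]
      tr$last_centroid <- cent[j, ]
      tr$frames_since_seen <- 0L
      tr$provisional_id <- prov[[j]]
      tr$history <- rbind(tr$history,
                          data.frame(frame_index = frame_index,
                                     cx = cent[j, 1], cy = cent[j, 2]))
      if (nrow(tr$history) > tracker$history_limit) {
        tr$history <- utils::tail(tr$history, tracker$history_limit)
      }
      tracker$tracks[[id]] <- tr
    }
  }
  # unmatched active tracks age; overdue ones are retired
  matched_ids <- as.character(assigned_track[!is.na(assigned_track)])
  for (id in setdiff(active_ids, matched_ids)) {
    tr <- tracker$tracks[[id]]
    tr$frames_since_seen <- tr$frames_since_seen + 1L
    if (tr$frames_since_seen > cfg$max_missed_frames) tr$active <- FALSE
    tracker$tracks[[id]] <- tr
  }
  tracker$last_frame <- frame_index
  list(tracker = tracker,
       assignments = data.frame(detection_index = seq_len(nd),
                                track_id = assigned_track,
                                new_track = new_flag,
                                cx = cent[, 1], cy = cent[, 2]))
}

#' Active track ids
#' @param tracker a `tracker`.
#' @return integer vector of active track ids.
#' @export
active_tracks <- function(tracker) {
  ids <- names(tracker$tracks)[vapply(tracker$tracks, `[[`, TRUE, "active")]
  as.integer(ids)
}
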