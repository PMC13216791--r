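#' @title Pose detection streams
#' @description Data model and line-delimited JSON I/O for per-frame pose
#'   detections — the contract a real pose detector adapter or the scene
#'   simulator must satisfy — plus face-redaction rectangle geometry.
#' @name pose-stream
NULL

.coco17 <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
             "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
             "left_wrist", "right_wrist", "left_hip", "right_hip",
             "left_knee", "right_knee", "left_ankle", "right_ankle")

.head_landmarks <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear")

#' Landmark vocabularies
#'
#' `coco_keypoints()` is the fixed 17-name COCO pose vocabulary every
#' detection must draw its landmark names from. `monitored_landmarks()` is
#' the subset used for zone containment by default: head (nose and ears),
#' wrists, hips and ankles — the anatomy most likely to breach a bedside
#' perimeter. Eyes, shoulders, elbows and knees may be present in a stream
#' but are ignored for containment unless explicitly requested.
#'
#' @return character vector of landmark names.
#' @export
coco_keypoints <- function() .coco17

#' @rdname coco_keypoints
#' @export
monitored_landmarks <- function() {
  c("nose", "left_ear", "right_ear", "left_wrist", "right_wrist",
    "left_hip", "right_hip", "left_ankle", "right_ankle")
}

#' Construct a single-person pose detection
#'
#' @param frame_index non-negative integer frame number.
#' @param timestamp seconds from stream start.
#' @param keypoints data frame with columns `name`, `x`, `y`, `confidence`;
#'   names must be unique and drawn from [coco_keypoints()], confidences in
#'   `[0, 1]`.
#' @param detection_confidence overall detection confidence in `[0, 1]`.
#' @param provisional_id optional upstream identifier (never trusted as a
#'   persistent identity; see [associate()]).
#' @return an object of class `pose_detection`.
#' @export
pose_detection <- function(frame_index, timestamp, keypoints,
                           detection_confidence = 1, provisional_id = NULL) {
  kp <- as.data.frame(keypoints)
  stopifnot(all(c("name", "x", "y", "confidence") %in% names(kp)))
  kp$name <- as.character(kp$name)
  bad <- setdiff(kp$name, .coco17)
  if (length(bad)) stop("unknown keypoint name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(kp$name)) stop("duplicate keypoint names within a detection")
  if (any(kp$confidence < 0 | kp$confidence > 1)) {
    stop("keypoint confidence outside [0, 1]")
  }
  if (nrow(kp) < 1L) stop("a pose detection needs at least one keypoint")
  structure(list(frame_index = as.integer(frame_index),
                 timestamp = as.double(timestamp),
                 keypoints = kp[, c("name", "x", "y", "confidence")],
                 detection_confidence = as.double(detection_confidence),
                 provisional_id = provisional_id),
            class = "pose_detection")
}

#' Construct a detection stream
#'
#' A stream is an ordered collection of frames; each frame holds zero or
#' more [pose_detection()]s. Frame indices must be strictly increasing.
#' Timestamps default to `frame_index / frame_rate` when absent.
#'
#' @param frames list of frame records, each a list with `frame` (integer
#'   index), `t` (seconds, optional) and `detections` (list of
#'   `pose_detection`).
#' @param frame_rate frames per second (> 0).
#' @param source_id free-text origin label.
#' @return an object of class `detection_stream`.
#' @export
detection_stream <- function(frames, frame_rate = 30, source_id = "sim") {
  stopifnot(frame_rate > 0)
  idx <- vapply(frames, function(f) as.integer(f$frame), integer(1))
  if (length(idx) > 1L && any(diff(idx) <= 0L)) {
    bad <- which(diff(idx) <= 0L)[1] + 1L
    stop("frame indices must be strictly increasing; violation at record ", bad)
  }
  frames <- lapply(frames, function(f) {
    if (is.null(f$t)) f$t <- f$frame / frame_rate
    f
  })
  structure(list(source_id = source_id, frame_rate = as.double(frame_rate),
                 frames = frames),
            class = "detection_stream")
}

#' @export
print.detection_stream <- function(x, ...) {
  nd <- sum(vapply(x$frames, function(f) length(f$detections), integer(1)))
  cat(sprintf("<detection_stream> '%s': %d frames at %g fps, %d detections\n",
              x$source_id, length(x$frames), x$frame_rate, nd))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream a `detection_stream`.
#' @export
n_frames <- function(stream) length(stream$frames)

#' Read a JSON-lines detection stream
#'
#' One UTF-8 JSON object per line, one object per frame:
#' `{"frame": int, "t": float, "detections": [{"id": ..., "conf": float,
#' "kp": {"name": [x, y, conf], ...}}]}`. Malformed lines, unknown keypoint
#' names and non-monotone frame indices are reported with their line
#' number. An empty file yields an empty stream, not an error.
#'
#' @param path file path.
#' @param frame_rate frames per second recorded with the stream.
#' @param source_id origin label for the returned stream.
#' @return a `detection_stream`.
#' @export
read_stream <- function(path, frame_rate = 30, source_id = basename(path)) {
  if (!file.exists(path)) stop("no such stream file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  frames <- vector("list", length(lines))
  last_frame <- -1L
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop("malformed JSON at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(obj$frame)) stop("missing 'frame' field at line ", i)
    fr <- as.integer(obj$frame)
    if (fr <= last_frame) {
      stop("non-monotone frame index at line ", i, ": frame ", fr,
           " after frame ", last_frame)
    }
    last_frame <- fr
    t <- if (is.null(obj$t)) fr / frame_rate else as.double(obj$t)
    dets <- lapply(obj$detections, function(d) {
      kp_names <- names(d$kp)
      bad <- setdiff(kp_names, .coco17)
      if (length(bad)) {
        stop("unknown keypoint name(s) at line ", i, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      mat <- do.call(rbind, lapply(d$kp, function(v) as.double(unlist(v))))
      kp <- data.frame(name = kp_names, x = mat[, 1], y = mat[, 2],
                       confidence = mat[, 3], stringsAsFactors = FALSE)
      pose_detection(fr, t, kp,
                     detection_confidence =
                       if (is.null(d$conf)) 1 else as.double(d$conf),
                     provisional_id = d$id)
    })
    frames[[i]] <- list(frame = fr, t = t, detections = dets)
  }
  detection_stream(frames, frame_rate = frame_rate, source_id = source_id)
}

#' Write a detection stream as JSON lines
#'
#' Inverse of [read_stream()]: coordinates and confidences are serialized
#' at full precision so `read_stream(write_stream(s))` reproduces `s`
#' exactly, including frames with zero detections.
#'
#' @param stream a `detection_stream`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "detection_stream"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (f in stream$frames) {
    dets <- lapply(f$detections, function(d) {
      kp <- d$keypoints
      kpl <- stats::setNames(
        lapply(seq_len(nrow(kp)), function(j) c(kp$x[j], kp$y[j], kp$confidence[j])),
        kp$name)
      out <- list(conf = d$detection_confidence, kp = kpl)
      if (!is.null(d$provisional_id)) out <- c(list(id = d$provisional_id), out)
      out
    })
    obj <- list(frame = f$frame, t = f$t, detections = dets)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                null = "null"), con)
  }
  invisible(path)
}

#' Face-redaction rectangle for one detection
#'
#' Computes the pixel rectangle an external blurring step should redact to
#' anonymize a person. The rectangle is the bounding box of the head
#' landmarks (nose, eyes, ears) at or above `min_confidence`, expanded by
#' `padding` pixels on all sides. Fail-safe: when no head landmark reaches
#' the threshold, the upper third of the person's full-keypoint bounding
#' box is returned instead (over-redaction is preferred to a missed face).
#' A degenerate (zero-width or zero-height) box is inflated to a 1-pixel
#' minimum.
#'
#' @param detection a [pose_detection()].
#' @param padding pixels added on every side of the head bounding box.
#' @param min_confidence minimum keypoint confidence for a head landmark to
#'   anchor the box.
#' @return named numeric vector `c(x_min, y_min, x_max, y_max)` with
#'   attribute `fallback` (`TRUE` when the upper-third rule was used).
#' @export
face_redaction_regions <- function(detection, padding = 10,
                                   min_confidence = 0.5) {
  stopifnot(inherits(detection, "pose_detection"))
  kp <- detection$keypoints
  head <- kp[kp$name %in% .head_landmarks & kp$confidence >= min_confidence, ]
  if (nrow(head) > 0L) {
    box <- c(min(head$x) - padding, min(head$y) - padding,
             max(head$x) + padding, max(head$y) + padding)
    fallback <- FALSE
  } else {
    box <- c(min(kp$x), min(kp$y), max(kp$x),
             min(kp$y) + (max(kp$y) - min(kp$y)) / 3)
    fallback <- TRUE
  }
  if (box[3] - box[1] < 1) {
    mid <- (box[1] + box[3]) / 2; box[1] <- mid - 0.5; box[3] <- mid + 0.5
  }
  if (box[4] - box[2] < 1) {
    mid <- (box[2] + box[4]) / 2; box[2] <- mid - 0.5; box[4] <- mid + 0.5
  }
  structure(stats::setNames(box, c("x_min", "y_min", "x_max", "y_max")),
            fallback = fallback)
}

#' Redaction regions for a whole stream, as a table
#'
#' @param stream a `detection_stream`.
#' @inheritParams face_redaction_regions
#' @return data frame with columns `frame_index`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, one row per detection, ready to be written as CSV
#'   for an external blurring step.
#' @export
redaction_table <- function(stream, padding = 10, min_confidence = 0.5) {
  rows <- list()
  for (f in stream$frames) {
    for (d in f$detections) {
      r <- face_redaction_regions(d, padding = padding,
                                  min_confidence = min_confidence)
      rows[[length(rows) + 1L]] <-
        data.frame(frame_index = f$frame, x_min = r[["x_min"]],
                   y_min = r[["y_min"]], x_max = r[["x_max"]],
                   y_max = r[["y_max"]])
    }
  }
  if (!length(rows)) {
    return(data.frame(frame_index = integer(0), x_min = double(0),
                      y_min = double(0), x_max = double(0), y_max = double(0)))
  }
  do.call(rbind, rows)
}
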