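#' @title Synthetic scene simulator
#' @description Generates detection streams with ground-truth entry labels,
#'   standing in for a ceiling camera plus pose detector so every pipeline
#'   stage is testable offline. Persons follow scripted waypoint
#'   trajectories; a fixed 17-keypoint body template (scaled per person to
#'   emulate body-size variation) is centred on the interpolated position;
#'   detector imperfection is modelled as per-keypoint dropout, Gaussian
#'   coordinate jitter and whole-person occlusion intervals. Gold entries
#'   are defined on the noiseless path and are therefore invariant to the
#'   noise model.
#' @name scene-simulator
NULL

# run code under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Room layout for simulation
#'
#' The monitored zone is the bed rectangle expanded outward by
#' `zone_margin` pixels on every side (the on-screen analogue of a 1-foot
#' perimeter around the bed), clipped to the image.
#'
#' @param image_size `c(width, height)` pixels.
#' @param bed_rectangle `c(x_min, y_min, x_max, y_max)` pixels, strictly
#'   inside the image.
#' @param zone_margin perimeter width in pixels; default 40 px at 640x480.
#' @return a list of class `room_layout`.
#' @export
room_layout <- function(image_size = c(640, 480),
                        bed_rectangle = c(220, 200, 420, 400),
                        zone_margin = 40) {
  b <- as.double(bed_rectangle)
  stopifnot(length(image_size) == 2L, length(b) == 4L,
            b[1] < b[3], b[2] < b[4], zone_margin >= 0)
  if (b[1] <= 0 || b[2] <= 0 || b[3] >= image_size[1] || b[4] >= image_size[2]) {
    stop("bed rectangle must lie strictly inside the image")
  }
  structure(list(image_size = as.double(image_size), bed_rectangle = b,
                 zone_margin = as.double(zone_margin)),
            class = "room_layout")
}

#' Zone polygon implied by a room layout
#'
#' @param layout a [room_layout()].
#' @param label zone label.
#' @return a `zone_polygon`: the bed expanded by the margin, clipped to
#'   the image.
#' @export
zone_from_layout <- function(layout, label = "red zone") {
  b <- layout$bed_rectangle; m <- layout$zone_margin
  x0 <- max(0, b[1] - m); y0 <- max(0, b[2] - m)
  x1 <- min(layout$image_size[1], b[3] + m)
  y1 <- min(layout$image_size[2], b[4] + m)
  zone_from_corners(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
                    label = label)
}

#' Scripted person trajectory
#'
#' Piecewise-linear path through waypoints; the person holds the first
#' waypoint before its time and the last after it. `scale` multiplies the
#' body template to emulate differences in body size (typical range
#' 0.8-1.2).
#'
#' @param person_id integer identity (carried into the stream as the
#'   detection's provisional id and into gold labels).
#' @param waypoints data frame with columns `time_s`, `x`, `y`; times
#'   strictly increasing.
#' @param scale body-template scale factor.
#' @return a list of class `trajectory_script`.
#' @export
trajectory_script <- function(person_id, waypoints, scale = 1) {
  w <- as.data.frame(waypoints)
  stopifnot(all(c("time_s", "x", "y") %in% names(w)), nrow(w) >= 1L,
            scale > 0)
  if (nrow(w) > 1L && any(diff(w$time_s) <= 0)) {
    stop("waypoint times must be strictly increasing")
  }
  structure(list(person_id = as.integer(person_id),
                 waypoints = w[, c("time_s", "x", "y")],
                 scale = as.double(scale)),
            class = "trajectory_script")
}

#' Detector noise model
#'
#' @param keypoint_jitter_sd Gaussian jitter standard deviation, pixels,
#'   applied independently per coordinate.
#' @param dropout_prob probability a keypoint is missing in a frame;
#'   either a scalar or a named vector over [coco_keypoints()] (names
#'   absent from the vector fall back to 0), so distal landmarks can drop
#'   more often than proximal ones.
#' @param occlusion_intervals data frame with columns `start_s`, `end_s`,
#'   `person_id`; during `[start_s, end_s)` the person emits no detections
#'   at all (full occlusion, the track-splitting failure mode).
#' @param confidence_range `c(low, high)` uniform range for simulated
#'   keypoint confidences.
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   streams.
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(keypoint_jitter_sd = 0, dropout_prob = 0,
                        occlusion_intervals = NULL,
                        confidence_range = c(0.6, 0.95), seed = 1) {
  if (!is.null(occlusion_intervals)) {
    oi <- as.data.frame(occlusion_intervals)
    stopifnot(all(c("start_s", "end_s", "person_id") %in% names(oi)),
              all(oi$start_s < oi$end_s))
  } else {
    oi <- data.frame(start_s = double(0), end_s = double(0),
                     person_id = integer(0))
  }
  stopifnot(keypoint_jitter_sd >= 0, all(dropout_prob >= 0 & dropout_prob <= 1),
            length(confidence_range) == 2L,
            confidence_range[1] <= confidence_range[2])
  structure(list(keypoint_jitter_sd = as.double(keypoint_jitter_sd),
                 dropout_prob = dropout_prob,
                 occlusion_intervals = oi,
                 confidence_range = as.double(confidence_range),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Body keypoint template
#'
#' Fixed offsets (pixels) of the 17 COCO keypoints from the body centroid
#' for a nominal standing figure seen from a ceiling camera at the foot of
#' the bed; multiplied by `scale`. Orientation is fixed and limbs do not
#' articulate — sufficient because the engine consumes positions only.
#'
#' @param scale multiplicative size factor.
#' @return 17 x 2 matrix with rownames [coco_keypoints()].
#' @export
body_template <- function(scale = 1) {
  offs <- rbind(
    nose = c(0, -50), left_eye = c(-5, -55), right_eye = c(5, -55),
    left_ear = c(-10, -52), right_ear = c(10, -52),
    left_shoulder = c(-20, -30), right_shoulder = c(20, -30),
    left_elbow = c(-30, -10), right_elbow = c(30, -10),
    left_wrist = c(-38, 10), right_wrist = c(38, 10),
    left_hip = c(-12, 10), right_hip = c(12, 10),
    left_knee = c(-14, 40), right_knee = c(14, 40),
    left_ankle = c(-15, 70), right_ankle = c(15, 70))
  offs[.coco17, , drop = FALSE] * scale
}

# interpolated centre position of a script at times t (clamped at ends)
.script_position <- function(script, t) {
  w <- script$waypoints
  if (nrow(w) == 1L) {
    return(cbind(x = rep(w$x, length(t)), y = rep(w$y, length(t))))
  }
  cbind(x = stats::approx(w$time_s, w$x, xout = t, rule = 2)$y,
        y = stats::approx(w$time_s, w$y, xout = t, rule = 2)$y)
}

#' Simulate a scene
#'
#' Renders each scripted person frame by frame: the body template is
#' centred on the interpolated waypoint position, then (unless the person
#' is occluded) each keypoint is independently dropped with its dropout
#' probability and jittered with Gaussian noise; confidences are drawn
#' uniformly from the configured range. The random draw order is fixed
#' (frames, then persons in script order; dropout before jitter before
#' confidence) so a given seed reproduces the stream bit for bit.
#'
#' Gold entry events are computed from the *noiseless* template positions
#' with the same any-landmark containment rule the engine uses: an entry
#' is a frame where some monitored landmark is inside the zone after the
#' person was fully outside; a person already inside at the first frame is
#' not an entry.
#'
#' @param layout a [room_layout()].
#' @param scripts list of [trajectory_script()]s.
#' @param noise a [noise_model()].
#' @param frame_rate frames per second.
#' @param duration_s scene length, seconds.
#' @return list with `stream` (a `detection_stream`), `gold` (data frame
#'   `person_id`, `frame_index`, `entry_time_s`), and `zone` (the layout's
#'   `zone_polygon`).
#' @export
simulate_scene <- function(layout, scripts, noise = noise_model(),
                           frame_rate = 30, duration_s = 10) {
  stopifnot(inherits(layout, "room_layout"), frame_rate > 0, duration_s > 0)
  if (inherits(scripts, "trajectory_script")) scripts <- list(scripts)
  zone <- zone_from_layout(layout)
  W <- layout$image_size[1]; H <- layout$image_size[2]
  for (s in scripts) {
    w <- s$waypoints
    if (any(w$x < 0 | w$x > W | w$y < 0 | w$y > H)) {
      stop("waypoints outside the image for person ", s$person_id)
    }
  }
  nf <- as.integer(floor(duration_s * frame_rate)) + 1L
  times <- (seq_len(nf) - 1L) / frame_rate
  mon <- monitored_landmarks()

  # per-keypoint dropout probabilities
  dp <- noise$dropout_prob
  if (length(dp) == 1L && is.null(names(dp))) {
    dp <- stats::setNames(rep(as.double(dp), 17L), .coco17)
  } else {
    full <- stats::setNames(rep(0, 17L), .coco17)
    full[names(dp)] <- as.double(dp)
    dp <- full
  }

  # noiseless landmark positions and gold labels
  pos <- lapply(scripts, function(s) .script_position(s, times))
  gold <- list()
  for (k in seq_along(scripts)) {
    s <- scripts[[k]]
    tmpl <- body_template(s$scale)[mon, , drop = FALSE]
    inside <- vapply(seq_len(nf), function(i) {
      any(point_in_zone(pos[[k]][i, 1] + tmpl[, 1],
                        pos[[k]][i, 2] + tmpl[, 2], zone))
    }, logical(1))
    trans <- which(inside & !c(TRUE, inside[-nf]))  # first frame treated as no-entry
    for (fr in trans) {
      gold[[length(gold) + 1L]] <-
        data.frame(person_id = s$person_id, frame_index = fr - 1L,
                   entry_time_s = times[fr])
    }
  }
  gold <- if (length(gold)) do.call(rbind, gold) else
    data.frame(person_id = integer(0), frame_index = integer(0),
               entry_time_s = double(0))
  gold <- gold[order(gold$entry_time_s, gold$person_id), , drop = FALSE]

  occl <- noise$occlusion_intervals
  frames <- .with_seed(noise$seed, {
    lapply(seq_len(nf), function(i) {
      t <- times[i]
      dets <- list()
      for (k in seq_along(scripts)) {
        s <- scripts[[k]]
        hid <- any(occl$person_id == s$person_id &
                     occl$start_s <= t & t < occl$end_s)
        if (hid) next
        tmpl <- body_template(s$scale)
        keep <- stats::runif(17L) >= dp
        if (!any(keep)) next
        jx <- stats::rnorm(17L, 0, max(noise$keypoint_jitter_sd, 0))
        jy <- stats::rnorm(17L, 0, max(noise$keypoint_jitter_sd, 0))
        conf <- stats::runif(17L, noise$confidence_range[1],
                             noise$confidence_range[2])
        kp <- data.frame(name = .coco17,
                         x = pos[[k]][i, 1] + tmpl[, 1] + jx,
                         y = pos[[k]][i, 2] + tmpl[, 2] + jy,
                         confidence = conf)[keep, , drop = FALSE]
        dets[[length(dets) + 1L]] <-
          pose_detection(i - 1L, t, kp,
                         detection_confidence = mean(kp$confidence),
                         provisional_id = s$person_id)
      }
      list(frame = i - 1L, t = t, detections = dets)
    })
  })
  list(stream = detection_stream(frames, frame_rate = frame_rate,
                                 source_id = "simulated"),
       gold = gold, zone = zone)
}

#' Deterministic scenario battery
#'
#' A fixed set of six named scenes exercising the failure modes the
#' pipeline must handle: a plain enter-and-leave visit, a corridor
#' walk-past that never approaches the bed, a reach-in where only a wrist
#' breaches the perimeter, a head-of-bed approach with elevated dropout on
#' distal landmarks, two persons crossing paths outside the zone, and an
#' entry with a mid-zone occlusion gap that splits naive tracks. Body
#' scales vary across persons (0.8-1.2) to emulate body-size differences
#' (skin tone has no analogue in keypoint space and is not represented).
#'
#' @param layout a [room_layout()].
#' @param seed integer seed; scenario `k` uses `seed + k` so scenes are
#'   independent but jointly reproducible.
#' @param noiseless logical: strip jitter, dropout and occlusion from
#'   every scenario (ground-truth recovery conditions).
#' @param frame_rate frames per second.
#' @return named list of scenarios, each a list with `name`, `stream`,
#'   `gold`, `zone`.
#' @export
scenario_battery <- function(layout = room_layout(), seed = 1,
                             noiseless = FALSE, frame_rate = 30) {
  mk_noise <- function(k, jitter = 1.5, dropout = 0.02, occl = NULL) {
    if (noiseless) {
      noise_model(0, 0, NULL, seed = seed + k)
    } else {
      noise_model(jitter, dropout, occl, seed = seed + k)
    }
  }
  wp <- function(...) {
    m <- rbind(...)
    data.frame(time_s = m[, 1], x = m[, 2], y = m[, 3])
  }
  scenes <- list()

  scenes$enter_and_leave <- list(
    scripts = list(trajectory_script(1, wp(c(0, 60, 300), c(4, 320, 300),
                                           c(8, 60, 300)), scale = 1.0)),
    noise = mk_noise(1), duration_s = 8)

  scenes$walk_past <- list(
    scripts = list(trajectory_script(1, wp(c(0, 60, 60), c(8, 580, 60)),
                                     scale = 1.1)),
    noise = mk_noise(2), duration_s = 8)

  scenes$reach_in <- list(
    scripts = list(trajectory_script(1, wp(c(0, 60, 300), c(3, 145, 300),
                                           c(5, 145, 300), c(8, 60, 300)),
                                     scale = 1.0)),
    noise = mk_noise(3), duration_s = 8)

  scenes$head_of_bed <- list(
    scripts = list(trajectory_script(1, wp(c(0, 320, 40), c(5, 320, 230),
                                           c(7, 320, 230), c(10, 320, 40)),
                                     scale = 0.9)),
    noise = mk_noise(4, dropout = c(left_wrist = 0.5, right_wrist = 0.5,
                                    left_ankle = 0.5, right_ankle = 0.5)),
    duration_s = 10)

  scenes$two_person_cross <- list(
    scripts = list(
      trajectory_script(1, wp(c(0, 60, 60), c(8, 580, 60)), scale = 1.2),
      trajectory_script(2, wp(c(0, 580, 90), c(8, 60, 90)), scale = 0.8)),
    noise = mk_noise(5), duration_s = 8)

  scenes$occlusion_split <- list(
    scripts = list(trajectory_script(1, wp(c(0, 60, 300), c(3, 320, 300),
                                           c(7, 320, 300), c(10, 60, 300)),
                                     scale = 1.0)),
    noise = mk_noise(6, jitter = 0, dropout = 0,
                     occl = data.frame(start_s = 4.0, end_s = 4.3,
                                       person_id = 1)),
    duration_s = 10)

  lapply(stats::setNames(names(scenes), names(scenes)), function(nm) {
    sc <- scenes[[nm]]
    sim <- simulate_scene(layout, sc$scripts, sc$noise,
                          frame_rate = frame_rate,
                          duration_s = sc$duration_s)
    c(list(name = nm), sim)
  })
}

#' Write a simulated scene to disk
#'
#' Exports the stream in the standard JSON-lines format plus the gold
#' labels as CSV (`person_id`, `frame_index`, `entry_time_s`).
#'
#' @param scene a scenario from [simulate_scene()] or [scenario_battery()].
#' @param stream_path,gold_path output paths.
#' @export
write_scene <- function(scene, stream_path, gold_path) {
  write_stream(scene$stream, stream_path)
  utils::write.csv(scene$gold, gold_path, row.names = FALSE)
  invisible(c(stream_path, gold_path))
}
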