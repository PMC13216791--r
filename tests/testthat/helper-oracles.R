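# Independent oracles, kept deliberately separate from the package
# implementation: containment is checked against a winding-number
# formulation (the package uses even-odd ray casting), and greedy track
# association against exhaustive minimum-total-distance assignment.

# winding-number point-in-polygon, vectorized over points; boundary
# points (distance <= tol from an edge) count as inside, matching the
# package's inclusive rule
winding_in_polygon <- function(px, py, v, tol = 1e-9) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  wn <- integer(length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[nxt[i], 1]; y2 <- v[nxt[i], 2]
    dx <- x2 - x1; dy <- y2 - y1
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / (dx * dx + dy * dy)))
    on_edge <- on_edge | ((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2) <= tol^2
    cross <- dx * (py - y1) - (px - x1) * dy
    up <- (y1 <= py) & (y2 > py) & (cross > 0)
    dn <- (y1 > py) & (y2 <= py) & (cross < 0)
    wn <- wn + up - dn
  }
  (wn != 0L) | on_edge
}

# star-shaped (often concave) simple polygon around a centre: vertices at
# sorted angles with varying radii. Simplicity is guaranteed by keeping
# every angular gap below pi: each edge then lies in its own convex wedge,
# and distinct wedges share only the apex, so edges cannot cross.
random_simple_polygon <- function(n_vertices, cx = 0, cy = 0) {
  repeat {
    gaps <- stats::runif(n_vertices)
    gaps <- 2 * pi * gaps / sum(gaps)
    if (max(gaps) < 0.95 * pi) break
  }
  ang <- cumsum(gaps) + stats::runif(1, 0, 2 * pi)
  rad <- stats::runif(n_vertices, 2, 10)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

l_shaped_zone <- function() {
  zone_polygon(rbind(c(0, 0), c(6, 0), c(6, 2), c(2, 2), c(2, 6), c(0, 6)),
               label = "L")
}

# exhaustive minimum-total-distance assignment of detections to tracks
# (all injections of the smaller set into the larger)
brute_force_assignment <- function(track_pts, det_pts) {
  nt <- nrow(track_pts); nd <- nrow(det_pts)
  dist <- outer(seq_len(nt), seq_len(nd), function(i, j) {
    sqrt((track_pts[i, 1] - det_pts[j, 1])^2 +
           (track_pts[i, 2] - det_pts[j, 2])^2)
  })
  k <- min(nt, nd)
  best <- NULL; best_cost <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  track_subsets <- utils::combn(nt, k, simplify = FALSE)
  det_perms <- perms(seq_len(nd))
  for (ts in track_subsets) {
    for (dp in det_perms) {
      dsel <- dp[seq_len(k)]
      cost <- sum(dist[cbind(ts, dsel)])
      if (cost < best_cost) {
        best_cost <- cost
        best <- cbind(track = ts, det = dsel)
      }
    }
  }
  best[order(best[, "det"]), , drop = FALSE]
}

# minimal keypoint table: one named landmark at (x, y)
kp1 <- function(name, x, y, conf = 0.9) {
  data.frame(name = name, x = x, y = y, confidence = conf)
}

# full-body detection centred at (cx, cy) using the package template
body_detection <- function(frame, t, cx, cy, scale = 1, conf = 0.9) {
  tmpl <- body_template(scale)
  pose_detection(frame, t,
                 data.frame(name = rownames(tmpl), x = cx + tmpl[, 1],
                            y = cy + tmpl[, 2], confidence = conf))
}

unit_rect_zone <- function() {
  zone_from_corners(rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))
}
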