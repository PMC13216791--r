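#' @title Red-zone polygon geometry
#' @description Construction and validation of the monitored zone polygon,
#'   and the geometric containment test deciding whether a pose landmark
#'   falls inside it.
#' @name zone-geometry
NULL

# absolute distance (pixels) at which a point counts as lying on an edge
.boundary_tol <- 1e-9

#' Create a validated zone polygon
#'
#' A zone is an ordered list of vertices in image pixel coordinates
#' (origin top-left, y increasing downward). The polygon must be simple
#' (non-self-intersecting), have at least three vertices, no two identical
#' consecutive vertices, and non-zero area. Either winding order is
#' accepted and vertices are stored in construction order.
#'
#' @param vertices two-column numeric matrix or data frame of (x, y) pixel
#'   coordinates, one row per vertex, in drawing order.
#' @param label free-text label for the zone (default `"red zone"`).
#' @return an object of class `zone_polygon` with elements `vertices`
#'   (n x 2 matrix) and `label`.
#' @examples
#' z <- zone_polygon(rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))
#' point_in_zone(5, 2.5, z)
#' @export
zone_polygon <- function(vertices, label = "red zone") {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    stop("vertices must be a two-column numeric matrix of (x, y) coordinates")
  }
  storage.mode(v) <- "double"
  n <- nrow(v)
  if (n < 3L) stop("a zone polygon needs at least 3 vertices, got ", n)
  if (any(!is.finite(v))) {
    bad <- which(rowSums(!is.finite(v)) > 0)
    stop("non-finite vertex coordinates at position(s) ",
         paste(bad, collapse = ", "))
  }
  nxt <- c(2:n, 1L)
  dup <- which(v[, 1] == v[nxt, 1] & v[, 2] == v[nxt, 2])
  if (length(dup)) {
    stop("degenerate zone: consecutive duplicate vertices at position(s) ",
         paste(dup, collapse = ", "))
  }
  # all vertices on one line is degenerate (a bowtie also has zero signed
  # area, so collinearity is tested directly and crossings separately)
  cr <- (v[2, 1] - v[1, 1]) * (v[, 2] - v[1, 2]) -
    (v[2, 2] - v[1, 2]) * (v[, 1] - v[1, 1])
  if (all(abs(cr) < 1e-9)) {
    stop("degenerate zone: vertices are collinear (zero area), vertices ",
         paste(seq_len(n), collapse = ", "))
  }
  cross <- .self_intersections(v)
  if (nrow(cross)) {
    stop("self-intersecting zone polygon: edge from vertex ", cross[1, 1],
         " crosses edge from vertex ", cross[1, 2],
         "; reorder the corner points")
  }
  structure(list(vertices = v, label = as.character(label)[1]),
            class = "zone_polygon")
}

#' @export
print.zone_polygon <- function(x, ...) {
  cat(sprintf("<zone_polygon> '%s', %d vertices\n", x$label, nrow(x$vertices)))
  print(x$vertices)
  invisible(x)
}

# non-adjacent edge pairs that properly cross, as a matrix of index pairs
.self_intersections <- function(v) {
  n <- nrow(v)
  bad <- matrix(integer(0), ncol = 2)
  if (n <= 3L) return(bad)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (share a vertex); for i == 1 also skip the last edge
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (.segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        bad <- rbind(bad, c(i, j))
      }
    }
  }
  bad
}

# proper or improper crossing of segments ab and cd (shared endpoints
# between adjacent edges are excluded by the caller)
.segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r) {
    val <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    if (abs(val) < 1e-12) 0 else sign(val)
  }
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(p, q, r) {
    # r collinear with pq: does r lie within the bounding box of pq?
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
      min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  (o1 == 0 && on_seg(a, b, c)) || (o2 == 0 && on_seg(a, b, d)) ||
    (o3 == 0 && on_seg(c, d, a)) || (o4 == 0 && on_seg(c, d, b))
}

#' Build a zone from four manually selected corner points
#'
#' Mirrors the field workflow of clicking four points on the video feed to
#' outline the perimeter around a patient's bed. The corners are validated
#' as a simple quadrilateral; a "bowtie" ordering (crossing diagonals) or
#' collinear corners are rejected.
#'
#' @param corners 4 x 2 numeric matrix (or data frame) of pixel corners in
#'   drawing order.
#' @inheritParams zone_polygon
#' @return a `zone_polygon`.
#' @export
zone_from_corners <- function(corners, label = "red zone") {
  v <- as.matrix(corners)
  if (nrow(v) != 4L) stop("expected exactly 4 corner points, got ", nrow(v))
  zone_polygon(v, label = label)
}

#' Test whether points lie inside the zone
#'
#' Ray-casting (even-odd) containment with an explicit boundary test:
#' points on a polygon edge or vertex count as inside. The rationale is
#' operational — a hand exactly on the zone border is an exposure risk, so
#' the test errs toward detection. Vectorized over points.
#'
#' @param x,y numeric vectors of pixel coordinates (recycled to a common
#'   length).
#' @param zone a `zone_polygon`.
#' @return logical vector, `TRUE` where the point is inside or on the
#'   boundary.
#' @export
point_in_zone <- function(x, y, zone) {
  stopifnot(inherits(zone, "zone_polygon"))
  m <- max(length(x), length(y))
  x <- rep_len(as.double(x), m)
  y <- rep_len(as.double(y), m)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite point coordinates passed to point_in_zone")
  }
  v <- zone$vertices
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  inside <- rep(FALSE, m)
  on_edge <- rep(FALSE, m)
  for (i in seq_len(n)) {
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[nxt[i], 1]; y2 <- v[nxt[i], 2]
    # boundary: squared distance from point to segment within tolerance
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2))
    d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
    on_edge <- on_edge | d2 <= .boundary_tol^2
    # even-odd ray cast toward +x
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Decide whether any pose landmark falls inside the zone
#'
#' Implements the any-landmark entry criterion: the detection is contained
#' if at least one monitored landmark with confidence at or above
#' `min_confidence` lies inside the zone. Landmarks below the threshold are
#' ignored. When no monitored landmark reaches the threshold the verdict is
#' not-contained with an `insufficient` flag (never an error), so upstream
#' code can log the frame rather than crash.
#'
#' @param detection a [pose_detection()].
#' @param zone a `zone_polygon`.
#' @param min_confidence minimum keypoint confidence, in `[0, 1]`.
#' @param landmarks character vector of landmark names considered for
#'   containment; defaults to [monitored_landmarks()] (head, wrists, hips,
#'   ankles).
#' @return list with `contained` (logical scalar),
#'   `contained_landmark_names` (character), and `insufficient` (logical:
#'   no landmark reached the confidence threshold).
#' @export
landmarks_in_zone <- function(detection, zone, min_confidence = 0.5,
                              landmarks = monitored_landmarks()) {
  stopifnot(inherits(detection, "pose_detection"))
  kp <- detection$keypoints
  use <- kp$name %in% landmarks & kp$confidence >= min_confidence
  if (!any(use)) {
    return(list(contained = FALSE, contained_landmark_names = character(0),
                insufficient = TRUE))
  }
  hit <- point_in_zone(kp$x[use], kp$y[use], zone)
  list(contained = any(hit),
       contained_landmark_names = kp$name[use][hit],
       insufficient = FALSE)
}

#' Read or write a zone configuration file
#'
#' The zone config is a small JSON file with fields `label`, `vertices`
#' (list of `[x, y]` pairs) and `min_confidence`. Coordinates are written
#' at full precision so a read–write cycle is bit-exact.
#'
#' @param path file path.
#' @return `read_zone_config()` returns a list with `zone` (a
#'   `zone_polygon`) and `min_confidence`.
#' @export
read_zone_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  verts <- obj$vertices
  if (is.list(verts)) verts <- do.call(rbind, verts)
  list(zone = zone_polygon(verts, label = obj$label),
       min_confidence = as.double(obj$min_confidence))
}

#' @rdname read_zone_config
#' @param zone a `zone_polygon` to serialize.
#' @param min_confidence keypoint confidence threshold stored with the zone.
#' @export
write_zone_config <- function(zone, path, min_confidence = 0.5) {
  stopifnot(inherits(zone, "zone_polygon"))
  obj <- list(label = zone$label,
              vertices = unname(lapply(seq_len(nrow(zone$vertices)),
                                       function(i) zone$vertices[i, ])),
              min_confidence = min_confidence)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}
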