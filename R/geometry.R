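# Nuclear geometry: centroid series plus a boundary (ellipse or simple
# polygon), and the ray casting used by the normalized radial distance.

#' Ellipse boundary description
#'
#' @param center Length-2 numeric, ellipse center in micrometres.
#' @param a,b Semi-axes in micrometres (a along the rotated x axis).
#' @param theta Rotation of the major axis, radians counter-clockwise.
#' @return An object of class `nucleus_boundary` (type `"ellipse"`).
#' @export
ellipse_boundary <- function(center, a, b, theta = 0) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2L, is.finite(a), is.finite(b), a > 0, b > 0)
  structure(list(type = "ellipse", center = center, a = a, b = b,
                 theta = theta),
            class = "nucleus_boundary")
}

#' Polygon boundary description
#'
#' The polygon must be simple (no self-intersections) and is treated as
#' closed; a repeated final vertex is dropped.
#'
#' @param vertices An n x 2 matrix of vertices in micrometres, n >= 3.
#' @return An object of class `nucleus_boundary` (type `"polygon"`).
#' @export
polygon_boundary <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, all(is.finite(vertices)))
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1L, ] == vertices[n, ])) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  if (!polygon_is_simple(vertices)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  structure(list(type = "polygon", vertices = vertices),
            class = "nucleus_boundary")
}

#' Nuclear geometry record
#'
#' @param cell_id Cell identifier.
#' @param centroid Nuclear centroid: a length-2 vector (static) or an
#'   n x 2 matrix of per-frame centroids in micrometres.
#' @param boundary A [ellipse_boundary()] or [polygon_boundary()], or `NULL`
#'   when only motion calibration (no radiality) is needed.
#' @param centroid_frames Optional 0-based frame indices matching the rows of
#'   a per-frame centroid matrix; defaults to `0:(n-1)`.
#' @return Object of class `nucleus_geometry`.
#' @export
nucleus_geometry <- function(cell_id, centroid, boundary = NULL,
                             centroid_frames = NULL) {
  if (is.null(dim(centroid))) centroid <- matrix(centroid, nrow = 1L)
  centroid <- as.matrix(centroid)
  stopifnot(ncol(centroid) == 2L, all(is.finite(centroid)))
  if (is.null(centroid_frames)) centroid_frames <- seq_len(nrow(centroid)) - 1L
  stopifnot(length(centroid_frames) == nrow(centroid))
  if (!is.null(boundary)) {
    stopifnot(inherits(boundary, "nucleus_boundary"))
    for (i in seq_len(nrow(centroid))) {
      if (!point_in_boundary(centroid[i, ], boundary)) {
        stop(sprintf("centroid of cell %s (frame %d) lies outside the boundary",
                     cell_id, centroid_frames[i]), call. = FALSE)
      }
    }
  }
  structure(list(cell_id = as.character(cell_id),
                 centroid_series = centroid,
                 centroid_frames = as.integer(centroid_frames),
                 boundary = boundary),
            class = "nucleus_geometry")
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf("<nucleus_geometry> cell %s: %s boundary, %d centroid frame(s)\n",
              x$cell_id,
              if (is.null(x$boundary)) "no" else x$boundary$type,
              nrow(x$centroid_series)))
  invisible(x)
}

# -- low-level predicates ----------------------------------------------------

seg_intersect <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  denom <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(denom) < 1e-14) return(FALSE)  # parallel: treat as non-crossing
  t <- ((q1[1L] - p1[1L]) * d2[2L] - (q1[2L] - p1[2L]) * d2[1L]) / denom
  u <- ((q1[1L] - p1[1L]) * d1[2L] - (q1[2L] - p1[2L]) * d1[1L]) / denom
  t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  idx <- rbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap-around
      if (seg_intersect(v[idx[1L, i], ], v[idx[2L, i], ],
                        v[idx[1L, j], ], v[idx[2L, j], ])) return(FALSE)
    }
  }
  TRUE
}

point_in_polygon <- function(p, v) {
  # even-odd rule
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 2L]; yj <- v[j, 2L]
    if ((yi > p[2L]) != (yj > p[2L])) {
      xint <- v[i, 1L] + (p[2L] - yi) / (yj - yi) * (v[j, 1L] - v[i, 1L])
      if (p[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_in_boundary <- function(p, boundary, tol = 0) {
  if (boundary$type == "ellipse") {
    q <- rotate2(p - boundary$center, -boundary$theta)
    (q[1L] / boundary$a)^2 + (q[2L] / boundary$b)^2 <= 1 + tol
  } else {
    point_in_polygon(p, boundary$vertices)
  }
}

rotate2 <- function(p, theta) {
  c(cos(theta) * p[1L] - sin(theta) * p[2L],
    sin(theta) * p[1L] + cos(theta) * p[2L])
}

#' Distance from a point to the boundary along a ray
#'
#' Casts a ray from `origin` in direction `direction` and returns the
#' distance to the boundary. For a polygon the furthest intersection on the
#' ray is taken, so the returned length always spans the full nucleus even
#' for mildly non-convex outlines.
#'
#' @param boundary A `nucleus_boundary`.
#' @param origin Length-2 point inside the boundary (micrometres).
#' @param direction Length-2 direction vector (need not be normalized).
#' @return Distance in micrometres.
#' @export
ray_boundary_distance <- function(boundary, origin, direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero", call. = FALSE)
  u <- direction / nrm
  if (boundary$type == "ellipse") {
    # quadratic |M (origin + t u - center)|^2 = 1 with M = diag(1/a,1/b) R(-theta)
    o <- rotate2(origin - boundary$center, -boundary$theta) /
      c(boundary$a, boundary$b)
    d <- rotate2(u, -boundary$theta) / c(boundary$a, boundary$b)
    A <- sum(d^2); B <- 2 * sum(o * d); C <- sum(o^2) - 1
    disc <- B^2 - 4 * A * C
    if (disc < 0) stop("ray does not meet the ellipse (origin outside?)",
                       call. = FALSE)
    t <- (-B + sqrt(disc)) / (2 * A)
    if (t <= 0) stop("origin lies outside the ellipse", call. = FALSE)
    return(t)
  }
  v <- boundary$vertices
  n <- nrow(v)
  tmax <- -Inf
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    e <- b - a
    denom <- u[1L] * (-e[2L]) + u[2L] * e[1L]
    if (abs(denom) < 1e-14) next
    w <- a - origin
    t <- (w[1L] * (-e[2L]) + w[2L] * e[1L]) / denom
    s <- (u[1L] * w[2L] - u[2L] * w[1L]) / denom
    if (t > 0 && s >= -1e-12 && s <= 1 + 1e-12) tmax <- max(tmax, t)
  }
  if (!is.finite(tmax)) {
    stop("ray does not meet the polygon boundary (origin outside?)",
         call. = FALSE)
  }
  tmax
}
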