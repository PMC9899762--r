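#' Planar geometry primitives for annotation contours
#'
#' Annotations are stored in micrometre coordinates with y increasing
#' downward (image convention). A contour is an ordered vertex matrix of a
#' simple closed polygon (the closing edge last -> first is implicit); a
#' polyline is an ordered vertex matrix of an open path. Areas are computed
#' with the shoelace formula, so all derived statistics are exact polygon
#' quantities, not pixel counts.
#'
#' @name geometry
NULL

as_xy_matrix <- function(x, what = "contour") {
  if (is.data.frame(x)) x <- as.matrix(x[, c(1, 2)])
  if (!is.matrix(x) || ncol(x) != 2 || !is.numeric(x)) {
    stop(sprintf("a %s must be a numeric matrix with columns (x, y)", what),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s coordinates must be finite", what), call. = FALSE)
  }
  unname(x)
}

#' Create a closed contour
#'
#' @param xy numeric matrix or data frame with columns (x, y) in micrometres;
#'   vertices ordered along the boundary, closing edge implicit. A repeated
#'   final vertex equal to the first is dropped.
#' @param check_simple verify that the polygon does not self-intersect
#'   (O(n^2); disable for trusted generated contours).
#' @return the vertex matrix with class `"contour"`.
#' @export
contour <- function(xy, check_simple = TRUE) {
  xy <- as_xy_matrix(xy, "contour")
  n <- nrow(xy)
  if (n >= 2 && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3) stop("a contour needs at least 3 distinct vertices", call. = FALSE)
  if (abs(signed_area(xy)) <= 0) stop("contour encloses zero area", call. = FALSE)
  if (check_simple && !is_simple_polygon(xy)) {
    stop("contour is self-intersecting", call. = FALSE)
  }
  structure(xy, class = c("contour", "matrix", "array"))
}

#' Create an open polyline
#'
#' @param xy numeric matrix or data frame with columns (x, y) in micrometres.
#' @return the vertex matrix with class `"polyline"`.
#' @export
polyline <- function(xy) {
  xy <- as_xy_matrix(xy, "polyline")
  if (nrow(xy) < 2) stop("a polyline needs at least 2 vertices", call. = FALSE)
  if (path_length(xy) <= 0) stop("polyline has zero arc length", call. = FALSE)
  structure(xy, class = c("polyline", "matrix", "array"))
}

signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#' @param c a [contour()] or vertex matrix.
#' @return enclosed area in square micrometres (always positive).
#' @export
polygon_area <- function(c) abs(signed_area(unclass(c)))

#' Polygon perimeter
#' @inheritParams polygon_area
#' @return boundary length in micrometres.
#' @export
polygon_perimeter <- function(c) {
  xy <- unclass(c)
  path_length(rbind(xy, xy[1, ]))
}

#' Polyline arc length
#' @param p a [polyline()] or vertex matrix.
#' @return summed segment length in micrometres.
#' @export
path_length <- function(p) {
  xy <- unclass(p)
  sum(sqrt(rowSums(diff(xy)^2)))
}

# Segment intersection test for the simplicity check. Touching at shared
# endpoints of adjacent edges is allowed; any other contact is not.
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    d(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(q1, q2, p1) || on_seg(q1, q2, p2) || on_seg(p1, p2, q1) || on_seg(p1, p2, q2)
}

is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip edges sharing a vertex
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(xy[idx[i, 1], ], xy[idx[i, 2], ],
                         xy[idx[j, 1], ], xy[idx[j, 2], ])) return(FALSE)
    }
  }
  TRUE
}

#' Exact area moments of a polygon
#'
#' Centroid and second central moments of the filled region, from the
#' closed-form polygon moment integrals (no rasterization).
#'
#' @inheritParams polygon_area
#' @return list with `area`, `centroid` (x, y) and the 2x2 covariance matrix
#'   of the uniform distribution over the region.
#' @export
polygon_moments <- function(c) {
  xy <- unclass(c)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # raw second moments about the origin
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # central, normalized by area -> covariance of the uniform region
  cov <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                  ixy / a - cx * cy, iyy / a - cy^2), 2, 2)
  if (a < 0) { a <- -a }
  list(area = a, centroid = c(x = cx, y = cy), cov = cov)
}

#' Moment-matched fitted ellipse
#'
#' The ellipse with the same area-normalized second central moments as the
#' filled polygon, the convention used by standard particle analysis. For an
#' exact ellipse the recovered axes equal its own axes.
#'
#' @inheritParams polygon_area
#' @return list with `major` and `minor` full axis lengths (micrometres) and
#'   `angle` of the major axis in radians.
#' @export
fit_ellipse <- function(c) {
  m <- polygon_moments(c)
  e <- eigen(m$cov, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  list(major = 4 * sqrt(lam[1]), minor = 4 * sqrt(lam[2]),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

#' Circularity of a closed contour
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, approaching 0 for
#' an infinitely elongated outline. Digitized circles can overshoot 1
#' slightly through perimeter estimation bias; values are clamped at 1 after
#' asserting they do not exceed `1 + tol`.
#'
#' @inheritParams polygon_area
#' @param tol permitted digitization overshoot above 1 before an error is
#'   raised (default 0.02).
#' @return circularity in (0, 1].
#' @export
circularity <- function(c, tol = 0.02) {
  a <- polygon_area(c)
  p <- polygon_perimeter(c)
  if (p <= 0) stop("degenerate contour: zero perimeter", call. = FALSE)
  val <- 4 * pi * a / p^2
  if (val > 1 + tol) {
    stop(sprintf("circularity %.4f exceeds 1 + tol; contour is inconsistent", val),
         call. = FALSE)
  }
  min(val, 1)
}

#' Roundness of a closed contour
#'
#' `4 * area / (pi * major_axis^2)` with the major axis taken from the
#' moment-matched fitted ellipse ([fit_ellipse()]): the inverse aspect ratio
#' of the particle, 1 for a circle, b/a for an ellipse with semi-axes a > b.
#'
#' @inheritParams circularity
#' @return roundness in (0, 1].
#' @export
roundness <- function(c, tol = 0.02) {
  a <- polygon_area(c)
  if (a <= 0) stop("degenerate contour: zero area", call. = FALSE)
  maj <- fit_ellipse(c)$major
  if (maj <= 0) stop("degenerate contour: zero extent", call. = FALSE)
  val <- 4 * a / (pi * maj^2)
  if (val > 1 + tol) {
    stop(sprintf("roundness %.4f exceeds 1 + tol; contour is inconsistent", val),
         call. = FALSE)
  }
  min(val, 1)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized over query points; boundary points count as inside.
#'
#' @param px,py numeric vectors of query coordinates.
#' @inheritParams polygon_area
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, c) {
  xy <- unclass(c)
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from each point to a polyline/polygon boundary (vectorized
# over points, looped over edges).
points_to_path_distance <- function(px, py, xy, closed = FALSE) {
  xy <- unclass(xy)
  if (closed) xy <- rbind(xy, xy[1, ])
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(xy) - 1)) {
    ax <- xy[i, 1]; ay <- xy[i, 2]
    bx <- xy[i + 1, 1]; by <- xy[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    if (len2 == 0) {
      dd <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
      dd <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

# First intersection of the ray p + t*d (t > 0) with a closed polygon; returns
# the smallest positive t or NA.
ray_polygon_first_hit <- function(p, d, xy) {
  xy <- unclass(xy)
  xy2 <- rbind(xy, xy[1, ])
  best <- NA_real_
  for (i in seq_len(nrow(xy2) - 1)) {
    a <- xy2[i, ]; b <- xy2[i + 1, ]
    e <- b - a
    den <- d[1] * e[2] - d[2] * e[1]
    if (abs(den) < 1e-14) next
    t <- ((a[1] - p[1]) * e[2] - (a[2] - p[2]) * e[1]) / den
    u <- ((a[1] - p[1]) * d[2] - (a[2] - p[2]) * d[1]) / den
    if (t > 1e-12 && u >= -1e-12 && u <= 1 + 1e-12) {
      if (is.na(best) || t < best) best <- t
    }
  }
  best
}

# Arc-length parameterized point on a closed polygon boundary: s in [0, L).
point_at_arclength <- function(xy, s) {
  xy <- unclass(xy)
  ring <- rbind(xy, xy[1, ])
  seglen <- sqrt(rowSums(diff(ring)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- s %% total
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seglen))
  f <- (s - cum[i]) / seglen[i]
  cbind(ring[i, 1] + f * (ring[i + 1, 1] - ring[i, 1]),
        ring[i, 2] + f * (ring[i + 1, 2] - ring[i, 2]))
}

# Sub-path of the closed polygon boundary from arc length s0 to s0 + len
# (wrapping allowed); follows the polygon exactly, so its arc length is len.
boundary_arc <- function(xy, s0, len) {
  xy <- unclass(xy)
  ring <- rbind(xy, xy[1, ])
  seglen <- sqrt(rowSums(diff(ring)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  stopifnot(len > 0, len <= total)
  s0 <- s0 %% total
  allb <- c(cum, cum + total)
  inner <- allb[allb > s0 + 1e-12 & allb < s0 + len - 1e-12]
  ss <- c(s0, sort(inner), s0 + len)
  pts <- point_at_arclength(xy, ss)
  polyline(pts)
}
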