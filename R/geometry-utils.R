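# Internal planar/vector geometry helpers shared across modules.
# All coordinates are in mm; angles in degrees unless a name says otherwise.

.norm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .norm(v)
  if (n < .Machine$double.eps * 10) stop("cannot normalise a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal in-plane basis (u, v) for a unit normal n, right-handed so
# that cross(u, v) == n.
.plane_basis <- function(n) {
  helper <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross3(helper, n))
  v <- .cross3(n, u)
  cbind(u, v)
}

# Section frame at a point with advancing tangent `t` and global up `up`
# (the basal-plane normal): right-handed columns (lateral, up-in-plane,
# tangent) with cross(l, u) == t, so ring orientation is comparable
# across sections of a stack.
.section_frame <- function(tangent, up) {
  t <- .unit(tangent)
  u <- up - sum(up * t) * t
  if (.norm(u) < 1e-8) {
    # section lies in the reference plane itself: any in-plane pair works
    B <- .plane_basis(t)
    return(cbind(B[, 1], B[, 2], t))
  }
  u <- .unit(u)
  l <- .cross3(u, t)
  cbind(l, u, t)
}

# Unwrap a sequence of angles in degrees so consecutive steps are in
# (-180, 180]; returns a continuous angle sequence.
.unwrap_deg <- function(ang) {
  d <- diff(ang)
  d <- (d + 180) %% 360 - 180
  c(ang[1], ang[1] + cumsum(d))
}

# Signed area (shoelace) of a 2D polygon given as an open ring (k x 2).
.polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Polygon centroid (area centroid) of a simple 2D ring.
.polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Ray-casting point-in-polygon for a single 2D point.
.point_in_polygon <- function(pt, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < (xn - x) * (pt[2] - y) / (yn - y) + x)
  sum(crosses) %% 2 == 1
}

# Vectorised proper-intersection test between all edge pairs of two rings.
.rings_edges_cross <- function(A, B) {
  ax1 <- A[, 1]; ay1 <- A[, 2]
  ax2 <- c(ax1[-1], ax1[1]); ay2 <- c(ay1[-1], ay1[1])
  bx1 <- B[, 1]; by1 <- B[, 2]
  bx2 <- c(bx1[-1], bx1[1]); by2 <- c(by1[-1], by1[1])
  na <- length(ax1); nb <- length(bx1)
  i <- rep(seq_len(na), times = nb); j <- rep(seq_len(nb), each = na)
  p1x <- ax1[i]; p1y <- ay1[i]; p2x <- ax2[i]; p2y <- ay2[i]
  q1x <- bx1[j]; q1y <- by1[j]; q2x <- bx2[j]; q2y <- by2[j]
  d1 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
  d2 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
  d3 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
  d4 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

# Do two simple 2D rings overlap (edge crossing or containment)?
.polygons_overlap <- function(A, B) {
  # cheap bounding-box reject
  if (max(A[, 1]) < min(B[, 1]) || max(B[, 1]) < min(A[, 1]) ||
      max(A[, 2]) < min(B[, 2]) || max(B[, 2]) < min(A[, 2])) {
    return(FALSE)
  }
  if (.rings_edges_cross(A, B)) return(TRUE)
  .point_in_polygon(A[1, ], B) || .point_in_polygon(B[1, ], A)
}

# Self-intersection test for a 2D ring (non-adjacent edge pairs).
# Rings cut from faceted meshes carry micrometre-scale zigzags where the
# sectioning plane grazes mesh edges; crossings whose two segments are
# both tiny relative to the perimeter are facet noise, not a
# figure-eight, and are ignored (tol_frac of the perimeter).
.ring_is_simple <- function(xy, tol_frac = 1e-3) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  tol <- tol_frac * sum(seg_len)
  i <- rep(seq_len(n), times = n); j <- rep(seq_len(n), each = n)
  keep <- j > i + 1 & !(i == 1 & j == n)
  i <- i[keep]; j <- j[keep]
  p1x <- x1[i]; p1y <- y1[i]; p2x <- x2[i]; p2y <- y2[i]
  q1x <- x1[j]; q1y <- y1[j]; q2x <- x2[j]; q2y <- y2[j]
  d1 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
  d2 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
  d3 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
  d4 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
  crossing <- d1 * d2 < 0 & d3 * d4 < 0
  if (!any(crossing)) return(TRUE)
  material <- pmax(seg_len[i[crossing]], seg_len[j[crossing]]) > tol
  !any(material)
}

# Resample a closed 3D ring (k x 3, no repeated end point) to n points
# uniformly spaced in arc length, starting at the first point.
.resample_ring <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-nrow(closed), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate ring with zero perimeter")
  target <- total * (seq_len(n) - 1) / n
  out <- matrix(0, n, 3)
  for (k in 1:3) out[, k] <- approx(s, closed[, k], xout = target, ties = "ordered")$y
  out
}

# Cyclically rotate ring rows so row `start` comes first.
.rotate_ring <- function(pts, start) {
  n <- nrow(pts)
  if (start == 1) return(pts)
  pts[c(start:n, 1:(start - 1)), , drop = FALSE]
}
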