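#' Best-fit basal plane of the cochlear basal turn
#'
#' Total-least-squares plane (orthogonal distance regression via SVD)
#' through the basilar-membrane landmarks of the first `extent` degrees of
#' the basal turn. The landmark subset is chosen by a provisional plane
#' fitted to all landmarks: in-plane angles about the landmark centroid
#' are unwrapped and points with angle <= `extent` kept for the final fit.
#' The normal is oriented so that apical landmarks (beyond `extent`) lie
#' at positive height.
#'
#' @param landmarks a [landmark_set()].
#' @param extent angular extent in degrees used for the fit (default 270).
#' @return object of class `basal_plane`: `origin` (point on plane),
#'   `normal` (unit vector), `basis` (3 x 2 in-plane orthonormal basis).
#' @export
fit_basal_plane <- function(landmarks, extent = 270) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pts <- landmarks$points
  fit_tls <- function(p) {
    ctr <- colMeans(p)
    sv <- svd(sweep(p, 2, ctr))
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
      stop("rank error: landmarks are collinear or degenerate")
    }
    list(origin = ctr, normal = sv$v[, 3])
  }
  prov <- fit_tls(pts)
  ang <- .inplane_angles(pts, prov$origin, prov$normal)
  sel <- ang <= extent
  if (sum(sel) < 4) stop("rank error: fewer than 4 landmarks within the basal extent")
  final <- fit_tls(pts[sel, , drop = FALSE])
  n <- final$normal
  apical <- pts[!sel, , drop = FALSE]
  if (nrow(apical) > 0) {
    if (mean((apical %*% n) - sum(final$origin * n)) < 0) n <- -n
  } else if (n[3] < 0) {
    n <- -n # no apical points: pick the +z-ish orientation
  }
  structure(list(origin = final$origin, normal = n, basis = .plane_basis(n)),
            class = "basal_plane")
}

#' @export
print.basal_plane <- function(x, ...) {
  cat(sprintf("basal_plane: origin (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

# unwrapped in-plane angles (deg, starting at 0) of points about a centre,
# increasing along the point ordering
.inplane_angles <- function(pts, centre, normal) {
  B <- .plane_basis(normal)
  d <- sweep(pts, 2, centre)
  x <- d %*% B[, 1]
  y <- d %*% B[, 2]
  raw <- atan2(y, x) * 180 / pi
  a <- .unwrap_deg(raw)
  a <- a - a[1]
  if (a[length(a)] < 0) a <- -a
  as.vector(a)
}

#' Signed height of points above a basal plane
#' @param pts n x 3 matrix or length-3 vector.
#' @param plane a `basal_plane`.
#' @return numeric vector of signed distances (mm).
#' @export
plane_height <- function(pts, plane) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  as.vector(pts %*% plane$normal) - sum(plane$origin * plane$normal)
}

#' Extract perpendicular cross-sections of the scala tympani lumen
#'
#' For each landmark, the mesh is cut by the plane through the landmark
#' whose normal is the local trajectory tangent (centred finite difference
#' of the landmark sequence, one-sided at the ends). When the infinite
#' plane cuts several turns of the spiral, the connected intersection
#' component nearest to the landmark is kept, eliminating intersections
#' through other turns.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param landmarks a [landmark_set()] ordered base to apex.
#' @return list of `cross_section` objects (ring, plane, landmark index);
#'   geometric properties are filled by [section_properties()].
#' @export
extract_cross_sections <- function(mesh, landmarks) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(landmarks, "landmark_set"))
  pts <- landmarks$points
  n <- nrow(pts)
  tangents <- matrix(0, n, 3)
  if (n > 2) {
    # second-order one-sided differences at the ends; an oblique first
    # cut inflates the basal radius, which the spiral flare term amplifies
    tangents[1, ] <- -3 * pts[1, ] + 4 * pts[2, ] - pts[3, ]
    tangents[n, ] <- 3 * pts[n, ] - 4 * pts[n - 1, ] + pts[n - 2, ]
    tangents[2:(n - 1), ] <- pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  } else {
    tangents[1, ] <- pts[2, ] - pts[1, ]
    tangents[n, ] <- pts[n, ] - pts[n - 1, ]
  }
  tangents <- tangents / sqrt(rowSums(tangents^2))
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    ring <- .mesh_plane_section(mesh, pts[i, ], tangents[i, ])
    sections[[i]] <- structure(
      list(ring = ring, plane_origin = pts[i, ], plane_normal = tangents[i, ],
           centroid = NULL, area = NULL, lateral_wall_height = NULL,
           theta = NA_real_, arc_distance = NA_real_,
           lateral_index = which.min(rowSums(sweep(ring, 2, pts[i, ])^2)),
           landmark = pts[i, ]),
      class = "cross_section")
  }
  sections
}

# Intersect a mesh with the plane (p0, n); return the ordered closed ring
# of the connected component nearest to p0. Errors if the plane misses the
# mesh or the intersection crosses an open boundary.
.mesh_plane_section <- function(mesh, p0, nrm) {
  v <- mesh$vertices
  f <- mesh$faces
  sd <- as.vector(v %*% nrm) - sum(p0 * nrm)
  sd[abs(sd) < 1e-12] <- 1e-12 # nudge on-plane vertices to one side
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossing <- !((s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0))
  if (!any(crossing)) stop("no-intersection error: sectioning plane misses the mesh")
  fc <- f[crossing, , drop = FALSE]
  # per crossing face: exactly two crossing edges among (1,2),(2,3),(3,1)
  edge_pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  keys <- matrix(0, nrow(fc), 2)
  pts_by_key <- new.env(parent = emptyenv())
  nv <- nrow(v)
  edge_key <- function(a, b) (pmin(a, b) - 1) * nv + pmax(a, b)
  face_keys <- matrix(NA_real_, nrow(fc), 3)
  cross_edge <- matrix(FALSE, nrow(fc), 3)
  for (e in 1:3) {
    a <- fc[, edge_pairs[[e]][1]]; b <- fc[, edge_pairs[[e]][2]]
    cross_edge[, e] <- sd[a] * sd[b] < 0
    face_keys[, e] <- edge_key(a, b)
  }
  if (any(rowSums(cross_edge) != 2)) {
    stop("integrity error: degenerate plane-mesh intersection")
  }
  # unique crossing edges and their interpolated points
  all_a <- c(fc[, 1], fc[, 2], fc[, 3])
  all_b <- c(fc[, 2], fc[, 3], fc[, 1])
  all_cross <- as.vector(cross_edge)
  ea <- all_a[all_cross]; eb <- all_b[all_cross]
  ek <- edge_key(ea, eb)
  uniq <- !duplicated(ek)
  ea_u <- ea[uniq]; eb_u <- eb[uniq]; ek_u <- ek[uniq]
  t <- sd[ea_u] / (sd[ea_u] - sd[eb_u])
  ipts <- v[ea_u, , drop = FALSE] + t * (v[eb_u, , drop = FALSE] - v[ea_u, , drop = FALSE])
  # segment list: each crossing face connects its two crossing edge points
  seg <- matrix(0L, nrow(fc), 2)
  for (i in seq_len(nrow(fc))) {
    ks <- face_keys[i, cross_edge[i, ]]
    seg[i, ] <- match(ks, ek_u)
  }
  # chain segments into loops
  npt <- length(ek_u)
  adj <- vector("list", npt)
  for (i in seq_len(nrow(seg))) {
    adj[[seg[i, 1]]] <- c(adj[[seg[i, 1]]], seg[i, 2])
    adj[[seg[i, 2]]] <- c(adj[[seg[i, 2]]], seg[i, 1])
  }
  deg <- lengths(adj)
  if (any(deg != 2)) stop("integrity error: intersection crosses an open boundary")
  visited <- logical(npt)
  loops <- list()
  for (start in seq_len(npt)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nbrs <- adj[[cur]]
      nxt <- if (nbrs[1] != prev) nbrs[1] else nbrs[2]
      prev <- cur; cur <- nxt
      if (cur == start) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  # keep the component whose nearest point to the landmark is minimal
  dmin <- vapply(loops, function(l) {
    min(rowSums(sweep(ipts[l, , drop = FALSE], 2, p0)^2))
  }, 0)
  ring <- ipts[loops[[which.min(dmin)]], , drop = FALSE]
  ring
}

#' Geometric properties of a cross-section
#'
#' Fills centroid (planar polygon centroid), area (shoelace in the section
#' plane), and lateral-wall height, defined as the extent of the ring
#' along the in-plane projection of the basal-plane normal (the "up"
#' direction within the section plane).
#'
#' @param section a `cross_section` from [extract_cross_sections()].
#' @param plane a `basal_plane` fixing the up direction.
#' @return the section with `centroid`, `area`, `lateral_wall_height` set.
#' @export
section_properties <- function(section, plane) {
  stopifnot(inherits(section, "cross_section"), inherits(plane, "basal_plane"))
  ring <- section$ring
  B <- .section_frame(section$plane_normal, plane$normal)
  ctr0 <- colMeans(ring)
  q <- sweep(ring, 2, ctr0) %*% B[, 1:2]
  if (!.ring_is_simple(q)) stop("geometry error: self-intersecting section ring")
  area <- abs(.polygon_signed_area(q))
  c2 <- .polygon_centroid(q)
  centroid <- ctr0 + B[, 1] * c2[1] + B[, 2] * c2[2]
  lwh <- diff(range(q[, 2]))
  section$centroid <- as.vector(centroid)
  section$area <- area
  section$lateral_wall_height <- lwh
  section
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section: %d ring points", nrow(x$ring)))
  if (!is.null(x$area)) cat(sprintf(", area %.3f mm^2, lateral wall %.3f mm", x$area, x$lateral_wall_height))
  if (!is.na(x$theta)) cat(sprintf(", theta %.1f deg, arc %.2f mm", x$theta, x$arc_distance))
  cat("\n")
  invisible(x)
}

#' Build the centreline of a section stack
#'
#' Orders section centroids by unwrapped in-plane angle about a
#' provisional centre (mean of the in-plane centroids, or the fitted
#' spiral centre when supplied), starting at 0 degrees at the basal-most
#' section, and records the signed height of each centroid above the
#' basal plane.
#'
#' @param sections list of `cross_section` with properties filled.
#' @param plane a `basal_plane`.
#' @param centre optional in-plane 2D centre (mm) overriding the
#'   provisional centroid mean.
#' @return object of class `centreline`: `theta` (deg), `centroids`
#'   (n x 3), `z_offset` (mm), `inplane` (n x 2 in plane basis), `centre`.
#' @export
build_centreline <- function(sections, plane, centre = NULL) {
  if (length(sections) < 3) stop("need at least 3 sections for a centreline")
  cts <- t(vapply(sections, function(s) {
    if (is.null(s$centroid)) stop("sections need properties; run section_properties()")
    s$centroid
  }, numeric(3)))
  d <- sweep(cts, 2, plane$origin)
  inplane <- d %*% plane$basis
  z <- plane_height(cts, plane)
  unwrap_about <- function(ctr) {
    rel <- sweep(inplane, 2, ctr)
    raw <- atan2(rel[, 2], rel[, 1]) * 180 / pi
    theta <- .unwrap_deg(raw)
    theta <- theta - theta[1]
    if (theta[length(theta)] < 0) theta <- -theta
    theta
  }
  if (is.null(centre)) {
    # provisional centre: the overall centroid mean, or - for a
    # decreasing spiral sampled densely at the base - the mean of the
    # apical quarter, which hugs the true centre; keep the first
    # candidate about which the unwrapped angle is monotone
    n <- nrow(inplane)
    candidates <- list(
      colMeans(inplane),
      colMeans(inplane[seq(max(1, floor(n * 0.75)), n), , drop = FALSE]))
    for (ctr in candidates) {
      th_try <- unwrap_about(ctr)
      if (all(diff(th_try) > 0)) {
        centre <- ctr
        break
      }
    }
    if (is.null(centre)) {
      stop("ordering error: centreline angle is not strictly increasing after unwrapping")
    }
  }
  theta <- unwrap_about(centre)
  if (any(diff(theta) <= 0)) {
    stop("ordering error: centreline angle is not strictly increasing after unwrapping")
  }
  structure(list(theta = as.vector(theta), centroids = cts,
                 z_offset = as.vector(z), inplane = inplane, centre = centre),
            class = "centreline")
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf("centreline: %d samples, theta 0-%.1f deg, rise %.2f mm\n",
              length(x$theta), max(x$theta), x$z_offset[length(x$z_offset)] - x$z_offset[1]))
  invisible(x)
}

# Double-exponential spiral radius (theta in degrees).
.spiral_radius <- function(theta, R_scale, theta1, theta2, theta0 = 0) {
  R_scale * (exp(-(theta + theta0) / theta1) + exp(-(theta + theta0) / theta2))
}

#' Fit the double-exponential cochlear spiral
#'
#' Fits `R(theta) = R_scale * (exp(-theta/theta1) + exp(-theta/theta2))`
#' to the in-plane centreline radii by nonlinear least squares
#' ([minpack.lm::nls.lm]), co-estimating the 2D spiral centre and a small
#' angular origin offset `theta0` (the basal-most sample need not sit at
#' the spiral's nominal origin). A multi-start grid over
#' `theta1 in {45, 90, 180}` and `theta2 in {180, 360, 720}` degrees
#' guards against local minima; since the model is symmetric in the two
#' terms, the result is canonicalised to `theta1 <= theta2` (basal
#' flaring vs central spiral).
#'
#' @param centreline a [build_centreline()] result.
#' @param starts_theta1,starts_theta2 multi-start grids in degrees.
#' @return object of class `spiral_fit` with `R_scale` (mm), `theta1`,
#'   `theta2`, `theta0` (deg), `centre` (in-plane mm), `rmse` (mm),
#'   `degenerate` flag, and the per-sample `theta`/`radius`/`fitted`.
#' @export
fit_spiral <- function(centreline,
                       starts_theta1 = c(45, 90, 180),
                       starts_theta2 = c(180, 360, 720)) {
  stopifnot(inherits(centreline, "centreline"))
  xy <- centreline$inplane
  if (nrow(xy) < 6) stop("fit error: need at least 6 centreline samples")
  if (max(centreline$theta) - min(centreline$theta) < 270) {
    stop("fit error: centreline must span at least 270 degrees")
  }
  obj <- function(par) {
    cx <- par[1]; cy <- par[2]
    Rs <- exp(par[3]); t1 <- exp(par[4]); t2 <- exp(par[5]); th0 <- par[6]
    dx <- xy[, 1] - cx; dy <- xy[, 2] - cy
    r <- sqrt(dx^2 + dy^2)
    raw <- atan2(dy, dx) * 180 / pi
    th <- .unwrap_deg(raw)
    th <- th - th[1]
    if (th[length(th)] < 0) th <- -th
    r - .spiral_radius(th, Rs, t1, t2, th0)
  }
  c0 <- centreline$centre
  r0 <- sqrt(sum((xy[1, ] - c0)^2))
  best <- NULL
  for (t1s in starts_theta1) {
    for (t2s in starts_theta2) {
      par0 <- c(c0[1], c0[2], log(r0 / 2), log(t1s), log(t2s), 0)
      fit <- tryCatch(
        minpack.lm::nls.lm(par = par0, fn = obj,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }
  if (is.null(best)) stop("fit error: spiral fit failed to converge for all starts")
  p <- best$par
  t1 <- exp(p[4]); t2 <- exp(p[5])
  if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
  res <- obj(best$par)
  degenerate <- t2 > 2e4 || !(best$info %in% 1:4)
  if (degenerate) {
    warning("spiral fit is degenerate (near-constant radius or non-convergence)")
  }
  dx <- xy[, 1] - p[1]; dy <- xy[, 2] - p[2]
  raw <- atan2(dy, dx) * 180 / pi
  th <- .unwrap_deg(raw); th <- th - th[1]
  if (th[length(th)] < 0) th <- -th
  structure(list(R_scale = unname(exp(p[3])), theta1 = unname(t1),
                 theta2 = unname(t2), theta0 = unname(p[6]),
                 centre = unname(c(p[1], p[2])), rmse = sqrt(mean(res^2)),
                 residuals = res, theta = as.vector(th),
                 radius = sqrt(dx^2 + dy^2),
                 fitted = .spiral_radius(as.vector(th), exp(p[3]), t1, t2, p[6]),
                 degenerate = degenerate, info = best$info),
            class = "spiral_fit")
}

#' @export
print.spiral_fit <- function(x, digits = 4, ...) {
  cat("Double-exponential spiral fit  R(theta) = R_scale (e^{-theta/theta1} + e^{-theta/theta2})\n")
  cat(sprintf("  R_scale = %.*g mm, theta1 = %.*g deg, theta2 = %.*g deg (theta0 = %.3g deg)\n",
              digits, x$R_scale, digits, x$theta1, digits, x$theta2, x$theta0))
  cat(sprintf("  centre (%.3f, %.3f) mm in basal plane; rmse %.4g mm over %d samples\n",
              x$centre[1], x$centre[2], x$rmse, length(x$theta)))
  if (isTRUE(x$degenerate)) cat("  [degenerate fit]\n")
  invisible(x)
}

#' @export
coef.spiral_fit <- function(object, ...) {
  c(R_scale = object$R_scale, theta1 = object$theta1, theta2 = object$theta2,
    theta0 = object$theta0, centre_x = object$centre[1], centre_y = object$centre[2])
}

#' @export
summary.spiral_fit <- function(object, ...) {
  structure(list(coef = coef(object), rmse = object$rmse,
                 n = length(object$theta), degenerate = object$degenerate,
                 resid_quartiles = quantile(object$residuals, c(0.25, 0.5, 0.75))),
            class = "summary.spiral_fit")
}

#' @export
print.summary.spiral_fit <- function(x, ...) {
  cat("spiral_fit summary\n")
  print(x$coef)
  cat(sprintf("rmse %.4g mm on %d samples; residual quartiles: %s mm\n",
              x$rmse, x$n, paste(signif(x$resid_quartiles, 3), collapse = " / ")))
  invisible(x)
}

#' Predict spiral radius at given angles
#' @param object a `spiral_fit`.
#' @param theta angles in degrees (from the basal start).
#' @param ... unused.
#' @return radii in mm.
#' @export
predict.spiral_fit <- function(object, theta = object$theta, ...) {
  .spiral_radius(theta, object$R_scale, object$theta1, object$theta2, object$theta0)
}

#' @export
residuals.spiral_fit <- function(object, ...) object$residuals

#' @export
plot.spiral_fit <- function(x, ...) {
  plot(x$theta, x$radius, xlab = "angle (deg)", ylab = "in-plane radius (mm)",
       main = "Cochlear spiral fit", ...)
  ths <- seq(min(x$theta), max(x$theta), length.out = 200)
  lines(ths, predict(x, ths), col = 2, lwd = 2)
  invisible(x)
}

#' Map between insertion distance and angular insertion depth
#'
#' Builds the monotone piecewise-linear relation between cumulative chord
#' length along the basilar-membrane landmarks (the lateral-wall path a
#' straight electrode follows) and the unwrapped in-plane angle about the
#' spiral centre. Exposes both directions.
#'
#' @param landmarks a [landmark_set()].
#' @param plane a `basal_plane`.
#' @param centre in-plane 2D centre (mm), typically `spiral_fit$centre`.
#' @return object of class `angle_distance_map` with `knots`
#'   (arc_distance mm, theta deg) and conversion via
#'   [distance_to_angle()] / [angle_to_distance()].
#' @export
build_angle_distance_map <- function(landmarks, plane, centre) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pts <- landmarks$points
  d <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  rel <- sweep(sweep(pts, 2, plane$origin) %*% plane$basis, 2, centre)
  raw <- atan2(rel[, 2], rel[, 1]) * 180 / pi
  theta <- .unwrap_deg(raw)
  theta <- theta - theta[1]
  if (theta[length(theta)] < 0) theta <- -theta
  .angle_distance_map(d, as.vector(theta))
}

.angle_distance_map <- function(arc_distance, theta) {
  if (any(diff(arc_distance) <= 0)) stop("arc distances must be strictly increasing")
  if (any(diff(theta) <= 0)) stop("error: unwrapped angle is not strictly increasing")
  knots <- data.frame(arc_distance = arc_distance, theta = theta)
  structure(list(knots = knots,
                 .to_angle = approxfun(arc_distance, theta),
                 .to_distance = approxfun(theta, arc_distance)),
            class = "angle_distance_map")
}

#' @export
print.angle_distance_map <- function(x, ...) {
  k <- x$knots
  cat(sprintf("angle_distance_map: %d knots, %.2f mm / %.1f deg span\n",
              nrow(k), max(k$arc_distance), max(k$theta)))
  invisible(x)
}

#' Convert insertion distance (mm) to angular depth (deg)
#' @param map an `angle_distance_map`.
#' @param distance insertion distances in mm.
#' @return angles in degrees.
#' @export
distance_to_angle <- function(map, distance) {
  rng <- range(map$knots$arc_distance)
  if (any(distance < rng[1] - 1e-9 | distance > rng[2] + 1e-9)) {
    stop(sprintf("range error: distance outside map range [%.3f, %.3f] mm", rng[1], rng[2]))
  }
  map$.to_angle(pmin(pmax(distance, rng[1]), rng[2]))
}

#' Convert angular depth (deg) to insertion distance (mm)
#' @param map an `angle_distance_map`.
#' @param theta angles in degrees.
#' @return distances in mm.
#' @export
angle_to_distance <- function(map, theta) {
  rng <- range(map$knots$theta)
  if (any(theta < rng[1] - 1e-9 | theta > rng[2] + 1e-9)) {
    stop(sprintf("range error: angle outside map range [%.1f, %.1f] deg", rng[1], rng[2]))
  }
  map$.to_distance(pmin(pmax(theta, rng[1]), rng[2]))
}

#' Full scala-tympani characterisation
#'
#' Convenience wrapper chaining basal-plane fitting, cross-section
#' extraction, section properties, centreline construction, spiral
#' fitting, and the angle-distance map, and labelling each section with
#' its angular (`theta`) and lateral-wall arc (`arc_distance`)
#' coordinates.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param landmarks a [landmark_set()].
#' @param extent basal-plane fitting extent in degrees.
#' @return object of class `st_characterisation`: `plane`, `stack`
#'   (a [section_stack()]), `centreline`, `spiral`, `map`.
#' @export
characterise_st <- function(mesh, landmarks, extent = 270) {
  plane <- fit_basal_plane(landmarks, extent = extent)
  sections <- extract_cross_sections(mesh, landmarks)
  sections <- lapply(sections, section_properties, plane = plane)
  cl <- build_centreline(sections, plane)
  spiral <- fit_spiral(cl)
  cl <- build_centreline(sections, plane, centre = spiral$centre)
  map <- build_angle_distance_map(landmarks, plane, spiral$centre)
  pts <- landmarks$points
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  lm_theta <- distance_to_angle(map, arc)
  for (i in seq_along(sections)) {
    sections[[i]]$theta <- lm_theta[i]
    sections[[i]]$arc_distance <- arc[i]
  }
  stack <- section_stack(sections, plane, spiral)
  structure(list(plane = plane, stack = stack, centreline = cl,
                 spiral = spiral, map = map),
            class = "st_characterisation")
}

#' @export
print.st_characterisation <- function(x, ...) {
  cat("st_characterisation\n")
  print(x$spiral)
  print(x$map)
  invisible(x)
}

#' Write a characterisation report (JSON + CSV)
#'
#' Writes `spiral.json` (fit parameters) and `sections.csv` (per-section
#' theta, arc distance, area, lateral-wall height, centroid height).
#'
#' @param char an `st_characterisation`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_characterisation <- function(char, dir) {
  stopifnot(inherits(char, "st_characterisation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(spiral = as.list(coef(char$spiral)),
         rmse_mm = char$spiral$rmse,
         plane = list(origin = char$plane$origin, normal = char$plane$normal)),
    file.path(dir, "spiral.json"), auto_unbox = TRUE, digits = NA)
  secs <- char$stack$sections
  df <- data.frame(
    theta_deg = vapply(secs, function(s) s$theta, 0),
    arc_distance_mm = vapply(secs, function(s) s$arc_distance, 0),
    area_mm2 = vapply(secs, function(s) s$area, 0),
    lateral_wall_height_mm = vapply(secs, function(s) s$lateral_wall_height, 0),
    z_offset_mm = plane_height(t(vapply(secs, function(s) s$centroid, numeric(3))), char$plane))
  write.csv(df, file.path(dir, "sections.csv"), row.names = FALSE)
  invisible(dir)
}
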