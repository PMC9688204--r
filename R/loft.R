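#' Loft a section stack into a triangulated mesh
#'
#' Reconstructs a surface by (1) sorting each ring clockwise with respect
#' to the base (viewed from the basal side along the advancing tangent),
#' (2) resampling each ring to `ring_points` vertices uniformly in arc
#' length, (3) aligning the seam of consecutive rings by nearest-point
#' start correspondence (minimising inter-ring twist), (4) triangulating
#' each band with `2 * ring_points` triangles, and (5) capping the ends
#' with triangle fans from the end-ring centroids. A fully capped loft is
#' watertight with consistent outward winding.
#'
#' @param stack a [section_stack()] with at least 2 sections.
#' @param ring_points vertices per ring after resampling (default 100).
#' @param cap_ends cap both ends (default TRUE); overridden by
#'   `cap_base` / `cap_apex`.
#' @param cap_base,cap_apex logical; leave FALSE for an open boundary.
#' @param vent_diameter if non-NULL, the apical cap is built as an
#'   annulus leaving an open access hole of this diameter (mm) instead of
#'   a closed fan.
#' @param name mesh label.
#' @return a [triangle_mesh()].
#' @export
loft <- function(stack, ring_points = 100, cap_ends = TRUE,
                 cap_base = cap_ends, cap_apex = cap_ends,
                 vent_diameter = NULL, name = "lofted") {
  stopifnot(inherits(stack, "section_stack"))
  ns <- length(stack$sections)
  if (ns < 2) stop("value error: lofting needs at least 2 sections")
  plane <- stack$plane
  cts <- .stack_centroids(stack)
  adv <- .stack_tangents(cts)
  rings <- vector("list", ns)
  frames <- vector("list", ns)
  for (i in seq_len(ns)) {
    s <- stack$sections[[i]]
    t_i <- s$plane_normal
    if (sum(t_i * adv[i, ]) < 0) t_i <- -t_i
    B <- .section_frame(t_i, plane$normal)
    ctr <- colMeans(s$ring)
    q <- sweep(s$ring, 2, ctr) %*% B[, 1:2]
    if (!.ring_is_simple(q)) stop("geometry error: self-intersecting ring at section ", i)
    ring <- s$ring
    if (.polygon_signed_area(q) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    rings[[i]] <- .resample_ring(ring, ring_points)
    frames[[i]] <- B
  }
  for (i in 2:ns) {
    start_prev <- rings[[i - 1]][1, ]
    d2 <- rowSums(sweep(rings[[i]], 2, start_prev)^2)
    rings[[i]] <- .rotate_ring(rings[[i]], which.min(d2))
  }
  n <- ring_points
  vertices <- do.call(rbind, rings)
  idx <- function(ring_i, pt_j) (ring_i - 1L) * n + ((pt_j - 1L) %% n) + 1L
  faces <- vector("list", ns + 1)
  j <- seq_len(n)
  for (i in seq_len(ns - 1)) {
    p <- idx(i, j); p1 <- idx(i, j + 1)
    q <- idx(i + 1, j); q1 <- idx(i + 1, j + 1)
    faces[[i]] <- rbind(cbind(p, p1, q1), cbind(p, q1, q))
  }
  if (isTRUE(cap_base)) {
    cb <- nrow(vertices) + 1L
    vertices <- rbind(vertices, colMeans(rings[[1]]))
    faces[[ns]] <- cbind(rep(cb, n), idx(1, j + 1), idx(1, j))
  }
  if (!is.null(vent_diameter)) {
    if (vent_diameter <= 0) stop("value error: vent_diameter must be > 0")
    B <- frames[[ns]]
    ctr <- colMeans(rings[[ns]])
    phi <- 2 * pi * (j - 1) / n
    circ <- sweep((vent_diameter / 2) * cbind(cos(phi), sin(phi)) %*% t(B[, 1:2]),
                  2, ctr, "+")
    # orient + align the vent ring with the end ring's traversal
    qe <- sweep(rings[[ns]], 2, ctr) %*% B[, 1:2]
    if (.polygon_signed_area(qe) < 0) circ <- circ[rev(j), , drop = FALSE]
    d2 <- rowSums(sweep(circ, 2, rings[[ns]][1, ])^2)
    circ <- .rotate_ring(circ, which.min(d2))
    base_i <- nrow(vertices)
    vertices <- rbind(vertices, circ)
    ci <- function(pt_j) base_i + ((pt_j - 1L) %% n) + 1L
    e <- idx(ns, j); e1 <- idx(ns, j + 1)
    faces[[ns + 1]] <- rbind(cbind(e, e1, ci(j + 1)), cbind(e, ci(j + 1), ci(j)))
  } else if (isTRUE(cap_apex)) {
    ca <- nrow(vertices) + 1L
    vertices <- rbind(vertices, colMeans(rings[[ns]]))
    faces[[ns + 1]] <- cbind(rep(ca, n), idx(ns, j), idx(ns, j + 1))
  }
  faces <- do.call(rbind, faces[!vapply(faces, is.null, TRUE)])
  mesh <- triangle_mesh(vertices, faces, name = name)
  if (isTRUE(cap_base) && (isTRUE(cap_apex) && is.null(vent_diameter))) {
    if (.signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  } else {
    # open meshes: fix winding from the band construction so bands face
    # outward (band normals should point away from the section centroid)
    a <- vertices[faces[1, 1], ]; b <- vertices[faces[1, 2], ]; c_ <- vertices[faces[1, 3], ]
    nrm <- .cross3(b - a, c_ - a)
    if (sum(nrm * (a - cts[1, ])) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  }
  mesh
}

#' Prepare a lofted model for 3D printing
#'
#' Applies the consistent print orientation (the chord of the first
#' `orient_extent` degrees of the centreline along +x, basal-plane normal
#' as close to +z as the chord allows), leaves the basal end open for a
#' consistent electrode entry trajectory, and (optionally) opens an
#' apical access hole used to flush the printed model with solutions.
#'
#' @param mesh a lofted [triangle_mesh()] (used for its name only; the
#'   geometry is re-lofted from the stack so the openings are exact).
#' @param stack the [section_stack()] the mesh was lofted from.
#' @param vent_diameter apical access-hole diameter in mm (default 0.6);
#'   `NULL` disables the vent.
#' @param orient_extent angular extent of the orientation chord (deg).
#' @param ring_points vertices per ring for the re-loft.
#' @return a `triangle_mesh` with one (no vent) or two (vent) boundary
#'   loops; attribute `transform` records the rigid motion
#'   (`rotation`, `origin`) applied.
#' @export
prepare_print_model <- function(mesh, stack, vent_diameter = 0.6,
                                orient_extent = 15, ring_points = 100) {
  stopifnot(inherits(stack, "section_stack"))
  th <- vapply(stack$sections, function(s) s$theta, 0)
  if (any(is.na(th))) stop("stack sections lack theta coordinates")
  cts <- .stack_centroids(stack)
  target <- min(th) + orient_extent
  if (max(th) < target) stop("stack does not span the orientation extent")
  chord_end <- vapply(1:3, function(k) approx(th, cts[, k], xout = target)$y, 0)
  chord <- chord_end - cts[1, ]
  x_axis <- .unit(chord)
  nB <- stack$plane$normal
  z_axis <- nB - sum(nB * x_axis) * x_axis
  if (.norm(z_axis) < 1e-8) stop("geometry error: orientation chord parallel to basal-plane normal")
  z_axis <- .unit(z_axis)
  y_axis <- .cross3(z_axis, x_axis)
  rot <- cbind(x_axis, y_axis, z_axis) # world -> print coords via t(rot)
  origin <- cts[1, ]
  tf <- function(p) sweep(p, 2, origin) %*% rot
  new_stack <- stack
  for (i in seq_along(stack$sections)) {
    s <- stack$sections[[i]]
    s$ring <- tf(s$ring)
    s$centroid <- as.vector(tf(matrix(s$centroid, 1)))
    s$plane_origin <- as.vector(tf(matrix(s$plane_origin, 1)))
    s$plane_normal <- as.vector(matrix(s$plane_normal, 1) %*% rot)
    if (!is.null(s$landmark)) s$landmark <- as.vector(tf(matrix(s$landmark, 1)))
    new_stack$sections[[i]] <- s
  }
  new_stack$plane <- structure(
    list(origin = as.vector(tf(matrix(stack$plane$origin, 1))),
         normal = as.vector(matrix(nB, 1) %*% rot),
         basis = .plane_basis(as.vector(matrix(nB, 1) %*% rot))),
    class = "basal_plane")
  out <- loft(new_stack, ring_points = ring_points, cap_base = FALSE,
              cap_apex = TRUE, vent_diameter = vent_diameter,
              name = paste0(mesh$name, "_print"))
  attr(out, "transform") <- list(rotation = rot, origin = origin)
  out
}

#' Nominal-actual surface deviation
#'
#' Quantifies how far a test surface deviates from a reference surface:
#' points are sampled uniformly by area on the test mesh, the nearest
#' point on the reference surface is found for each, and the distances
#' (reported in micrometres) are summarised by quantiles. Signs follow
#' the reference face normals (positive outside).
#'
#' @param test a [triangle_mesh()] whose surface is sampled.
#' @param reference the reference [triangle_mesh()].
#' @param n_samples number of surface samples (default 1e5).
#' @param seed RNG seed for reproducible sampling.
#' @return object of class `deviation_report`: `distances_um` (signed),
#'   `quantiles_um` (absolute, at 50/90/95/100%), `histogram`,
#'   `n_samples`.
#' @export
nominal_actual_deviation <- function(test, reference, n_samples = 100000, seed = 1) {
  stopifnot(inherits(test, "triangle_mesh"), inherits(reference, "triangle_mesh"))
  if (mesh_surface_area(reference) <= 0) stop("error: degenerate reference mesh")
  samples <- sample_mesh_surface(test, n_samples, seed = seed)
  nn <- mesh_nearest_cpp(samples, reference$vertices, reference$faces)
  signed_um <- nn$distance * sign(nn$side) * 1000
  signed_um[nn$side == 0] <- abs(signed_um[nn$side == 0])
  abs_um <- abs(signed_um)
  qs <- quantile(abs_um, c(0.5, 0.9, 0.95, 1.0), names = FALSE)
  h <- hist(signed_um, breaks = 50, plot = FALSE)
  structure(list(distances_um = signed_um,
                 quantiles_um = setNames(qs, c("50", "90", "95", "100")),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 n_samples = n_samples),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  q <- x$quantiles_um
  cat(sprintf(paste0("deviation_report: %d samples; |deviation| quantiles ",
                     "50%%: %.2f um, 90%%: %.2f um, 95%%: %.2f um, max: %.2f um\n"),
              x$n_samples, q["50"], q["90"], q["95"], q["100"]))
  invisible(x)
}

#' @export
plot.deviation_report <- function(x, ...) {
  hist(x$distances_um, breaks = 50, xlab = "signed deviation (um)",
       main = "Nominal-actual surface deviation", ...)
  invisible(x)
}

#' Sample points uniformly by area on a mesh surface
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of samples.
#' @param seed RNG seed.
#' @return n x 3 matrix of points (mm).
#' @export
sample_mesh_surface <- function(mesh, n, seed = 1) {
  set.seed(seed)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  areas <- sqrt(cx^2 + cy^2 + cz^2) / 2
  tri <- sample.int(nrow(f), n, replace = TRUE, prob = areas)
  u <- runif(n); w <- runif(n)
  flip <- u + w > 1
  u[flip] <- 1 - u[flip]; w[flip] <- 1 - w[flip]
  a[tri, , drop = FALSE] + u * e1[tri, , drop = FALSE] + w * e2[tri, , drop = FALSE]
}
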