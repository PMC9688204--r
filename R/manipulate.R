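#' Ordered stack of cross-sections
#'
#' A `section_stack` is the manipulable representation of a scala
#' tympani: ordered cross-sections sharing one basal plane, optionally
#' carrying the fitted spiral (required by [reshape_curvature()]). It is
#' the input to [loft()].
#'
#' @param sections list of `cross_section` objects ordered by theta.
#' @param plane a `basal_plane`.
#' @param spiral optional `spiral_fit`.
#' @return object of class `section_stack`.
#' @export
section_stack <- function(sections, plane, spiral = NULL) {
  stopifnot(is.list(sections), inherits(plane, "basal_plane"))
  th <- vapply(sections, function(s) s$theta, 0)
  if (!all(is.na(th)) && any(diff(th) < 0)) stop("sections must be ordered by theta")
  structure(list(sections = sections, plane = plane, spiral = spiral),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  th <- vapply(x$sections, function(s) s$theta, 0)
  cat(sprintf("section_stack: %d sections, theta %.1f-%.1f deg%s\n",
              length(x$sections), min(th), max(th),
              if (!is.null(x$spiral)) ", spiral attached" else ""))
  invisible(x)
}

# centroid matrix of a stack
.stack_centroids <- function(stack) {
  t(vapply(stack$sections, function(s) s$centroid, numeric(3)))
}

# advancing (base-to-apex) unit tangents by centred differences of the
# section centroids, one-sided at the ends
.stack_tangents <- function(centroids) {
  n <- nrow(centroids)
  tg <- matrix(0, n, 3)
  tg[1, ] <- centroids[2, ] - centroids[1, ]
  tg[n, ] <- centroids[n, ] - centroids[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- centroids[3:n, , drop = FALSE] - centroids[1:(n - 2), , drop = FALSE]
  tg / sqrt(rowSums(tg^2))
}

# recompute lateral-wall arc distances from each section's lateral point
.update_arc_distances <- function(stack) {
  lat <- t(vapply(stack$sections, function(s) s$ring[s$lateral_index, ], numeric(3)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(lat)^2))))
  for (i in seq_along(stack$sections)) stack$sections[[i]]$arc_distance <- arc[i]
  stack
}

# translate one section rigidly
.translate_section <- function(section, delta) {
  section$ring <- sweep(section$ring, 2, delta, "+")
  section$centroid <- section$centroid + delta
  section$plane_origin <- section$plane_origin + delta
  if (!is.null(section$landmark)) section$landmark <- section$landmark + delta
  section
}

#' Manipulation specification
#'
#' Describes one procedural shape manipulation; exactly the fields
#' relevant to `kind` may be set.
#'
#' @param kind one of `"volume_scale"`, `"flatten"`, `"non_planarity"`,
#'   `"curvature"`, `"uniform_cs"`.
#' @param volume_ratio target volume ratio (e.g. 1.10 for the "large"
#'   model, 0.90 for "small").
#' @param np_amplitude sinusoid amplitude in mm (0.2 mm in the
#'   non-planarity conditions).
#' @param np_period sinusoid period in degrees (270 for NP1, 135 for NP2).
#' @param np_extent angular extent of the sinusoid (default 270).
#' @param theta2_multiplier multiplier on the central-spiral parameter
#'   theta2 (2 for "loose", 0.5 for "tighter").
#' @param uniform_cs_source_depth lateral-wall arc depth (mm) of the
#'   section reused along the whole model (default 1).
#' @return object of class `manipulation_spec`.
#' @export
manipulation_spec <- function(kind = c("volume_scale", "flatten", "non_planarity",
                                       "curvature", "uniform_cs"),
                              volume_ratio = NULL, np_amplitude = NULL,
                              np_period = NULL, np_extent = 270,
                              theta2_multiplier = NULL,
                              uniform_cs_source_depth = 1.0) {
  kind <- match.arg(kind)
  if (kind == "volume_scale") {
    if (is.null(volume_ratio) || volume_ratio <= 0) stop("value error: volume_ratio must be > 0")
  }
  if (kind == "non_planarity") {
    if (is.null(np_amplitude) || np_amplitude < 0) stop("value error: np_amplitude must be >= 0")
    if (is.null(np_period) || np_period <= 0) stop("value error: np_period must be > 0")
  }
  if (kind == "curvature") {
    if (is.null(theta2_multiplier) || theta2_multiplier <= 0) {
      stop("value error: theta2_multiplier must be > 0")
    }
  }
  structure(list(kind = kind, volume_ratio = volume_ratio,
                 np_amplitude = np_amplitude, np_period = np_period,
                 np_extent = np_extent, theta2_multiplier = theta2_multiplier,
                 uniform_cs_source_depth = uniform_cs_source_depth),
            class = "manipulation_spec")
}

#' Volumetric scaling of a mesh
#'
#' Multiplies the vertices by `volume_ratio^(1/3)` about the vertex
#' centroid, so the enclosed volume scales by exactly `volume_ratio`
#' ("110% volumetric scaling" means `volume_ratio = 1.10`).
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param volume_ratio target volume ratio (> 0).
#' @return scaled `triangle_mesh`; attributes `linear_factor` and
#'   `scale_centre` record the transform so companion point sets
#'   (landmarks) can be scaled identically.
#' @export
scale_volume <- function(mesh, volume_ratio) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is.numeric(volume_ratio) || volume_ratio <= 0) {
    stop("value error: volume_ratio must be > 0")
  }
  s <- volume_ratio^(1 / 3)
  ctr <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2, ctr) * s
  out <- triangle_mesh(sweep(v, 2, ctr, "+"), mesh$faces,
                       name = sprintf("%s_scaled_%g", mesh$name, volume_ratio))
  attr(out, "linear_factor") <- s
  attr(out, "scale_centre") <- ctr
  out
}

#' Flatten the vertical trajectory of a section stack
#'
#' Translates every section along the basal-plane normal so its centroid
#' height is zero (a two-dimensional spiral in the basal plane), then
#' truncates the stack at the first angle where a section would overlap
#' the radially aligned section one turn further out - flattening removes
#' the vertical separation between turns, so the apical part of the
#' spiral eventually collides with the basal turn.
#'
#' @param stack a [section_stack()].
#' @return flattened (possibly truncated) `section_stack`.
#' @export
flatten <- function(stack) {
  stopifnot(inherits(stack, "section_stack"))
  plane <- stack$plane
  for (i in seq_along(stack$sections)) {
    z <- plane_height(stack$sections[[i]]$centroid, plane)
    stack$sections[[i]] <- .translate_section(stack$sections[[i]], -z * plane$normal)
  }
  th <- vapply(stack$sections, function(s) s$theta, 0)
  if (!any(is.na(th)) && max(th) - min(th) > 360) {
    centre <- if (!is.null(stack$spiral)) stack$spiral$centre else {
      colMeans(sweep(.stack_centroids(stack), 2, plane$origin) %*% plane$basis)
    }
    rint <- t(vapply(stack$sections, function(s) {
      q <- sweep(sweep(s$ring, 2, plane$origin) %*% plane$basis, 2, centre)
      range(sqrt(rowSums(q^2)))
    }, numeric(2)))
    spacing <- max(diff(th))
    cut <- NA_integer_
    for (j in seq_along(th)) {
      outer <- which(abs(th - (th[j] - 360)) <= spacing)
      if (length(outer) == 0) next
      if (any(rint[j, 2] >= rint[outer, 1])) { cut <- j; break }
    }
    if (!is.na(cut)) stack$sections <- stack$sections[seq_len(cut - 1)]
  }
  .update_arc_distances(stack)
}

#' Add artificial non-planarity to the basal-turn trajectory
#'
#' Adds a sinusoidal vertical displacement
#' `amplitude * sin(360 * theta / period)` to every section with
#' `theta <= extent`, emulating the "rollercoaster" basal-turn
#' trajectories reported in imaging studies. The period must divide the
#' extent so the sinusoid returns to zero at the extent boundary (270 and
#' 135 both do for the default 270-degree extent).
#'
#' @param stack a [section_stack()] (typically flattened first).
#' @param amplitude sinusoid amplitude in mm (>= 0).
#' @param period sinusoid period in degrees.
#' @param extent angular extent of the modification (default 270).
#' @return modified `section_stack`.
#' @export
add_non_planarity <- function(stack, amplitude, period, extent = 270) {
  stopifnot(inherits(stack, "section_stack"))
  if (amplitude < 0) stop("value error: amplitude must be >= 0")
  if (period <= 0) stop("value error: period must be > 0")
  if (abs(sin(pi * 2 * extent / period)) > 1e-9) {
    stop("value error: sinusoid must return to zero at the extent boundary ",
         "(extent must be a multiple of period/2)")
  }
  nB <- stack$plane$normal
  for (i in seq_along(stack$sections)) {
    th <- stack$sections[[i]]$theta
    if (is.na(th) || th > extent) next
    dz <- amplitude * sin(2 * pi * th / period)
    stack$sections[[i]] <- .translate_section(stack$sections[[i]], dz * nB)
  }
  .update_arc_distances(stack)
}

#' Reshape spiral curvature
#'
#' Recomputes the target radius from the fitted double-exponential spiral
#' with `theta2` multiplied by `theta2_multiplier` (theta1 and R_scale
#' unchanged; 2 loosens, 0.5 tightens the central spiral), moves each
#' section's centroid radially in-plane to the new radius at its original
#' angle, and rigidly re-orients each ring so its plane normal follows
#' the new local trajectory tangent.
#'
#' @param stack a [section_stack()] carrying a `spiral_fit`.
#' @param theta2_multiplier positive multiplier on theta2.
#' @return reshaped `section_stack` (its `spiral` is updated too).
#' @export
reshape_curvature <- function(stack, theta2_multiplier) {
  stopifnot(inherits(stack, "section_stack"))
  if (theta2_multiplier <= 0) stop("value error: theta2_multiplier must be > 0")
  if (is.null(stack$spiral)) stop("stack carries no spiral fit")
  sp <- stack$spiral
  plane <- stack$plane
  cts <- .stack_centroids(stack)
  th <- vapply(stack$sections, function(s) s$theta, 0)
  inpl <- sweep(cts, 2, plane$origin) %*% plane$basis
  rel <- sweep(inpl, 2, sp$centre)
  r_cur <- sqrt(rowSums(rel^2))
  r_new <- .spiral_radius(th, sp$R_scale, sp$theta1, sp$theta2 * theta2_multiplier, sp$theta0)
  scale_r <- r_new / r_cur
  disp2 <- rel * (scale_r - 1)
  disp3 <- disp2 %*% t(plane$basis)
  cts_new <- cts + disp3
  tg_old <- .stack_tangents(cts)
  tg_new <- .stack_tangents(cts_new)
  for (i in seq_along(stack$sections)) {
    s <- stack$sections[[i]]
    B_old <- .section_frame(tg_old[i, ], plane$normal)
    B_new <- .section_frame(tg_new[i, ], plane$normal)
    q <- sweep(s$ring, 2, s$centroid) %*% B_old
    s$ring <- sweep(q %*% t(B_new), 2, cts_new[i, ], "+")
    s$centroid <- cts_new[i, ]
    s$plane_origin <- cts_new[i, ]
    s$plane_normal <- tg_new[i, ]
    stack$sections[[i]] <- s
  }
  sp$theta2 <- sp$theta2 * theta2_multiplier
  stack$spiral <- sp
  .update_arc_distances(stack)
}

#' Uniformise the cross-section along the centreline
#'
#' Replaces every section's ring with the ring found at
#' `source_depth` mm of lateral-wall arc distance (1 mm from the basal
#' opening by default), transported rigidly into each section's local
#' frame (tangent, in-plane lateral and up directions); the centreline is
#' unchanged.
#'
#' @param stack a [section_stack()] with arc-distance coordinates.
#' @param source_depth lateral-wall arc depth of the source section (mm).
#' @return modified `section_stack` with constant cross-section.
#' @export
uniformise_cross_section <- function(stack, source_depth = 1.0) {
  stopifnot(inherits(stack, "section_stack"))
  arc <- vapply(stack$sections, function(s) s$arc_distance, 0)
  if (any(is.na(arc))) stop("stack sections lack arc-distance coordinates")
  if (source_depth < min(arc) || source_depth > max(arc)) {
    stop(sprintf("range error: source_depth %.2f mm outside stack range [%.2f, %.2f]",
                 source_depth, min(arc), max(arc)))
  }
  src_i <- which.min(abs(arc - source_depth))
  src <- stack$sections[[src_i]]
  plane <- stack$plane
  B_src <- .section_frame(src$plane_normal, plane$normal)
  q_src <- sweep(src$ring, 2, src$centroid) %*% B_src[, 1:2]
  for (i in seq_along(stack$sections)) {
    s <- stack$sections[[i]]
    B <- .section_frame(s$plane_normal, plane$normal)
    s$ring <- sweep(q_src %*% t(B[, 1:2]), 2, s$centroid, "+")
    s$area <- src$area
    s$lateral_wall_height <- src$lateral_wall_height
    s$lateral_index <- src$lateral_index
    stack$sections[[i]] <- s
  }
  .update_arc_distances(stack)
}

#' Apply a manipulation specification
#'
#' Dispatches a [manipulation_spec()] onto a section stack (or, for
#' `volume_scale`, a mesh). Non-planarity and curvature manipulations are
#' applied to the flattened stack, matching the experimental design in
#' which those conditions isolate one geometric factor at a time.
#'
#' @param stack a [section_stack()].
#' @param spec a [manipulation_spec()].
#' @return manipulated `section_stack`.
#' @export
apply_manipulation <- function(stack, spec) {
  stopifnot(inherits(spec, "manipulation_spec"))
  switch(spec$kind,
    flatten = flatten(stack),
    non_planarity = add_non_planarity(flatten(stack), spec$np_amplitude,
                                      spec$np_period, spec$np_extent),
    # reshape first, then flatten: the flat-model truncation must reflect
    # the reshaped spiral's own inter-turn clearance
    curvature = flatten(reshape_curvature(stack, spec$theta2_multiplier)),
    uniform_cs = uniformise_cross_section(stack, spec$uniform_cs_source_depth),
    volume_scale = stop("volume_scale acts on the mesh; use scale_volume()"))
}
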