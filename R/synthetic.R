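#' Specification of the synthetic scala tympani
#'
#' Parametric model of a human-scale ST lumen used as the package's
#' fixture cochlea. The centreline follows the double-exponential spiral
#' `R(theta) = R_scale (e^{-theta/theta1} + e^{-theta/theta2})` with a
#' linear vertical rise; cross-sections are superellipse rings whose area
#' tapers log-linearly through the anchors (0 mm, `area_basal`),
#' (1 mm, `area_at_1mm`), (20 mm, `area_at_20mm`) of lateral-wall arc
#' distance, and whose height tapers linearly from `lw_height_basal` to
#' `lw_height_at_20mm`. Landmarks sit on the superior-lateral ring point,
#' the basilar-membrane edge analogue. Defaults reproduce the published
#' anatomical anchors (2.6 to 1.0 mm^2 area, 1.6 to 0.9 mm lateral-wall
#' height over the insertion extent) and give an angle-distance map
#' spanning well over 540 degrees at 20 mm so that a full insertion
#' exceeds one turn.
#'
#' @param R_scale spiral scale in mm.
#' @param theta1 basal-flaring decay constant, degrees.
#' @param theta2 central-spiral decay constant, degrees.
#' @param total_angle angular extent of the model, degrees.
#' @param area_basal,area_at_1mm,area_at_20mm cross-sectional area
#'   anchors, mm^2, at 0/1/20 mm lateral-wall arc distance.
#' @param lw_height_basal,lw_height_at_20mm lateral-wall height anchors, mm.
#' @param rise_total vertical ascent of the centreline over the full
#'   extent, mm (default 4.2; 0 gives a pre-flattened cochlea).
#' @param section_spacing angular spacing of generated sections, degrees.
#' @param ring_points vertices per section ring.
#' @param n_landmarks number of basilar-membrane landmarks (default 68).
#' @param superellipse_n exponent of the superellipse ring shape
#'   (2 = ellipse; 3, the default, is slightly boxier, closer to the
#'   rounded-triangular ST section).
#' @param landmark_inset basal inset of the first landmark, degrees
#'   (keeps sectioning planes clear of the basal end cap).
#' @param apical_margin apical margin of the last landmark, degrees.
#' @param seed RNG seed carried for provenance (generation itself is
#'   deterministic).
#' @return object of class `synthetic_st_spec`.
#' @export
synthetic_st_spec <- function(R_scale = 1.6, theta1 = 90, theta2 = 900,
                              total_angle = 810,
                              area_basal = 2.6, area_at_1mm = 2.5,
                              area_at_20mm = 1.0,
                              lw_height_basal = 1.6, lw_height_at_20mm = 0.9,
                              rise_total = 4.2, section_spacing = 5,
                              ring_points = 100, n_landmarks = 68,
                              superellipse_n = 3, landmark_inset = 3,
                              apical_margin = 10, seed = 1) {
  if (any(c(area_basal, area_at_1mm, area_at_20mm) <= 0) ||
      area_basal < area_at_1mm || area_at_1mm < area_at_20mm) {
    stop("validation error: areas must be positive and non-increasing base to apex")
  }
  if (lw_height_basal <= 0 || lw_height_at_20mm <= 0 ||
      lw_height_basal < lw_height_at_20mm) {
    stop("validation error: lateral-wall heights must be positive and non-increasing")
  }
  if (R_scale <= 0 || theta1 <= 0 || theta2 <= 0) stop("spiral parameters must be > 0")
  structure(as.list(environment()), class = "synthetic_st_spec")
}

#' @export
print.synthetic_st_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic_st_spec: R_scale %.2f mm, theta1 %g deg, theta2 %g deg, ",
                     "%g deg total, %g mm rise\n"),
              x$R_scale, x$theta1, x$theta2, x$total_angle, x$rise_total))
  cat(sprintf("  area %.1f->%.1f mm^2, lateral wall %.1f->%.1f mm over 20 mm\n",
              x$area_basal, x$area_at_20mm, x$lw_height_basal, x$lw_height_at_20mm))
  invisible(x)
}

# area taper (mm^2) vs lateral-wall arc distance s (mm): log-linear
# through the three anchors, extrapolated with the 1-20 mm slope
.area_taper <- function(spec, s) {
  k1 <- log(spec$area_at_1mm / spec$area_basal) / 1
  k2 <- log(spec$area_at_20mm / spec$area_at_1mm) / 19
  ifelse(s <= 1, spec$area_basal * exp(k1 * s),
         spec$area_at_1mm * exp(k2 * (s - 1)))
}

# lateral-wall height taper (mm): linear through the anchors, floored to
# stay positive past the insertion extent
.height_taper <- function(spec, s) {
  slope <- (spec$lw_height_basal - spec$lw_height_at_20mm) / 20
  pmax(spec$lw_height_basal - slope * s, 0.4)
}

# superellipse area factor: area = factor * a * b for |x/a|^n+|y/b|^n=1
.superellipse_factor <- function(n) {
  4 * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

# Arc distance along the landmark (superior-lateral) curve as a function
# of theta, by fixed-point iteration: ring half-width depends on arc
# distance which depends on the lateral curve including the half-width.
.landmark_arc <- function(spec, theta_grid) {
  thr <- theta_grid * pi / 180
  Rc <- .spiral_radius(theta_grid, spec$R_scale, spec$theta1, spec$theta2)
  zc <- spec$rise_total * theta_grid / spec$total_angle
  sf <- .superellipse_factor(spec$superellipse_n)
  off <- (1 / 2)^(1 / spec$superellipse_n) # ring point at the 45-deg direction
  s <- c(0, cumsum(sqrt(diff(Rc * cos(thr))^2 + diff(Rc * sin(thr))^2 + diff(zc)^2)))
  for (it in 1:8) {
    A <- .area_taper(spec, s)
    b <- .height_taper(spec, s) / 2
    a <- A / (sf * b)
    rl <- Rc + a * off
    zl <- zc + b * off
    s <- c(0, cumsum(sqrt(diff(rl * cos(thr))^2 + diff(rl * sin(thr))^2 + diff(zl)^2)))
  }
  s
}

# centreline point, tangent and local frame at angle theta (deg)
.generator_frame <- function(spec, theta) {
  thr <- theta * pi / 180
  R <- .spiral_radius(theta, spec$R_scale, spec$theta1, spec$theta2)
  dR <- -spec$R_scale * (exp(-theta / spec$theta1) / spec$theta1 +
                         exp(-theta / spec$theta2) / spec$theta2)
  centre <- c(R * cos(thr), R * sin(thr), spec$rise_total * theta / spec$total_angle)
  tangent <- c(dR * cos(thr) - R * sin(thr) * pi / 180,
               dR * sin(thr) + R * cos(thr) * pi / 180,
               spec$rise_total / spec$total_angle)
  e_r <- c(cos(thr), sin(thr), 0)
  list(centre = centre, tangent = .unit(tangent), e_r = e_r)
}

#' Generate the synthetic scala tympani fixture
#'
#' Builds the parametric ST of a [synthetic_st_spec()]: the analytic
#' section stack, the basilar-membrane landmark set (on the
#' superior-lateral ring edge), and a watertight mesh produced by the
#' package's own [loft()].
#'
#' @param spec a [synthetic_st_spec()].
#' @return object of class `synthetic_st`: list with `mesh`
#'   ([triangle_mesh()]), `landmarks` ([landmark_set()]), `stack`
#'   ([section_stack()] carrying the true spiral), and `spec`.
#' @export
generate_st <- function(spec = synthetic_st_spec()) {
  stopifnot(inherits(spec, "synthetic_st_spec"))
  fine <- seq(0, spec$total_angle, by = 0.5)
  s_fine <- .landmark_arc(spec, fine)
  arc_of <- approxfun(fine, s_fine)
  sf <- .superellipse_factor(spec$superellipse_n)
  off <- (1 / 2)^(1 / spec$superellipse_n)
  plane <- structure(list(origin = c(0, 0, 0), normal = c(0, 0, 1),
                          basis = .plane_basis(c(0, 0, 1))),
                     class = "basal_plane")
  ring_shape <- function(a, b, k, n_exp) {
    phi <- 2 * pi * (seq_len(k) - 1) / k
    cbind(a * sign(cos(phi)) * abs(cos(phi))^(2 / n_exp),
          b * sign(sin(phi)) * abs(sin(phi))^(2 / n_exp))
  }
  make_section <- function(theta) {
    fr <- .generator_frame(spec, theta)
    s <- arc_of(theta)
    A <- .area_taper(spec, s)
    b <- .height_taper(spec, s) / 2
    a <- A / (sf * b)
    u <- .unit(plane$normal - sum(plane$normal * fr$tangent) * fr$tangent)
    l <- fr$e_r - sum(fr$e_r * fr$tangent) * fr$tangent
    l <- .unit(l - sum(l * u) * u) # exact orthonormal (lateral, up) pair
    q <- ring_shape(a, b, spec$ring_points, spec$superellipse_n)
    ring <- sweep(q[, 1, drop = FALSE] %*% rbind(l) + q[, 2, drop = FALSE] %*% rbind(u),
                  2, fr$centre, "+")
    lat_target <- fr$centre + a * off * l + b * off * u
    structure(list(ring = ring, plane_origin = fr$centre, plane_normal = fr$tangent,
                   centroid = fr$centre, area = A, lateral_wall_height = 2 * b,
                   theta = theta, arc_distance = s,
                   lateral_index = which.min(rowSums(sweep(ring, 2, lat_target)^2)),
                   landmark = lat_target),
              class = "cross_section")
  }
  thetas <- seq(0, spec$total_angle, by = spec$section_spacing)
  sections <- lapply(thetas, make_section)
  spiral <- structure(list(R_scale = spec$R_scale, theta1 = spec$theta1,
                           theta2 = spec$theta2, theta0 = 0,
                           centre = c(0, 0), rmse = 0, degenerate = FALSE,
                           theta = thetas,
                           radius = .spiral_radius(thetas, spec$R_scale,
                                                   spec$theta1, spec$theta2),
                           source = "generator"),
                      class = "spiral_fit")
  stack <- section_stack(sections, plane, spiral)
  mesh <- loft(stack, ring_points = spec$ring_points, cap_ends = TRUE,
               name = "synthetic_st")
  # landmarks evenly spaced in arc length along the basilar-membrane edge
  # (as a person marking the membrane would place them): denser in angle
  # through the wide basal flare than near the tight apex
  theta_of_arc <- approxfun(s_fine, fine)
  lm_arcs <- seq(arc_of(spec$landmark_inset),
                 arc_of(spec$total_angle - spec$apical_margin),
                 length.out = spec$n_landmarks)
  lm_thetas <- theta_of_arc(lm_arcs)
  lm_pts <- t(vapply(lm_thetas, function(th) {
    fr <- .generator_frame(spec, th)
    s <- arc_of(th)
    A <- .area_taper(spec, s)
    b <- .height_taper(spec, s) / 2
    a <- A / (sf * b)
    u <- .unit(plane$normal - sum(plane$normal * fr$tangent) * fr$tangent)
    l <- fr$e_r - sum(fr$e_r * fr$tangent) * fr$tangent
    l <- .unit(l - sum(l * u) * u)
    fr$centre + a * off * l + b * off * u
  }, numeric(3)))
  structure(list(mesh = mesh, landmarks = landmark_set(lm_pts),
                 stack = stack, spec = spec),
            class = "synthetic_st")
}

#' @export
print.synthetic_st <- function(x, ...) {
  cat("synthetic_st fixture\n")
  print(x$spec)
  print(x$mesh)
  print(x$landmarks)
  invisible(x)
}

# angle-distance map taken directly from a (possibly manipulated) stack:
# cumulative chord along the per-section lateral-wall points vs theta
.stack_angle_distance_map <- function(stack) {
  lat <- t(vapply(stack$sections, function(s) s$ring[s$lateral_index, ], numeric(3)))
  th <- vapply(stack$sections, function(s) s$theta, 0)
  d <- c(0, cumsum(sqrt(rowSums(diff(lat)^2))))
  .angle_distance_map(d, th - th[1])
}

#' Simulate a replicated insertion-force dataset
#'
#' Runs [simulate_insertion()] `n_reps` times per condition with
#' sub-seeds drawn deterministically from the master seed, emulating the
#' repeated-insertion design of a robotic insertion experiment.
#'
#' @param models named list: condition label -> [insertion_model()].
#' @param map an `angle_distance_map`, or a named list of maps (one per
#'   condition).
#' @param n_reps replicates per condition (default 10).
#' @param seed master seed; same seed, identical dataset.
#' @param max_distance insertion depth in mm, or named vector per
#'   condition.
#' @param noise_sd force noise sd in mN.
#' @param ... further arguments passed to [simulate_insertion()].
#' @return list of `force_trace` objects with attributes `condition` and
#'   `rep`; names are `<condition>_<rep>`.
#' @export
generate_force_dataset <- function(models, map, n_reps = 10, seed = 1,
                                   max_distance = 20, noise_sd = 2, ...) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("models must be a named list of conditions")
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(models) * n_reps)
  traces <- list()
  k <- 0
  for (cond in names(models)) {
    m <- map
    if (is.list(map) && !inherits(map, "angle_distance_map")) m <- map[[cond]]
    md <- if (length(max_distance) > 1) max_distance[[cond]] else max_distance
    for (r in seq_len(n_reps)) {
      k <- k + 1
      tr <- simulate_insertion(models[[cond]], m, max_distance = md,
                               noise_sd = noise_sd, seed = sub_seeds[k], ...)
      attr(tr, "condition") <- cond
      attr(tr, "rep") <- r
      traces[[paste(cond, r, sep = "_")]] <- tr
    }
  }
  traces
}
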