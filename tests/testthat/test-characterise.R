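test_that("basal plane fit is exact on planar and tilted landmark sets", {
  # planar: z = 0 spiral points
  xy <- spiral_points(3, 90, 360, thetas = seq(0, 400, by = 10))
  lm <- landmark_set(cbind(xy, 0))
  pl <- fit_basal_plane(lm)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_lt(max(abs(plane_height(lm$points, pl))), 1e-12)
  # same points on a plane tilted 5 degrees about x
  a <- 5 * pi / 180
  rot <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  lm2 <- landmark_set(cbind(xy, 0) %*% t(rot))
  pl2 <- fit_basal_plane(lm2)
  truth <- rot %*% c(0, 0, 1)
  ang <- acos(min(1, abs(sum(pl2$normal * truth))))
  expect_lt(ang, 1e-6)
})

test_that("degenerate landmark sets are rejected for plane fitting", {
  expect_error(landmark_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "at least 4")
  lin <- landmark_set(cbind(seq(0, 3), 0, 0))
  expect_error(fit_basal_plane(lin), "rank error")
})

test_that("cylinder sections recover the analytic disc area", {
  cyl <- make_cylinder_mesh(radius = 1, height = 4, n = 360)
  lm <- landmark_set(cbind(1, 0, c(1.4, 1.8, 2.2, 2.6)))
  secs <- extract_cross_sections(cyl, lm)
  secs <- lapply(secs, section_properties, plane = xy_plane())
  areas <- vapply(secs, function(s) s$area, 0)
  expect_true(all(abs(areas - pi) / pi < 0.005))
})

test_that("the intersection component nearest the landmark is selected", {
  torus <- make_torus_mesh(R = 3, r = 0.5)
  # landmarks along one limb; the sectioning plane cuts both limbs
  lm_pos <- landmark_set(cbind(3.0, c(-0.3, -0.1, 0.1, 0.3), 0))
  ring <- extract_cross_sections(torus, lm_pos)[[2]]$ring
  expect_gt(mean(ring[, 1]), 2) # limb at +x selected
  lm_neg <- landmark_set(cbind(-3.0, c(0.3, 0.1, -0.1, -0.3), 0))
  ring2 <- extract_cross_sections(torus, lm_neg)[[2]]$ring
  expect_lt(mean(ring2[, 1]), -2)
  # oracle: the chosen ring is closer to the landmark than the other limb
  d_own <- min(sqrt(rowSums(sweep(ring, 2, c(3, -0.1, 0))^2)))
  d_other <- min(sqrt(rowSums(sweep(ring2, 2, c(3, -0.1, 0))^2)))
  expect_lt(d_own, d_other)
})

test_that("section properties match closed forms on simple rings", {
  # rings in a vertical plane (normal +x), as real sections sit relative
  # to the basal plane
  sq <- make_section(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1)),
                     c(1, 0, 0), plane = xy_plane())
  expect_equal(sq$area, 1.0, tolerance = 1e-12)
  expect_equal(sq$centroid, c(0, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(sq$lateral_wall_height, 1.0, tolerance = 1e-12)
  phi <- 2 * pi * (0:199) / 200
  a <- 2; b <- 0.7
  el <- make_section(cbind(0, a * cos(phi), b * sin(phi)), c(1, 0, 0),
                     plane = xy_plane())
  expect_lt(abs(el$area - pi * a * b) / (pi * a * b), 0.005)
  expect_equal(el$lateral_wall_height, 2 * b, tolerance = 1e-4)
  bow <- make_section(rbind(c(0, 0, 0), c(0, 1, 1), c(0, 1, 0), c(0, 0, 1)),
                      c(1, 0, 0))
  expect_error(section_properties(bow, xy_plane()), "self-intersecting")
})

test_that("synthetic basal section reproduces the anatomical anchors", {
  s1 <- sections_fixture()[[1]]
  expect_lt(abs(s1$area - 2.6) / 2.6, 0.01)           # 2.6 mm^2 basal area
  expect_lt(abs(s1$lateral_wall_height - 1.6) / 1.6, 0.01) # 1.6 mm wall height
})

test_that("centreline separates vertical and radial components", {
  # planar archimedean spiral: all z offsets zero
  th <- seq(0, 540, by = 10)
  xy <- cbind((2 + th / 360) * cos(th * pi / 180),
              (2 + th / 360) * sin(th * pi / 180))
  cl <- centreline_from_xy(xy)
  expect_lt(max(abs(cl$z_offset)), 1e-12)
  expect_true(all(diff(cl$theta) > 0))
  # circle of centroids: constant radius, uniform angular steps
  phc <- seq(0, 350, by = 10)
  circ <- cbind(4 + 2 * cos(phc * pi / 180), -1 + 2 * sin(phc * pi / 180))
  secs <- lapply(seq_len(nrow(circ)), function(i) {
    s <- make_section(cbind(circ[i, 1] + c(-0.01, 0.01, 0),
                            circ[i, 2] + c(-0.01, -0.01, 0.01), 0),
                      c(0, 0, 1), plane = xy_plane())
    s$centroid <- c(circ[i, ], 0)
    s
  })
  cl2 <- build_centreline(secs, xy_plane())
  r <- sqrt(rowSums(sweep(cl2$inplane, 2, cl2$centre)^2))
  expect_equal(max(r) - min(r), 0, tolerance = 1e-9)
  expect_equal(unname(diff(cl2$theta)), rep(10, length(phc) - 1), tolerance = 1e-9)
  # synthetic ST: theta strictly increasing past a full turn
  st <- st_fixture()
  cl3 <- build_centreline(sections_fixture(), gen_plane())
  expect_true(all(diff(cl3$theta) > 0))
  expect_gt(max(cl3$theta), 360)
})

test_that("spiral fit recovers exact model parameters", {
  xy <- spiral_points(4, 90, 360, centre = c(1, 2))
  fit <- fit_spiral(centreline_from_xy(xy))
  expect_equal(fit$R_scale, 4, tolerance = 1e-6)
  expect_equal(fit$theta1, 90, tolerance = 1e-6)
  expect_equal(fit$theta2, 360, tolerance = 1e-6)
  # the centre is reported in basal-plane basis coordinates
  centre_truth <- as.vector(crossprod(xy_plane()$basis, c(1, 2, 0)))
  expect_equal(fit$centre, centre_truth, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-7)
  expect_false(fit$degenerate)
  # fitted radius is strictly decreasing wherever theta1, theta2 > 0
  grid <- seq(0, 720, by = 1)
  expect_true(all(diff(predict(fit, grid)) < 0))
})

test_that("term exchange symmetry: swapped starts give the same optimum", {
  xy <- spiral_points(4, 90, 360, centre = c(0.5, -0.5))
  cl <- centreline_from_xy(xy)
  f1 <- fit_spiral(cl, starts_theta1 = c(45, 180), starts_theta2 = c(200, 720))
  f2 <- fit_spiral(cl, starts_theta1 = c(200, 720), starts_theta2 = c(45, 180))
  expect_equal(f1$theta1, f2$theta1, tolerance = 1e-6)
  expect_equal(f1$theta2, f2$theta2, tolerance = 1e-6)
  expect_lte(f1$theta1, f1$theta2)
})

test_that("constant-radius data degrades gracefully with a warning flag", {
  phc <- seq(0, 710, by = 10)
  circ <- cbind(3 * cos(phc * pi / 180), 3 * sin(phc * pi / 180))
  secs <- lapply(seq_len(nrow(circ)), function(i) {
    s <- make_section(cbind(circ[i, 1] + c(-0.01, 0.01, 0),
                            circ[i, 2] + c(-0.01, -0.01, 0.01), 0),
                      c(0, 0, 1), plane = xy_plane())
    s$centroid <- c(circ[i, ], 0)
    s
  })
  cl <- build_centreline(secs, xy_plane())
  expect_warning(fit <- fit_spiral(cl), "degenerate")
  expect_true(fit$degenerate)
  expect_true(is.finite(fit$rmse))
})

test_that("spiral scale is stable under micrometre radial noise", {
  set.seed(101)
  thetas <- seq(0, 720, by = 10)
  recov <- replicate(100, {
    r <- 4 * (exp(-thetas / 90) + exp(-thetas / 360)) + rnorm(length(thetas), 0, 0.01)
    xy <- cbind(r * cos(thetas * pi / 180), r * sin(thetas * pi / 180))
    fit_spiral(centreline_from_xy(xy),
               starts_theta1 = 90, starts_theta2 = 360)$R_scale
  })
  expect_lt(abs(mean(recov) - 4) / 4, 0.02)
})

test_that("angle-distance map matches the closed form on a circle", {
  r <- 2.5
  phc <- seq(0, 350, by = 10) * pi / 180
  lm <- landmark_set(cbind(r * cos(phc), r * sin(phc), 0))
  map <- build_angle_distance_map(lm, xy_plane(), centre = c(0, 0))
  knots <- map$knots
  chord_total <- max(knots$arc_distance)
  expect_equal(max(knots$theta), 350, tolerance = 1e-9)
  # theta(d) is linear on a circle: knot angles proportional to distances
  expect_equal(knots$theta, knots$arc_distance * 350 / chord_total,
               tolerance = 1e-9)
  expect_equal(distance_to_angle(map, 0), 0)
  expect_error(distance_to_angle(map, chord_total + 1), "range error")
  expect_error(angle_to_distance(map, -5), "range error")
})

test_that("map and inverse compose to the identity", {
  map <- map_fixture()
  d <- seq(0.5, 19.5, by = 0.5)
  expect_equal(angle_to_distance(map, distance_to_angle(map, d)), d,
               tolerance = 1e-9)
  expect_true(all(diff(distance_to_angle(map, d)) > 0))
})

test_that("synthetic map agrees with a fine-quadrature arc-length oracle", {
  st <- st_fixture()
  spec <- st$spec
  # oracle: cumulative chord length of the analytic landmark curve on a
  # 0.1-degree grid, rebuilt here from the spec parameters
  th <- seq(spec$landmark_inset, spec$total_angle - spec$apical_margin, by = 0.1)
  sfac <- 4 * gamma(1 + 1 / spec$superellipse_n)^2 / gamma(1 + 2 / spec$superellipse_n)
  off <- 0.5^(1 / spec$superellipse_n)
  R <- spec$R_scale * (exp(-th / spec$theta1) + exp(-th / spec$theta2))
  z <- spec$rise_total * th / spec$total_angle
  s <- c(0, cumsum(sqrt(diff(R * cos(th * pi / 180))^2 +
                        diff(R * sin(th * pi / 180))^2 + diff(z)^2)))
  for (it in 1:8) {
    k1 <- log(spec$area_at_1mm / spec$area_basal)
    k2 <- log(spec$area_at_20mm / spec$area_at_1mm) / 19
    A <- ifelse(s <= 1, spec$area_basal * exp(k1 * s),
                spec$area_at_1mm * exp(k2 * (s - 1)))
    b <- pmax(spec$lw_height_basal -
                (spec$lw_height_basal - spec$lw_height_at_20mm) / 20 * s, 0.4) / 2
    a <- A / (sfac * b)
    rl <- R + a * off; zl <- z + b * off
    s <- c(0, cumsum(sqrt(diff(rl * cos(th * pi / 180))^2 +
                          diff(rl * sin(th * pi / 180))^2 + diff(zl)^2)))
  }
  oracle_theta_at <- approxfun(s, th - th[1])
  map <- build_angle_distance_map(st$landmarks, gen_plane(), centre = c(0, 0))
  d <- seq(1, 20, by = 1)
  rel_err <- abs(distance_to_angle(map, d) - oracle_theta_at(d)) /
    oracle_theta_at(d)
  expect_lt(max(rel_err), 0.01)
})
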