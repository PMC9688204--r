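test_that("volumetric scaling hits the target ratio exactly", {
  st <- st_fixture()
  v0 <- mesh_volume(st$mesh)
  for (ratio in c(1.10, 0.90)) {
    scaled <- scale_volume(st$mesh, ratio)
    expect_equal(mesh_volume(scaled) / v0, ratio, tolerance = 1e-9)
    expect_equal(mesh_surface_area(scaled) / mesh_surface_area(st$mesh),
                 ratio^(2 / 3), tolerance = 1e-9)
  }
  ident <- scale_volume(st$mesh, 1.0)
  expect_lt(max(abs(ident$vertices - st$mesh$vertices)), 1e-12)
  cube <- make_cube_mesh()
  expect_equal(mesh_volume(scale_volume(cube, 0.9)), 0.9, tolerance = 1e-12)
  expect_error(scale_volume(cube, 0), "value error")
  expect_error(scale_volume(cube, -1), "value error")
})

test_that("volumetric scaling commutes with rigid motions", {
  cube <- make_cube_mesh()
  a <- 0.7
  rot <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  shift <- c(3, -2, 5)
  moved <- triangle_mesh(sweep(cube$vertices %*% t(rot), 2, shift, "+"), cube$faces)
  s1 <- scale_volume(moved, 1.25)
  s2 <- scale_volume(cube, 1.25)
  s2_moved <- sweep(s2$vertices %*% t(rot), 2, shift, "+")
  expect_lt(max(abs(s1$vertices - s2_moved)), 1e-9)
})

test_that("flattening zeroes centroid heights and keeps in-plane positions", {
  st <- st_fixture()
  fl <- flatten(st$stack)
  plane <- gen_plane()
  cts_fl <- t(vapply(fl$sections, function(s) s$centroid, numeric(3)))
  expect_lt(max(abs(plane_height(cts_fl, plane))), 1e-12)
  n_kept <- length(fl$sections)
  cts_orig <- t(vapply(st$stack$sections[seq_len(n_kept)],
                       function(s) s$centroid, numeric(3)))
  expect_lt(max(abs(cts_fl[, 1:2] - cts_orig[, 1:2])), 1e-9)
  # idempotent
  fl2 <- flatten(fl)
  expect_equal(length(fl2$sections), n_kept)
  expect_lt(max(abs(fl2$sections[[5]]$ring - fl$sections[[5]]$ring)), 1e-12)
  # an already-flat stack passes through unchanged
  tube <- make_tube_stack()
  tube_fl <- flatten(tube)
  expect_equal(length(tube_fl$sections), length(tube$sections))
})

test_that("flat-model truncation matches a brute-force overlap oracle", {
  st <- st_fixture()
  fl <- flatten(st$stack)
  kept_max <- max(vapply(fl$sections, function(s) s$theta, 0))
  # oracle: flatten all sections, project rings in-plane, and find the
  # first section whose radial interval reaches into the aligned section
  # one turn further out
  plane <- gen_plane()
  centre <- st$stack$spiral$centre
  th <- vapply(st$stack$sections, function(s) s$theta, 0)
  rint <- t(vapply(st$stack$sections, function(s) {
    q <- sweep(sweep(s$ring, 2, plane$origin) %*% plane$basis, 2, centre)
    range(sqrt(rowSums(q^2)))
  }, numeric(2)))
  first_overlap <- Inf
  for (j in seq_along(th)) {
    outer <- which(abs(th - (th[j] - 360)) <= max(diff(th)))
    if (length(outer) && any(rint[j, 2] >= rint[outer, 1])) {
      first_overlap <- th[j]
      break
    }
  }
  expect_lt(kept_max, first_overlap)
  expect_gte(first_overlap, kept_max) # truncated exactly at the boundary
  expect_equal(sum(th < first_overlap), length(fl$sections))
})

test_that("artificial non-planarity adds the exact sinusoid over its extent", {
  st <- st_fixture()
  fl <- flatten(st$stack)
  plane <- gen_plane()
  for (period in c(270, 135)) {
    np <- add_non_planarity(fl, 0.2, period)
    th <- vapply(np$sections, function(s) s$theta, 0)
    z <- plane_height(t(vapply(np$sections, function(s) s$centroid, numeric(3))), plane)
    target <- ifelse(th <= 270, 0.2 * sin(2 * pi * th / period), 0)
    expect_lt(max(abs(z - target)), 1e-12)
    # amplitude reached to within the angular sampling of the stack
    expect_equal(max(abs(z[th <= 270])), 0.2, tolerance = 2e-3)
    expect_true(all(abs(z[th > 270]) == 0))
    # in-plane positions untouched
    cts_np <- t(vapply(np$sections, function(s) s$centroid, numeric(3)))
    cts_fl <- t(vapply(fl$sections, function(s) s$centroid, numeric(3)))
    expect_lt(max(abs(cts_np[, 1:2] - cts_fl[, 1:2])), 1e-12)
  }
  expect_error(add_non_planarity(fl, -0.1, 270), "value error")
  # sinusoid must return to zero at the extent boundary
  expect_error(add_non_planarity(fl, 0.2, 200), "extent")
  # amplitude zero is the identity
  np0 <- add_non_planarity(fl, 0, 270)
  expect_lt(max(abs(np0$sections[[10]]$ring - fl$sections[[10]]$ring)), 1e-12)
})

test_that("curvature reshaping is the identity at multiplier one", {
  st <- st_fixture()
  rs <- reshape_curvature(st$stack, 1.0)
  dev <- max(vapply(seq_along(rs$sections), function(i) {
    max(abs(rs$sections[[i]]$ring - st$stack$sections[[i]]$ring))
  }, 0))
  expect_lt(dev, 1e-9)
})

test_that("loosening moves sections outward, tightening shortens the spiral", {
  st <- st_fixture()
  loose <- reshape_curvature(st$stack, 2.0)
  r_orig <- vapply(st$stack$sections, function(s) sqrt(sum(s$centroid[1:2]^2)), 0)
  r_loose <- vapply(loose$sections, function(s) sqrt(sum(s$centroid[1:2]^2)), 0)
  expect_true(all(r_loose[-1] >= r_orig[-1]))
  # tighter spiral: more unwrapped angle for the same lateral-wall arc
  tight <- reshape_curvature(st$stack, 0.5)
  arc_at <- function(stack, theta) {
    th <- vapply(stack$sections, function(s) s$theta, 0)
    arc <- vapply(stack$sections, function(s) s$arc_distance, 0)
    approx(arc, th, xout = theta)$y
  }
  expect_gt(arc_at(tight, 14), arc_at(st$stack, 14))
  # ring areas preserved under rigid transport (measured both ways, so
  # the analytic-vs-polygon discretisation offset cancels)
  a0 <- vapply(lapply(st$stack$sections, section_properties, plane = gen_plane()),
               function(s) s$area, 0)
  a1 <- vapply(lapply(tight$sections, section_properties, plane = gen_plane()),
               function(s) s$area, 0)
  expect_lt(max(abs(a1 - a0) / a0), 0.001)
  expect_error(reshape_curvature(st$stack, 0), "value error")
})

test_that("cross-section uniformisation transports the source ring rigidly", {
  # identity on a uniform tube
  tube <- make_tube_stack(radius = 1, length = 10, n_sections = 11)
  un_tube <- uniformise_cross_section(tube, 5)
  dev <- max(vapply(seq_along(tube$sections), function(i) {
    max(abs(un_tube$sections[[i]]$ring - tube$sections[[i]]$ring))
  }, 0))
  expect_lt(dev, 1e-3) # <= 1 um
  # synthetic ST: all areas become the source-section area
  st <- st_fixture()
  un <- uniformise_cross_section(st$stack, 1)
  areas <- vapply(lapply(un$sections, section_properties, plane = gen_plane()),
                  function(s) s$area, 0)
  expect_lt(diff(range(areas)) / mean(areas), 1e-9)
  arc <- vapply(st$stack$sections, function(s) s$arc_distance, 0)
  src <- section_properties(st$stack$sections[[which.min(abs(arc - 1))]],
                            gen_plane())
  expect_equal(mean(areas), src$area, tolerance = 1e-6)
  # centroids unchanged
  cts0 <- t(vapply(st$stack$sections, function(s) s$centroid, numeric(3)))
  cts1 <- t(vapply(un$sections, function(s) s$centroid, numeric(3)))
  expect_lt(max(abs(cts1 - cts0)), 1e-9)
  # idempotent
  un2 <- uniformise_cross_section(un, 1)
  expect_lt(max(abs(un2$sections[[30]]$ring - un$sections[[30]]$ring)), 1e-3)
  expect_error(uniformise_cross_section(st$stack, 100), "range error")
})
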