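# Shared fixtures, memoised so expensive geometry is built once per run.
.fx <- new.env(parent = emptyenv())

st_fixture <- function() {
  if (is.null(.fx$st)) .fx$st <- generate_st()
  .fx$st
}

# generator basal plane (z = 0), the fixture's known ground truth
gen_plane <- function() st_fixture()$stack$plane

# cross-sections of the fixture mesh at its landmarks, properties filled
sections_fixture <- function() {
  if (is.null(.fx$secs)) {
    st <- st_fixture()
    secs <- extract_cross_sections(st$mesh, st$landmarks)
    .fx$secs <- lapply(secs, section_properties, plane = gen_plane())
  }
  .fx$secs
}

map_fixture <- function() {
  if (is.null(.fx$map)) {
    .fx$map <- cochleaST:::.stack_angle_distance_map(st_fixture()$stack)
  }
  .fx$map
}

# landmark arc distances of the fixture
arc_fixture <- function() {
  pts <- st_fixture()$landmarks$points
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# --- primitive meshes built in code ------------------------------------

# axis-aligned unit cube with consistent outward winding
make_cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  triangle_mesh(v, f, name = "cube")
}

# closed right cylinder along +z
make_cylinder_mesh <- function(radius = 1, height = 1, n = 360) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  ring0 <- cbind(radius * cos(phi), radius * sin(phi), 0)
  ring1 <- cbind(radius * cos(phi), radius * sin(phi), height)
  v <- rbind(ring0, ring1, c(0, 0, 0), c(0, 0, height))
  jn <- function(j) (j - 1) %% n + 1
  j <- seq_len(n)
  side <- rbind(cbind(j, jn(j + 1), n + jn(j + 1)),
                cbind(j, n + jn(j + 1), n + j))
  cap0 <- cbind(2 * n + 1, jn(j + 1), j)
  cap1 <- cbind(2 * n + 2, n + j, n + jn(j + 1))
  triangle_mesh(v, rbind(side, cap0, cap1), name = "cylinder")
}

# torus around the z axis (centre-circle radius R, tube radius r)
make_torus_mesh <- function(R = 3, r = 0.5, nu = 72, nv = 24) {
  iu <- seq_len(nu) - 1
  iv <- seq_len(nv) - 1
  u <- 2 * pi * iu / nu
  v <- 2 * pi * iv / nv
  verts <- matrix(0, nu * nv, 3)
  for (i in seq_len(nu)) {
    cu <- cos(u[i]); su <- sin(u[i])
    verts[(i - 1) * nv + seq_len(nv), ] <-
      cbind((R + r * cos(v)) * cu, (R + r * cos(v)) * su, r * sin(v))
  }
  idx <- function(i, j) ((i - 1) %% nu) * nv + ((j - 1) %% nv) + 1
  faces <- NULL
  for (i in seq_len(nu)) {
    j <- seq_len(nv)
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  triangle_mesh(verts, faces, name = "torus")
}

# lat-long sphere
make_sphere_mesh <- function(radius = 1, nu = 96, nv = 48) {
  th <- pi * seq_len(nv - 1) / nv # latitudes, poles handled separately
  ph <- 2 * pi * (seq_len(nu) - 1) / nu
  verts <- NULL
  for (t in th) {
    verts <- rbind(verts, cbind(radius * sin(t) * cos(ph),
                                radius * sin(t) * sin(ph),
                                radius * cos(t)))
  }
  np <- nrow(verts)
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, -radius))
  top <- np + 1; bot <- np + 2
  idx <- function(i, j) (i - 1) * nu + ((j - 1) %% nu) + 1
  faces <- NULL
  j <- seq_len(nu)
  faces <- rbind(faces, cbind(top, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(nv - 2)) {
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  faces <- rbind(faces, cbind(bot, idx(nv - 1, j + 1), idx(nv - 1, j)))
  triangle_mesh(verts, faces, name = "sphere")
}

# minimal cross-section object for stack-level tests
make_section <- function(ring, normal, theta = NA_real_, arc = NA_real_,
                         plane = NULL) {
  ctr <- colMeans(ring)
  s <- structure(list(ring = ring, plane_origin = ctr, plane_normal = normal,
                      centroid = ctr, area = NULL, lateral_wall_height = NULL,
                      theta = theta, arc_distance = arc, lateral_index = 1L),
                 class = "cross_section")
  if (!is.null(plane)) s <- section_properties(s, plane)
  s
}

xy_plane <- function() {
  structure(list(origin = c(0, 0, 0), normal = c(0, 0, 1),
                 basis = cochleaST:::.plane_basis(c(0, 0, 1))),
            class = "basal_plane")
}

# straight tube along +x with circular rings (identity cases)
make_tube_stack <- function(radius = 1, length = 10, n_sections = 11,
                            ring_points = 60) {
  phi <- 2 * pi * (seq_len(ring_points) - 1) / ring_points
  xs <- seq(0, length, length.out = n_sections)
  secs <- lapply(seq_along(xs), function(i) {
    ring <- cbind(xs[i], radius * cos(phi), radius * sin(phi))
    make_section(ring, c(1, 0, 0), theta = NA_real_, arc = xs[i],
                 plane = xy_plane())
  })
  section_stack(secs, xy_plane())
}

# points exactly on the double-exponential spiral, for fit tests
spiral_points <- function(R_scale, theta1, theta2, centre = c(0, 0),
                          thetas = seq(0, 720, by = 5)) {
  r <- R_scale * (exp(-thetas / theta1) + exp(-thetas / theta2))
  cbind(centre[1] + r * cos(thetas * pi / 180),
        centre[2] + r * sin(thetas * pi / 180))
}

# centreline object from bare in-plane points (z = 0): tiny placeholder
# rings centred on the points, centroids set directly
centreline_from_xy <- function(xy) {
  secs <- lapply(seq_len(nrow(xy)), function(i) {
    ring <- cbind(xy[i, 1] + c(-0.01, 0.01, 0.01, -0.01),
                  xy[i, 2] + c(-0.01, -0.01, 0.01, 0.01),
                  0)
    s <- make_section(ring, c(0, 0, 1))
    s$centroid <- c(xy[i, ], 0)
    s
  })
  build_centreline(secs, xy_plane())
}

# independent R implementation of point-to-triangle distance (projection
# onto the plane, clamped to edges), used as the brute-force oracle
point_triangle_distance <- function(p, a, b, c_) {
  seg_dist <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    t <- min(1, max(0, t))
    sqrt(sum((p - (u + t * d))^2))
  }
  n <- cochleaST:::.cross3(b - a, c_ - a)
  nn <- sum(n * n)
  if (nn < 1e-30) return(min(seg_dist(p, a, b), seg_dist(p, b, c_), seg_dist(p, c_, a)))
  q <- p - sum((p - a) * n) / nn * n
  # barycentric coordinates of the projection
  v0 <- b - a; v1 <- c_ - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(sqrt(sum((p - q)^2)))
  min(seg_dist(p, a, b), seg_dist(p, b, c_), seg_dist(p, c_, a))
}

brute_force_nearest <- function(points, mesh) {
  apply(points, 1, function(p) {
    min(vapply(seq_len(nrow(mesh$faces)), function(i) {
      f <- mesh$faces[i, ]
      point_triangle_distance(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                              mesh$vertices[f[3], ])
    }, 0))
  })
}
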