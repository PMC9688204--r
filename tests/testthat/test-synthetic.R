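test_that("the default fixture reproduces the published anatomical anchors", {
  st <- st_fixture()
  expect_true(is_watertight(st$mesh))
  expect_equal(st$landmarks$count, 68L)
  secs <- sections_fixture()
  expect_lt(abs(secs[[1]]$area - 2.6) / 2.6, 0.01)
  # area and height profiles extracted from the mesh track the taper
  # within 1% over the insertion extent, sampled at the generator's own
  # section planes where the arc coordinate is exact
  spec <- st$spec
  k1 <- log(spec$area_at_1mm / spec$area_basal)
  k2 <- log(spec$area_at_20mm / spec$area_at_1mm) / 19
  sections <- st$stack$sections
  arc_s <- vapply(sections, function(s) s$arc_distance, 0)
  # every 4th section; the theta = 0 plane coincides with the basal end
  # cap, so start inside the lumen
  pick <- which(arc_s > 0.2 & arc_s <= 20)[c(TRUE, FALSE, FALSE, FALSE)]
  for (i in pick) {
    ring <- cochleaST:::.mesh_plane_section(st$mesh, sections[[i]]$plane_origin,
                                            sections[[i]]$plane_normal)
    meas <- section_properties(
      make_section(ring, sections[[i]]$plane_normal), gen_plane())
    s_i <- arc_s[i]
    a_target <- if (s_i <= 1) spec$area_basal * exp(k1 * s_i) else
      spec$area_at_1mm * exp(k2 * (s_i - 1))
    h_target <- spec$lw_height_basal -
      (spec$lw_height_basal - spec$lw_height_at_20mm) / 20 * s_i
    expect_lt(abs(meas$area - a_target) / a_target, 0.01)
    expect_lt(abs(meas$lateral_wall_height - h_target) / h_target, 0.01)
  }
})

test_that("a zero-rise specification yields a pre-flattened cochlea", {
  flat_st <- generate_st(synthetic_st_spec(rise_total = 0, section_spacing = 10,
                                           n_landmarks = 30))
  z <- vapply(flat_st$stack$sections, function(s) s$centroid[3], 0)
  expect_lt(max(abs(z)), 1e-12)
})

test_that("inconsistent taper anchors are rejected", {
  expect_error(synthetic_st_spec(area_basal = 1, area_at_1mm = 2), "validation error")
  expect_error(synthetic_st_spec(lw_height_basal = 0.5, lw_height_at_20mm = 0.9),
               "validation error")
  expect_error(synthetic_st_spec(theta2 = -1), "> 0")
})

test_that("characterisation round-trip recovers the generator spiral", {
  st <- st_fixture()
  cl <- build_centreline(sections_fixture(), gen_plane())
  fit <- fit_spiral(cl)
  expect_lt(abs(fit$R_scale - st$spec$R_scale) / st$spec$R_scale, 0.02)
  expect_lt(abs(fit$theta1 - st$spec$theta1) / st$spec$theta1, 0.02)
  expect_lt(abs(fit$theta2 - st$spec$theta2) / st$spec$theta2, 0.02)
})

test_that("the angle-distance map spans beyond one and a half turns at 20 mm", {
  map <- map_fixture()
  expect_true(all(diff(map$knots$theta) > 0))
  expect_true(all(diff(map$knots$arc_distance) > 0))
  expect_gt(distance_to_angle(map, 20), 540)
})

test_that("replicated force datasets share a backbone but differ in noise", {
  map <- map_fixture()
  models <- list(original = insertion_model())
  traces <- generate_force_dataset(models, map, n_reps = 10, seed = 42,
                                   max_distance = 15, noise_sd = 2)
  expect_length(traces, 10)
  backbone <- simulate_insertion(insertion_model(), map, max_distance = 15)
  res <- vapply(traces, function(tr) {
    expect_false(isTRUE(all.equal(tr$force_mN, backbone$force_mN)))
    mean(tr$force_mN - backbone$force_mN)
  }, 0)
  expect_lt(max(abs(res)), 0.5) # noise has mean ~0 around the backbone
  # identical master seed reproduces byte-identical CSV output
  t2 <- generate_force_dataset(models, map, n_reps = 10, seed = 42,
                               max_distance = 15, noise_sd = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_force_trace(traces[[3]], f1)
  write_force_trace(t2[[3]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("equal-coefficient conditions rarely test significant (type I control)", {
  map <- map_fixture()
  models <- list(a = insertion_model(), b = insertion_model())
  set.seed(9)
  seeds <- sample.int(1e6, 100)
  false_pos <- vapply(seeds, function(s) {
    traces <- generate_force_dataset(models, map, n_reps = 10, seed = s,
                                     max_distance = 15, noise_sd = 2)
    mu <- lapply(split(traces, vapply(traces, attr, "", "condition")),
                 function(grp) vapply(grp, function(tr) {
                   fit_capstan(tr, 10, 100)$mu_prime_hat
                 }, 0))
    compare_groups(mu)$anova_p < 0.05
  }, TRUE)
  expect_gte(mean(!false_pos), 0.95)
})
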