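# simple linear angle-distance map: landmarks on a circle of radius r
linear_map <- function(r = 2, span_deg = 700) {
  ph <- seq(0, span_deg, by = 5) * pi / 180
  lm <- landmark_set(cbind(r * cos(ph), r * sin(ph), seq(0, 1e-6, length.out = length(ph))))
  build_angle_distance_map(lm, xy_plane(), centre = c(0, 0))
}

test_that("capstan closed form: frictionless, doubling and extreme wraps", {
  expect_equal(capstan_load(7.3, 0, 12), 7.3)
  expect_equal(capstan_load(5, 0.1, log(2) / 0.1), 10, tolerance = 1e-12)
  # five full turns at mu = 0.7: a 1 kg hold supports millions of tonnes
  tonnes <- capstan_load(1, 0.7, 10 * pi) / 1000
  expect_gt(tonnes, 3.5e6)
  expect_lt(tonnes, 4e6)
  # multiplicativity in the wrap angle
  expect_equal(capstan_load(1, 0.3, 5),
               capstan_load(capstan_load(1, 0.3, 2), 0.3, 3), tolerance = 1e-12)
  expect_error(capstan_load(-1, 0.5, 1), "T2")
})

test_that("capstan model and per-degree coefficient agree under unit conversion", {
  m <- insertion_model(F_tip = 5, mu_prime = 0.008, contact_angle = 0)
  theta_deg <- 250
  via_model <- m$F_tip * exp(m$mu_prime * theta_deg)
  via_capstan <- capstan_load(m$F_tip, m$mu_prime * 180 / pi, theta_deg * pi / 180)
  expect_equal(via_model, via_capstan, tolerance = 1e-12)
})

test_that("simulated insertion follows the exponential force law exactly", {
  map <- linear_map()
  m0 <- insertion_model(F_tip = 3, mu_prime = 0, contact_angle = 100)
  tr0 <- simulate_insertion(m0, map, max_distance = 15)
  ins <- tr0[tr0$phase == "insert", ]
  expect_true(all(ins$force_mN[ins$angle_deg < 100] == 0))
  expect_true(all(ins$force_mN[ins$angle_deg >= 100] == 3))
  # closed-form force at full insertion
  m <- insertion_model(F_tip = 3, mu_prime = 0.008, contact_angle = 100)
  d400 <- angle_to_distance(map, 400)
  tr <- simulate_insertion(m, map, max_distance = d400)
  f_end <- tail(tr$force_mN[tr$phase == "insert"], 1)
  expect_equal(f_end, 3 * exp(0.008 * 300), tolerance = 1e-9)
})

test_that("trace simulation is deterministic under a fixed seed", {
  map <- linear_map()
  m <- insertion_model()
  t1 <- simulate_insertion(m, map, noise_sd = 2, seed = 99)
  t2 <- simulate_insertion(m, map, noise_sd = 2, seed = 99)
  expect_identical(t1$force_mN, t2$force_mN)
  t3 <- simulate_insertion(m, map, noise_sd = 2, seed = 100)
  expect_false(identical(t1$force_mN, t3$force_mN))
  expect_error(simulate_insertion(m, map, max_distance = 1000), "range error")
})

test_that("trace phases respect the commanded kinematics", {
  map <- linear_map()
  tr <- simulate_insertion(insertion_model(), map, speed = 0.5, max_distance = 10,
                           hold_s = 5)
  expect_true(all(diff(tr$time_s) > 0))
  ins <- tr[tr$phase == "insert", ]
  expect_true(all(diff(ins$distance_mm) >= 0))
  expect_equal(max(ins$distance_mm), 10)
  expect_equal(max(ins$time_s), 20) # 10 mm at 0.5 mm/s
  expect_equal(sum(tr$phase == "hold") * 0.05, 5, tolerance = 0.05)
  ret <- tr[tr$phase == "retract", ]
  expect_true(all(diff(ret$distance_mm) <= 0))
})

test_that("fixed-intercept exponential fit inverts the noiseless simulator", {
  map <- linear_map()
  m <- insertion_model(F_tip = 10, mu_prime = 0.008, contact_angle = 100)
  tr <- simulate_insertion(m, map, max_distance = 15)
  fit <- fit_capstan(tr, 10, 100)
  expect_lt(abs(fit$mu_prime_hat - 0.008), 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-12)
  expect_equal(fit$n_points, sum(tr$phase == "insert" & tr$angle_deg > 100))
  # constant forces give a zero coefficient
  flat <- data.frame(time_s = 1:20, distance_mm = 1:20, angle_deg = seq(110, 300, by = 10),
                     force_mN = 10, phase = "insert")
  expect_equal(fit_capstan(flat, 10, 100)$mu_prime_hat, 0)
  # error paths
  short <- flat[1:5, ]
  expect_error(fit_capstan(short, 10, 100), "fewer than 10")
  neg <- flat; neg$force_mN[3] <- -1
  expect_error(fit_capstan(neg, 10, 100), "transform error")
})

test_that("the exponential coefficient is recovered without bias from noisy traces", {
  map <- linear_map()
  m <- insertion_model(F_tip = 10, mu_prime = 0.008, contact_angle = 100)
  set.seed(2024)
  seeds <- sample.int(1e6, 100)
  mu_hat <- vapply(seeds, function(s) {
    tr <- simulate_insertion(m, map, max_distance = 15, noise_sd = 2, seed = s)
    fit_capstan(tr, 10, 100)$mu_prime_hat
  }, 0)
  expect_lt(abs(mean(mu_hat) - 0.008) / 0.008, 0.02)
  expect_lt(sd(mu_hat) / 0.008, 0.05)
})

test_that("the fit is invariant to how the trace is sampled in distance", {
  map <- linear_map()
  m <- insertion_model(F_tip = 10, mu_prime = 0.008, contact_angle = 100)
  tr <- simulate_insertion(m, map, max_distance = 15)
  ins <- tr[tr$phase == "insert", ]
  # irregular subsample in distance; angles still come from the same map
  set.seed(5)
  keep <- sort(sample(which(ins$angle_deg > 100), 60))
  sub <- ins[keep, ]
  f1 <- fit_capstan(ins, 10, 100)$mu_prime_hat
  f2 <- fit_capstan(sub, 10, 100)$mu_prime_hat
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("relaxation ratio closes the simulate-measure loop", {
  map <- linear_map()
  tr <- simulate_insertion(insertion_model(), map, max_distance = 15)
  expect_equal(relaxation_ratio(tr), 0.69, tolerance = 1e-12)
  # constant-force hold gives 1
  const <- data.frame(time_s = 1:20, distance_mm = c(1:10, rep(10, 10)),
                      angle_deg = 1, force_mN = 5,
                      phase = rep(c("insert", "hold"), each = 10))
  expect_equal(relaxation_ratio(const), 1.0)
  no_hold <- const[const$phase == "insert", ]
  expect_error(relaxation_ratio(no_hold), "hold")
  zero <- const; zero$force_mN <- 0
  expect_error(relaxation_ratio(zero), "zero maximum")
})

test_that("group comparison flags only real differences in mu prime", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  cmp <- compare_groups(same)
  expect_gt(cmp$anova_p, 0.99)
  expect_false(any(cmp$pairs$significant))
  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(compare_groups(list(a = c(1, 2))), "at least 2")
})

test_that("a doubled coefficient is detected in almost every replicate", {
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    g <- list(a = rnorm(10, 0.008, 1e-4), b = rnorm(10, 0.016, 1e-4))
    any(compare_groups(g)$pairs$significant)
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("pairwise p-values agree with a permutation-test oracle", {
  set.seed(77)
  g <- list(a = rnorm(10, 0.008, 1e-3), b = rnorm(10, 0.0085, 1e-3),
            c = rnorm(10, 0.015, 1e-3))
  cmp <- compare_groups(g)
  perm_p <- function(x, y, n_perm = 10000) {
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    hits <- vapply(seq_len(n_perm), function(i) {
      idx <- sample(length(pool), length(x))
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
    }, TRUE)
    mean(hits)
  }
  p_ab <- perm_p(g$a, g$b)
  row_ab <- cmp$pairs[cmp$pairs$pair == "b-a", ]
  expect_lt(abs(row_ab$p_raw - p_ab), 0.05) # null-ish pair: p-values agree
  p_ac <- perm_p(g$a, g$c)
  row_ac <- cmp$pairs[cmp$pairs$pair == "c-a", ]
  expect_lt(p_ac, 0.01)
  expect_lt(row_ac$p_raw, 0.01)
  expect_true(row_ac$significant)
  expect_false(row_ab$significant)
})

test_that("force traces round-trip through CSV", {
  map <- linear_map()
  tr <- simulate_insertion(insertion_model(), map, max_distance = 12,
                           noise_sd = 1, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_trace(tr, path)
  back <- read_force_trace(path)
  expect_equal(back$force_mN, tr$force_mN, tolerance = 1e-9)
  expect_equal(back$phase, tr$phase)
})
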