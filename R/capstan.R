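#' Capstan load amplification
#'
#' Closed form of the classical Capstan (belt-friction) problem: the pull
#' `T1` needed to slide a flexible line held with restraining load `T2`
#' around a curved rigid surface grows exponentially with the product of
#' the friction coefficient and the wrap angle, `T1 = T2 * exp(mu * theta)`.
#' With mu = 0.7 (roughly steel on steel) and five full wraps, a 1 kg
#' hold supports several million tonnes.
#'
#' @param T2 restraining load (any unit; `T1` is returned in the same).
#' @param mu coefficient of friction (>= 0, dimensionless).
#' @param theta_wrap contact (wrap) angle in radians (>= 0).
#' @return the amplified load `T1`.
#' @examples
#' capstan_load(1, 0.7, 10 * pi) / 1000 # 1 kg held vs tonnes pulled
#' @export
capstan_load <- function(T2, mu, theta_wrap) {
  if (any(T2 <= 0)) stop("T2 must be > 0")
  if (any(mu < 0)) stop("mu must be >= 0")
  if (any(theta_wrap < 0)) stop("theta_wrap must be >= 0")
  T2 * exp(mu * theta_wrap)
}

#' Exponential insertion-force model
#'
#' Parameters of the Capstan-type model of cochlear-implant insertion:
#' after the electrode first contacts the lateral wall at
#' `contact_angle` degrees of angular depth, the force on the implant
#' grows as `F(theta) = F_tip * exp(mu_prime * (theta - contact_angle))`.
#' `F_tip` is the tip-bending force at first contact; `mu_prime` (per
#' degree) is linearly related to the friction coefficient but folds in
#' surface roughness and the spiral geometry.
#'
#' @param F_tip tip force in mN (> 0).
#' @param mu_prime exponential coefficient per degree (>= 0).
#' @param contact_angle angular depth of first lateral-wall contact,
#'   degrees from the round window (>= 0).
#' @return object of class `insertion_model`.
#' @export
insertion_model <- function(F_tip = 10, mu_prime = 0.008, contact_angle = 100) {
  if (F_tip <= 0) stop("F_tip must be > 0")
  if (mu_prime < 0) stop("mu_prime must be >= 0")
  if (contact_angle < 0) stop("contact_angle must be >= 0")
  structure(list(F_tip = F_tip, mu_prime = mu_prime, contact_angle = contact_angle),
            class = "insertion_model")
}

#' @export
print.insertion_model <- function(x, ...) {
  cat(sprintf("insertion_model: F_tip %.2f mN, mu' %.4g /deg, contact at %.0f deg\n",
              x$F_tip, x$mu_prime, x$contact_angle))
  invisible(x)
}

# noiseless insertion force at angular depth theta (deg)
.insertion_force <- function(model, theta) {
  ifelse(theta < model$contact_angle, 0,
         model$F_tip * exp(model$mu_prime * (theta - model$contact_angle)))
}

#' Simulate a cochlear-implant insertion force trace
#'
#' Emulates a motorised insertion experiment: constant-speed insertion to
#' `max_distance`, a hold at maximum insertion, and retraction at the
#' same speed. During insertion the force follows the exponential Capstan
#' model (zero before lateral-wall contact) plus i.i.d. Gaussian noise.
#' The hold phase decays exponentially from the final insertion force to
#' `relaxation_ratio` times it (reaching the target exactly at the end of
#' the hold), reproducing the stress-relaxation ratio observed when a
#' flexible electrode is held at depth; the retraction force is the
#' insertion profile scaled by the same ratio. Hold and retraction shapes
#' are phenomenological conveniences of the simulator, not model claims.
#'
#' @param model an [insertion_model()].
#' @param map an `angle_distance_map` for the target geometry.
#' @param speed insertion speed in mm/s (default 0.5).
#' @param max_distance insertion depth from the basal opening in mm
#'   (default 20; must be within the map range).
#' @param hold_s hold duration at maximum insertion in s (default 5).
#' @param noise_sd force noise standard deviation in mN (default 0).
#' @param relaxation_ratio end-of-hold force as a fraction of the
#'   maximum insertion force (default 0.69).
#' @param seed RNG seed; same seed, same trace.
#' @param dt sampling interval in s (default 0.05).
#' @return a `force_trace` data frame with columns `time_s`,
#'   `distance_mm`, `angle_deg`, `force_mN`, `phase`.
#' @export
simulate_insertion <- function(model, map, speed = 0.5, max_distance = 20,
                               hold_s = 5, noise_sd = 0,
                               relaxation_ratio = 0.69, seed = NULL, dt = 0.05) {
  stopifnot(inherits(model, "insertion_model"), inherits(map, "angle_distance_map"))
  rng <- range(map$knots$arc_distance)
  if (max_distance > rng[2] + 1e-9) {
    stop(sprintf("range error: max_distance %.2f mm beyond map range %.2f mm",
                 max_distance, rng[2]))
  }
  if (!is.null(seed)) set.seed(seed)
  t_ins <- max_distance / speed
  times_ins <- unique(c(seq(0, t_ins, by = dt), t_ins))
  d_ins <- pmin(times_ins * speed, max_distance)
  th_ins <- distance_to_angle(map, d_ins)
  f_ins <- .insertion_force(model, th_ins)
  f_end <- f_ins[length(f_ins)]
  f_max <- max(f_ins)
  f_relax <- relaxation_ratio * f_max
  times_hold <- seq(dt, hold_s, by = dt)
  if (abs(times_hold[length(times_hold)] - hold_s) > 1e-9) times_hold <- c(times_hold, hold_s)
  k <- 5 # decay rate in hold-lengths; shifted so the target is hit exactly
  decay <- (exp(-k * times_hold / hold_s) - exp(-k)) / (1 - exp(-k))
  f_hold <- f_relax + (f_end - f_relax) * decay
  times_ret <- seq(dt, t_ins, by = dt)
  if (abs(times_ret[length(times_ret)] - t_ins) > 1e-9) times_ret <- c(times_ret, t_ins)
  d_ret <- pmax(max_distance - times_ret * speed, 0)
  th_ret <- distance_to_angle(map, d_ret)
  f_ret <- relaxation_ratio * .insertion_force(model, th_ret)
  n_all <- length(times_ins) + length(times_hold) + length(times_ret)
  noise <- if (noise_sd > 0) rnorm(n_all, 0, noise_sd) else numeric(n_all)
  df <- data.frame(
    time_s = c(times_ins, t_ins + times_hold, t_ins + hold_s + times_ret),
    distance_mm = c(d_ins, rep(max_distance, length(times_hold)), d_ret),
    angle_deg = c(th_ins, rep(th_ins[length(th_ins)], length(times_hold)), th_ret),
    force_mN = c(f_ins, f_hold, f_ret) + noise,
    phase = c(rep("insert", length(times_ins)), rep("hold", length(times_hold)),
              rep("retract", length(times_ret))),
    stringsAsFactors = FALSE)
  structure(df, class = c("force_trace", "data.frame"),
            axis = "implant_axial", model = model,
            params = list(speed = speed, max_distance = max_distance,
                          hold_s = hold_s, noise_sd = noise_sd,
                          relaxation_ratio = relaxation_ratio, dt = dt))
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace: %d samples (%s axis), %.1f mm / %.0f deg max, peak %.1f mN\n",
              nrow(x), attr(x, "axis"), max(x$distance_mm), max(x$angle_deg),
              max(x$force_mN)))
  invisible(x)
}

#' @export
plot.force_trace <- function(x, against = c("angle", "distance", "time"), ...) {
  against <- match.arg(against)
  xv <- switch(against, angle = x$angle_deg, distance = x$distance_mm, time = x$time_s)
  xl <- switch(against, angle = "angular depth (deg)",
               distance = "insertion distance (mm)", time = "time (s)")
  ins <- x$phase == "insert"
  plot(xv[ins], x$force_mN[ins], type = "l", xlab = xl, ylab = "force (mN)",
       main = "Insertion force", ...)
  invisible(x)
}

#' Write / read force traces as CSV
#'
#' @param trace a `force_trace`.
#' @param path CSV path (`time_s,distance_mm,angle_deg,force_mN,phase`).
#' @return `path` (write) or a `force_trace` (read).
#' @export
write_force_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_trace
#' @export
read_force_trace <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "distance_mm", "angle_deg", "force_mN", "phase")
  if (!all(need %in% names(df))) stop("parse error: missing force-trace columns")
  structure(df[need], class = c("force_trace", "data.frame"), axis = "implant_axial")
}

#' Fit the Capstan exponential to an insertion-force trace
#'
#' With the tip force fixed (the tip force at first lateral-wall contact
#' is very similar across insertions of one experiment), the only free
#' parameter is the exponential coefficient: `mu_prime` is estimated by
#' least squares of `log(force) - log(F_tip)` on
#' `theta - contact_angle` with zero intercept, over the insertion-phase
#' samples from contact to maximum insertion. The goodness of fit `r2` is
#' reported on the linear (force) scale.
#'
#' @param trace a `force_trace`.
#' @param F_tip_fixed fixed tip force in mN.
#' @param contact_angle first-contact angle in degrees.
#' @return object of class `capstan_fit`: `mu_prime_hat` (per degree),
#'   `F_tip_fixed`, `fit_window` (deg), `r_squared`, `n_points`.
#' @export
fit_capstan <- function(trace, F_tip_fixed, contact_angle) {
  stopifnot(is.data.frame(trace))
  ins <- trace[trace$phase == "insert" & trace$angle_deg > contact_angle, , drop = FALSE]
  if (nrow(ins) < 10) stop("error: fewer than 10 insertion samples beyond the contact angle")
  if (any(ins$force_mN <= 0)) {
    stop("transform error: non-positive forces in the fit window")
  }
  x <- ins$angle_deg - contact_angle
  y <- log(ins$force_mN) - log(F_tip_fixed)
  mu_hat <- sum(x * y) / sum(x^2)
  fitted <- F_tip_fixed * exp(mu_hat * x)
  ss_res <- sum((ins$force_mN - fitted)^2)
  ss_tot <- sum((ins$force_mN - mean(ins$force_mN))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(mu_prime_hat = mu_hat, F_tip_fixed = F_tip_fixed,
                 contact_angle = contact_angle,
                 fit_window = c(min(ins$angle_deg), max(ins$angle_deg)),
                 r_squared = r2, n_points = nrow(ins),
                 data = data.frame(theta = ins$angle_deg, force = ins$force_mN),
                 fitted = fitted),
            class = "capstan_fit")
}

#' @export
print.capstan_fit <- function(x, digits = 4, ...) {
  cat("Capstan insertion-force fit  F(theta) = F_tip exp(mu' (theta - contact))\n")
  cat(sprintf("  mu' = %.*g /deg (F_tip fixed at %.3g mN, contact %.0f deg)\n",
              digits, x$mu_prime_hat, x$F_tip_fixed, x$contact_angle))
  cat(sprintf("  window %.0f-%.0f deg, n = %d, r^2 = %.4f\n",
              x$fit_window[1], x$fit_window[2], x$n_points, x$r_squared))
  invisible(x)
}

#' @export
coef.capstan_fit <- function(object, ...) {
  c(mu_prime = object$mu_prime_hat, F_tip = object$F_tip_fixed,
    contact_angle = object$contact_angle)
}

#' @export
summary.capstan_fit <- function(object, ...) {
  res <- object$data$force - object$fitted
  structure(list(coef = coef(object), r_squared = object$r_squared,
                 n = object$n_points, sigma = sd(res)),
            class = "summary.capstan_fit")
}

#' @export
print.summary.capstan_fit <- function(x, ...) {
  cat("capstan_fit summary\n")
  print(x$coef)
  cat(sprintf("r^2 = %.4f, residual sd = %.3g mN, n = %d\n", x$r_squared, x$sigma, x$n))
  invisible(x)
}

#' Predict insertion force at angular depths
#' @param object a `capstan_fit`.
#' @param theta angular depths in degrees.
#' @param ... unused.
#' @return forces in mN (0 before contact).
#' @export
predict.capstan_fit <- function(object, theta = object$data$theta, ...) {
  ifelse(theta < object$contact_angle, 0,
         object$F_tip_fixed * exp(object$mu_prime_hat * (theta - object$contact_angle)))
}

#' @export
residuals.capstan_fit <- function(object, ...) object$data$force - object$fitted

#' @export
plot.capstan_fit <- function(x, ...) {
  plot(x$data$theta, x$data$force, xlab = "angular depth (deg)",
       ylab = "force (mN)", main = "Capstan fit", ...)
  ths <- seq(x$fit_window[1], x$fit_window[2], length.out = 200)
  lines(ths, predict(x, ths), col = 2, lwd = 2)
  invisible(x)
}

#' Force relaxation ratio of a trace
#'
#' Ratio of the force at the end of the hold phase to the maximum force
#' during insertion - a measure of the elastic stress stored in the
#' implant relaxing while it is held at depth.
#'
#' @param trace a `force_trace` with insert and hold phases.
#' @return dimensionless ratio.
#' @export
relaxation_ratio <- function(trace) {
  stopifnot(is.data.frame(trace))
  ins <- trace$force_mN[trace$phase == "insert"]
  hold <- trace$force_mN[trace$phase == "hold"]
  if (length(hold) == 0) stop("error: trace has no hold phase")
  if (length(ins) == 0) stop("error: trace has no insert phase")
  fmax <- max(ins)
  if (fmax <= 0) stop("error: zero maximum insertion force; ratio undefined")
  hold[length(hold)] / fmax
}

#' Compare exponential coefficients across conditions
#'
#' One-way ANOVA of the fitted `mu_prime` values across condition groups,
#' followed by Tukey honest-significant-difference pairwise comparisons,
#' flagged at alpha = 0.05.
#'
#' @param fits named list: condition label -> numeric vector of
#'   `mu_prime` estimates (or of `capstan_fit` objects).
#' @param alpha significance level (default 0.05).
#' @return object of class `capstan_comparison`: `anova_p`, `anova_F`,
#'   `groups` (means, sd, n), `pairs` (difference, adjusted p,
#'   significance flag).
#' @export
compare_groups <- function(fits, alpha = 0.05) {
  if (length(fits) < 2) stop("need at least 2 groups")
  vals <- lapply(fits, function(g) {
    if (is.list(g)) vapply(g, function(f) f$mu_prime_hat, 0) else as.numeric(g)
  })
  n <- lengths(vals)
  if (any(n < 2)) stop("error: every group needs n >= 2")
  df <- data.frame(mu = unlist(vals, use.names = FALSE),
                   condition = factor(rep(names(vals), n), levels = names(vals)))
  fit <- aov(mu ~ condition, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$condition
  # unadjusted pairwise Welch p-values alongside the Tukey-adjusted ones
  labs <- strsplit(rownames(tk), "-", fixed = TRUE)
  p_raw <- vapply(labs, function(l) {
    tryCatch(stats::t.test(vals[[l[1]]], vals[[l[2]]])$p.value,
             error = function(e) NA_real_) # e.g. identical noiseless fits
  }, 0)
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_raw = p_raw, p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
  groups <- data.frame(condition = names(vals),
                       mean = vapply(vals, mean, 0),
                       sd = vapply(vals, sd, 0), n = as.integer(n),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 alpha = alpha, groups = groups, pairs = pairs),
            class = "capstan_comparison")
}

#' @export
print.capstan_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA of mu': F = %.3f, p = %.4g (alpha = %g)\n",
              x$anova_F, x$anova_p, x$alpha))
  print(x$groups, digits = 4)
  cat("Tukey pairwise comparisons:\n")
  print(x$pairs, digits = 4)
  invisible(x)
}
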