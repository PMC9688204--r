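#' Experiment configuration
#'
#' Describes a full in-silico insertion experiment: the fixture cochlea,
#' the shape-manipulation conditions, and the insertion/force-model
#' parameters. Constrained conditions (the smaller or tighter-spiral
#' models, where a full insertion would risk the implant) use a 17 mm
#' depth; all others 20 mm. If a manipulated geometry cannot accommodate
#' the requested depth (a flattened spiral truncates where its turns
#' would collide), the depth is clamped to the available lateral-wall
#' arc and the clamp is recorded in the report.
#'
#' @param spec a [synthetic_st_spec()] for the fixture cochlea.
#' @param conditions named list: label -> `NULL` (original geometry) or a
#'   [manipulation_spec()].
#' @param model an [insertion_model()] shared by all conditions, or a
#'   named list per condition.
#' @param max_distance named numeric vector of insertion depths (mm);
#'   conditions absent from it default to `default_distance`.
#' @param default_distance default insertion depth (mm).
#' @param n_reps insertion replicates per condition.
#' @param noise_sd force noise sd (mN).
#' @param seed master seed; all randomness derives from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(spec = synthetic_st_spec(),
                              conditions = default_conditions(),
                              model = insertion_model(),
                              max_distance = c(small = 17, tight = 17),
                              default_distance = 20,
                              n_reps = 10, noise_sd = 2, seed = 1) {
  if (length(conditions) == 0) stop("error: empty condition list")
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("conditions must be named")
  }
  structure(list(spec = spec, conditions = conditions, model = model,
                 max_distance = max_distance, default_distance = default_distance,
                 n_reps = n_reps, noise_sd = noise_sd, seed = seed),
            class = "experiment_config")
}

#' Default shape-manipulation conditions
#'
#' The nine-condition suite: original; 110%/90% volumetric scaling
#' (large/small); flattened vertical trajectory; two artificial
#' non-planarity conditions (0.2 mm amplitude, 270 / 135 degree period);
#' loosened / tightened spiral curvature (theta2 doubled / halved); and
#' the uniform cross-section model built from the section 1 mm from the
#' basal opening.
#'
#' @return named list of [manipulation_spec()] (NULL for `original`).
#' @export
default_conditions <- function() {
  list(
    original = NULL,
    large = manipulation_spec("volume_scale", volume_ratio = 1.10),
    small = manipulation_spec("volume_scale", volume_ratio = 0.90),
    flat = manipulation_spec("flatten"),
    np1 = manipulation_spec("non_planarity", np_amplitude = 0.2, np_period = 270),
    np2 = manipulation_spec("non_planarity", np_amplitude = 0.2, np_period = 135),
    loose = manipulation_spec("curvature", theta2_multiplier = 2),
    tight = manipulation_spec("curvature", theta2_multiplier = 0.5),
    uniform = manipulation_spec("uniform_cs", uniform_cs_source_depth = 1))
}

#' Run the full in-silico insertion experiment
#'
#' For every condition: manipulate the fixture geometry, derive its
#' angle-distance map, simulate `n_reps` noisy insertions, and fit the
#' Capstan exponential to each; then compare the fitted `mu_prime`
#' coefficients across conditions (one-way ANOVA + Tukey pairwise).
#' Optionally writes a report bundle (JSON summary, per-trace CSVs,
#' noiseless force-vs-distance/angle profiles, and PNG figures).
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory for the report bundle (NULL: no files).
#' @param write_meshes also write each condition's manipulated mesh as STL.
#' @param plots write PNG figures (force vs distance/angle).
#' @return object of class `st_experiment`: per-condition results
#'   (`map`, `max_distance`, `traces`, `fits`, `mu_prime`), the
#'   `comparison`, and noiseless `profiles`.
#' @export
run_experiment <- function(config, out_dir = NULL, write_meshes = FALSE,
                           plots = !is.null(out_dir)) {
  stopifnot(inherits(config, "experiment_config"))
  st <- generate_st(config$spec)
  char <- characterise_st(st$mesh, st$landmarks)
  conds <- list()
  for (label in names(config$conditions)) {
    mspec <- config$conditions[[label]]
    cond <- list(label = label, manipulation = mspec)
    if (is.null(mspec)) {
      cond$stack <- st$stack
      cond$map <- .stack_angle_distance_map(st$stack)
    } else if (mspec$kind == "volume_scale") {
      mesh2 <- scale_volume(st$mesh, mspec$volume_ratio)
      s <- attr(mesh2, "linear_factor")
      ctr <- attr(mesh2, "scale_centre")
      lm2 <- landmark_set(sweep(sweep(st$landmarks$points, 2, ctr) * s, 2, ctr, "+"))
      cond$mesh <- mesh2
      char2 <- characterise_st(mesh2, lm2)
      cond$stack <- char2$stack
      cond$map <- char2$map
    } else {
      cond$stack <- apply_manipulation(st$stack, mspec)
      cond$map <- .stack_angle_distance_map(cond$stack)
    }
    req <- if (label %in% names(config$max_distance)) {
      config$max_distance[[label]]
    } else {
      config$default_distance
    }
    avail <- max(cond$map$knots$arc_distance)
    cond$max_distance <- min(req, floor(avail * 10) / 10)
    cond$clamped <- cond$max_distance < req
    conds[[label]] <- cond
  }
  models <- lapply(conds, function(cond) {
    if (inherits(config$model, "insertion_model")) config$model else config$model[[cond$label]]
  })
  names(models) <- names(conds)
  traces <- generate_force_dataset(
    models, lapply(conds, function(c) c$map),
    n_reps = config$n_reps, seed = config$seed,
    max_distance = vapply(conds, function(c) c$max_distance, 0),
    noise_sd = config$noise_sd)
  fits <- list()
  for (label in names(conds)) {
    m <- models[[label]]
    cond_traces <- traces[vapply(traces, function(t) attr(t, "condition"), "") == label]
    conds[[label]]$traces <- cond_traces
    conds[[label]]$fits <- lapply(cond_traces, fit_capstan,
                                  F_tip_fixed = m$F_tip,
                                  contact_angle = m$contact_angle)
    conds[[label]]$mu_prime <- vapply(conds[[label]]$fits,
                                      function(f) f$mu_prime_hat, 0)
    fits[[label]] <- conds[[label]]$mu_prime
  }
  comparison <- compare_groups(fits)
  profiles <- lapply(conds, function(cond) {
    m <- models[[cond$label]]
    d <- seq(0, cond$max_distance, by = 0.1)
    th <- distance_to_angle(cond$map, d)
    data.frame(condition = cond$label, distance_mm = d, angle_deg = th,
               force_mN = .insertion_force(m, th))
  })
  result <- structure(list(conditions = conds, comparison = comparison,
                           profiles = profiles, characterisation = char,
                           config = config),
                      class = "st_experiment")
  if (!is.null(out_dir)) {
    .write_experiment(result, st, out_dir, write_meshes = write_meshes, plots = plots)
  }
  result
}

#' @export
print.st_experiment <- function(x, ...) {
  cat(sprintf("st_experiment: %d conditions x %d insertions\n",
              length(x$conditions), x$config$n_reps))
  mu <- vapply(x$conditions, function(c) mean(c$mu_prime), 0)
  for (label in names(x$conditions)) {
    c <- x$conditions[[label]]
    cat(sprintf("  %-9s mu' = %.5f /deg (depth %.1f mm%s)\n", label, mu[label],
                c$max_distance, if (isTRUE(c$clamped)) ", clamped" else ""))
  }
  cat(sprintf("ANOVA across conditions: p = %.4g\n", x$comparison$anova_p))
  invisible(x)
}

.write_experiment <- function(result, st, out_dir, write_meshes = FALSE, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_characterisation(result$characterisation, file.path(out_dir, "characterisation"))
  write_landmarks(st$landmarks, file.path(out_dir, "landmarks.csv"))
  for (label in names(result$conditions)) {
    cond <- result$conditions[[label]]
    cdir <- file.path(out_dir, label)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(cond$traces)) {
      write_force_trace(cond$traces[[nm]], file.path(cdir, paste0(nm, ".csv")))
    }
    write.csv(result$profiles[[label]], file.path(cdir, "profile_noiseless.csv"),
              row.names = FALSE)
    if (write_meshes) {
      mesh <- if (!is.null(cond$mesh)) cond$mesh else loft(cond$stack, name = label)
      write_mesh(mesh, file.path(cdir, paste0(label, ".stl")))
    }
  }
  summary_js <- list(
    seed = result$config$seed,
    n_reps = result$config$n_reps,
    noise_sd_mN = result$config$noise_sd,
    conditions = lapply(result$conditions, function(cond) {
      list(max_distance_mm = cond$max_distance, clamped = cond$clamped,
           mu_prime_mean = mean(cond$mu_prime), mu_prime_sd = sd(cond$mu_prime))
    }),
    anova_p = result$comparison$anova_p,
    pairs = result$comparison$pairs)
  jsonlite::write_json(summary_js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (plots) {
    cols <- seq_along(result$profiles)
    png(file.path(out_dir, "force_profiles.png"), width = 1200, height = 500)
    par(mfrow = c(1, 2))
    for (mode in c("distance_mm", "angle_deg")) {
      xl <- if (mode == "distance_mm") "insertion distance (mm)" else "angular depth (deg)"
      xmax <- max(vapply(result$profiles, function(p) max(p[[mode]]), 0))
      ymax <- max(vapply(result$profiles, function(p) max(p$force_mN), 0))
      plot(NA, xlim = c(0, xmax), ylim = c(0, ymax), xlab = xl, ylab = "force (mN)",
           main = sprintf("Noiseless force vs %s", xl))
      for (i in cols) {
        lines(result$profiles[[i]][[mode]], result$profiles[[i]]$force_mN, col = i)
      }
      legend("topleft", legend = names(result$profiles), col = cols, lty = 1, cex = 0.8)
    }
    dev.off()
  }
  invisible(out_dir)
}
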