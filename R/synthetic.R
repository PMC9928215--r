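#' Configure a synthetic multi-activity gait population
#'
#' Parameterizes a simulated cohort with known, controllable individuality
#' structure. Each (mode, joint) has a smooth population mean cycle (order-`K`
#' Fourier series on the phase grid) modulated linearly by task speed and
#' incline. Each subject carries smooth deviation fields drawn in Fourier
#' coefficient space and scaled so a field's RMS amplitude over the cycle is
#' `sigma_subject` degrees. The deviation realized at a task is
#' `rho_task * (mode-shared field) + sqrt(1 - rho_task^2) * (task-specific
#' field)`, and each mode-shared field is `rho_mode * (subject-common field)
#' + sqrt(1 - rho_mode^2) * (mode-specific field)` — so `rho_task` controls
#' how persistent a subject's individuality is across tasks within a mode,
#' and `rho_mode` how much of it is shared across modes. Every stride adds
#' independent smooth noise (low-order Fourier, RMS `sigma_noise` degrees).
#'
#' Defaults mirror the study design the package targets: 10 subjects;
#' walking at 0.8/1.0/1.2 m/s on -10..+10 degree inclines; running at
#' 1.8-2.4 m/s; stair ascent/descent at 20-35 degree stair inclinations;
#' 30 strides per walking/running task and 5 per stair task.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param walk_speeds,walk_inclines Walking task grid (m/s, degrees); the
#'   grid is their Cartesian product. Empty vector drops the mode.
#' @param run_speeds Running speeds (m/s, level ground).
#' @param stair_inclines Stair inclination magnitudes (degrees), used for
#'   both ascent and descent.
#' @param strides_walk_run,strides_stair Strides recorded per task.
#' @param fourier_order Fourier order `K` of population and deviation curves.
#' @param sigma_subject Subject deviation RMS scale in degrees; a scalar or a
#'   named vector with entries `ankle`, `knee`, `hip`.
#' @param rho_task Within-mode persistence of a subject's deviation, in
#'   `[0, 1]`; 1 means the same deviation at every task of a mode.
#' @param rho_mode Cross-mode persistence, in `[0, 1]`.
#' @param sigma_noise Stride-level smooth noise RMS (degrees).
#' @param noise_order Fourier order of the stride noise.
#' @param n_phase Phase samples per stride (default 150).
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 10,
                             walk_speeds = c(0.8, 1.0, 1.2),
                             walk_inclines = c(-10, -5, 0, 5, 10),
                             run_speeds = c(1.8, 2.0, 2.2, 2.4),
                             stair_inclines = c(20, 25, 30, 35),
                             strides_walk_run = 30,
                             strides_stair = 5,
                             fourier_order = 6,
                             sigma_subject = 4,
                             rho_task = 0.95,
                             rho_mode = 0.35,
                             sigma_noise = 1,
                             noise_order = 3,
                             n_phase = 150,
                             seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory (a single integer).", class = "ikcgait_config_error")
  }
  stopifnot_config <- function(ok, msg) {
    if (!ok) abort(msg, class = "ikcgait_config_error")
  }
  stopifnot_config(n_subjects >= 2, "`n_subjects` must be at least 2.")
  stopifnot_config(
    all(c(sigma_subject, sigma_noise) >= 0),
    "Deviation and noise scales must be non-negative."
  )
  stopifnot_config(
    all(c(rho_task, rho_mode) >= 0) && all(c(rho_task, rho_mode) <= 1),
    "`rho_task` and `rho_mode` must lie in [0, 1]."
  )
  stopifnot_config(
    strides_walk_run >= 1 && strides_stair >= 1,
    "Stride counts must be at least 1."
  )
  stopifnot_config(
    n_phase >= 8 && fourier_order >= 1 && noise_order >= 1 &&
      2 * max(fourier_order, noise_order) < n_phase / 2,
    "Fourier orders must be positive and resolvable on the phase grid."
  )
  if (!is.null(names(sigma_subject))) {
    stopifnot_config(
      all(gait_joints %in% names(sigma_subject)),
      "Named `sigma_subject` must cover ankle, knee and hip."
    )
  }
  has_any_task <- length(walk_speeds) * length(walk_inclines) +
    length(run_speeds) + length(stair_inclines) > 0
  stopifnot_config(has_any_task, "The task grid must be nonempty.")

  structure(
    list(
      n_subjects = as.integer(n_subjects),
      walk_speeds = sort(walk_speeds), walk_inclines = sort(walk_inclines),
      run_speeds = sort(run_speeds), stair_inclines = sort(stair_inclines),
      strides_walk_run = as.integer(strides_walk_run),
      strides_stair = as.integer(strides_stair),
      fourier_order = as.integer(fourier_order),
      sigma_subject = sigma_subject,
      rho_task = rho_task, rho_mode = rho_mode,
      sigma_noise = sigma_noise, noise_order = as.integer(noise_order),
      n_phase = as.integer(n_phase), seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Fourier design matrix: intercept, then cos/sin pairs for k = 1..K, on the
# left-closed phase grid t = (phi - 1)/n.
fourier_basis <- function(n_phase, K) {
  t <- (seq_len(n_phase) - 1) / n_phase
  cols <- list(rep(1, n_phase))
  for (k in seq_len(K)) {
    cols <- c(cols, list(cos(2 * pi * k * t)), list(sin(2 * pi * k * t)))
  }
  do.call(cbind, cols)
}

# Coefficient standard deviations giving a field of RMS amplitude `sigma`
# over the cycle: var splits evenly between the offset and the K harmonics.
coef_sd <- function(sigma, K) {
  c(sigma / sqrt(2), rep(sigma / sqrt(2 * K), 2 * K))
}

# Fixed population Fourier coefficients per joint (degrees), loosely shaped
# like sagittal gait curves; only differences of curves matter downstream,
# so these are cosmetic but keep outputs in a plausible range.
pop_templates <- list(
  ankle = c(0, -5, 8, -6, 3, 2, -1),
  knee = c(25, -15, 20, 10, 5, 3, 2),
  hip = c(10, 20, 5, 2, 1, 0, 0)
)
mode_amplitude <- c(walk = 1.0, run = 1.3, stair_ascent = 1.4, stair_descent = 1.2)
mode_ref_speed <- c(walk = 1.0, run = 2.0, stair_ascent = NA, stair_descent = NA)
mode_ref_incline <- c(walk = 0, run = 0, stair_ascent = 27.5, stair_descent = 27.5)

population_curve <- function(basis, mode, joint, speed, incline, K) {
  coefs <- numeric(2 * K + 1)
  tmpl <- pop_templates[[joint]]
  coefs[seq_along(tmpl)] <- tmpl
  speed_term <- if (is.na(speed) || is.na(mode_ref_speed[[mode]])) 0 else 0.15 * (speed - mode_ref_speed[[mode]])
  incline_term <- 0.004 * (incline - mode_ref_incline[[mode]])
  scale <- mode_amplitude[[mode]] * (1 + speed_term + incline_term)
  coefs[-1] <- coefs[-1] * scale
  drop(basis %*% coefs)
}

task_grid_from_config <- function(config) {
  grids <- list()
  if (length(config$walk_speeds) > 0 && length(config$walk_inclines) > 0) {
    grids$walk <- tidyr::expand_grid(
      mode = "walk", speed_mps = config$walk_speeds,
      incline_deg = config$walk_inclines
    )
  }
  if (length(config$run_speeds) > 0) {
    grids$run <- tibble::tibble(
      mode = "run", speed_mps = config$run_speeds, incline_deg = 0
    )
  }
  if (length(config$stair_inclines) > 0) {
    grids$stair_ascent <- tibble::tibble(
      mode = "stair_ascent", speed_mps = NA_real_, incline_deg = config$stair_inclines
    )
    grids$stair_descent <- tibble::tibble(
      mode = "stair_descent", speed_mps = NA_real_, incline_deg = config$stair_inclines
    )
  }
  dplyr::bind_rows(grids)
}

resolve_sigma <- function(sigma_subject, joint) {
  if (is.null(names(sigma_subject))) sigma_subject[[1]] else sigma_subject[[joint]]
}

#' Generate a synthetic multi-activity gait dataset
#'
#' Draws the population described by a [synthetic_config()]: for every
#' subject, joint and task, a smooth deviation field is added to the task's
#' population mean cycle, and each stride adds smooth noise. The injected
#' per-task deviations (the generator's ground truth) travel with the result
#' and are retrievable via [gait_truth()] and [truth_ikc()].
#'
#' Identical configurations (including the seed) produce bit-identical
#' datasets.
#'
#' @param config A `synthetic_config`.
#' @return A gait tibble in the canonical long layout (class
#'   `synthetic_gait`), with the configuration in `attr(, "config")` and the
#'   injected deviation curves in `attr(, "truth")`.
#' @export
generate_gait <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().", class = "ikcgait_config_error")
  }
  set.seed(config$seed)
  K <- config$fourier_order
  n_phase <- config$n_phase
  basis <- fourier_basis(n_phase, K)
  noise_basis <- fourier_basis(n_phase, config$noise_order)
  noise_sd <- coef_sd(config$sigma_noise, config$noise_order)
  unit_sd <- coef_sd(1, K)
  d <- 2 * K + 1

  tasks <- task_grid_from_config(config)
  active_modes <- unique(tasks$mode)
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  blocks <- list()
  truth <- list()
  bi <- 0L

  for (subj in subjects) {
    for (joint in gait_joints) {
      z_common <- rnorm(d)
      for (mode in active_modes) {
        z_mode <- rnorm(d)
        shared <- config$rho_mode * z_common +
          sqrt(1 - config$rho_mode^2) * z_mode
        mode_tasks <- tasks[tasks$mode == mode, , drop = FALSE]
        sigma <- resolve_sigma(config$sigma_subject, joint)
        n_strides <- if (mode %in% c("walk", "run")) {
          config$strides_walk_run
        } else {
          config$strides_stair
        }
        for (ti in seq_len(nrow(mode_tasks))) {
          speed <- mode_tasks$speed_mps[ti]
          incline <- mode_tasks$incline_deg[ti]
          z_task <- rnorm(d)
          dev_coef <- sigma * unit_sd *
            (config$rho_task * shared + sqrt(1 - config$rho_task^2) * z_task)
          deviation <- drop(basis %*% dev_coef)
          pop <- population_curve(basis, mode, joint, speed, incline, K)
          noise_coef <- matrix(
            rnorm(length(noise_sd) * n_strides, sd = noise_sd),
            nrow = length(noise_sd)
          )
          angles <- (pop + deviation) + noise_basis %*% noise_coef
          bi <- bi + 1L
          blocks[[bi]] <- tibble::tibble(
            subject = subj, mode = mode, speed_mps = speed,
            incline_deg = incline, joint = joint,
            stride_id = rep(seq_len(n_strides), each = n_phase),
            side = rep(
              rep_len(c("L", "R"), n_strides),
              each = n_phase
            ),
            phase_index = rep(seq_len(n_phase), n_strides),
            angle_deg = as.vector(angles)
          )
          truth[[bi]] <- tibble::tibble(
            subject = subj, mode = mode, speed_mps = speed,
            incline_deg = incline, joint = joint,
            phase_index = seq_len(n_phase),
            deviation_deg = deviation
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  attr(out, "config") <- config
  class(out) <- unique(c("synthetic_gait", class(out)))
  out
}

#' Ground-truth deviation curves of a synthetic dataset
#'
#' @param data A dataset from [generate_gait()].
#' @return A tibble of the injected per-subject deviation curves: subject,
#'   task, joint, `phase_index`, `deviation_deg`.
#' @export
gait_truth <- function(data) {
  truth <- attr(data, "truth")
  if (is.null(truth)) {
    abort("`data` carries no ground truth; was it made by generate_gait()?",
      class = "ikcgait_lookup_error"
    )
  }
  truth
}

#' Noise-free target IKC of a synthetic subject at one task
#'
#' The injected deviation of `subject` at the task minus the mean injected
#' deviation of the other subjects — exactly what the empirical IKC estimates
#' in the absence of stride noise.
#'
#' @param data A dataset from [generate_gait()].
#' @param subject Subject identifier (e.g. `"S01"`).
#' @param mode,speed,incline Task selector (`speed = NA` for stairs).
#' @param joint Joint name.
#' @return A tibble with `phase_index` and `ikc_deg`.
#' @export
truth_ikc <- function(data, subject, mode, speed, incline, joint) {
  truth <- gait_truth(data)
  task <- filter_task(truth, mode, speed, incline)
  task <- task[task$joint == joint, , drop = FALSE]
  if (nrow(task) == 0 || !subject %in% task$subject) {
    abort("Unknown subject/task/joint in the ground truth.",
      class = "ikcgait_lookup_error"
    )
  }
  task %>%
    dplyr::group_by(.data$phase_index) %>%
    dplyr::summarise(
      ikc_deg = {
        own <- .data$deviation_deg[.data$subject == !!subject]
        others <- .data$deviation_deg[.data$subject != !!subject]
        own - mean(others)
      },
      .groups = "drop"
    )
}
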