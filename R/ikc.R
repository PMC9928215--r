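#' Baseline task per ambulation mode
#'
#' The modal baseline is the single representative task at which a subject's
#' individuality is measured before being transferred to the rest of the
#' mode's task space. Defaults: walking at 1.0 m/s on level ground, running
#' at 2.0 m/s, stair ascent and descent at a 30 degree stair inclination —
#' mid-range tasks that are easy to replicate in a clinic.
#'
#' @param walk_speed,walk_incline Walking baseline task (m/s, degrees).
#' @param run_speed Running baseline speed (m/s, level ground).
#' @param stair_ascent_incline,stair_descent_incline Stair baseline
#'   inclination magnitudes (degrees).
#' @return A tibble with one row per mode: `mode`, `speed_mps`, `incline_deg`.
#' @export
#' @examples
#' default_baselines()
default_baselines <- function(walk_speed = 1.0, walk_incline = 0,
                              run_speed = 2.0,
                              stair_ascent_incline = 30,
                              stair_descent_incline = 30) {
  tibble::tibble(
    mode = gait_modes,
    speed_mps = c(walk_speed, run_speed, NA_real_, NA_real_),
    incline_deg = c(walk_incline, 0, stair_ascent_incline, stair_descent_incline)
  )
}

baseline_for <- function(baselines, mode) {
  row <- dplyr::filter(baselines, .data$mode == !!mode)
  if (nrow(row) != 1) {
    abort(paste0("No baseline task declared for mode '", mode, "'."),
      class = "ikcgait_baseline_error"
    )
  }
  row
}

# Filter a gait (or mean-curve) table down to one task. `speed` may be NA
# (stairs), matched with is.na().
filter_task <- function(data, mode, speed, incline) {
  speed_match <- if (is.na(speed)) is.na(data$speed_mps) else !is.na(data$speed_mps) & data$speed_mps == speed
  data[data$mode == mode & speed_match & data$incline_deg == incline, , drop = FALSE]
}

#' Leave-one-out population mean at one task
#'
#' The pointwise mean trajectory over all subjects other than
#' `exclude_subject`, with equal subject weighting: each remaining subject's
#' strides are averaged into one representative cycle first, then those
#' cycles are averaged.
#'
#' @param data A gait tibble.
#' @param exclude_subject Subject identifier to leave out.
#' @param mode,speed,incline Task selector (`speed = NA` for stair tasks).
#' @param joint Joint name (`"ankle"`, `"knee"`, `"hip"`).
#' @param strides Which strides feed each subject's representative cycle:
#'   `"all"` (default), or `"train"`/`"validation"` to use one interleaved
#'   half (see [split_strides()]).
#' @return A tibble with `phase_index` and `angle_deg` for the leave-one-out
#'   mean cycle.
#' @export
loo_mean <- function(data, exclude_subject, mode, speed, incline, joint,
                     strides = c("all", "train", "validation")) {
  strides <- match.arg(strides)
  task <- filter_task(data, mode, speed, incline)
  task <- task[task$joint == joint, , drop = FALSE]
  if (nrow(task) == 0) {
    abort("Task/joint not present in the dataset.", class = "ikcgait_missing_task_error")
  }
  others <- task[task$subject != exclude_subject, , drop = FALSE]
  if (dplyr::n_distinct(others$subject) < 1 ||
    dplyr::n_distinct(task$subject) < 2) {
    abort("Leave-one-out mean needs at least 2 subjects at the task.",
      class = "ikcgait_loo_error"
    )
  }
  if (strides != "all") {
    others <- split_strides(others)
    others <- others[others$half == strides, , drop = FALSE]
  }
  mean_cycle(others) %>%
    dplyr::group_by(.data$phase_index) %>%
    dplyr::summarise(angle_deg = mean(.data$angle_deg), .groups = "drop")
}

#' Individual kinematic contributions for every subject, task and joint
#'
#' The individual kinematic contribution (IKC) is a subject's pointwise
#' deviation from the leave-one-out population mean:
#' `C[phi] = d[phi] - dbar[phi]`, where `d` is the subject's representative
#' cycle and `dbar` is the equal-weight mean of the other subjects'
#' representative cycles at the same task and joint.
#'
#' @param data A gait tibble with at least 2 subjects per task.
#' @param strides Stride subset feeding each subject's own representative
#'   cycle (`"all"`, `"train"`, or `"validation"`); leave-one-out means always
#'   use the other subjects' full stride sets.
#' @return A tibble of class `ikc_curves`: one row per subject, task, joint
#'   and phase sample with `angle_deg` (subject mean), `loo_deg`
#'   (leave-one-out mean) and `ikc_deg = angle_deg - loo_deg`.
#' @export
#' @examples
#' d <- generate_gait(synthetic_config(
#'   n_subjects = 3, walk_speeds = 1, walk_inclines = 0,
#'   run_speeds = numeric(), stair_inclines = numeric(),
#'   strides_walk_run = 4, seed = 7
#' ))
#' compute_ikc(d)
compute_ikc <- function(data, strides = c("all", "train", "validation")) {
  strides <- match.arg(strides)
  subject_curves <- if (strides == "all") {
    mean_cycle(data)
  } else {
    halves <- split_strides(data)
    mean_cycle(halves[halves$half == strides, , drop = FALSE])
  }
  loo_all <- mean_cycle(data) %>% add_loo()
  if (strides == "all") {
    out <- dplyr::mutate(loo_all, ikc_deg = .data$angle_deg - .data$loo_deg)
  } else {
    out <- subject_curves %>%
      dplyr::inner_join(
        dplyr::select(loo_all, -"angle_deg", -"n_strides"),
        by = c("subject", task_columns, "joint", "phase_index")
      ) %>%
      dplyr::mutate(ikc_deg = .data$angle_deg - .data$loo_deg)
  }
  new_ikc_curves(out)
}

# Adds a leave-one-out mean column to a mean-curve table. For n subjects with
# per-subject means m_i, the LOO mean for subject i is (sum(m) - m_i)/(n-1).
add_loo <- function(curves) {
  curves %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(task_columns, "joint", "phase_index")))) %>%
    dplyr::mutate(.n_subj = dplyr::n()) %>%
    {
      if (any(.$.n_subj < 2)) {
        abort("Leave-one-out mean needs at least 2 subjects at every task.",
          class = "ikcgait_loo_error"
        )
      }
      .
    } %>%
    dplyr::mutate(loo_deg = (sum(.data$angle_deg) - .data$angle_deg) / (.data$.n_subj - 1)) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".n_subj")
}

new_ikc_curves <- function(x) {
  class(x) <- unique(c("ikc_curves", class(x)))
  x
}

#' Predict a subject's kinematics by adding a baseline IKC to the group mean
#'
#' Pure addition: the individualized prediction at a target task is the
#' leave-one-out mean at that task plus the subject's IKC measured at the
#' baseline task. No phase re-alignment or amplitude scaling is applied.
#'
#' @param loo_target Numeric vector: leave-one-out mean cycle at the target
#'   task (degrees).
#' @param baseline_ikc Numeric vector: the subject's baseline-task IKC, same
#'   grid length.
#' @return Numeric vector: the predicted individualized trajectory.
#' @export
predict_with_baseline <- function(loo_target, baseline_ikc) {
  check_same_grid(loo_target, baseline_ikc)
  loo_target + baseline_ikc
}

#' RMSE between predicted and observed IKC over the gait cycle
#'
#' `sqrt(sum((predicted - observed)^2) / I)` over the `I` phase samples, in
#' degrees. This is also the RMSE between the individualized trajectory
#' prediction and the subject's observed trajectory, since the common
#' leave-one-out mean cancels.
#'
#' @param predicted_ikc,observed_ikc Numeric vectors on the same phase grid.
#' @return RMSE in degrees (scalar, >= 0).
#' @export
#' @examples
#' ikc_rmse(c(3, 4), c(0, 0)) # sqrt((9 + 16)/2)
ikc_rmse <- function(predicted_ikc, observed_ikc) {
  check_same_grid(predicted_ikc, observed_ikc)
  sqrt(mean((predicted_ikc - observed_ikc)^2))
}

#' Benchmark RMSE of the non-individualized population average
#'
#' The RMSE obtained with a zero IKC, i.e. when the population (leave-one-out)
#' average itself is used as the prediction: the RMS magnitude of the
#' observed IKC.
#'
#' @param observed_ikc Numeric vector: the subject's observed IKC (degrees).
#' @return RMSE in degrees.
#' @export
benchmark_rmse <- function(observed_ikc) {
  ikc_rmse(rep(0, length(observed_ikc)), observed_ikc)
}

check_same_grid <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) || length(x) == 0) {
    abort("Curves must be numeric vectors on the same phase grid.",
      class = "ikcgait_shape_error"
    )
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("Curves must be finite.", class = "ikcgait_value_error")
  }
  invisible(TRUE)
}
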