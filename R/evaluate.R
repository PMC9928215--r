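#' Evaluate individualized predictions for one ambulation mode
#'
#' For every subject, joint and target task in `mode`, measures the subject's
#' IKC at a baseline task, transfers it to the target task, and scores the
#' transferred prediction against the subject's observed IKC with the
#' gait-cycle RMSE. Two transfer methods are supported:
#' `"walking_baseline"` applies the IKC measured at the level-ground walking
#' baseline to every mode, while `"modal_baseline"` uses the target mode's
#' own baseline task.
#'
#' Stride policies: walking and running baselines have enough strides to be
#' split, so the baseline IKC is trained on the interleaved training half and
#' — when the target task is the baseline task itself — validated against
#' the held-out half. Stair baselines keep all strides for training and the
#' stair modal baseline task is omitted from the evaluated targets
#' altogether. Observed IKCs at all other target tasks use the full stride
#' sets, as do all leave-one-out means.
#'
#' @param data A gait tibble covering the baseline task and the target mode.
#' @param mode Target ambulation mode (`"walk"`, `"run"`, `"stair_ascent"`,
#'   `"stair_descent"`).
#' @param method `"modal_baseline"` or `"walking_baseline"`.
#' @param baselines Baseline task per mode, see [default_baselines()].
#' @return A tibble of class `ikc_records`, one row per (subject, target
#'   task, joint): `rmse_deg`, `benchmark_rmse_deg` (the non-individualized
#'   population-average error), `improvement_deg = benchmark_rmse_deg -
#'   rmse_deg` (positive when individualization helped) and
#'   `percent_improvement`.
#' @export
#' @examples
#' d <- generate_gait(synthetic_config(
#'   n_subjects = 4, walk_speeds = 1, walk_inclines = c(0, 5),
#'   run_speeds = numeric(), stair_inclines = numeric(),
#'   strides_walk_run = 6, seed = 11
#' ))
#' evaluate_mode(d, "walk", "modal_baseline")
evaluate_mode <- function(data, mode,
                          method = c("modal_baseline", "walking_baseline"),
                          baselines = default_baselines()) {
  method <- match.arg(method)
  mode <- match.arg(mode, gait_modes)

  b_mode <- if (method == "walking_baseline") "walk" else mode
  b <- baseline_for(baselines, b_mode)

  mode_data <- data[data$mode == mode, , drop = FALSE]
  if (nrow(mode_data) == 0) {
    abort(paste0("No records for mode '", mode, "'."), class = "ikcgait_missing_task_error")
  }
  base_data <- filter_task(data, b_mode, b$speed_mps, b$incline_deg)
  if (nrow(base_data) == 0) {
    abort("Baseline task absent from the dataset.", class = "ikcgait_missing_task_error")
  }
  subjects <- sort(unique(mode_data$subject))
  missing_subj <- setdiff(subjects, unique(base_data$subject))
  if (length(missing_subj) > 0) {
    abort(
      paste0(
        "Baseline task missing for subject(s): ",
        paste(missing_subj, collapse = ", ")
      ),
      class = "ikcgait_coverage_error"
    )
  }

  # Baseline IKC: subject curve from the training half (walk/run baselines)
  # or all strides (stair baselines); LOO mean from the others' full sets.
  split_baseline <- b_mode %in% c("walk", "run")
  base_full_means <- mean_cycle(base_data) %>% add_loo()
  base_subject <- if (split_baseline) {
    halves <- split_strides(base_data)
    mean_cycle(halves[halves$half == "train", , drop = FALSE])
  } else {
    dplyr::select(base_full_means, -"loo_deg")
  }
  baseline_ikc <- base_subject %>%
    dplyr::inner_join(
      dplyr::select(base_full_means, "subject", "joint", "phase_index", "loo_deg"),
      by = c("subject", "joint", "phase_index")
    ) %>%
    dplyr::transmute(
      subject = .data$subject, joint = .data$joint,
      phase_index = .data$phase_index,
      ikc_baseline = .data$angle_deg - .data$loo_deg
    )

  # Observed IKCs at the target tasks. The mode's own modal baseline task is
  # dropped for stair modes (training-only); when the target task IS the
  # split baseline task, the subject's observed curve comes from the
  # validation half.
  obs_means <- mean_cycle(mode_data) %>% add_loo()
  if (mode %in% c("stair_ascent", "stair_descent")) {
    mb <- baseline_for(baselines, mode)
    keep <- !(is.na(obs_means$speed_mps) & obs_means$incline_deg == mb$incline_deg)
    obs_means <- obs_means[keep, , drop = FALSE]
    if (nrow(obs_means) == 0) {
      abort("No stair target tasks remain once the baseline task is omitted.",
        class = "ikcgait_missing_task_error"
      )
    }
  }
  if (split_baseline && b_mode == mode) {
    val_means <- {
      halves <- split_strides(base_data)
      mean_cycle(halves[halves$half == "validation", , drop = FALSE])
    }
    is_base <- !is.na(obs_means$speed_mps) &
      obs_means$speed_mps == b$speed_mps & obs_means$incline_deg == b$incline_deg
    obs_means$angle_deg[is_base] <- val_means$angle_deg[
      match(
        paste(obs_means$subject[is_base], obs_means$joint[is_base],
          obs_means$phase_index[is_base]),
        paste(val_means$subject, val_means$joint, val_means$phase_index)
      )
    ]
  }
  observed_ikc <- dplyr::mutate(obs_means, ikc_obs = .data$angle_deg - .data$loo_deg)

  records <- observed_ikc %>%
    dplyr::inner_join(baseline_ikc, by = c("subject", "joint", "phase_index")) %>%
    dplyr::group_by(
      .data$subject, .data$mode, .data$speed_mps, .data$incline_deg, .data$joint
    ) %>%
    dplyr::summarise(
      rmse_deg = sqrt(mean((.data$ikc_baseline - .data$ikc_obs)^2)),
      benchmark_rmse_deg = sqrt(mean(.data$ikc_obs^2)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      method = method,
      improvement_deg = .data$benchmark_rmse_deg - .data$rmse_deg,
      percent_improvement = 100 * .data$improvement_deg / .data$benchmark_rmse_deg
    ) %>%
    dplyr::select(
      "subject", "mode", "speed_mps", "incline_deg", "joint", "method",
      "rmse_deg", "benchmark_rmse_deg", "improvement_deg", "percent_improvement"
    )
  new_ikc_records(records)
}

#' Evaluate all requested modes and transfer methods
#'
#' Convenience wrapper around [evaluate_mode()]. For walking the two methods
#' coincide (the walking baseline is the modal baseline), so walking is
#' evaluated once, under the `"modal_baseline"` label.
#'
#' @inheritParams evaluate_mode
#' @param modes Modes to evaluate (default: every mode present in `data`).
#' @param methods Transfer methods to evaluate.
#' @return A combined `ikc_records` tibble.
#' @export
evaluate_all <- function(data,
                         modes = intersect(gait_modes, unique(data$mode)),
                         methods = c("modal_baseline", "walking_baseline"),
                         baselines = default_baselines()) {
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- tidyr::expand_grid(mode = modes, method = methods)
  grid <- grid[!(grid$mode == "walk" & grid$method == "walking_baseline" &
    "modal_baseline" %in% methods), , drop = FALSE]
  records <- purrr::pmap(grid, function(mode, method) {
    evaluate_mode(data, mode, method, baselines = baselines)
  })
  new_ikc_records(dplyr::bind_rows(records))
}

new_ikc_records <- function(x) {
  class(x) <- unique(c("ikc_records", class(x)))
  x
}

#' Summarize RMSE improvement over the non-individualized benchmark
#'
#' @param records An `ikc_records` tibble from [evaluate_mode()].
#' @param by Grouping columns (default mode, joint, method).
#' @return A tibble per group with `n_records`, `mean_improvement_deg`
#'   (mean of benchmark minus individualized RMSE), `percent_improvement`
#'   (100 x mean improvement / mean benchmark RMSE, a ratio of means) and
#'   `fraction_improved` (share of records with strictly positive
#'   improvement).
#' @export
summarize_improvement <- function(records, by = c("mode", "joint", "method")) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a nonempty prediction-record table.",
      class = "ikcgait_value_error"
    )
  }
  records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      n_records = dplyr::n(),
      mean_improvement_deg = mean(.data$improvement_deg),
      percent_improvement = 100 * mean(.data$improvement_deg) / mean(.data$benchmark_rmse_deg),
      fraction_improved = mean(.data$improvement_deg > 0),
      .groups = "drop"
    )
}
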