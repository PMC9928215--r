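# Small synthetic configurations used across the suite. Kept deliberately
# tiny so replicated tests stay fast; the full study-sized grid is exercised
# once in the pipeline tests and in scripts/acceptance.R.

walk_only_config <- function(seed, n_subjects = 4, speeds = 1,
                             inclines = c(0, 5), strides = 6, ...) {
  synthetic_config(
    n_subjects = n_subjects, walk_speeds = speeds, walk_inclines = inclines,
    run_speeds = numeric(), stair_inclines = numeric(),
    strides_walk_run = strides, seed = seed, ...
  )
}

# A minimal hand-built gait tibble: constant-angle strides on a short phase
# grid, one walking task, one joint per call.
constant_stride_data <- function(values_by_subject, n_phase = 4,
                                 n_strides = 2, joint = "ankle") {
  purrr::imap_dfr(values_by_subject, function(val, subj) {
    tidyr::expand_grid(stride_id = seq_len(n_strides), phase_index = seq_len(n_phase)) %>%
      dplyr::mutate(
        subject = subj, mode = "walk", speed_mps = 1, incline_deg = 0,
        joint = joint, side = NA_character_, angle_deg = val
      ) %>%
      dplyr::select(dplyr::all_of(c(
        "subject", "mode", "speed_mps", "incline_deg", "joint",
        "stride_id", "side", "phase_index", "angle_deg"
      )))
  })
}

# Random gait fixture over an arbitrary phase grid (no smoothness), useful
# for brute-force oracles.
random_stride_data <- function(n_subjects, n_strides, n_phase, seed,
                               joint = "ankle") {
  withr::with_seed(seed, {
    purrr::map_dfr(sprintf("P%02d", seq_len(n_subjects)), function(subj) {
      tidyr::expand_grid(stride_id = seq_len(n_strides), phase_index = seq_len(n_phase)) %>%
        dplyr::mutate(
          subject = subj, mode = "walk", speed_mps = 1, incline_deg = 0,
          joint = joint, side = NA_character_,
          angle_deg = rnorm(dplyr::n(), sd = 5)
        ) %>%
        dplyr::select(dplyr::all_of(c(
          "subject", "mode", "speed_mps", "incline_deg", "joint",
          "stride_id", "side", "phase_index", "angle_deg"
        )))
    })
  })
}

# Matrix of per-subject mean cycles at one task/joint: subjects x phase.
subject_mean_matrix <- function(data, joint = "ankle") {
  mc <- mean_cycle(data[data$joint == joint, , drop = FALSE])
  tidyr::pivot_wider(
    dplyr::select(mc, "subject", "phase_index", "angle_deg"),
    names_from = "phase_index", values_from = "angle_deg"
  ) %>%
    tibble::column_to_rownames("subject") %>%
    as.matrix()
}
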