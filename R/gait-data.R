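#' Validate a long-form gait table
#'
#' Checks that a data frame conforms to the canonical long-form gait layout
#' used throughout the package: one row per phase sample of one stride, with
#' columns `subject`, `mode`, `speed_mps`, `incline_deg`, `joint`,
#' `stride_id`, `side`, `phase_index`, `angle_deg`. Phase samples index
#' `1:n_phase` (default 150) from heel strike to the next ipsilateral heel
#' strike, left-closed (sample 1 at 0% of the cycle, no duplicated endpoint).
#'
#' @param data A data frame in the long gait layout.
#' @param n_phase Expected number of phase samples per stride. `NULL`
#'   (default) infers it as `max(phase_index)`.
#' @return `data` invisibly, as a tibble, if valid; otherwise an error of
#'   class `ikcgait_schema_error` (wrong columns), `ikcgait_value_error`
#'   (bad mode/joint/task values or non-finite angles) or
#'   `ikcgait_integrity_error` (incomplete phase grid for some stride).
#' @export
#' @examples
#' d <- generate_gait(synthetic_config(
#'   n_subjects = 2, walk_speeds = 1, walk_inclines = 0,
#'   run_speeds = numeric(), stair_inclines = numeric(),
#'   strides_walk_run = 2, seed = 1
#' ))
#' validate_gait_data(d)
validate_gait_data <- function(data, n_phase = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "ikcgait_schema_error")
  }
  missing_cols <- setdiff(gait_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "ikcgait_schema_error"
    )
  }
  data <- tibble::as_tibble(data)

  bad_mode <- setdiff(unique(data$mode), gait_modes)
  if (length(bad_mode) > 0) {
    abort(
      paste0("Unknown ambulation mode(s): ", paste(bad_mode, collapse = ", ")),
      class = "ikcgait_value_error"
    )
  }
  bad_joint <- setdiff(unique(data$joint), gait_joints)
  if (length(bad_joint) > 0) {
    abort(
      paste0("Unknown joint(s): ", paste(bad_joint, collapse = ", ")),
      class = "ikcgait_value_error"
    )
  }
  if (!is.numeric(data$angle_deg) || anyNA(data$angle_deg) || any(!is.finite(data$angle_deg))) {
    abort("`angle_deg` must be finite and numeric for every row.",
      class = "ikcgait_value_error"
    )
  }
  if (!is.numeric(data$phase_index)) {
    abort("`phase_index` must be numeric.", class = "ikcgait_value_error")
  }
  n_phase <- n_phase %||% max(data$phase_index)

  # Task shape: walk carries speed and incline; run carries speed with
  # incline 0; stair tasks carry an incline magnitude and no speed.
  walk_bad <- data$mode == "walk" & (is.na(data$speed_mps) | is.na(data$incline_deg))
  run_bad <- data$mode == "run" & (is.na(data$speed_mps) | data$incline_deg != 0)
  stair_bad <- data$mode %in% c("stair_ascent", "stair_descent") &
    (!is.na(data$speed_mps) | is.na(data$incline_deg) | data$incline_deg <= 0)
  if (any(walk_bad) || any(run_bad) || any(stair_bad)) {
    abort(
      paste0(
        "Malformed task labels: walk needs speed and incline, run needs ",
        "speed with incline 0, stair tasks need a positive incline ",
        "magnitude and no speed (see read_gait_csv() for sign normalization)."
      ),
      class = "ikcgait_value_error"
    )
  }

  # Every stride must cover phase 1..n_phase exactly once.
  per_stride <- data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(stride_columns))) %>%
    dplyr::summarise(
      n = dplyr::n(),
      lo = min(.data$phase_index),
      hi = max(.data$phase_index),
      uniq = dplyr::n_distinct(.data$phase_index),
      .groups = "drop"
    )
  bad <- per_stride$n != n_phase | per_stride$lo != 1 |
    per_stride$hi != n_phase | per_stride$uniq != n_phase
  if (any(bad)) {
    first <- per_stride[which(bad)[1], ]
    abort(
      sprintf(
        "Incomplete phase grid (expected 1..%d) for subject '%s', mode '%s', stride_id %s.",
        n_phase, first$subject, first$mode, first$stride_id
      ),
      class = "ikcgait_integrity_error"
    )
  }
  invisible(data)
}

#' Read the canonical long-form gait CSV
#'
#' Reads a UTF-8 CSV with header columns exactly `subject, mode, speed_mps,
#' incline_deg, joint, stride_id, side, phase_index, angle_deg` and returns a
#' validated gait tibble. `speed_mps` is empty for stair rows; `side` is `L`,
#' `R`, or empty. Negative stair inclines (a descent sign convention) are
#' normalized to their magnitude — mode already encodes direction.
#'
#' @param path Path to the CSV file.
#' @param n_phase Expected phase samples per stride (`NULL` infers it).
#' @return A validated gait tibble (see [validate_gait_data()]), rows ordered
#'   by subject, task, joint, stride and phase.
#' @export
read_gait_csv <- function(path, n_phase = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "ikcgait_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(gait_columns, header)
  extra_cols <- setdiff(header, gait_columns)
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    abort(
      paste0(
        "Column mismatch in ", path,
        if (length(missing_cols)) paste0("; missing: ", paste(missing_cols, collapse = ", ")),
        if (length(extra_cols)) paste0("; unexpected: ", paste(extra_cols, collapse = ", "))
      ),
      class = "ikcgait_schema_error"
    )
  }
  data <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(),
      mode = readr::col_character(),
      speed_mps = readr::col_double(),
      incline_deg = readr::col_double(),
      joint = readr::col_character(),
      stride_id = readr::col_integer(),
      side = readr::col_character(),
      phase_index = readr::col_integer(),
      angle_deg = readr::col_double()
    ),
    show_col_types = FALSE
  ))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(
      sprintf(
        "Could not parse %s: %s at row %d (%s).",
        path, probs$expected[1], probs$row[1], probs$col[1]
      ),
      class = "ikcgait_parse_error"
    )
  }
  # Normalize stair sign convention and run incline before validation.
  stair <- data$mode %in% c("stair_ascent", "stair_descent")
  data$incline_deg[stair] <- abs(data$incline_deg[stair])
  data$incline_deg[data$mode == "run" & is.na(data$incline_deg)] <- 0
  data <- dplyr::arrange(
    data, .data$subject, .data$mode, .data$speed_mps, .data$incline_deg,
    .data$joint, .data$stride_id, .data$phase_index
  )
  validate_gait_data(data, n_phase = n_phase)
  data
}

#' Write a gait table to the canonical long CSV
#'
#' @param data A gait tibble (validated before writing).
#' @param path Output file path.
#' @return `data` invisibly.
#' @export
write_gait_csv <- function(data, path) {
  validate_gait_data(data)
  readr::write_csv(dplyr::select(data, dplyr::all_of(gait_columns)), path)
  invisible(data)
}

#' Resample one stride onto the fixed phase grid
#'
#' Linearly interpolates a time-ordered joint-angle sequence spanning exactly
#' one gait cycle (first sample at heel strike) onto `n_out` evenly spaced
#' phase samples. Input samples are treated as uniformly spaced and
#' left-closed over the cycle (sample `i` of `m` at fraction `(i-1)/m`), the
#' same convention as the output grid, so resampling a curve already on the
#' target grid is the identity. Inputs shorter than the target grid are
#' extended periodically (the cycle wraps to its first sample) before
#' interpolation.
#'
#' @param x Numeric vector of joint angles (degrees), length >= 4.
#' @param n_out Number of output phase samples (default 150).
#' @return Numeric vector of length `n_out`.
#' @export
#' @examples
#' resample_cycle(sin(2 * pi * (0:299) / 300), n_out = 150)[1:5]
resample_cycle <- function(x, n_out = 150L) {
  if (!is.numeric(x) || length(x) < 4) {
    abort("Need at least 4 samples spanning one gait cycle.",
      class = "ikcgait_insufficient_data_error"
    )
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("Input angles must be finite.", class = "ikcgait_value_error")
  }
  m <- length(x)
  t_in <- (seq_len(m) - 1) / m
  t_out <- (seq_len(n_out) - 1) / n_out
  if (max(t_out) > max(t_in)) {
    # periodic extension: the cycle wraps back to its first sample at t = 1
    t_in <- c(t_in, 1)
    x <- c(x, x[1])
  }
  approx(t_in, x, xout = t_out, method = "linear")$y
}

#' Average strides into one representative cycle per subject, task and joint
#'
#' Computes the pointwise (per phase sample) arithmetic mean across strides
#' within each `(subject, mode, speed_mps, incline_deg, joint)` group. The
#' result is the per-task representative trajectory used for all
#' individuality computations.
#'
#' @param data A gait tibble.
#' @return A tibble with one row per subject, task, joint and phase sample:
#'   grouping columns, `phase_index`, `angle_deg` (the mean), and `n_strides`.
#' @export
mean_cycle <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a nonempty gait table.", class = "ikcgait_value_error")
  }
  data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(
      "subject", "mode", "speed_mps", "incline_deg", "joint", "phase_index"
    )))) %>%
    dplyr::summarise(
      n_strides = dplyr::n_distinct(.data$stride_id),
      angle_deg = mean(.data$angle_deg),
      .groups = "drop"
    )
}

#' Split strides into training and validation halves
#'
#' Deterministic interleaved split within each `(subject, task, joint)`
#' group: strides in recorded order (by `stride_id`) alternate train,
#' validation, train, ... so the 1st, 3rd, 5th, ... strides form the training
#' half. With an odd stride count the training half gets the extra stride.
#' Interleaving (rather than a first-half/second-half cut) cancels slow
#' drift over a 30-second treadmill trial.
#'
#' @param data A gait tibble.
#' @return `data` with an added `half` column (`"train"` or `"validation"`).
#' @export
split_strides <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a nonempty gait table.", class = "ikcgait_value_error")
  }
  out <- data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("subject", "mode", "speed_mps", "incline_deg", "joint")
    ))) %>%
    dplyr::mutate(
      .rank = match(.data$stride_id, sort(unique(.data$stride_id))),
      .n_strides = dplyr::n_distinct(.data$stride_id)
    ) %>%
    dplyr::ungroup()
  if (any(out$.n_strides < 2)) {
    abort(
      "Cannot split a group with a single stride; use all strides instead (stair baseline policy).",
      class = "ikcgait_split_error"
    )
  }
  out %>%
    dplyr::mutate(half = ifelse(.data$.rank %% 2 == 1, "train", "validation")) %>%
    dplyr::select(-".rank", -".n_strides")
}
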