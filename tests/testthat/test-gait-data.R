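test_that("long CSV round-trips losslessly through write and read", {
  d <- generate_gait(walk_only_config(seed = 101, strides = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(d, path)
  back <- read_gait_csv(path)

  key <- c("subject", "mode", "speed_mps", "incline_deg", "joint", "stride_id", "phase_index")
  a <- dplyr::arrange(tibble::as_tibble(d)[, c(key, "angle_deg")], dplyr::across(dplyr::all_of(key)))
  b <- dplyr::arrange(back[, c(key, "angle_deg")], dplyr::across(dplyr::all_of(key)))
  expect_equal(a[key], b[key], ignore_attr = TRUE)
  expect_lt(max(abs(a$angle_deg - b$angle_deg)), 1e-9)

  # a second write/read cycle is stable to the same tolerance
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(back, path2)
  again <- read_gait_csv(path2)
  expect_lt(max(abs(b$angle_deg - again$angle_deg)), 1e-9)
})

test_that("reader enforces the schema and phase-grid integrity", {
  d <- generate_gait(walk_only_config(seed = 102, n_subjects = 2, inclines = 0, strides = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(d, path)

  # missing column
  tab <- readr::read_csv(path, show_col_types = FALSE)
  p_missing <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(tab, -"side"), p_missing)
  expect_error(read_gait_csv(p_missing), class = "ikcgait_schema_error", regexp = "side")

  # extra column
  p_extra <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(tab, bogus = 1), p_extra)
  expect_error(read_gait_csv(p_extra), class = "ikcgait_schema_error", regexp = "bogus")

  # a dropped phase sample is an integrity error naming the stride
  p_hole <- withr::local_tempfile(fileext = ".csv")
  hole <- tab[!(tab$subject == "S01" & tab$stride_id == 2 & tab$phase_index == 77), ]
  readr::write_csv(hole, p_hole)
  expect_error(read_gait_csv(p_hole), class = "ikcgait_integrity_error", regexp = "stride_id 2")

  # non-numeric angle is a parse error with a row reference
  p_bad <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(path)
  lines[3] <- sub("(,[^,]*)$", ",not_a_number", lines[3])
  writeLines(lines, p_bad)
  expect_error(read_gait_csv(p_bad), class = "ikcgait_parse_error", regexp = "row")
})

test_that("reader normalizes the stair descent sign convention", {
  d <- generate_gait(synthetic_config(
    n_subjects = 2, walk_speeds = numeric(), walk_inclines = numeric(),
    run_speeds = numeric(), stair_inclines = 30, strides_stair = 2, seed = 103
  ))
  tab <- tibble::as_tibble(d)
  tab$incline_deg[tab$mode == "stair_descent"] <- -tab$incline_deg[tab$mode == "stair_descent"]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- read_gait_csv(path)
  expect_true(all(back$incline_deg == 30))
})

test_that("resample_cycle is exact on constants and affine ramps", {
  expect_equal(resample_cycle(rep(5, 200)), rep(5, 150))
  # left-closed ramp: input sample i of m at 10*(i-1)/m maps to 10*(phi-1)/150
  m <- 300
  ramp <- 10 * (seq_len(m) - 1) / m
  expect_equal(resample_cycle(ramp), 10 * (0:149) / 150, tolerance = 1e-12)
})

test_that("resample_cycle is idempotent on the target grid", {
  x <- sin(2 * pi * (0:299) / 300) * 20
  once <- resample_cycle(x)
  twice <- resample_cycle(once)
  expect_lt(max(abs(once - twice)), 1e-9)
})

test_that("resample_cycle rejects short or non-finite input", {
  expect_error(resample_cycle(c(1, 2, 3)), class = "ikcgait_insufficient_data_error")
  expect_error(resample_cycle(c(1, 2, NA, 4, 5)), class = "ikcgait_value_error")
  expect_error(resample_cycle(c(1, 2, Inf, 4, 5)), class = "ikcgait_value_error")
})

test_that("mean_cycle averages strides pointwise", {
  one <- constant_stride_data(list(A = 7), n_strides = 1)
  expect_equal(mean_cycle(one)$angle_deg, rep(7, 4))

  two <- constant_stride_data(list(A = 0), n_strides = 1) %>%
    dplyr::bind_rows(
      constant_stride_data(list(A = 10), n_strides = 1) %>%
        dplyr::mutate(stride_id = 2L)
    )
  expect_equal(mean_cycle(two)$angle_deg, rep(5, 4))
  expect_equal(unique(mean_cycle(two)$n_strides), 2L)
})

test_that("mean_cycle of many noisy strides converges on the true curve", {
  n_phase <- 150
  truth <- 10 * sin(2 * pi * (0:(n_phase - 1)) / n_phase)
  withr::with_seed(2024, {
    strides <- purrr::map_dfr(1:30, function(s) {
      tibble::tibble(
        subject = "A", mode = "walk", speed_mps = 1, incline_deg = 0,
        joint = "ankle", stride_id = s, side = NA_character_,
        phase_index = seq_len(n_phase),
        angle_deg = truth + rnorm(n_phase)
      )
    })
  })
  m <- mean_cycle(strides)
  # unit-variance noise averaged over 30 strides: 3 sigma/sqrt(30) pointwise
  expect_lt(max(abs(m$angle_deg - truth)), 3 / sqrt(30))
})

test_that("split_strides partitions strides deterministically by interleaving", {
  d <- generate_gait(walk_only_config(seed = 104, n_subjects = 2, inclines = 0, strides = 30))
  s <- split_strides(d)
  per_group <- s %>%
    dplyr::distinct(.data$subject, .data$joint, .data$stride_id, .data$half) %>%
    dplyr::count(.data$subject, .data$joint, .data$half)
  expect_true(all(per_group$n == 15))

  # train and validation are disjoint and jointly complete
  ids <- s %>% dplyr::distinct(.data$subject, .data$joint, .data$stride_id, .data$half)
  expect_equal(nrow(ids), nrow(dplyr::distinct(ids, .data$subject, .data$joint, .data$stride_id)))

  # interleaving: odd-position strides train, even validation
  one <- ids[ids$subject == "S01" & ids$joint == "ankle", ]
  one <- one[order(one$stride_id), ]
  expect_equal(one$half, rep(c("train", "validation"), 15))

  # identical output across calls
  expect_identical(split_strides(d), s)
})

test_that("split_strides handles small and degenerate stride counts", {
  d2 <- constant_stride_data(list(A = 1), n_strides = 2)
  s2 <- split_strides(d2)
  expect_setequal(unique(s2$half), c("train", "validation"))

  d5 <- constant_stride_data(list(A = 1), n_strides = 5)
  tallies <- split_strides(d5) %>%
    dplyr::distinct(.data$stride_id, .data$half) %>%
    dplyr::count(.data$half)
  expect_equal(tallies$n[tallies$half == "train"], 3L)
  expect_equal(tallies$n[tallies$half == "validation"], 2L)

  d1 <- constant_stride_data(list(A = 1), n_strides = 1)
  expect_error(split_strides(d1), class = "ikcgait_split_error")
})

test_that("validate_gait_data flags malformed task labels", {
  d <- constant_stride_data(list(A = 1))
  bad <- dplyr::mutate(d, speed_mps = NA_real_)
  expect_error(validate_gait_data(bad), class = "ikcgait_value_error")
  expect_silent(validate_gait_data(d))
})
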