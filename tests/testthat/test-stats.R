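# Hand-rolled sums-of-squares oracle for a balanced main-effects design:
# SS_factor = sum over levels of n_level * (level mean - grand mean)^2.
ss_oracle <- function(df, response, factors) {
  y <- df[[response]]
  grand <- mean(y)
  ss <- vapply(factors, function(f) {
    means <- tapply(y, df[[f]], mean)
    ns <- tapply(y, df[[f]], length)
    sum(ns * (means - grand)^2)
  }, numeric(1))
  total <- sum((y - grand)^2)
  c(ss, residual = total - sum(ss), total = total)
}

null_run_records <- function(seed, effect_modal = 0) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      speed_mps = c(1.8, 2.0, 2.2, 2.4),
      joint = c("ankle", "knee", "hip")
    )
    grid %>%
      dplyr::mutate(
        subject = "S01", mode = "run", incline_deg = 0,
        benchmark_rmse_deg = 5 + rnorm(dplyr::n(), sd = 0.5)
      ) %>%
      tidyr::expand_grid(method = c("walking_baseline", "modal_baseline")) %>%
      dplyr::mutate(
        rmse_deg = 5 + rnorm(dplyr::n(), sd = 0.5) -
          effect_modal * (method == "modal_baseline"),
        improvement_deg = benchmark_rmse_deg - rmse_deg,
        percent_improvement = 100 * improvement_deg / benchmark_rmse_deg
      )
  })
}

test_that("the RMSE ANOVA reproduces a hand-computed sums-of-squares table", {
  records <- null_run_records(501)
  fit <- anova_rmse(records, "run")
  tab <- tidy(fit)

  # rebuild the same expanded design (benchmark as method level "none")
  none <- records %>%
    dplyr::distinct(subject, mode, speed_mps, incline_deg, joint, benchmark_rmse_deg) %>%
    dplyr::mutate(method = "none", rmse_deg = benchmark_rmse_deg)
  df <- dplyr::bind_rows(records, none) %>%
    dplyr::mutate(velocity = factor(speed_mps), joint = factor(joint), method = factor(method))
  expect_equal(fit$n, nrow(df))

  oracle <- ss_oracle(df, "rmse_deg", c("velocity", "joint", "method"))
  got <- setNames(tab$sumsq, tab$term)
  expect_equal(got[["velocity"]], oracle[["velocity"]], tolerance = 1e-6)
  expect_equal(got[["joint"]], oracle[["joint"]], tolerance = 1e-6)
  expect_equal(got[["method"]], oracle[["method"]], tolerance = 1e-6)
  expect_equal(got[["Residuals"]], oracle[["residual"]], tolerance = 1e-6)
  # decomposition: factor + residual sums of squares equal the total
  expect_equal(sum(tab$sumsq), oracle[["total"]], tolerance = 1e-6)

  # F = (SS_f/df_f)/(SS_res/df_res)
  res <- tab[tab$term == "Residuals", ]
  f_velocity <- (oracle[["velocity"]] / 3) / (res$sumsq / res$df)
  expect_equal(tab$statistic[tab$term == "velocity"], f_velocity, tolerance = 1e-6)
})

test_that("a large injected method effect is detected and phantom effects are not", {
  records <- null_run_records(502, effect_modal = 3)
  tab <- tidy(anova_rmse(records, "run"))
  p <- setNames(tab$p.value, tab$term)
  expect_lt(p[["method"]], 1e-4)
  expect_gt(p[["velocity"]], 0.05)
  expect_gt(p[["joint"]], 0.05)
})

test_that("constant RMSE leaves no variance for any factor", {
  records <- null_run_records(503) %>%
    dplyr::mutate(rmse_deg = 5, benchmark_rmse_deg = 5)
  tab <- tidy(anova_rmse(records, "run"))
  expect_lt(max(tab$sumsq), 1e-20)
})

test_that("single-level factors are rejected by name", {
  records <- null_run_records(504) %>% dplyr::filter(speed_mps == 2.0)
  expect_error(anova_rmse(records, "run"),
    class = "ikcgait_design_error", regexp = "velocity"
  )
})

test_that("mode-specific factor sets are fitted", {
  d <- generate_gait(synthetic_config(
    n_subjects = 3, walk_speeds = c(1.0, 1.2), walk_inclines = c(0, 5),
    run_speeds = c(2.0, 2.2), stair_inclines = c(20, 25, 30),
    strides_walk_run = 4, strides_stair = 3, seed = 505
  ))
  rec <- evaluate_all(d)
  expect_setequal(
    tidy(anova_rmse(rec, "walk"))$term,
    c("subject", "velocity", "incline", "joint", "method", "Residuals")
  )
  expect_setequal(
    tidy(anova_rmse(rec, "run"))$term,
    c("velocity", "joint", "method", "Residuals")
  )
  expect_setequal(
    tidy(anova_rmse(rec, "stair_descent"))$term,
    c("subject", "incline", "joint", "method", "Residuals")
  )
  g <- glance(anova_rmse(rec, "walk"))
  expect_true(g$r.squared >= 0 && g$r.squared <= 1)
})

test_that("Tukey-Kramer contrasts: identical groups give p near 1", {
  vals <- c(1, 2, 3, 4)
  records <- tidyr::expand_grid(
    method = c("walking_baseline", "modal_baseline"), i = 1:4
  ) %>%
    dplyr::mutate(
      subject = paste0("S", i), mode = "run", speed_mps = 2, incline_deg = 0,
      joint = "ankle", rmse_deg = vals[i], benchmark_rmse_deg = vals[i],
      improvement_deg = 0, percent_improvement = 0
    )
  tk <- tukey_method_contrast(records, "run", "ankle")
  expect_true(all(tk$adj.p.value > 0.99))
  expect_equal(nrow(tk), 3) # all pairs among wb, mb, none
})

test_that("Tukey-Kramer flags a strongly separated method", {
  withr::with_seed(506, {
    records <- tidyr::expand_grid(
      method = c("walking_baseline", "modal_baseline"), i = 1:10
    ) %>%
      dplyr::mutate(
        subject = paste0("S", i), mode = "run", speed_mps = 2, incline_deg = 0,
        joint = "ankle",
        rmse_deg = 5 + rnorm(dplyr::n(), sd = 0.3) -
          10 * 0.3 * (method == "modal_baseline"),
        benchmark_rmse_deg = 5 + rnorm(dplyr::n(), sd = 0.3),
        improvement_deg = benchmark_rmse_deg - rmse_deg,
        percent_improvement = 100 * improvement_deg / benchmark_rmse_deg
      )
  })
  tk <- tukey_method_contrast(records, "run", "ankle")
  sep <- tk[tk$contrast == "none-modal_baseline", ]
  expect_lt(sep$adj.p.value, 1e-4)
})

test_that("sparse groups cannot be contrasted", {
  records <- null_run_records(507)[1, ]
  expect_error(
    tukey_method_contrast(records, "run", "ankle"),
    class = "ikcgait_contrast_error"
  )
})
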