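# Mode-specific factor sets for the RMSE ANOVA. Running lacks subject and
# incline terms; stairs lack velocity.
anova_factor_sets <- list(
  walk = c("subject", "velocity", "incline", "joint", "method"),
  run = c("velocity", "joint", "method"),
  stair_ascent = c("subject", "incline", "joint", "method"),
  stair_descent = c("subject", "incline", "joint", "method")
)

# Expands prediction records with the non-individualized benchmark as an
# explicit method level ("none"): one extra row per distinct
# (subject, task, joint) carrying the benchmark RMSE. This makes the
# benchmark available as a contrast level in the ANOVA and post-hoc tests.
with_benchmark_records <- function(records) {
  none <- records %>%
    dplyr::distinct(
      .data$subject, .data$mode, .data$speed_mps, .data$incline_deg,
      .data$joint, .data$benchmark_rmse_deg
    ) %>%
    dplyr::mutate(method = "none", rmse_deg = .data$benchmark_rmse_deg)
  dplyr::bind_rows(
    dplyr::select(
      records, "subject", "mode", "speed_mps", "incline_deg", "joint",
      "method", "rmse_deg"
    ),
    dplyr::select(
      none, "subject", "mode", "speed_mps", "incline_deg", "joint",
      "method", "rmse_deg"
    )
  )
}

#' Per-mode N-way ANOVA of prediction RMSE
#'
#' Fits a main-effects fixed-factor ANOVA of the gait-cycle RMSE for one
#' ambulation mode, with the mode-specific factor set: walking uses subject,
#' velocity, incline, joint and individualization method; running uses
#' velocity, joint and method; stair ascent/descent use subject, incline,
#' joint and method. The non-individualized benchmark enters as an extra
#' `method` level (`"none"`) so contrasts against it are available. All
#' factors are fixed and RMSE enters untransformed (degrees).
#'
#' @param records An `ikc_records` tibble (see [evaluate_mode()]); must
#'   contain the mode's records, with stair records already excluding the
#'   modal baseline task.
#' @param mode Ambulation mode whose model to fit.
#' @return An object of class `ikc_anova` wrapping the fitted [stats::aov()]
#'   model; use [tidy()] for the F table and [glance()] for fit summaries.
#' @export
anova_rmse <- function(records, mode) {
  mode <- match.arg(mode, gait_modes)
  factors <- anova_factor_sets[[mode]]
  df <- with_benchmark_records(records[records$mode == mode, , drop = FALSE])
  if (nrow(df) == 0) {
    abort(paste0("No records for mode '", mode, "'."), class = "ikcgait_value_error")
  }
  df <- dplyr::transmute(df,
    rmse = .data$rmse_deg,
    subject = factor(.data$subject),
    velocity = factor(.data$speed_mps),
    incline = factor(.data$incline_deg),
    joint = factor(.data$joint),
    method = factor(.data$method)
  )
  n_levels <- vapply(df[factors], nlevels, integer(1))
  if (any(n_levels < 2)) {
    abort(
      paste0(
        "Factor(s) with a single level cannot enter the ANOVA: ",
        paste(factors[n_levels < 2], collapse = ", ")
      ),
      class = "ikcgait_design_error"
    )
  }
  fit <- aov(stats::reformulate(factors, response = "rmse"), data = df)
  structure(
    list(mode = mode, factors = factors, fit = fit, n = nrow(df)),
    class = "ikc_anova"
  )
}

#' @export
print.ikc_anova <- function(x, ...) {
  cat("N-way ANOVA of prediction RMSE - mode:", x$mode, "\n")
  cat("Factors:", paste(x$factors, collapse = ", "), " (n =", x$n, ")\n\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the per-factor F table of an RMSE ANOVA
#'
#' @param x An `ikc_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per factor plus the residual row: `term`,
#'   `df`, `sumsq`, `meansq`, `statistic` (F), `p.value`.
#' @export
tidy.ikc_anova <- function(x, ...) {
  tab <- summary(x$fit)[[1]]
  tibble::tibble(
    mode = x$mode,
    term = trimws(rownames(tab)),
    df = tab[["Df"]],
    sumsq = tab[["Sum Sq"]],
    meansq = tab[["Mean Sq"]],
    statistic = tab[["F value"]],
    p.value = tab[["Pr(>F)"]]
  )
}

#' One-row summary of an RMSE ANOVA
#'
#' @inheritParams tidy.ikc_anova
#' @return A tibble with `mode`, `n`, `df.residual`, `r.squared`, and
#'   `sigma` (residual standard deviation, degrees).
#' @export
glance.ikc_anova <- function(x, ...) {
  tab <- tidy(x)
  resid <- tab[tab$term == "Residuals", ]
  tibble::tibble(
    mode = x$mode,
    n = x$n,
    df.residual = resid$df,
    r.squared = 1 - resid$sumsq / sum(tab$sumsq),
    sigma = sqrt(resid$meansq)
  )
}

#' Tukey-Kramer contrasts of individualization method within a joint
#'
#' All pairwise comparisons of individualization methods (including the
#' `"none"` benchmark level) for one mode and joint, with Tukey-Kramer
#' adjusted p-values from [stats::TukeyHSD()] on a one-way fit, which handles
#' unequal group sizes.
#'
#' @param records An `ikc_records` tibble.
#' @param mode,joint Group selector.
#' @return A tibble with one row per method pair: `contrast`, `estimate`
#'   (difference in mean RMSE, degrees), `conf.low`, `conf.high`,
#'   `adj.p.value`.
#' @export
tukey_method_contrast <- function(records, mode, joint) {
  mode <- match.arg(mode, gait_modes)
  joint <- match.arg(joint, gait_joints)
  df <- with_benchmark_records(records[records$mode == mode, , drop = FALSE])
  df <- df[df$joint == joint, , drop = FALSE]
  counts <- table(df$method)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("Need at least 2 methods with at least 2 records each.",
      class = "ikcgait_contrast_error"
    )
  }
  df$method <- factor(df$method)
  fit <- aov(rmse_deg ~ method, data = df)
  tk <- TukeyHSD(fit)$method
  tibble::tibble(
    mode = mode,
    joint = joint,
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"],
    adj.p.value = tk[, "p adj"]
  )
}
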