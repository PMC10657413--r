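#' Tidy a GRI result
#'
#' @param x A `gri_result` from [gri()].
#' @param ... Unused.
#' @return A one-row tibble: `treatment`, `control`, `vehicle`,
#'   `gri_percent`, `t_stat`, `df`, `p_value`, `day_lo`, `day_hi`.
#' @export
tidy.gri_result <- function(x, ...) {
  tibble(
    treatment = x$treatment, control = x$control, vehicle = x$vehicle,
    gri_percent = x$gri_percent, t_stat = unname(x$t_stat),
    df = unname(x$df), p_value = unname(x$p_value),
    day_lo = x$day_window[1], day_hi = x$day_window[2]
  )
}

#' @rdname tidy.gri_result
#' @export
glance.gri_result <- function(x, ...) tidy(x, ...)

#' @export
print.gri_result <- function(x, ...) {
  cat(sprintf(
    "Growth-rate inhibition: %s vs %s (vehicle %s)\n", x$treatment,
    x$control, x$vehicle
  ))
  cat(sprintf("  GRI = %.1f%%  (Welch t = %.3f, df = %.2f, p = %.4g)\n",
              x$gri_percent, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Tidy a synergy result
#'
#' @param x A `synergy_result` from [synergy_score()].
#' @param ... Unused.
#' @return A one-row tibble: the four arm labels plus vehicle,
#'   `score_percent`, `se`, `df`, `t_stat`, `p_value`, `label`.
#' @export
tidy.synergy_result <- function(x, ...) {
  tibble(
    ab = unname(x$arms["ab"]), a = unname(x$arms["a"]),
    b = unname(x$arms["b"]), control = unname(x$arms["control"]),
    vehicle = unname(x$arms["vehicle"]),
    score_percent = x$score_percent, se = x$se, df = x$df,
    t_stat = x$t_stat, p_value = x$p_value, label = x$label
  )
}

#' @rdname tidy.synergy_result
#' @export
glance.synergy_result <- function(x, ...) tidy(x, ...)

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("Growth-rate synergy score: %s = %s + %s (control %s)\n",
              x$arms["ab"], x$arms["a"], x$arms["b"], x$arms["control"]))
  cat(sprintf("  score = %.1f%%  (SE %.1f, t = %.3f, df = %.2f, p = %.4g)\n",
              x$score_percent, x$se, x$t_stat, x$df, x$p_value))
  cat(sprintf("  classification at alpha = %.2g: %s\n", x$alpha, x$label))
  invisible(x)
}

#' Tidy a log-rank result
#'
#' @param x A `logrank_result` from [logrank_test()].
#' @param ... Unused.
#' @return A one-row tibble: `chi_square`, `df`, `p_value`.
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value)
}

#' @rdname tidy.logrank_result
#' @export
glance.logrank_result <- function(x, ...) tidy(x, ...)

#' @export
print.logrank_result <- function(x, ...) {
  cat("Two-sided log-rank test\n")
  cat(sprintf("  chi-square = %.3f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  arms: %s\n",
              paste(names(x$n), "(n =", x$n, ")", collapse = ", ")))
  invisible(x)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d arms, %d animals, %d measurements (seed %s)\n",
    nrow(x$config$arms), nrow(x$truth), nrow(x$table),
    format(x$config$seed)
  ))
  invisible(x)
}
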