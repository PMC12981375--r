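#' Convert standardized gaps into policy-relevant effect summaries
#'
#' Back-transforms the treated brand's gap series to the equivalized-unit
#' scale using the treated brand's own standardization parameters. Because
#' both the actual and the synthetic series are mapped through the same
#' affine transform, the location term cancels in their difference:
#' `units_gap = gap * scale`. This is also why the cumulative unit effect is
#' identical across standardization methods whenever the fitted gaps agree.
#'
#' @param fit The treated brand's [fit_scm()].
#' @param std The [standardize_panel()] result used for the fit.
#' @param panel The raw [sales_panel()].
#' @param window Week indices to accumulate over (default: the post window,
#'   see [effect_window()]).
#' @return Object of class `effect_summary`: `window_used`,
#'   `cumulative_units` (negative = reduction), `final_week_pct`
#'   (percent by which actual sales fall short of synthetic at the last
#'   analyzed week), `weekly_units_gap` (all weeks), `sd_gap_final`
#'   (standardized gap at the final analyzed week), `final_week`,
#'   `actual_final_units`, `synthetic_final_units`.
#' @export
effect_summary <- function(fit, std, panel,
                           window = effect_window(fit$windows)) {
  stopifnot(inherits(fit, "scm_fit"), inherits(std, "standardized_panel"),
            inherits(panel, "sales_panel"))
  if (any(window < 1L) || any(window > length(fit$gap))) {
    stop("window outside analyzed weeks", call. = FALSE)
  }
  focal <- fit$focal_id
  sc <- std$scale[[focal]]
  loc <- std$location[[focal]]
  weekly_units_gap <- fit$gap * sc
  cumulative_units <- sum(weekly_units_gap[window])
  final_week <- max(window)
  synth_final <- destandardize(fit$synthetic[final_week], loc, sc)
  actual_final <- panel$sales[focal, final_week]
  if (is.finite(synth_final) && synth_final > 0) {
    final_week_pct <- 100 * (synth_final - actual_final) / synth_final
  } else {
    warning("destandardized synthetic is non-positive at the final week; ",
            "percent reduction undefined", call. = FALSE)
    final_week_pct <- NA_real_
  }
  structure(list(window_used = window,
                 cumulative_units = cumulative_units,
                 final_week_pct = final_week_pct,
                 weekly_units_gap = weekly_units_gap,
                 sd_gap_final = fit$gap[final_week],
                 final_week = final_week,
                 actual_final_units = actual_final,
                 synthetic_final_units = synth_final),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  w <- x$window_used
  cat("Effect summary over weeks ", w[1], "-", w[length(w)], "\n", sep = "")
  dir <- if (x$cumulative_units < 0) "reduction" else "increase"
  cat(sprintf("  cumulative %s: %s equivalized units\n", dir,
              format(round(abs(x$cumulative_units)), big.mark = ",")))
  if (is.finite(x$final_week_pct)) {
    cat(sprintf("  final-week (week %d) sales %.1f%% %s synthetic\n",
                x$final_week, abs(x$final_week_pct),
                if (x$final_week_pct >= 0) "below" else "above"))
  }
  cat(sprintf("  final-week gap: %.1f standardized units\n", x$sd_gap_final))
  invisible(x)
}
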