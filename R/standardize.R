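#' Rescale each brand's sales using pre-intervention statistics
#'
#' Weekly unit sales differ across brands by four orders of magnitude, so the
#' synthetic-control fit is run on a per-brand rescaled panel. All location
#' and scale parameters are estimated from the pre-intervention window only,
#' then applied to all weeks, which keeps the transform exactly invertible
#' and prevents post-period information from leaking into the fit.
#'
#' Three methods are supported:
#' \describe{
#'   \item{zscore}{subtract the pre-period mean, divide by the pre-period SD
#'     (sample SD, `n-1` denominator, by default).}
#'   \item{minmax}{subtract the pre-period minimum, divide by the pre-period
#'     range.}
#'   \item{robust}{subtract the pre-period median, divide by the pre-period
#'     IQR (interpolated quantiles, `type = 7`, by default).}
#' }
#'
#' Brands whose scale is zero under the chosen method (constant pre-period
#' sales; zero IQR) cannot be rescaled: donor brands are dropped with a
#' warning, a degenerate treated brand is a fatal error.
#'
#' @param panel A [sales_panel()] with no missing cells
#'   (run [filter_brands()] first).
#' @param windows A [study_windows()] object.
#' @param method One of `"zscore"`, `"minmax"`, `"robust"`.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n) denominator
#'   for the z-score SD.
#' @param quantile_type Quantile algorithm for the robust method, passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @return An object of class `standardized_panel`: list with `values`
#'   (brand x week matrix), `method`, `location`, `scale` (named per-brand
#'   vectors), `treated_id`, `windows`, and `dropped` (ids of zero-scale
#'   donors removed).
#' @export
standardize_panel <- function(panel, windows,
                              method = c("zscore", "minmax", "robust"),
                              sd_type = c("sample", "population"),
                              quantile_type = 7) {
  stopifnot(inherits(panel, "sales_panel"), inherits(windows, "study_windows"))
  method <- match.arg(method)
  sd_type <- match.arg(sd_type)
  if (length(panel$incomplete_brands)) {
    stop("panel has incomplete brands; run filter_brands() first",
         call. = FALSE)
  }
  if (ncol(panel$sales) != windows$n_weeks) {
    stop("panel and windows disagree on the number of weeks", call. = FALSE)
  }
  pre <- panel$sales[, windows$pre, drop = FALSE]
  loc_scale <- switch(method,
    zscore = {
      m <- rowMeans(pre)
      s <- apply(pre, 1L, stats::sd)
      if (sd_type == "population") {
        n <- ncol(pre)
        s <- s * sqrt((n - 1) / n)
      }
      list(location = m, scale = s)
    },
    minmax = {
      lo <- apply(pre, 1L, min)
      hi <- apply(pre, 1L, max)
      list(location = lo, scale = hi - lo)
    },
    robust = {
      med <- apply(pre, 1L, stats::median)
      q <- t(apply(pre, 1L, stats::quantile, probs = c(0.25, 0.75),
                   type = quantile_type, names = FALSE))
      list(location = med, scale = q[, 2] - q[, 1])
    })
  location <- loc_scale$location
  scale <- loc_scale$scale
  names(location) <- names(scale) <- panel$brand_ids
  bad <- !is.finite(scale) | scale <= 0
  if (bad[panel$treated_id]) {
    stop("fatal: treated brand '", panel$treated_id,
         "' has zero pre-period scale under method '", method, "'",
         call. = FALSE)
  }
  dropped <- panel$brand_ids[bad]
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " donor brand(s) with zero pre-period scale under '", method,
            "': ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  keep <- !bad
  values <- (panel$sales[keep, , drop = FALSE] - location[keep]) / scale[keep]
  structure(list(values = values,
                 method = method,
                 location = location[keep],
                 scale = scale[keep],
                 treated_id = panel$treated_id,
                 brand_ids = panel$brand_ids[keep],
                 windows = windows,
                 dropped = dropped),
            class = "standardized_panel")
}

#' @export
print.standardized_panel <- function(x, ...) {
  cat("Standardized panel (", x$method, "): ", nrow(x$values), " brands x ",
      ncol(x$values), " weeks\n", sep = "")
  if (length(x$dropped)) cat("  dropped zero-scale donors:",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Invert a per-brand standardization
#'
#' Maps a standardized series back to equivalized units:
#' `values * scale + location`. Used to express synthetic (counterfactual)
#' series and gaps on the unit scale.
#'
#' @param values Numeric vector of standardized values.
#' @param location Location parameter of the brand (pre-period mean /
#'   minimum / median).
#' @param scale Positive scale parameter (pre-period SD / range / IQR).
#' @return Numeric vector on the equivalized-unit scale.
#' @export
destandardize <- function(values, location, scale) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive",
                                            call. = FALSE)
  values * scale + location
}
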