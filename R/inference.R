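#' Mean squared gap over a window
#'
#' @param gap Numeric gap series (focal minus synthetic).
#' @param window Integer week indices.
#' @return Non-negative scalar: `mean(gap[window]^2)`.
#' @export
window_mse <- function(gap, window) {
  if (length(window) == 0L) stop("window is empty", call. = FALSE)
  mean(gap[window]^2)
}

#' Permutation (Fisher-exact-style) p-value
#'
#' The p-value is the share of units whose statistic is at least as extreme
#' as the treated unit's; ties count as "at least as extreme". With
#' `include_treated = TRUE` (the convention used throughout: the treated unit
#' is one of the n units being ranked) the smallest attainable p is `1/n`.
#'
#' @param treated_stat Scalar test statistic of the treated unit.
#' @param placebo_stats Numeric vector of placebo statistics (treated
#'   excluded).
#' @param include_treated Count the treated unit itself in numerator and
#'   denominator (default `TRUE`).
#' @return p-value in `(0, 1]`.
#' @export
fisher_p <- function(treated_stat, placebo_stats, include_treated = TRUE) {
  if (length(placebo_stats) == 0L) stop("placebo_stats is empty",
                                        call. = FALSE)
  hits <- sum(placebo_stats >= treated_stat)
  n <- length(placebo_stats)
  if (include_treated) {
    hits <- hits + 1L
    n <- n + 1L
  }
  hits / n
}

#' Placebo analysis: every brand gets its own synthetic control
#'
#' Runs an in-space placebo study. The treated brand is fitted against all
#' other brands. Each remaining brand is then cast as a "false treated" unit
#' and fitted against a donor pool that excludes both itself and (by
#' default) the genuinely treated brand, so the null distribution is not
#' contaminated by the real effect. Each brand contributes a gap series, a
#' pre- and post-window MSE, and their ratio — the test statistic of the
#' overall permutation test. Brands whose placebo fit fails are excluded
#' from the null distribution with a warning and `n` adjusted.
#'
#' @param std A [standardize_panel()] result.
#' @param treated_id Treated brand (default: the panel's).
#' @param windows A [study_windows()] (default: the panel's).
#' @param include_treated_in_pools Keep the treated brand in placebo donor
#'   pools (default `FALSE`).
#' @param weekly_stat `"absolute"` (default, two-sided: compare `|gap|`) or
#'   `"signed"` (one-sided: compare `-gap`, i.e. larger sales drops are more
#'   extreme) for week-specific p-values.
#' @return Object of class `placebo_distribution`: `brand_ids`, `gaps`
#'   (brand x week), `pre_mse`, `post_mse`, `mse_ratio` (named vectors),
#'   `rank_of_treated`, `p_overall`, `p_weekly` (named by week, over
#'   intervention and post weeks), `treated_fit` (the treated brand's
#'   [fit_scm()] object), `failed` (ids excluded), `n`.
#' @export
placebo_analysis <- function(std, treated_id = std$treated_id,
                             windows = std$windows,
                             include_treated_in_pools = FALSE,
                             weekly_stat = c("absolute", "signed")) {
  stopifnot(inherits(std, "standardized_panel"))
  weekly_stat <- match.arg(weekly_stat)
  ids <- std$brand_ids
  if (length(ids) < 3L) stop("need at least 3 brands", call. = FALSE)
  if (!treated_id %in% ids) stop("treated brand not in panel", call. = FALSE)

  fits <- vector("list", length(ids))
  names(fits) <- ids
  failed <- character(0)
  for (b in ids) {
    pool <- setdiff(ids, b)
    if (!include_treated_in_pools && b != treated_id) {
      pool <- setdiff(pool, treated_id)
    }
    fits[[b]] <- tryCatch(
      fit_scm(std, focal_id = b, donor_ids = pool, windows = windows),
      error = function(e) {
        warning("placebo fit failed for '", b, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  if (is.null(fits[[treated_id]])) {
    stop("synthetic-control fit failed for the treated brand", call. = FALSE)
  }
  failed <- ids[vapply(fits, is.null, logical(1))]
  kept <- setdiff(ids, failed)
  gaps <- do.call(rbind, lapply(fits[kept], function(f) f$gap))
  rownames(gaps) <- kept
  pre_mse <- vapply(kept, function(b) window_mse(gaps[b, ], windows$pre),
                    numeric(1))
  post_mse <- vapply(kept, function(b) window_mse(gaps[b, ], windows$post),
                     numeric(1))
  mse_ratio <- post_mse / pre_mse
  n <- length(kept)
  treated_ratio <- mse_ratio[[treated_id]]
  rank_of_treated <- sum(mse_ratio >= treated_ratio)
  p_overall <- rank_of_treated / n

  analysis_weeks <- c(windows$intervention, windows$post)
  stat_mat <- if (weekly_stat == "absolute") abs(gaps) else -gaps
  p_weekly <- vapply(analysis_weeks, function(wk) {
    fisher_p(stat_mat[treated_id, wk],
             stat_mat[setdiff(kept, treated_id), wk],
             include_treated = TRUE)
  }, numeric(1))
  names(p_weekly) <- as.character(analysis_weeks)

  structure(list(brand_ids = kept,
                 treated_id = treated_id,
                 gaps = gaps,
                 pre_mse = pre_mse,
                 post_mse = post_mse,
                 mse_ratio = mse_ratio,
                 rank_of_treated = rank_of_treated,
                 p_overall = p_overall,
                 p_weekly = p_weekly,
                 weekly_stat = weekly_stat,
                 treated_fit = fits[[treated_id]],
                 failed = failed,
                 n = n,
                 windows = windows),
            class = "placebo_distribution")
}

#' @export
print.placebo_distribution <- function(x, ...) {
  cat("Placebo distribution over ", x$n, " brands (treated: '",
      x$treated_id, "')\n", sep = "")
  cat(sprintf("  treated MSE ratio: %.2f (rank %d of %d)\n",
              x$mse_ratio[[x$treated_id]], x$rank_of_treated, x$n))
  cat(sprintf("  overall p = %.4f (%d/%d)\n", x$p_overall,
              x$rank_of_treated, x$n))
  fw <- names(x$p_weekly)[length(x$p_weekly)]
  cat(sprintf("  final-week p = %.4f (week %s)\n",
              x$p_weekly[[length(x$p_weekly)]], fw))
  invisible(x)
}

#' Week-specific permutation p-value
#'
#' Compares the treated brand's gap at one week against every brand's gap at
#' that week (treated included in the count), using the statistic configured
#' in the placebo analysis (absolute gap by default).
#'
#' @param placebos A [placebo_analysis()] result.
#' @param week Week index within the intervention or post window.
#' @return p-value in `[1/n, 1]`.
#' @export
weekly_p <- function(placebos, week) {
  stopifnot(inherits(placebos, "placebo_distribution"))
  key <- as.character(week)
  if (!key %in% names(placebos$p_weekly)) {
    stop("week ", week, " is outside the intervention/post analysis range",
         call. = FALSE)
  }
  placebos$p_weekly[[key]]
}

#' Diagnostic table of pre/post MSEs and ratio ranks
#'
#' One row per brand: pre-window MSE, post-window MSE, their ratio, and the
#' rank of the ratio (1 = largest; ties share the max-style rank). Sorted by
#' rank. Useful for spotting brands whose high rank is driven by a tiny
#' pre-period MSE denominator rather than a large post-period divergence.
#'
#' @param placebos A [placebo_analysis()] result.
#' @return data.frame with columns `brand`, `pre_mse`, `post_mse`, `ratio`,
#'   `rank`, `is_treated`.
#' @export
mse_scatter <- function(placebos) {
  stopifnot(inherits(placebos, "placebo_distribution"))
  r <- placebos$mse_ratio
  rk <- vapply(r, function(x) sum(r >= x), numeric(1))
  out <- data.frame(brand = placebos$brand_ids,
                    pre_mse = unname(placebos$pre_mse),
                    post_mse = unname(placebos$post_mse),
                    ratio = unname(r),
                    rank = as.integer(unname(rk)),
                    is_treated = placebos$brand_ids == placebos$treated_id,
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$brand), , drop = FALSE]
}
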