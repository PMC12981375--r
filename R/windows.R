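#' Define the pre/intervention/post partition of the study weeks
#'
#' The analysis splits the weekly calendar into three contiguous, disjoint
#' blocks: a pre-intervention window used to estimate standardization
#' parameters and synthetic-control weights, an intervention window during
#' which the regulatory actions roll out, and a post-intervention window over
#' which effects are summarized. Defaults correspond to a 52-week year with
#' the intervention spanning weeks 20--30 (import alert through
#' distributor warning letters) and a 22-week post period.
#'
#' @param pre Integer vector of pre-intervention week indices (default `1:19`).
#' @param intervention Integer vector of intervention week indices
#'   (default `20:30`).
#' @param post Integer vector of post-intervention week indices
#'   (default `31:52`).
#' @return An object of class `study_windows`: a list with elements `pre`,
#'   `intervention`, `post`, and `n_weeks`.
#' @examples
#' w <- study_windows()
#' w$post[1]   # first post-intervention week
#' @export
study_windows <- function(pre = 1:19, intervention = 20:30, post = 31:52) {
  pre <- as.integer(pre)
  intervention <- as.integer(intervention)
  post <- as.integer(post)
  blocks <- list(pre = pre, intervention = intervention, post = post)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (length(b) == 0L) stop("window '", nm, "' is empty", call. = FALSE)
    if (any(diff(b) != 1L)) {
      stop("window '", nm, "' must be contiguous with unit step", call. = FALSE)
    }
  }
  if (length(pre) < 2L) {
    stop("pre window needs at least 2 weeks (scale estimation requires dispersion)",
         call. = FALSE)
  }
  all_weeks <- c(pre, intervention, post)
  n <- length(all_weeks)
  if (anyDuplicated(all_weeks) || !identical(all_weeks, seq_len(n))) {
    stop("windows must be disjoint, ordered, and cover weeks 1..T exactly",
         call. = FALSE)
  }
  structure(list(pre = pre, intervention = intervention, post = post,
                 n_weeks = n),
            class = "study_windows")
}

#' @export
print.study_windows <- function(x, ...) {
  cat("Study windows over", x$n_weeks, "weeks\n")
  cat("  pre:         ", x$pre[1], "-", x$pre[length(x$pre)], "\n")
  cat("  intervention:", x$intervention[1], "-",
      x$intervention[length(x$intervention)], "\n")
  cat("  post:        ", x$post[1], "-", x$post[length(x$post)], "\n")
  invisible(x)
}

#' Weeks over which effects are accumulated
#'
#' The conservative default accumulates effects over the post-intervention
#' window only. Setting `include_intervention = TRUE` additionally counts the
#' intervention weeks, i.e. measures the impact from the first action onward.
#'
#' @param windows A [study_windows()] object.
#' @param include_intervention Logical; include the intervention window.
#' @return Integer vector of week indices.
#' @export
effect_window <- function(windows, include_intervention = FALSE) {
  stopifnot(inherits(windows, "study_windows"))
  if (include_intervention) c(windows$intervention, windows$post) else windows$post
}
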