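#' Least squares on the probability simplex
#'
#' Solves `min_w ||y - X w||^2` subject to `w >= 0`, `sum(w) = 1` with a
#' primal active-set algorithm (Lawson-Hanson style, adapted to the simplex
#' constraint). Each iteration solves the equality-constrained KKT system on
#' the current support; variables driven negative are clipped at the boundary
#' and removed, and a zero-weight variable is admitted only when its reduced
#' gradient is below the support's Lagrange multiplier. The method is exact
#' up to linear-solve precision, fully deterministic (uniform-weight start,
#' first-index tie-breaks), and needs no seed. A tiny ridge proportional to
#' `trace(X'X)` regularises the linear solves so collinear (even identical)
#' donor columns yield a well-defined, reproducible solution.
#'
#' @param X Numeric matrix (weeks x donors) of pre-period donor outcomes.
#' @param y Numeric vector of pre-period focal outcomes.
#' @param tol Convergence tolerance on the KKT conditions.
#' @param max_iter Iteration cap (each iteration is one small dense solve).
#' @return List with `w` (weights), `objective` (sum of squared residuals),
#'   `iterations`, and `converged`.
#' @keywords internal
simplex_lsq <- function(X, y, tol = 1e-9, max_iter = 1000L) {
  J <- ncol(X)
  if (J < 1L) stop("need at least one donor", call. = FALSE)
  obj_of <- function(w) sum((y - X %*% w)^2)
  if (J == 1L) {
    return(list(w = 1, objective = obj_of(1), iterations = 0L,
                converged = TRUE))
  }
  Q <- crossprod(X)
  c0 <- drop(crossprod(X, y))
  ridge <- 1e-12 * max(mean(diag(Q)), 1)
  solve_support <- function(P) {
    k <- length(P)
    A <- rbind(cbind(Q[P, P, drop = FALSE] + diag(ridge, k), rep(1, k)),
               c(rep(1, k), 0))
    sol <- tryCatch(solve(A, c(c0[P], 1)),
                    error = function(e) qr.solve(A, c(c0[P], 1),
                                                 tol = 1e-14))
    list(z = sol[seq_len(k)], lambda = sol[k + 1L])
  }
  w <- rep(1 / J, J)
  P <- seq_len(J)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    es <- solve_support(P)
    z <- es$z
    if (min(z) >= -tol) {
      wP <- pmax(z, 0)
      wP <- wP / sum(wP)
      w[] <- 0
      w[P] <- wP
      g <- drop(Q %*% w) - c0
      lambda <- mean(g[P])
      out <- setdiff(seq_len(J), P)
      if (!length(out)) { converged <- TRUE; break }
      mu <- g[out] - lambda
      jmin <- which.min(mu)
      if (mu[jmin] >= -tol * max(1, abs(lambda))) { converged <- TRUE; break }
      P <- sort(c(P, out[jmin]))
    } else {
      wP <- w[P]
      neg <- which(z < 0)
      alpha <- min(wP[neg] / (wP[neg] - z[neg]))
      wP <- wP + alpha * (z - wP)
      wP[wP < 1e-15] <- 0
      w[] <- 0
      w[P] <- wP
      P <- P[wP > 0]
      if (!length(P)) { # numerically wiped out; restart from best vertex
        P <- which.min(colSums((y - X)^2))
        w[] <- 0
        w[P] <- 1
      }
    }
  }
  w <- pmax(w, 0)
  w <- w / sum(w)
  if (!converged) {
    # iteration cap hit (degenerate cycling); accept if KKT residual is tiny
    g <- drop(Q %*% w) - c0
    lambda <- mean(g[w > 0])
    if (min(g - lambda) >= -1e-6 * max(1, abs(lambda))) converged <- TRUE
  }
  list(w = w, objective = obj_of(w), iterations = iter, converged = converged)
}

#' Fit a synthetic control for one focal brand
#'
#' Estimates non-negative donor weights summing to one that minimise the
#' squared discrepancy between the focal brand's standardized sales and the
#' weighted donor combination over the pre-intervention weeks, with all pre
#' weeks weighted equally (the predictors are the pre-window outcomes
#' themselves; no auxiliary covariates). Weights below `sparsity` are zeroed
#' and the rest renormalized, so the reported count of contributing donors is
#' stable against solver dust.
#'
#' @param std A [standardize_panel()] result.
#' @param focal_id Brand cast as treated for this fit.
#' @param donor_ids Donor pool (defaults to every other brand in `std`).
#' @param windows A [study_windows()]; defaults to the windows stored in
#'   `std`.
#' @param sparsity Threshold below which weights are zeroed (default 1e-6).
#' @param tol Solver KKT tolerance.
#' @return Object of class `scm_fit`: `focal_id`, `donor_ids`, `weights`,
#'   `synthetic` (standardized, all weeks), `gap` (focal minus synthetic),
#'   `pre_mse`, `post_mse`, `objective`, `converged`.
#' @export
fit_scm <- function(std, focal_id, donor_ids = NULL, windows = std$windows,
                    sparsity = 1e-6, tol = 1e-9) {
  stopifnot(inherits(std, "standardized_panel"))
  if (is.null(donor_ids)) donor_ids <- setdiff(std$brand_ids, focal_id)
  if (!focal_id %in% std$brand_ids) {
    stop("focal brand '", focal_id, "' not in standardized panel",
         call. = FALSE)
  }
  if (focal_id %in% donor_ids) {
    stop("focal brand must not be in its own donor pool", call. = FALSE)
  }
  missing_donors <- setdiff(donor_ids, std$brand_ids)
  if (length(missing_donors)) {
    stop("donor(s) not in panel: ", paste(missing_donors, collapse = ", "),
         call. = FALSE)
  }
  if (length(donor_ids) < 2L) {
    stop("need at least 2 donors", call. = FALSE)
  }
  Xpre <- t(std$values[donor_ids, windows$pre, drop = FALSE])
  ypre <- std$values[focal_id, windows$pre]
  sol <- simplex_lsq(Xpre, ypre, tol = tol)
  if (!sol$converged) {
    stop("SCM solver failed to converge after ", sol$iterations,
         " iterations (focal '", focal_id, "', ", length(donor_ids),
         " donors, objective ", format(sol$objective), ")", call. = FALSE)
  }
  w <- sol$w
  w[w < sparsity] <- 0
  w <- w / sum(w)
  synthetic <- drop(w %*% std$values[donor_ids, , drop = FALSE])
  gap <- std$values[focal_id, ] - synthetic
  structure(list(focal_id = focal_id,
                 donor_ids = donor_ids,
                 weights = stats::setNames(w, donor_ids),
                 synthetic = synthetic,
                 gap = gap,
                 pre_mse = mean(gap[windows$pre]^2),
                 post_mse = mean(gap[windows$post]^2),
                 objective = sol$objective,
                 converged = sol$converged,
                 windows = windows),
            class = "scm_fit")
}

#' @export
print.scm_fit <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat("Synthetic control fit for '", x$focal_id, "'\n", sep = "")
  cat("  contributing donors:", nz, "of", length(x$donor_ids), "\n")
  cat("  pre-window MSE: ", format(x$pre_mse, digits = 4),
      "   post-window MSE: ", format(x$post_mse, digits = 4), "\n", sep = "")
  top <- sort(x$weights[x$weights > 0], decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  largest weights:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted donor combination over all weeks
#'
#' @param fit An [fit_scm()] result.
#' @param std The standardized panel the fit was computed on (or any panel
#'   containing the fit's donors).
#' @return Numeric vector: the synthetic series in standardized units.
#' @export
synthetic_series <- function(fit, std) {
  stopifnot(inherits(fit, "scm_fit"), inherits(std, "standardized_panel"))
  missing_donors <- setdiff(fit$donor_ids, std$brand_ids)
  if (length(missing_donors)) {
    stop("donor(s) not in panel: ", paste(missing_donors, collapse = ", "),
         call. = FALSE)
  }
  drop(fit$weights %*% std$values[fit$donor_ids, , drop = FALSE])
}

#' Mean percent gap over the pre-intervention window, on the unit scale
#'
#' Destandardizes the focal and synthetic series with the focal brand's own
#' location/scale and reports the mean of `100 * (actual - synthetic) /
#' synthetic` over pre weeks. A value near zero indicates the synthetic
#' closely tracks the treated brand before the intervention, the SCM
#' analogue of a parallel-trends check.
#'
#' @param fit An [fit_scm()] result.
#' @param panel The raw [sales_panel()].
#' @param std The [standardize_panel()] result used for the fit.
#' @return Mean percent gap (scalar). `NA` with a warning if the
#'   destandardized synthetic is non-positive at any pre week.
#' @export
pre_fit_diagnostic <- function(fit, panel, std) {
  stopifnot(inherits(fit, "scm_fit"), inherits(panel, "sales_panel"),
            inherits(std, "standardized_panel"))
  pre <- fit$windows$pre
  loc <- std$location[[fit$focal_id]]
  sc <- std$scale[[fit$focal_id]]
  synth_units <- destandardize(fit$synthetic[pre], loc, sc)
  actual_units <- panel$sales[fit$focal_id, pre]
  if (any(synth_units <= 0)) {
    warning("synthetic series non-positive in the pre window; ",
            "percent diagnostic undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(100 * (actual_units - synth_units) / synth_units)
}
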