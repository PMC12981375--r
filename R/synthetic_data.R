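#' Configuration for the synthetic retail-sales generator
#'
#' The generator emulates the statistical structure of a national weekly
#' e-cigarette scanner panel: ~52 brands over 52 weeks; heavy-tailed brand
#' sizes (log-normal, median near 1,400 weekly equivalized units with the
#' largest brands in the millions); a mild common downward trend; a low-rank
#' common-factor structure with multiplicative log-normal noise; one treated
#' brand constructed as a convex combination of a handful of donors (so a
#' synthetic control exists by design); and a multiplicative intervention
#' effect ramping in from an onset week to a final-week reduction fraction.
#'
#' @param n_brands Total brands including the treated one (default 52).
#' @param n_weeks Weeks in the panel (default 52).
#' @param windows A [study_windows()] (default: standard 19/11/22 split).
#' @param size_log_mean,size_log_sd Log-normal parameters of mean brand
#'   size; defaults `log(1400)` and `3` reproduce a ~1,400-unit median with
#'   multi-million-unit top brands across 52 draws.
#' @param trend_per_week Common multiplicative trend (default -0.002, i.e.
#'   -0.2%/week).
#' @param n_factors Number of common log-scale factors (default 2).
#' @param factor_loading_sd SD of per-brand factor loadings (default 0.1).
#' @param market_loading Mean loading on the first factor (default 0.3).
#'   A positive market factor makes all brands comove, as weekly scanner
#'   panels do; with mean-zero loadings a multi-donor combination would
#'   average away its variance and become unmatchable after per-brand
#'   rescaling.
#' @param noise_cv Coefficient of variation of multiplicative brand-week
#'   noise (default 0.05).
#' @param treated_n_donors Donors combined into the treated brand's
#'   no-effect path (default 10).
#' @param treated_noise_cv CV of the treated brand's own multiplicative
#'   noise (default 0.02, keeping the pre-period fit within ~1%).
#' @param effect_final_fraction Fraction by which treated sales are below
#'   the counterfactual at the end of the ramp (default 0.685).
#' @param effect_onset_week Week at which the multiplier starts declining
#'   from 1 (default 20; must lie in the intervention window).
#' @param effect_ramp_weeks Weeks from onset to full effect (default: ramp
#'   ends at the final week).
#' @param effect_shape `"linear"` (multiplier declines linearly) or `"log"`
#'   (log-multiplier declines linearly).
#' @param seed Integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_brands = 52L, n_weeks = 52L,
                             windows = study_windows(),
                             size_log_mean = log(1400), size_log_sd = 3,
                             trend_per_week = -0.002,
                             n_factors = 2L, factor_loading_sd = 0.1,
                             market_loading = 0.3,
                             noise_cv = 0.05,
                             treated_n_donors = 10L,
                             treated_noise_cv = 0.02,
                             effect_final_fraction = 0.685,
                             effect_onset_week = 20L,
                             effect_ramp_weeks = NULL,
                             effect_shape = c("linear", "log"),
                             seed = 1L) {
  effect_shape <- match.arg(effect_shape)
  if (is.null(effect_ramp_weeks)) effect_ramp_weeks <- n_weeks - effect_onset_week
  cfg <- list(n_brands = as.integer(n_brands), n_weeks = as.integer(n_weeks),
              windows = windows,
              size_log_mean = size_log_mean, size_log_sd = size_log_sd,
              trend_per_week = trend_per_week,
              n_factors = as.integer(n_factors),
              factor_loading_sd = factor_loading_sd,
              market_loading = market_loading,
              noise_cv = noise_cv,
              treated_n_donors = as.integer(treated_n_donors),
              treated_noise_cv = treated_noise_cv,
              effect_final_fraction = effect_final_fraction,
              effect_onset_week = as.integer(effect_onset_week),
              effect_ramp_weeks = as.integer(effect_ramp_weeks),
              effect_shape = effect_shape,
              seed = as.integer(seed))
  if (cfg$treated_n_donors >= cfg$n_brands) {
    stop("config error: treated_n_donors must be < n_brands", call. = FALSE)
  }
  if (cfg$n_brands < 3L) stop("config error: need at least 3 brands",
                              call. = FALSE)
  if (!cfg$effect_onset_week %in% windows$intervention) {
    stop("config error: effect_onset_week must lie in the intervention window",
         call. = FALSE)
  }
  if (cfg$n_weeks != windows$n_weeks) {
    stop("config error: n_weeks must match the windows", call. = FALSE)
  }
  if (cfg$noise_cv < 0 || cfg$treated_noise_cv < 0) {
    stop("config error: noise CVs must be >= 0", call. = FALSE)
  }
  if (cfg$effect_final_fraction < 0 || cfg$effect_final_fraction >= 1) {
    stop("config error: effect_final_fraction must be in [0, 1)",
         call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# log-normal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

#' Generate a synthetic weekly sales panel with known ground truth
#'
#' Donor brand j at week t has expected sales
#' `mu_j * (1 + trend)^(t-1) * exp(sum_k lambda_jk f_kt)` times multiplicative
#' log-normal noise. The treated brand's counterfactual (no-effect) path is a
#' random convex combination of `treated_n_donors` realized donor paths times
#' its own noise; its observed path is the counterfactual times an effect
#' multiplier equal to 1 before `effect_onset_week`, declining to
#' `1 - effect_final_fraction` at the end of the ramp and flat thereafter.
#' Donor series are identical whether or not an effect is injected.
#'
#' @param config A [generator_config()].
#' @return List with `panel` (a [sales_panel()], treated id `"treated"`) and
#'   `truth`: `counterfactual` (treated no-effect path), `multiplier`
#'   (per-week effect multiplier), `donor_ids`, `donor_weights`, and
#'   `config`.
#' @export
generate_panel <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nb <- config$n_brands
  nw <- config$n_weeks
  n_donors <- nb - 1L
  donor_ids <- sprintf("brand_%02d", seq_len(n_donors))

  mu <- stats::rlnorm(n_donors, meanlog = config$size_log_mean,
                      sdlog = config$size_log_sd)
  trend <- (1 + config$trend_per_week)^(seq_len(nw) - 1)
  f <- matrix(stats::rnorm(config$n_factors * nw), config$n_factors, nw)
  lambda <- matrix(stats::rnorm(n_donors * config$n_factors,
                                sd = config$factor_loading_sd),
                   n_donors, config$n_factors)
  lambda[, 1] <- lambda[, 1] + config$market_loading
  common <- exp(lambda %*% f)                      # brands x weeks
  noise <- matrix(rlnorm_cv(n_donors * nw, config$noise_cv), n_donors, nw)
  donors <- mu * sweep(common, 2L, trend, `*`) * noise
  rownames(donors) <- donor_ids

  picked <- sort(sample(donor_ids, config$treated_n_donors))
  gw <- stats::rgamma(config$treated_n_donors, shape = 1)
  w_true <- gw / sum(gw)
  names(w_true) <- picked
  counterfactual <- drop(w_true %*% donors[picked, , drop = FALSE]) *
    rlnorm_cv(nw, config$treated_noise_cv)

  mult <- rep(1, nw)
  ramp_end <- min(config$effect_onset_week + config$effect_ramp_weeks, nw)
  ramp <- seq(config$effect_onset_week, ramp_end)
  frac <- (ramp - config$effect_onset_week) /
    max(ramp_end - config$effect_onset_week, 1L)
  floor_mult <- 1 - config$effect_final_fraction
  mult[ramp] <- if (config$effect_shape == "linear") {
    1 - frac * config$effect_final_fraction
  } else {
    exp(log(floor_mult) * frac)
  }
  if (ramp_end < nw) mult[(ramp_end + 1L):nw] <- floor_mult

  sales <- rbind(donors, treated = counterfactual * mult)
  meta <- data.frame(brand = rownames(sales),
                     product_type = "e-cigarette",
                     stringsAsFactors = FALSE)
  panel <- sales_panel(sales, treated_id = "treated", brand_meta = meta)
  list(panel = panel,
       truth = list(counterfactual = counterfactual,
                    multiplier = mult,
                    donor_ids = picked,
                    donor_weights = w_true,
                    config = config))
}

#' Exact effect implied by the generator's counterfactual
#'
#' @param truth The `truth` element returned by [generate_panel()].
#' @param window Week indices to accumulate over.
#' @return List with `cumulative_units` (sum of actual minus counterfactual;
#'   negative = reduction) and `final_week_fraction` (`1 - multiplier` at
#'   the last week of `window`).
#' @export
ground_truth_effect <- function(truth, window) {
  stopifnot(is.list(truth), !is.null(truth$counterfactual))
  cf <- truth$counterfactual[window]
  actual <- truth$counterfactual[window] * truth$multiplier[window]
  list(cumulative_units = sum(actual - cf),
       final_week_fraction = 1 - truth$multiplier[max(window)])
}
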