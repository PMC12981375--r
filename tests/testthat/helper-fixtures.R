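# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Small complete panel with deterministic values; brand "b1" is treated.
toy_panel <- function(n_brands = 3, n_weeks = 52, seed = 101) {
  set.seed(seed)
  m <- matrix(round(runif(n_brands * n_weeks, 100, 1000)), n_brands, n_weeks)
  rownames(m) <- paste0("b", seq_len(n_brands))
  sales_panel(m, treated_id = "b1")
}

# Long-format data.frame for read_panel tests.
toy_long <- function(panel) {
  data.frame(
    brand = rep(panel$brand_ids, each = length(panel$week_index)),
    week = rep(panel$week_index, times = length(panel$brand_ids)),
    sales = as.vector(t(panel$sales)),
    stringsAsFactors = FALSE)
}

# Compact windows for fast tests: 12 weeks, pre 1-6, intervention 7-8, post 9-12.
small_windows <- function() study_windows(pre = 1:6, intervention = 7:8,
                                          post = 9:12)

# Panel whose treated brand is an exact convex combination of donors over the
# pre window (and everywhere), with optional noise; handy for solver tests.
combo_panel <- function(weights = c(b2 = 0.5, b3 = 0.5), n_weeks = 12,
                        n_extra = 0, seed = 7) {
  set.seed(seed)
  donors <- matrix(exp(rnorm((length(weights) + n_extra) * n_weeks,
                             mean = 5, sd = 0.4)),
                   ncol = n_weeks)
  rownames(donors) <- paste0("b", seq_len(nrow(donors)) + 1L)
  treated <- drop(weights %*% donors[names(weights), , drop = FALSE])
  m <- rbind(b1 = treated, donors)
  sales_panel(m, treated_id = "b1")
}

# Dense grid search over the simplex (step h) minimizing ||y - Xw||^2.
# Independent oracle for the active-set solver; exact up to grid resolution.
grid_simplex_objective <- function(X, y, h = 1e-3) {
  J <- ncol(X)
  stopifnot(J %in% 2:3)
  k <- round(1 / h)
  if (J == 2) {
    w1 <- seq(0, k) / k
    W <- cbind(w1, 1 - w1)
  } else {
    i <- unlist(lapply(0:k, function(a) rep(a, k - a + 1)))
    j <- unlist(lapply(0:k, function(a) 0:(k - a)))
    W <- cbind(i, j, k - i - j) / k
  }
  R <- W %*% t(X)                       # points x weeks
  obj <- rowSums((R - matrix(y, nrow(R), length(y), byrow = TRUE))^2)
  min(obj)
}
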