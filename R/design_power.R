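# Study-design helpers: Monte-Carlo simulators for the expected number of
# zero/low-frequency transition-table cells under a planned design, and
# sample-size calculators (exact noncentral-t for t designs, Fisher-z for
# correlations).

check_cell_probs <- function(cell_probs) {
  p <- as.numeric(cell_probs)
  if (length(p) != 8L) stop("`cell_probs` must have 8 entries (4 x 2 table)",
                            call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("cell probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  p / sum(p)
}

#' Expected number of zero- and low-frequency transition-table cells
#'
#' Simulates the per-dyad 4 x 2 lagged transition table expected under a
#' planned design: in each of `n_sims` simulations the cell assignments are
#' drawn i.i.d. multinomially from the expected cell probabilities, and the
#' numbers of cells with frequency zero and frequency below `low_threshold`
#' are counted. By default one draw is made per transition (`T - 1` draws
#' for `T` intervals); `draws = "intervals"` makes `T` draws instead.
#'
#' A structurally impossible cell (probability 0) contributes exactly 1 to
#' the expected zero-cell count.
#'
#' @param cell_probs Expected cell probabilities: 4 x 2 matrix or length-8
#'   vector summing to 1.
#' @param n_intervals Planned number of observation intervals `T >= 2`.
#' @param low_threshold Cells with frequency strictly below this count as
#'   low-frequency (default 5).
#' @param n_sims Number of simulations (default 10000).
#' @param seed Optional seed; fixed seed gives deterministic output.
#' @param draws `"transitions"` (default, `T - 1` draws) or `"intervals"`
#'   (`T` draws).
#' @return Object of class `cell_freq_sim` with expected counts, their
#'   Monte-Carlo standard errors, and the full count distributions.
#' @export
est_freq <- function(cell_probs, n_intervals, low_threshold = 5L,
                     n_sims = 10000L, seed = NULL,
                     draws = c("transitions", "intervals")) {
  draws <- match.arg(draws)
  p <- check_cell_probs(cell_probs)
  stopifnot(n_intervals >= 2L, n_sims >= 1L)
  n_draw <- n_intervals - (draws == "transitions")
  sims <- with_seed(seed, stats::rmultinom(n_sims, n_draw, p))  # 8 x n_sims
  zero_ct <- colSums(sims == 0L)
  low_ct <- colSums(sims < low_threshold)
  structure(list(
    expected_zero_cells = mean(zero_ct),
    expected_low_cells = mean(low_ct),
    se_zero = stats::sd(zero_ct) / sqrt(n_sims),
    se_low = stats::sd(low_ct) / sqrt(n_sims),
    zero_distribution = table(zero_ct) / n_sims,
    low_distribution = table(low_ct) / n_sims,
    n_intervals = n_intervals, n_draws = n_draw,
    low_threshold = low_threshold, n_sims = n_sims, draws = draws
  ), class = "cell_freq_sim")
}

#' @export
#' @method print cell_freq_sim
print.cell_freq_sim <- function(x, digits = 3, ...) {
  cat("<cell_freq_sim> T = ", x$n_intervals, " (", x$n_draws, " draws), ",
      x$n_sims, " simulations\n", sep = "")
  cat("  expected zero-frequency cells:", round(x$expected_zero_cells, digits),
      "(MC SE", paste0(round(x$se_zero, digits + 1), ")"), "\n")
  cat("  expected cells below ", x$low_threshold, ": ",
      round(x$expected_low_cells, digits),
      " (MC SE ", round(x$se_low, digits + 1), ")\n", sep = "")
  invisible(x)
}

#' Minimum number of intervals keeping problem cells below a tolerance
#'
#' Finds the smallest `T` whose expected number of zero-frequency (or
#' low-frequency) cells, estimated by [est_freq()] with common random
#' numbers (the same seed at every `T`), is at most `tolerance`. Search is
#' by doubling followed by bisection; the expected count is non-increasing
#' in `T`.
#'
#' @inheritParams est_freq
#' @param tolerance Largest acceptable expected number of problem cells.
#' @param which Count `"zero"`-frequency or `"low"`-frequency cells.
#' @param T_max Search cap (default 100000); structurally unreachable
#'   tolerances raise an error.
#' @return List with `n_intervals` (the minimal `T`), `expected` (the
#'   estimate there), `which`, `tolerance`.
#' @export
est_time <- function(cell_probs, tolerance, which = c("low", "zero"),
                     low_threshold = 5L, n_sims = 10000L, seed = 1L,
                     draws = c("transitions", "intervals"), T_max = 100000L) {
  which <- match.arg(which)
  draws <- match.arg(draws)
  p <- check_cell_probs(cell_probs)
  stopifnot(tolerance >= 0)
  n_structural_zero <- sum(p == 0)
  if (which == "zero" && tolerance < n_structural_zero) {
    stop("infeasible: ", n_structural_zero, " structurally empty cell(s) ",
         "always count as zero-frequency", call. = FALSE)
  }
  expected_at <- function(Tn) {
    e <- est_freq(p, Tn, low_threshold = low_threshold, n_sims = n_sims,
                  seed = seed, draws = draws)
    if (which == "zero") e$expected_zero_cells else e$expected_low_cells
  }
  lo <- 2L
  if (expected_at(lo) <= tolerance) {
    return(list(n_intervals = lo, expected = expected_at(lo), which = which,
                tolerance = tolerance))
  }
  hi <- lo
  repeat {
    hi <- min(hi * 2L, T_max)
    if (expected_at(hi) <= tolerance) break
    if (hi >= T_max) {
      stop("tolerance not reachable within T_max = ", T_max, call. = FALSE)
    }
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (expected_at(mid) <= tolerance) hi <- mid else lo <- mid
  }
  list(n_intervals = hi, expected = expected_at(hi), which = which,
       tolerance = tolerance)
}

# Exact power of a two- or one-tailed t test at sample size n.
t_test_power <- function(n, d, alpha, tails, design) {
  if (design == "one_sample") {
    df <- n - 1
    ncp <- d * sqrt(n)
  } else {                      # n = per-group size, two equal groups
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
  }
  if (df < 1) return(0)
  tcrit <- stats::qt(1 - alpha / tails, df)
  pw <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2L) pw <- pw + stats::pt(-tcrit, df, ncp = ncp)
  pw
}

smallest_n <- function(power_fn, target, n_min = 2L) {
  hi <- n_min
  while (power_fn(hi) < target) {
    hi <- hi * 2L
    if (hi > 1e7) stop("sample-size search did not terminate", call. = FALSE)
  }
  lo <- n_min - 1L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_fn(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Sample size for a t test via the exact noncentral-t distribution
#'
#' Smallest integer sample size reaching the target power: the power at `n`
#' is the probability that a noncentral-t variate (df `n - 1`, ncp
#' `d * sqrt(n)` for one sample; df `2n - 2`, ncp `d * sqrt(n/2)` per-group
#' for two samples) exceeds the central-t critical value at the given alpha
#' and tails. Search by doubling plus bisection.
#'
#' @param d Standardized effect size (Cohen's d), nonzero.
#' @param alpha Type-I error rate (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails 1 or 2 (default 2).
#' @param design `"one_sample"` (default) or `"two_sample"` (two equal
#'   groups).
#' @return List with `n` (one-sample: total; two-sample: per group),
#'   `total`, `design`, and `achieved_power` at the returned size.
#' @export
sample_size_t <- function(d, alpha = 0.05, power = 0.80, tails = 2L,
                          design = c("one_sample", "two_sample")) {
  design <- match.arg(design)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, tails %in% c(1L, 2L))
  if (d == 0) stop("infeasible: zero effect size", call. = FALSE)
  d <- abs(d)
  pf <- function(n) t_test_power(n, d, alpha, tails, design)
  n <- smallest_n(pf, power)
  list(n = n,
       total = if (design == "two_sample") 2L * n else n,
       design = design, achieved_power = pf(n))
}

#' Sample size for detecting a correlation (Fisher-z approximation)
#'
#' `n = ((z_{1-alpha/tails} + z_{power}) / atanh(|r|))^2 + 3`, rounded up.
#'
#' @param r Population correlation, `0 < |r| < 1`.
#' @inheritParams sample_size_t
#' @return Integer sample size.
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.80, tails = 2L) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, tails %in% c(1L, 2L))
  if (abs(r) <= 0 || abs(r) >= 1) {
    stop("|r| must be strictly between 0 and 1", call. = FALSE)
  }
  za <- stats::qnorm(1 - alpha / tails)
  zb <- stats::qnorm(power)
  max(4L, as.integer(ceiling(((za + zb) / atanh(abs(r)))^2 + 3)))
}
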