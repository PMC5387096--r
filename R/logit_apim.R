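# Aggregated logit actor-partner models: per-dyad lagged transition tables,
# a saturated effect-coded logit in closed form, across-dyad aggregation with
# one-sample t tests, and group comparisons.

ROW_LABELS <- c("a1_b1", "a1_b0", "a0_b1", "a0_b0")

#' Lagged state-transition table for one dyad
#'
#' Cross-tabulates, over transitions `t = 2..T_obs`, the joint prior state of
#' both behaviors at `t - 1` (rows, ordered (A=yes,B=yes), (yes,no), (no,yes),
#' (no,no)) against occurrence of the target partner's behavior at `t`
#' (columns yes/no). Total count is `T_obs - 1`.
#'
#' @param pair A [dyad_pair()].
#' @param target Which partner's behavior is the outcome: `"b"` (default)
#'   or `"a"`.
#' @return A 4 x 2 integer matrix of class `transition_table` with
#'   attributes `target`, `dyad_id` and `n` (number of transitions).
#' @export
transition_table <- function(pair, target = c("b", "a")) {
  stopifnot(inherits(pair, "dyad_pair"))
  target <- match.arg(target)
  a <- pair$seq_a
  b <- pair$seq_b
  Tn <- length(a)
  prior_a <- a[-Tn]
  prior_b <- b[-Tn]
  out <- if (target == "b") b[-1L] else a[-1L]
  row <- 1L + 2L * (1L - prior_a) + (1L - prior_b)
  counts <- matrix(0L, 4L, 2L, dimnames = list(ROW_LABELS, c("yes", "no")))
  for (k in seq_along(row)) {
    counts[row[k], 2L - out[k]] <- counts[row[k], 2L - out[k]] + 1L
  }
  structure(counts, class = c("transition_table", "matrix"),
            target = target, dyad_id = pair$dyad_id, n = Tn - 1L)
}

#' Wrap printed 4 x 2 counts as a transition table
#'
#' For single-case analyses starting from a published table rather than raw
#' sequences. Rows must be ordered (A=yes,B=yes), (yes,no), (no,yes),
#' (no,no); columns (yes, no) of the target behavior.
#'
#' @param counts 4 x 2 matrix (or length-8 row-major vector) of nonnegative
#'   counts.
#' @param target `"a"` or `"b"`; which partner's behavior the columns count.
#' @param dyad_id Optional id.
#' @export
as_transition_table <- function(counts, target = c("b", "a"), dyad_id = NA_character_) {
  target <- match.arg(target)
  if (!is.matrix(counts)) counts <- matrix(counts, 4L, 2L, byrow = TRUE)
  stopifnot(nrow(counts) == 4L, ncol(counts) == 2L, all(counts >= 0))
  dimnames(counts) <- list(ROW_LABELS, c("yes", "no"))
  structure(counts, class = c("transition_table", "matrix"),
            target = target, dyad_id = dyad_id, n = sum(counts))
}

#' @export
#' @method print transition_table
print.transition_table <- function(x, ...) {
  cat("<transition_table> dyad ", attr(x, "dyad_id"), ", outcome = partner ",
      toupper(attr(x, "target")), ", ", attr(x, "n"), " transitions\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Fit the saturated effect-coded logit model for one transition table
#'
#' Because the model is saturated (four cells' log-odds, four parameters),
#' the maximum-likelihood solution has closed form: with
#' `L_s = ln((n_{s,yes} + c) / (n_{s,no} + c))` for the four prior-state rows
#' and effect codes (+1 shown / -1 not shown) for the two lagged behaviors,
#' the intercept is `mean(L)`, the actor effect `sum(own * L) / 4`, the
#' partner effect `sum(other * L) / 4`, and the interaction
#' `sum(own * other * L) / 4`. With `constant = 0` and all cells positive
#' this equals an iteratively fitted logistic regression on the grouped data.
#' A positive constant (default 0.5, added to every cell) keeps the model
#' estimable when cells are empty, at the cost of a weak conservative bias.
#'
#' @param table A [transition_table()].
#' @param constant Nonnegative value added to all eight cells (default 0.5).
#' @return A [logit_params()] with `constant_used` recorded.
#' @export
fit_saturated_logit <- function(table, constant = 0.5) {
  stopifnot(inherits(table, "transition_table"), constant >= 0)
  cts <- unclass(table)
  if (constant == 0 && any(cts == 0)) {
    stop("zero-frequency cell(s) with constant = 0; use constant = 0.5 ",
         "(or exclude the dyad)", call. = FALSE)
  }
  L <- log((cts[, 1L] + constant) / (cts[, 2L] + constant))
  a_code <- c(1, 1, -1, -1)   # partner A shown at t-1, by row
  b_code <- c(1, -1, 1, -1)   # partner B shown at t-1, by row
  own <- if (attr(table, "target") == "b") b_code else a_code
  other <- if (attr(table, "target") == "b") a_code else b_code
  logit_params(b0 = mean(L),
               b_actor = sum(own * L) / 4,
               b_partner = sum(other * L) / 4,
               b_ixn = sum(a_code * b_code * L) / 4,
               constant_used = constant)
}

#' Aggregate per-dyad logit coefficients across a dataset
#'
#' Fits the saturated effect-coded logit to every dyad's transition table and
#' aggregates each coefficient by averaging; a one-sample t test against 0
#' (df = n - 1) provides inference, and `exp(mean)` gives the odds ratio.
#'
#' @param dataset A `dyad_dataset` with >= 2 usable dyads.
#' @param target `"b"` (default) or `"a"`: the outcome partner.
#' @param constant Zero-frequency constant, applied to all cells of every
#'   table under the `"correct"` policy.
#' @param policy `"correct"` (default: add `constant` everywhere) or
#'   `"drop"` (exclude dyads with any empty cell and fit the rest with
#'   constant 0).
#' @return Object of class `aggregate_logit`: a summary data frame plus the
#'   per-dyad coefficient matrix and exclusion bookkeeping.
#' @export
aggregate_logit <- function(dataset, target = c("b", "a"), constant = 0.5,
                            policy = c("correct", "drop")) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  target <- match.arg(target)
  policy <- match.arg(policy)
  tabs <- lapply(dataset$pairs, transition_table, target = target)
  excluded <- character(0)
  if (policy == "drop") {
    keep <- vapply(tabs, function(tb) all(unclass(tb) > 0L), logical(1))
    excluded <- names(tabs)[!keep]
    tabs <- tabs[keep]
    constant <- 0
  }
  if (length(tabs) < 2L) stop("fewer than 2 usable dyads", call. = FALSE)
  B <- t(vapply(tabs, function(tb) coef(fit_saturated_logit(tb, constant)),
                numeric(4)))
  n <- nrow(B)
  mean_b <- colMeans(B)
  sd_b <- apply(B, 2L, stats::sd)
  tval <- ifelse(sd_b > 0, mean_b / (sd_b / sqrt(n)), NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df = n - 1L)
  if (any(sd_b == 0)) {
    warning("zero between-dyad SD for: ",
            paste(colnames(B)[sd_b == 0], collapse = ", "),
            "; t statistic undefined", call. = FALSE)
  }
  summary_df <- data.frame(parameter = colnames(B), mean = mean_b, sd = sd_b,
                           t = tval, df = n - 1L, p = pval,
                           odds_ratio = exp(mean_b), row.names = NULL)
  structure(list(summary = summary_df, per_dyad = B, target = target,
                 constant = constant, policy = policy, n_dyads = n,
                 n_excluded = length(excluded), excluded = excluded),
            class = "aggregate_logit")
}

#' @export
#' @method print aggregate_logit
print.aggregate_logit <- function(x, digits = 2, ...) {
  cat("<aggregate_logit> outcome = partner ", toupper(x$target), ", n = ",
      x$n_dyads, " dyads", sep = "")
  if (x$n_excluded) cat(" (", x$n_excluded, " excluded)", sep = "")
  cat(", constant = ", x$constant, "\n", sep = "")
  out <- x$summary
  out[-1] <- lapply(out[-1], function(v) round(v, digits))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Full actor-partner summary: both behaviors as outcome
#'
#' Runs [aggregate_logit()] with partner B's behavior as the outcome, then
#' again with partner A's behavior, and reports per-parameter between-outcome
#' differences with paired t tests over the common dyads.
#'
#' @inheritParams aggregate_logit
#' @return Object of class `apim_summary` with elements `outcome_b`,
#'   `outcome_a` (both `aggregate_logit`) and `difference` (data frame of
#'   B-minus-A mean differences, paired t, df, p).
#' @export
apim_summary <- function(dataset, constant = 0.5, policy = c("correct", "drop")) {
  policy <- match.arg(policy)
  agg_b <- aggregate_logit(dataset, target = "b", constant = constant, policy = policy)
  agg_a <- aggregate_logit(dataset, target = "a", constant = constant, policy = policy)
  common <- intersect(rownames(agg_b$per_dyad), rownames(agg_a$per_dyad))
  D <- agg_b$per_dyad[common, , drop = FALSE] - agg_a$per_dyad[common, , drop = FALSE]
  n <- nrow(D)
  mean_d <- colMeans(D)
  sd_d <- apply(D, 2L, stats::sd)
  tval <- ifelse(sd_d > 0, mean_d / (sd_d / sqrt(n)), NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df = n - 1L)
  diff_df <- data.frame(parameter = colnames(D), mean_diff = mean_d,
                        t = tval, df = n - 1L, p = pval, row.names = NULL)
  structure(list(outcome_b = agg_b, outcome_a = agg_a, difference = diff_df),
            class = "apim_summary")
}

#' @export
#' @method print apim_summary
print.apim_summary <- function(x, digits = 2, ...) {
  cat("== outcome: partner B ==\n"); print(x$outcome_b, digits = digits)
  cat("== outcome: partner A ==\n"); print(x$outcome_a, digits = digits)
  cat("== difference (B - A), paired t ==\n")
  out <- x$difference
  out[-1] <- lapply(out[-1], function(v) round(v, digits))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Compare per-dyad logit coefficients between two groups of dyads
#'
#' Welch two-sample t test (unequal variances, Welch-Satterthwaite df) per
#' parameter, e.g., comparing clusters found by sequence clustering.
#'
#' @param group1,group2 Per-dyad coefficient matrices (n x 4, as in
#'   `aggregate_logit()$per_dyad`), lists of [logit_params()], or
#'   `aggregate_logit` objects. Each group needs >= 2 dyads.
#' @return Data frame with group means, difference (group1 - group2), Welch
#'   t, df and two-tailed p per parameter.
#' @export
compare_logit_groups <- function(group1, group2) {
  as_mat <- function(g) {
    if (inherits(g, "aggregate_logit")) return(g$per_dyad)
    if (is.matrix(g)) return(g)
    if (is.list(g) && all(vapply(g, inherits, logical(1), "logit_params"))) {
      return(t(vapply(g, coef, numeric(4))))
    }
    stop("cannot interpret group as per-dyad logit coefficients", call. = FALSE)
  }
  m1 <- as_mat(group1)
  m2 <- as_mat(group2)
  stopifnot(nrow(m1) >= 2L, nrow(m2) >= 2L, ncol(m1) == 4L, ncol(m2) == 4L)
  res <- lapply(seq_len(4L), function(j) {
    x <- m1[, j]; y <- m2[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      d <- mean(x) - mean(y)
      data.frame(mean1 = mean(x), mean2 = mean(y), diff = d,
                 t = if (d == 0) 0 else NA_real_, df = NA_real_,
                 p = if (d == 0) 1 else NA_real_)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      data.frame(mean1 = mean(x), mean2 = mean(y), diff = mean(x) - mean(y),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  })
  out <- do.call(rbind, res)
  out <- cbind(parameter = colnames(m1), out)
  rownames(out) <- NULL
  out
}
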