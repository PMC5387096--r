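# Basic first-order Markov model over the four joint states: ML estimation
# by pooled transition-count ratios, conditional actor/partner effects read
# off the transition matrix, and BIC model comparison.

# Pooled 4x4 transition counts across a list of integer state sequences.
transition_counts <- function(state_list, K = 4L) {
  cts <- matrix(0L, K, K)
  for (s in state_list) {
    Tn <- length(s)
    if (Tn < 2L) next
    for (t in 2:Tn) cts[s[t - 1L], s[t]] <- cts[s[t - 1L], s[t]] + 1L
  }
  cts
}

# Fingerprint of the data a model was fitted on, for compare_bic().
data_fingerprint <- function(state_list) {
  c(n_seq = length(state_list),
    n_obs = sum(lengths(state_list)),
    checksum = sum(unlist(state_list) * seq_along(unlist(state_list)) %% 7919))
}

#' Fit a basic Markov model to expanded state sequences
#'
#' Maximum-likelihood estimation: the transition matrix is the row-normalized
#' matrix of pooled transition counts over all dyads, and the initial
#' distribution is the empirical distribution of first states. The
#' log-likelihood includes the initial terms:
#' `sum log initial(s_1) + sum log p(s_t | s_{t-1})`.
#'
#' A prior state never visited leaves its transition row undefined (`NaN`,
#' with a warning); such rows cannot contribute to the likelihood.
#'
#' @param x A `dyad_dataset`, a `dyad_pair`, or a list of state sequences
#'   (factors over the 4-state alphabet or integer codes 1..4).
#' @param n_type Sample size used in `BIC = -2 loglik + k log n`:
#'   `"observations"` (default; total observed intervals, matching the
#'   likelihood including the initial terms) or `"dyads"`.
#' @return A fitted [markov_model()] with `loglik`, `n_free_params = 15`,
#'   `bic`, and the raw `counts`.
#' @export
fit_markov <- function(x, n_type = c("observations", "dyads")) {
  n_type <- match.arg(n_type)
  sl <- as_state_list(x)
  stopifnot(length(sl) >= 1L, all(lengths(sl) >= 2L))
  cts <- transition_counts(sl)
  rs <- rowSums(cts)
  tm <- cts / rs
  if (any(rs == 0L)) {
    warning("prior state(s) never visited: ",
            paste(STATES[rs == 0L], collapse = ", "),
            "; transition row undefined (NaN)", call. = FALSE)
  }
  firsts <- vapply(sl, `[[`, integer(1), 1L)
  initial <- tabulate(firsts, 4L) / length(sl)
  ll <- sum(log(initial[firsts]))
  pos <- cts > 0L
  ll <- ll + sum(cts[pos] * log(tm[pos]))
  dimnames(tm) <- list(STATES, STATES)
  names(initial) <- STATES
  n_free <- 3L + 4L * 3L
  n_bic <- if (n_type == "observations") sum(lengths(sl)) else length(sl)
  m <- structure(list(initial = initial, transition = tm, loglik = ll,
                      n_free_params = n_free,
                      bic = -2 * ll + n_free * log(n_bic),
                      counts = cts, n = n_bic, n_type = n_type),
                 class = "markov_model")
  attr(m, "data_fp") <- data_fingerprint(sl)
  m
}

#' Conditional actor and partner effects from a Markov transition matrix
#'
#' The Markov model yields actor and partner effects as conditional
#' probabilities. The actor effect for behavior A given B was absent at
#' `t - 1` is the probability of showing A at `t` from the prior state
#' "A only": `p(a_only | a_only) + p(both | a_only)`; given B was present it
#' is the same column sum from the prior state "both". Partner effects
#' condition on the *other* partner's prior display instead: the partner
#' effect on A given A itself was absent is read from the prior state
#' "B only", given A was present from "both". B's effects are analogous.
#'
#' @param model A [markov_model()] over the 4-state alphabet.
#' @return A 4 x 2 matrix of probabilities; rows `actor_a`, `partner_a`,
#'   `actor_b`, `partner_b`, columns `without` / `with` (the conditioning
#'   behavior absent / present at `t - 1`). Undefined transition rows
#'   propagate `NaN` with a warning.
#' @export
conditional_effects <- function(model) {
  stopifnot(inherits(model, "markov_model"), length(model$initial) == 4L)
  tm <- model$transition
  a_cols <- c(2L, 4L)  # states containing behavior A
  b_cols <- c(3L, 4L)  # states containing behavior B
  out <- rbind(
    actor_a   = c(sum(tm[2L, a_cols]), sum(tm[4L, a_cols])),
    partner_a = c(sum(tm[3L, a_cols]), sum(tm[4L, a_cols])),
    actor_b   = c(sum(tm[3L, b_cols]), sum(tm[4L, b_cols])),
    partner_b = c(sum(tm[2L, b_cols]), sum(tm[4L, b_cols]))
  )
  colnames(out) <- c("without", "with")
  if (anyNA(out)) warning("undefined conditional effect(s): a required ",
                          "transition row was never visited", call. = FALSE)
  out
}

#' Compare fitted models by BIC
#'
#' Tabulates log-likelihood, free-parameter count and BIC for a set of models
#' fitted to the same data, flagging the smallest BIC as best. Models fitted
#' to different data (detected via a stored data fingerprint) are rejected.
#'
#' @param models List of fitted models (`markov_model`,
#'   `hidden_markov_model`, `mixture_markov_model`).
#' @param names Optional display names; defaults to list names or classes.
#' @return Data frame with columns `model`, `loglik`, `k`, `bic`, `best`.
#' @export
compare_bic <- function(models, names = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  fps <- lapply(models, attr, "data_fp")
  have <- !vapply(fps, is.null, logical(1))
  if (sum(have) >= 2L) {
    ref <- fps[have][[1L]]
    same <- vapply(fps[have], function(f) isTRUE(all.equal(f, ref)), logical(1))
    if (!all(same)) stop("models were fitted on different data", call. = FALSE)
  }
  if (is.null(names)) {
    names <- if (!is.null(base::names(models))) base::names(models)
             else vapply(models, function(m) class(m)[1L], character(1))
  }
  ll <- vapply(models, function(m) m$loglik %||% NA_real_, numeric(1))
  k <- vapply(models, function(m) as.numeric(m$n_free_params %||% NA), numeric(1))
  bic <- vapply(models, function(m) m$bic %||% NA_real_, numeric(1))
  data.frame(model = names, loglik = ll, k = k, bic = bic,
             best = seq_along(bic) == which.min(bic), row.names = NULL)
}
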