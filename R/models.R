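# Model-object constructors shared by the simulators and the fitters.

# Tolerance 0.02 admits published matrices rounded to 2 decimals; entries are
# kept as supplied (no renormalization) so printed arithmetic is reproduced.
check_prob_vec <- function(p, what, tol = 0.02) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    stop(what, " is not a probability distribution", call. = FALSE)
  }
  p
}

check_stochastic <- function(M, what, tol = 0.02) {
  if (any(M < 0)) stop(what, " has negative entries", call. = FALSE)
  rs <- rowSums(M)
  if (any(abs(rs - 1) > tol)) {
    stop(what, " rows must sum to 1 (non-stochastic matrix)", call. = FALSE)
  }
  M
}

#' Construct a basic (first-order) Markov model over the four joint states
#'
#' @param initial Probability vector over the state alphabet.
#' @param transition Row-stochastic transition matrix
#'   `p(state_t = j | state_{t-1} = i)`.
#' @return Object of class `markov_model`. Fitted models (from
#'   [fit_markov()]) additionally carry `loglik`, `n_free_params`, `bic`.
#' @export
markov_model <- function(initial, transition) {
  transition <- as.matrix(transition)
  K <- length(initial)
  stopifnot(nrow(transition) == K, ncol(transition) == K)
  initial <- check_prob_vec(initial, "initial distribution")
  transition <- check_stochastic(transition, "transition matrix")
  if (K == 4L && is.null(rownames(transition))) {
    dimnames(transition) <- list(STATES, STATES)
    names(initial) <- STATES
  }
  structure(list(initial = initial, transition = transition,
                 loglik = NULL, n_free_params = NULL, bic = NULL),
            class = "markov_model")
}

#' @export
#' @method print markov_model
print.markov_model <- function(x, digits = 3, ...) {
  cat("<markov_model> ", length(x$initial), " states\n", sep = "")
  cat("initial:\n")
  print(round(x$initial, digits))
  cat("transition:\n")
  print(round(x$transition, digits))
  if (!is.null(x$loglik)) {
    cat("loglik = ", format(x$loglik), ", k = ", x$n_free_params,
        ", BIC = ", format(round(x$bic, 1)), "\n", sep = "")
  }
  invisible(x)
}

#' Construct a hidden Markov model with categorical emissions
#'
#' The latent chain has `K` states; each interval the observed joint state
#' (over the 4-letter alphabet) is drawn from the emission row of the current
#' latent state. `zero_mask` marks transition entries structurally fixed at
#' zero (e.g., to make a latent state absorbing).
#'
#' @param initial Length-K initial distribution of the latent chain.
#' @param transition K x K row-stochastic latent transition matrix.
#' @param emission K x 4 row-stochastic matrix of
#'   `p(observed state | latent state)`.
#' @param zero_mask Optional K x K logical matrix; `TRUE` entries are fixed
#'   at exactly zero.
#' @return Object of class `hidden_markov_model`.
#' @export
hidden_markov_model <- function(initial, transition, emission, zero_mask = NULL) {
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  K <- length(initial)
  stopifnot(nrow(transition) == K, ncol(transition) == K,
            nrow(emission) == K, ncol(emission) == 4L)
  initial <- check_prob_vec(initial, "initial distribution")
  transition <- check_stochastic(transition, "transition matrix")
  emission <- check_stochastic(emission, "emission matrix")
  if (!is.null(zero_mask)) {
    zero_mask <- matrix(as.logical(zero_mask), K, K)
    if (any(transition[zero_mask] != 0)) {
      stop("transition entries under the zero mask must be exactly 0", call. = FALSE)
    }
  }
  colnames(emission) <- STATES
  structure(list(K = K, initial = initial, transition = transition,
                 emission = emission, zero_mask = zero_mask,
                 loglik = NULL, n_free_params = NULL, bic = NULL),
            class = "hidden_markov_model")
}

#' @export
#' @method print hidden_markov_model
print.hidden_markov_model <- function(x, digits = 3, ...) {
  cat("<hidden_markov_model> K =", x$K, "latent states\n")
  cat("initial:\n"); print(round(x$initial, digits))
  cat("transition:\n"); print(round(x$transition, digits))
  cat("emission:\n"); print(round(x$emission, digits))
  if (!is.null(x$loglik)) {
    cat("loglik = ", format(x$loglik), ", k = ", x$n_free_params,
        ", BIC = ", format(round(x$bic, 1)), "\n", sep = "")
  }
  invisible(x)
}

#' Construct a mixture of Markov models (latent classes of dyads)
#'
#' @param weights Class-weight probability vector.
#' @param models List of [markov_model()] objects, one per class.
#' @return Object of class `mixture_markov_model`.
#' @export
mixture_markov_model <- function(weights, models) {
  stopifnot(length(weights) == length(models))
  weights <- check_prob_vec(weights, "class weights")
  if (!all(vapply(models, inherits, logical(1), "markov_model"))) {
    stop("`models` must be a list of markov_model objects", call. = FALSE)
  }
  structure(list(K_classes = length(weights), weights = weights,
                 models = models, posterior = NULL, hard_labels = NULL,
                 loglik = NULL, n_free_params = NULL, bic = NULL),
            class = "mixture_markov_model")
}

#' @export
#' @method print mixture_markov_model
print.mixture_markov_model <- function(x, digits = 3, ...) {
  cat("<mixture_markov_model>", x$K_classes, "latent classes, weights:",
      paste(round(x$weights, digits), collapse = " / "), "\n")
  for (k in seq_along(x$models)) {
    cat("class", k, "transition:\n")
    print(round(x$models[[k]]$transition, digits))
  }
  if (!is.null(x$loglik)) {
    cat("loglik = ", format(x$loglik), ", k = ", x$n_free_params,
        ", BIC = ", format(round(x$bic, 1)), "\n", sep = "")
  }
  invisible(x)
}

#' Coefficients of the saturated effect-coded lagged logit model
#'
#' Holds the four coefficients of the per-dyad logit model in which the
#' log-odds of showing the target behavior at interval `t` are predicted by
#' the effect-coded (+1 shown / -1 not shown) lagged own behavior (actor),
#' lagged partner behavior (partner), and their product (interaction):
#' `logit P = b0 + b_actor*own + b_partner*other + b_ixn*own*other`.
#'
#' @param b0 Grand-mean logit.
#' @param b_actor Actor effect (own lagged behavior).
#' @param b_partner Partner effect (partner's lagged behavior).
#' @param b_ixn Interaction effect (lagged product term).
#' @param constant_used Zero-frequency constant added to all cells when the
#'   coefficients were estimated (NA for externally supplied truth values).
#' @return Object of class `logit_params`.
#' @export
logit_params <- function(b0, b_actor, b_partner, b_ixn,
                         constant_used = NA_real_) {
  co <- c(b0 = b0, b_actor = b_actor, b_partner = b_partner, b_ixn = b_ixn)
  if (!is.na(constant_used) && constant_used > 0 && any(!is.finite(co))) {
    stop("non-finite coefficients with a positive constant", call. = FALSE)
  }
  structure(list(coef = co, constant_used = constant_used),
            class = "logit_params")
}

#' @export
coef.logit_params <- function(object, ...) object$coef

#' @export
#' @method print logit_params
print.logit_params <- function(x, digits = 3, ...) {
  out <- cbind(beta = round(x$coef, digits),
               odds_ratio = round(exp(x$coef), digits))
  print(out)
  invisible(x)
}
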