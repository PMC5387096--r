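# Synthetic dyadic-sequence generators, one per model family. Defaults for
# the study-like conditions elsewhere in the package are 64 dyads x 48
# intervals; these functions take explicit sizes so the same generators also
# drive the large parameter-recovery runs.

# Draw one Markov chain of length T (integer codes).
sim_chain <- function(initial, transition, n_intervals) {
  K <- length(initial)
  s <- integer(n_intervals)
  s[1L] <- sample.int(K, 1L, prob = initial)
  for (t in 2:n_intervals) {
    s[t] <- sample.int(K, 1L, prob = transition[s[t - 1L], ])
  }
  s
}

# Optional geometric dropout: observed length min(T, 2 + Geom(p)).
dropout_length <- function(n_intervals, dropout_prob) {
  if (dropout_prob <= 0) return(n_intervals)
  min(n_intervals, 2L + stats::rgeom(1L, dropout_prob))
}

codes_to_pair <- function(code, id, covariates = NULL) {
  dyad_pair(id,
            as.integer(code %in% c(2L, 4L)),
            as.integer(code %in% c(3L, 4L)),
            covariates = covariates)
}

#' Simulate dyadic sequences from a basic Markov model
#'
#' Each dyad is an independent chain over the four joint states: the first
#' state is drawn from the initial distribution, each later state from the
#' transition row of the previous state, and the state sequence is collapsed
#' back into the two binary behavior streams.
#'
#' @param model A [markov_model()] over the 4-state alphabet.
#' @param n_dyads,n_intervals Number of dyads and intervals per dyad.
#' @param seed Optional integer; fixed seed gives bit-identical output.
#' @param dropout_prob Per-interval geometric dropout probability (0 = full
#'   sequences, the default; dyads never drop below 2 observed intervals).
#' @param label_a,label_b Stream display labels for the resulting dataset.
#' @return A [dyad_dataset()].
#' @export
simulate_markov <- function(model, n_dyads, n_intervals, seed = NULL,
                            dropout_prob = 0, label_a = "A", label_b = "B") {
  stopifnot(inherits(model, "markov_model"), length(model$initial) == 4L)
  with_seed(seed, {
    pairs <- lapply(seq_len(n_dyads), function(i) {
      Tl <- dropout_length(n_intervals, dropout_prob)
      codes_to_pair(sim_chain(model$initial, model$transition, Tl),
                    sprintf("dyad%03d", i))
    })
    dyad_dataset(pairs, label_a = label_a, label_b = label_b)
  })
}

#' Simulate dyadic sequences from a hidden Markov model
#'
#' The latent chain is simulated first; at every interval the observed joint
#' state is drawn from the emission row of the current latent state.
#'
#' @inheritParams simulate_markov
#' @param model A [hidden_markov_model()].
#' @return A [dyad_dataset()] with attribute `"latent"`: the list of latent
#'   state traces (integer vectors), for recovery checks.
#' @export
simulate_hmm <- function(model, n_dyads, n_intervals, seed = NULL,
                         dropout_prob = 0, label_a = "A", label_b = "B") {
  stopifnot(inherits(model, "hidden_markov_model"))
  with_seed(seed, {
    latent <- vector("list", n_dyads)
    pairs <- lapply(seq_len(n_dyads), function(i) {
      Tl <- dropout_length(n_intervals, dropout_prob)
      z <- sim_chain(model$initial, model$transition, Tl)
      latent[[i]] <<- z
      obs <- vapply(z, function(k) sample.int(4L, 1L, prob = model$emission[k, ]),
                    integer(1))
      codes_to_pair(obs, sprintf("dyad%03d", i))
    })
    ds <- dyad_dataset(pairs, label_a = label_a, label_b = label_b)
    attr(ds, "latent") <- stats::setNames(latent, names(ds$pairs))
    ds
  })
}

#' Simulate dyadic sequences from a mixture of Markov models
#'
#' A latent class is drawn per dyad from the class weights; the dyad's
#' sequence is then simulated from that class's Markov model.
#'
#' @inheritParams simulate_markov
#' @param model A [mixture_markov_model()].
#' @return List with `dataset` (a [dyad_dataset()]) and `classes` (named
#'   integer vector of the true class labels).
#' @export
simulate_mixture <- function(model, n_dyads, n_intervals, seed = NULL,
                             dropout_prob = 0, label_a = "A", label_b = "B") {
  stopifnot(inherits(model, "mixture_markov_model"))
  with_seed(seed, {
    cls <- sample.int(model$K_classes, n_dyads, replace = TRUE,
                      prob = model$weights)
    pairs <- lapply(seq_len(n_dyads), function(i) {
      m <- model$models[[cls[i]]]
      Tl <- dropout_length(n_intervals, dropout_prob)
      codes_to_pair(sim_chain(m$initial, m$transition, Tl),
                    sprintf("dyad%03d", i))
    })
    ds <- dyad_dataset(pairs, label_a = label_a, label_b = label_b)
    list(dataset = ds, classes = stats::setNames(cls, names(ds$pairs)))
  })
}

#' Simulate dyadic sequences from a lagged actor-partner logit process
#'
#' At every interval `t >= 2` the two behaviors are drawn independently as
#' Bernoulli with success probability `plogis(eta)`, where for each partner
#' `eta = b0 + b_actor*own_{t-1} + b_partner*other_{t-1} +
#' b_ixn*own_{t-1}*other_{t-1}` with effect-coded (+1/-1) lagged predictors.
#' The two behaviors are conditionally independent given interval `t - 1`
#' (the model has lagged predictors only). Dyad-level heterogeneity can be
#' added via `re_sd`: one normal perturbation per coefficient is drawn per
#' dyad and added to the corresponding coefficient of *both* partners,
#' mirroring shared dyad-level random effects.
#'
#' @param params_a,params_b [logit_params()] governing partner A's and
#'   partner B's behavior, respectively.
#' @param initial Joint-state distribution for the first interval (length 4,
#'   alphabet order; default uniform).
#' @param re_sd Length-4 vector of random-effect standard deviations for
#'   (b0, b_actor, b_partner, b_ixn); default no heterogeneity.
#' @inheritParams simulate_markov
#' @return A [dyad_dataset()].
#' @export
simulate_logit_apim <- function(params_a, params_b, n_dyads, n_intervals,
                                initial = rep(0.25, 4), seed = NULL,
                                re_sd = c(0, 0, 0, 0), dropout_prob = 0,
                                label_a = "A", label_b = "B") {
  stopifnot(inherits(params_a, "logit_params"), inherits(params_b, "logit_params"),
            length(initial) == 4L, length(re_sd) == 4L)
  initial <- check_prob_vec(initial, "initial joint-state distribution")
  ca <- coef(params_a)
  cb <- coef(params_b)
  if (any(!is.finite(c(ca, cb)))) stop("coefficients must be finite", call. = FALSE)
  with_seed(seed, {
    pairs <- lapply(seq_len(n_dyads), function(i) {
      delta <- stats::rnorm(4L, 0, re_sd)
      cai <- ca + delta
      cbi <- cb + delta
      Tl <- dropout_length(n_intervals, dropout_prob)
      a <- integer(Tl); b <- integer(Tl)
      s1 <- sample.int(4L, 1L, prob = initial)
      a[1L] <- as.integer(s1 %in% c(2L, 4L))
      b[1L] <- as.integer(s1 %in% c(3L, 4L))
      for (t in 2:Tl) {
        ea <- 2L * a[t - 1L] - 1L   # effect-coded lags
        eb <- 2L * b[t - 1L] - 1L
        eta_a <- cai[1L] + cai[2L] * ea + cai[3L] * eb + cai[4L] * ea * eb
        eta_b <- cbi[1L] + cbi[2L] * eb + cbi[3L] * ea + cbi[4L] * ea * eb
        a[t] <- stats::rbinom(1L, 1L, stats::plogis(eta_a))
        b[t] <- stats::rbinom(1L, 1L, stats::plogis(eta_b))
      }
      dyad_pair(sprintf("dyad%03d", i), a, b)
    })
    dyad_dataset(pairs, label_a = label_a, label_b = label_b)
  })
}
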