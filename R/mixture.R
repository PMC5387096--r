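# EM for the mixture (latent-class) Markov model: dyads belong to one of K
# latent classes, each with its own initial distribution and transition
# matrix; class membership is probabilistic.

logsumexp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Fit a mixture of Markov models by EM
#'
#' The per-dyad sufficient statistics (first state and 4 x 4 transition
#' counts) are computed once; each EM iteration evaluates class
#' log-likelihoods from them, updates responsibilities, and re-estimates the
#' class weights and per-class parameters from responsibility-weighted
#' counts. The log-likelihood is checked to be non-decreasing each
#' iteration; the best of `restarts` random initializations is kept. Classes
#' are reported sorted by descending weight (ties: lexicographic first
#' transition row). With `K = 1` the fit is exactly the basic Markov model.
#'
#' @inheritParams fit_hmm
#' @param K Number of latent classes.
#' @return A fitted [mixture_markov_model()] with `posterior` (n_dyads x K),
#'   `hard_labels` (most probable class per dyad), `loglik`, `loglik_trace`,
#'   `n_free_params = K*15 + K - 1`, and `bic` (n = total observed
#'   intervals).
#' @export
fit_mixture <- function(x, K, restarts = 10L, seed = NULL,
                        max_iter = 500L, tol = 1e-6) {
  sl <- as_state_list(x)
  stopifnot(K >= 1L, all(lengths(sl) >= 2L))
  n <- length(sl)
  firsts <- vapply(sl, `[[`, integer(1), 1L)
  C <- t(vapply(sl, function(s) as.numeric(transition_counts(list(s))),
                numeric(16)))   # n x 16, column-major 4x4 counts
  n_total_obs <- sum(lengths(sl))

  class_loglik <- function(pis, As) {
    # n x K matrix of per-dyad log-likelihoods under each class
    vapply(seq_len(K), function(k) {
      logA <- log(pmax(As[[k]], 1e-300))
      log(pmax(pis[[k]][firsts], 1e-300)) + as.numeric(C %*% as.numeric(logA))
    }, numeric(n))
  }

  run_em <- function() {
    # initialize from random responsibilities
    r <- matrix(stats::rgamma(n * K, 1), n, K)
    r <- r / rowSums(r)
    w <- colMeans(r)
    pis <- As <- vector("list", K)
    mstep <- function() {
      for (k in seq_len(K)) {
        pk <- vapply(1:4, function(s) sum(r[firsts == s, k]), numeric(1))
        pis[[k]] <<- pk / max(sum(pk), 1e-300)
        Ak <- matrix(as.numeric(crossprod(C, r[, k])), 4L, 4L)
        rs <- rowSums(Ak)
        Ak <- Ak / ifelse(rs > 0, rs, 1)
        Ak[rs == 0, ] <- 0.25  # class never visits the row: uniform filler
        As[[k]] <<- Ak
      }
    }
    mstep()
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    ll <- NA_real_
    for (it in seq_len(max_iter)) {
      lm <- class_loglik(pis, As)
      lr <- sweep(lm, 2L, log(pmax(w, 1e-300)), `+`)
      li <- logsumexp(lr)
      ll <- sum(li)
      trace <- c(trace, ll)
      if (ll < ll_prev - 1e-8) {
        warning("EM log-likelihood decreased at iteration ", it, call. = FALSE)
      }
      r <- exp(lr - li)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * max(1, abs(ll_prev))) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      w <- colMeans(r)
      mstep()
    }
    list(w = w, pis = pis, As = As, r = r, loglik = ll, trace = trace,
         converged = converged)
  }

  best <- NULL
  restart_lls <- numeric(restarts)
  with_seed(seed, {
    for (rr in seq_len(restarts)) {
      fit <- run_em()
      restart_lls[rr] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })

  ord <- order(-best$w,
               vapply(best$As, function(A) paste(round(A[1L, ], 10), collapse = ","),
                      character(1)))
  w <- best$w[ord]
  pis <- best$pis[ord]
  As <- best$As[ord]
  post <- best$r[, ord, drop = FALSE]
  rownames(post) <- names(sl)
  colnames(post) <- paste0("class", seq_len(K))
  if (any(w < 1e-6)) warning("empty latent class (weight < 1e-6)", call. = FALSE)
  models <- lapply(seq_len(K), function(k) markov_model(pis[[k]], As[[k]]))
  n_free <- (K - 1L) + K * 15L
  m <- structure(list(K_classes = K, weights = w, models = models,
                      posterior = post,
                      hard_labels = stats::setNames(max.col(post, ties.method = "first"),
                                                    names(sl)),
                      loglik = best$loglik, loglik_trace = best$trace,
                      n_free_params = n_free,
                      bic = -2 * best$loglik + n_free * log(n_total_obs),
                      converged = best$converged,
                      n_restarts = restarts, restart_logliks = restart_lls,
                      seed = seed),
                 class = "mixture_markov_model")
  attr(m, "data_fp") <- data_fingerprint(sl)
  if (!best$converged) warning("EM did not converge within ", max_iter,
                               " iterations", call. = FALSE)
  m
}
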