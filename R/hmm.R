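# Baum-Welch EM for the hidden Markov model with categorical emissions over
# the four joint states, scaled forward-backward, optional fixed-zero
# transition mask (multiplicative EM updates preserve exact zeros), random
# restarts, and a canonical latent-state order.

rdirichlet1 <- function(K) {
  g <- stats::rgamma(K, 1)
  g / sum(g)
}

# One E-step over a group of equal-length sequences stored as an n x T
# integer matrix. Returns sufficient statistics, the group log-likelihood,
# and (optionally) the per-sequence smoothed state probabilities.
.hmm_estep_group <- function(pi, A, E, S, keep_gamma = FALSE) {
  n <- nrow(S)
  Tn <- ncol(S)
  K <- length(pi)
  tE <- t(E)                             # 4 x K -> index rows by observation
  Bs <- lapply(seq_len(Tn), function(t) tE[S[, t], , drop = FALSE])  # n x K
  alphas <- vector("list", Tn)
  cs <- matrix(0, n, Tn)
  al <- Bs[[1L]] * rep(pi, each = n)
  cs[, 1L] <- rowSums(al)
  al <- al / cs[, 1L]
  alphas[[1L]] <- al
  if (Tn >= 2L) for (t in 2:Tn) {
    al <- (alphas[[t - 1L]] %*% A) * Bs[[t]]
    cs[, t] <- rowSums(al)
    al <- al / cs[, t]
    alphas[[t]] <- al
  }
  loglik <- sum(log(cs))
  # backward pass, accumulating transition and emission statistics
  xi_sum <- matrix(0, K, K)
  emis_sum <- matrix(0, K, 4L)
  beta <- matrix(1, n, K)
  gammas <- if (keep_gamma) vector("list", Tn)
  acc_emis <- function(gam, t) {
    for (o in unique(S[, t])) {
      idx <- S[, t] == o
      emis_sum[, o] <<- emis_sum[, o] + colSums(gam[idx, , drop = FALSE])
    }
  }
  gam <- alphas[[Tn]] * beta
  if (keep_gamma) gammas[[Tn]] <- gam
  acc_emis(gam, Tn)
  if (Tn >= 2L) for (t in (Tn - 1L):1L) {
    tmp <- Bs[[t + 1L]] * beta / cs[, t + 1L]       # n x K
    xi_sum <- xi_sum + A * crossprod(alphas[[t]], tmp)
    beta <- tmp %*% t(A)
    gam <- alphas[[t]] * beta
    if (keep_gamma) gammas[[t]] <- gam
    acc_emis(gam, t)
  }
  # after the loop `gam` holds the smoothed probabilities at t = 1
  list(loglik = loglik, gamma1 = colSums(gam),
       xi = xi_sum, emis = emis_sum, n = n, gammas = gammas)
}

# Group sequences by length into integer matrices for vectorized passes.
group_by_length <- function(state_list) {
  lens <- lengths(state_list)
  lapply(split(seq_along(state_list), lens), function(idx) {
    list(idx = idx,
         S = do.call(rbind, lapply(state_list[idx], as.integer)))
  })
}

#' Fit a hidden Markov model by Baum-Welch EM
#'
#' Scaled forward-backward expectation-maximization over all sequences, with
#' the log-likelihood checked to be non-decreasing at every iteration. The
#' best of `restarts` random (Dirichlet) initializations is kept. Transition
#' entries marked in `zero_mask` are fixed at exactly zero throughout
#' (EM's multiplicative updates preserve them bit-exactly), which is how
#' theoretical restrictions such as an absorbing latent state are imposed.
#'
#' Free parameters counted for the BIC: `K - 1` initial probabilities, the
#' unmasked transition entries minus one per row, and `K * 3` emission
#' probabilities; `n` is the total number of observed intervals.
#'
#' @param x Dataset, pair, or list of state sequences (see [fit_markov()]).
#' @param K Number of latent states.
#' @param zero_mask Optional K x K logical matrix; `TRUE` entries of the
#'   transition matrix are fixed at 0.
#' @param restarts Number of seeded random initializations (default 10).
#' @param seed Optional integer seed for the initializations.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change drops below `tol` (default 1e-6) or after
#'   `max_iter` (default 500) iterations.
#' @return A fitted [hidden_markov_model()] with `loglik`, `loglik_trace`
#'   (of the winning restart), `n_free_params`, `bic`, `converged`,
#'   `n_restarts`, and `restart_logliks`.
#' @export
fit_hmm <- function(x, K, zero_mask = NULL, restarts = 10L, seed = NULL,
                    max_iter = 500L, tol = 1e-6) {
  sl <- as_state_list(x)
  stopifnot(K >= 1L, all(lengths(sl) >= 1L))
  n_distinct <- length(unique(unlist(sl)))
  if (K > n_distinct) {
    warning("K = ", K, " exceeds the ", n_distinct,
            " distinct observed states; the model is weakly identified",
            call. = FALSE)
  }
  if (!is.null(zero_mask)) {
    zero_mask <- matrix(as.logical(zero_mask), K, K)
    if (any(rowSums(!zero_mask) == 0L)) {
      stop("zero mask leaves a transition row with no admissible entry",
           call. = FALSE)
    }
  }
  groups <- group_by_length(sl)
  n_total_obs <- sum(lengths(sl))
  n_seq <- length(sl)

  run_em <- function() {
    pi <- rdirichlet1(K)
    A <- t(vapply(seq_len(K), function(i) {
      row <- rep(0, K)
      free <- if (is.null(zero_mask)) rep(TRUE, K) else !zero_mask[i, ]
      row[free] <- rdirichlet1(sum(free))
      row
    }, numeric(K)))
    E <- t(vapply(seq_len(K), function(i) rdirichlet1(4L), numeric(4)))
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      g1 <- rep(0, K); xi <- matrix(0, K, K); em <- matrix(0, K, 4L)
      ll <- 0
      for (g in groups) {
        st <- .hmm_estep_group(pi, A, E, g$S)
        ll <- ll + st$loglik
        g1 <- g1 + st$gamma1
        xi <- xi + st$xi
        em <- em + st$emis
      }
      trace <- c(trace, ll)
      if (ll < ll_prev - 1e-8) {
        warning("EM log-likelihood decreased at iteration ", it, call. = FALSE)
      }
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * max(1, abs(ll_prev))) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      # M-step
      pi <- g1 / n_seq
      rs <- rowSums(xi)
      A_new <- xi / ifelse(rs > 0, rs, 1)
      A_new[rs == 0, ] <- A[rs == 0, ]  # state never occupied: keep row
      A <- A_new
      ers <- rowSums(em)
      E_new <- em / ifelse(ers > 0, ers, 1)
      E_new[ers == 0, ] <- E[ers == 0, ]
      E <- E_new
    }
    list(pi = pi, A = A, E = E, loglik = ll, trace = trace,
         converged = converged)
  }

  best <- NULL
  restart_lls <- numeric(restarts)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- run_em()
      restart_lls[r] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })

  # canonical order: latent states by descending initial probability,
  # ties broken by the first transition row lexicographically
  ord <- order(-best$pi, apply(best$A, 1L, function(r) paste(round(r, 10), collapse = ",")))
  pi <- best$pi[ord]
  A <- best$A[ord, ord, drop = FALSE]
  E <- best$E[ord, , drop = FALSE]
  mask <- if (!is.null(zero_mask)) zero_mask[ord, ord, drop = FALSE]
  if (!is.null(mask)) A[mask] <- 0  # exact zeros survive the permutation

  free_trans <- if (is.null(mask)) K * (K - 1L) else sum(!mask) - K
  n_free <- (K - 1L) + free_trans + K * 3L
  dimnames(A) <- list(paste0("state", seq_len(K)), paste0("state", seq_len(K)))
  dimnames(E) <- list(paste0("state", seq_len(K)), STATES)
  names(pi) <- paste0("state", seq_len(K))
  m <- structure(list(K = K, initial = pi, transition = A, emission = E,
                      zero_mask = mask, loglik = best$loglik,
                      loglik_trace = best$trace,
                      n_free_params = n_free,
                      bic = -2 * best$loglik + n_free * log(n_total_obs),
                      converged = best$converged,
                      n_restarts = restarts, restart_logliks = restart_lls,
                      seed = seed),
                 class = "hidden_markov_model")
  attr(m, "data_fp") <- data_fingerprint(sl)
  if (!best$converged) warning("EM did not converge within ", max_iter,
                               " iterations", call. = FALSE)
  m
}

#' Smoothed latent-state probabilities under a hidden Markov model
#'
#' Forward-backward posteriors `p(latent state at t | whole sequence)`; each
#' row of each returned matrix sums to 1.
#'
#' @param model A `hidden_markov_model` (fitted or constructed).
#' @param x Dataset, pair, or list of state sequences.
#' @return Named list of `T_obs x K` matrices, one per sequence.
#' @export
hmm_posterior <- function(model, x) {
  stopifnot(inherits(model, "hidden_markov_model"))
  sl <- as_state_list(x)
  out <- vector("list", length(sl))
  groups <- group_by_length(sl)
  for (g in groups) {
    st <- .hmm_estep_group(model$initial, model$transition, model$emission,
                           g$S, keep_gamma = TRUE)
    for (j in seq_along(g$idx)) {
      out[[g$idx[j]]] <- do.call(rbind, lapply(st$gammas, function(G) G[j, ]))
    }
  }
  names(out) <- names(sl)
  out
}
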