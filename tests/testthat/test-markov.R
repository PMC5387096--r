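# Basic, hidden, and mixture Markov estimation; conditional effects; BIC.

test_that("fit_markov equals the count-ratio estimator (exhaustive, T <= 8)", {
  # worked tiny example (rows 3-4 unvisited: warning expected)
  m <- suppressWarnings(fit_markov(list(c(1, 1, 2, 2))))
  expect_equal(unname(m$transition[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(m$transition[2, ]), c(0, 1, 0, 0))

  set.seed(61)
  suppressWarnings(for (i in 1:10) {
    sl <- lapply(1:5, function(j) sample(1:4, sample(2:8, 1), replace = TRUE))
    fit <- fit_markov(sl)
    cts <- count_oracle(sl)
    ref <- cts / rowSums(cts)
    expect_equal(unname(fit$transition), unname(ref))
    firsts <- vapply(sl, `[[`, integer(1), 1)
    expect_equal(unname(fit$initial), tabulate(firsts, 4) / 5)
    # loglik identity
    ll <- sum(log((tabulate(firsts, 4) / 5)[firsts])) +
      sum(cts[cts > 0] * log(ref[cts > 0]))
    expect_equal(fit$loglik, ll)
  })
})

test_that("fitted transition rows sum to one; unvisited rows are NaN-flagged", {
  ds <- random_dataset(10, 15, seed = 62)
  fit <- fit_markov(ds)
  expect_equal(unname(rowSums(fit$transition)), rep(1, 4), tolerance = 1e-10)
  expect_equal(fit$n_free_params, 15)
  expect_equal(fit$bic, -2 * fit$loglik + 15 * log(10 * 15), tolerance = 1e-10)

  expect_warning(f2 <- fit_markov(list(c(1, 1, 1, 1))), "never visited")
  expect_true(all(is.nan(f2$transition[2, ])))
})

test_that("conditional effects reproduce the printed worked values", {
  m <- markov_model(rep(0.25, 4), study_transition)
  ce <- conditional_effects(m)
  expect_equal(ce["actor_a", "without"], 0.33 + 0.40)
  expect_equal(ce["actor_a", "with"], 0.08 + 0.80)
  expect_true(all(ce >= 0 & ce <= 1))
  # identity transition matrix: all actor effects 1... and partner effects too
  mi <- markov_model(rep(0.25, 4), diag(4))
  expect_equal(unname(conditional_effects(mi)[, "with"]), rep(1, 4))
  expect_equal(unname(conditional_effects(mi)["actor_a", "without"]), 1)
})

test_that("K = 1 HMM collapses to the iid multinomial", {
  ds <- random_dataset(8, 12, seed = 63)
  fit <- fit_hmm(ds, K = 1, restarts = 2, seed = 1)
  os <- unlist(lapply(ds$pairs, function(p) as.integer(expand_states(p))))
  emp <- tabulate(os, 4) / length(os)
  expect_equal(unname(fit$emission[1, ]), emp, tolerance = 1e-6)
  expect_equal(fit$loglik, sum(tabulate(os, 4) * log(emp)), tolerance = 1e-6)
})

test_that("zero masks are preserved bit-exactly and EM is monotone", {
  h <- absorbing_hmm()
  sim <- simulate_hmm(h, 80, 30, seed = 42)
  mask <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2, byrow = TRUE)
  fit <- fit_hmm(sim, K = 2, zero_mask = mask, restarts = 4, seed = 7)
  expect_identical(fit$transition[2, 1], 0)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # per-interval smoothed probabilities sum to one
  post <- hmm_posterior(fit, sim)
  expect_equal(unname(rowSums(post[[1]])), rep(1, 30), tolerance = 1e-10)
  # free parameters: (K-1) + (unmasked - K) + K*3 = 1 + 1 + 6
  expect_equal(fit$n_free_params, 8)
})

test_that("HMM and mixture fitting handle unequal-length sequences", {
  h <- absorbing_hmm()
  sim <- simulate_hmm(h, 40, 25, seed = 2, dropout_prob = 0.08)
  expect_gt(length(unique(seq_lengths(sim))), 1)
  fit <- fit_hmm(sim, K = 2, restarts = 3, seed = 4)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  post <- hmm_posterior(fit, sim)
  lens <- seq_lengths(sim)
  expect_true(all(vapply(seq_along(post), function(i)
    nrow(post[[i]]) == lens[i], logical(1))))
  mx <- fit_mixture(sim, K = 2, restarts = 3, seed = 4)
  expect_equal(unname(rowSums(mx$posterior)), rep(1, 40), tolerance = 1e-10)
})

test_that("label permutation leaves the HMM likelihood unchanged", {
  h <- absorbing_hmm()
  sim <- simulate_hmm(h, 40, 20, seed = 8)
  # evaluate the data likelihood under the truth and its label-permuted twin
  ll_of <- function(model) {
    sl <- lapply(sim$pairs, function(p) as.integer(expand_states(p)))
    tot <- 0
    for (s in sl) {
      al <- model$initial * model$emission[, s[1]]
      ll <- log(sum(al)); al <- al / sum(al)
      for (t in 2:length(s)) {
        al <- (al %*% model$transition)[1, ] * model$emission[, s[t]]
        ll <- ll + log(sum(al)); al <- al / sum(al)
      }
      tot <- tot + ll
    }
    tot
  }
  perm <- hidden_markov_model(h$initial[2:1], h$transition[2:1, 2:1],
                              h$emission[2:1, ])
  expect_equal(ll_of(h), ll_of(perm), tolerance = 1e-10)
})

test_that("mixture: K = 1 equals the basic Markov fit; posteriors are proper", {
  ds <- random_dataset(12, 10, seed = 64)
  mx <- fit_mixture(ds, K = 1, restarts = 1, seed = 1)
  bm <- fit_markov(ds)
  expect_equal(mx$loglik, bm$loglik, tolerance = 1e-8)
  expect_equal(unname(mx$models[[1]]$transition), unname(bm$transition),
               tolerance = 1e-8)

  mx2 <- fit_mixture(ds, K = 2, restarts = 3, seed = 2)
  expect_equal(unname(rowSums(mx2$posterior)), rep(1, 12), tolerance = 1e-10)
  expect_true(all(diff(mx2$loglik_trace) >= -1e-8))
  expect_true(all(diff(order(-mx2$weights)) > 0))  # sorted by weight
  expect_equal(unname(mx2$hard_labels),
               unname(max.col(mx2$posterior, ties.method = "first")))
})

test_that("BIC comparison ranks models and rejects mismatched data", {
  ds <- random_dataset(10, 12, seed = 65)
  bm <- fit_markov(ds)
  hm <- fit_hmm(ds, K = 2, restarts = 3, seed = 3)
  tab <- compare_bic(list(markov = bm, hmm = hm))
  expect_equal(tab$bic, -2 * tab$loglik + tab$k * log(10 * 12), tolerance = 1e-8)
  expect_equal(sum(tab$best), 1L)
  expect_equal(tab$model[tab$best], tab$model[which.min(tab$bic)])
  # same model twice: identical rows
  tab2 <- compare_bic(list(a = bm, b = bm))
  expect_equal(tab2$bic[1], tab2$bic[2])

  other <- random_dataset(10, 12, seed = 66)
  expect_error(compare_bic(list(bm, fit_markov(other))), "different data")
})

test_that("BIC selects mixture on mixture data and basic Markov on plain data", {
  # well-separated two-class mixture
  m1 <- markov_model(rep(0.25, 4), matrix(c(.9,.05,.03,.02, .85,.1,.03,.02,
                                            .9,.02,.05,.03, .85,.05,.05,.05),
                                          4, 4, byrow = TRUE))
  m2 <- markov_model(rep(0.25, 4), matrix(c(.05,.05,.05,.85, .02,.03,.05,.9,
                                            .03,.02,.05,.9, .02,.03,.05,.9),
                                          4, 4, byrow = TRUE))
  mix <- mixture_markov_model(c(0.5, 0.5), list(m1, m2))
  sim <- simulate_mixture(mix, 80, 30, seed = 42)$dataset
  bm <- fit_markov(sim)
  mx <- fit_mixture(sim, K = 2, restarts = 4, seed = 5)
  expect_lt(mx$bic, bm$bic)

  plain <- simulate_markov(markov_model(rep(.25, 4), study_transition),
                           80, 30, seed = 42)
  bm2 <- fit_markov(plain)
  mx2 <- fit_mixture(plain, K = 2, restarts = 4, seed = 5)
  expect_lt(bm2$bic, mx2$bic)
})
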