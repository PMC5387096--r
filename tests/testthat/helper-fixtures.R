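# Shared fixtures and independent oracles, built in code.

# Published single-case 4x2 transition counts used for worked examples.
couple129_counts <- c(23, 4, 1, 1, 3, 1, 3, 11)

# Pooled 4-state transition matrix of the example study (rows: none, SC only,
# DC only, SC+DC), printed to 2 decimals.
study_transition <- matrix(c(
  0.79, 0.06, 0.06, 0.10,
  0.19, 0.33, 0.08, 0.40,
  0.32, 0.05, 0.31, 0.32,
  0.05, 0.08, 0.06, 0.80
), 4, 4, byrow = TRUE)

# Two-latent-state model with an absorbing "coped" state.
absorbing_hmm <- function() {
  hidden_markov_model(
    initial = c(1, 0),
    transition = matrix(c(0.97, 0.03, 0, 1), 2, 2, byrow = TRUE),
    emission = matrix(c(0.07, 0.09, 0.07, 0.77,
                        0.65, 0.09, 0.12, 0.14), 2, 4, byrow = TRUE),
    zero_mask = matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2, byrow = TRUE)
  )
}

# Two-class mixture ("fast" vs "slow" copers), printed to 2 decimals.
two_class_mixture <- function(initial = c(0.05, 0.05, 0.05, 0.85)) {
  m1 <- markov_model(initial, matrix(c(
    0.86, 0.03, 0.05, 0.07,
    0.24, 0.23, 0.09, 0.44,
    0.43, 0.06, 0.34, 0.17,
    0.04, 0.07, 0.04, 0.84), 4, 4, byrow = TRUE))
  m2 <- markov_model(initial, matrix(c(
    0.60, 0.12, 0.10, 0.18,
    0.16, 0.40, 0.07, 0.37,
    0.23, 0.04, 0.28, 0.46,
    0.07, 0.09, 0.09, 0.76), 4, 4, byrow = TRUE))
  mixture_markov_model(c(0.59, 0.41), list(m1, m2))
}

random_pair <- function(id, T_obs) {
  dyad_pair(id, sample(0:1, T_obs, replace = TRUE),
            sample(0:1, T_obs, replace = TRUE))
}

random_dataset <- function(n, T_obs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dyad_dataset(lapply(seq_len(n), function(i) random_pair(paste0("d", i), T_obs)))
}

# --- independent oracles -------------------------------------------------

# Exhaustive edit-script minimum (exponential recursion; tiny sequences only).
om_oracle <- function(s1, s2, sub, indel) {
  if (!length(s1)) return(length(s2) * indel)
  if (!length(s2)) return(length(s1) * indel)
  min(om_oracle(s1[-1], s2[-1], sub, indel) + sub[s1[1], s2[1]],
      om_oracle(s1[-1], s2, sub, indel) + indel,
      om_oracle(s1, s2[-1], sub, indel) + indel)
}

# Brute-force pooled transition counts by classifying each transition.
count_oracle <- function(state_list) {
  cts <- matrix(0L, 4, 4)
  for (s in state_list) {
    for (t in seq_along(s)[-1]) {
      i <- s[t - 1]; j <- s[t]
      cts[i, j] <- cts[i, j] + 1L
    }
  }
  cts
}

# Iteratively fitted (IRLS) logistic regression on the grouped 4x2 table,
# with the same effect coding as the closed form.
irls_oracle <- function(counts, target = "b") {
  a_code <- c(1, 1, -1, -1)
  b_code <- c(1, -1, 1, -1)
  own <- if (target == "b") b_code else a_code
  other <- if (target == "b") a_code else b_code
  df <- data.frame(yes = counts[, 1], no = counts[, 2],
                   own = own, other = other, ixn = a_code * b_code)
  fit <- stats::glm(cbind(yes, no) ~ own + other + ixn, family = binomial(),
                    data = df, control = stats::glm.control(epsilon = 1e-12))
  stats::setNames(coef(fit), c("b0", "b_actor", "b_partner", "b_ixn"))
}

# Hungarian-free best label matching accuracy for two-class recovery checks.
match_accuracy <- function(truth, labels) {
  agreement(truth, labels) / 100
}
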