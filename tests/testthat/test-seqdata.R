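# Data model, file I/O, state expansion and descriptive statistics.

test_that("dyad_pair validates codes, lengths and dropout structure", {
  p <- dyad_pair("d1", c(1, 1, 0), c(0, 1, 1))
  expect_s3_class(p, "dyad_pair")
  expect_length(p$seq_a, 3)

  # shared terminal NA suffix = dropout, trimmed
  p2 <- dyad_pair("d2", c(1, 0, NA), c(0, 1, NA))
  expect_equal(length(p2$seq_a), 2)

  # internal gap is invalid
  expect_error(dyad_pair("d3", c(1, NA, 0), c(0, NA, 1)), "non-terminal")
  # unmatched missingness between partners
  expect_error(dyad_pair("d4", c(1, 0, NA), c(0, 1, 1)), "unequal observed")
  # non-binary code
  expect_error(dyad_pair("d5", c(1, 2, 0), c(0, 1, 1)), "non-binary")
  # too short after trimming
  expect_error(dyad_pair("d6", c(1, NA, NA), c(0, NA, NA)), "fewer than 2")
})

test_that("read_dyads parses wide files, dropout suffixes, and errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "dyad_id,sc_1,sc_2,sc_3,dc_1,dc_2,dc_3,ability",
    "129,1,1,0,0,1,1,3.5",
    "130,1,0,,0,1,,2.0"
  ), tmp)
  ds <- read_dyads(tmp, a_prefix = "sc_", b_prefix = "dc_")
  expect_equal(n_dyads(ds), 2)
  expect_equal(unname(seq_lengths(ds)), c(3L, 2L))
  expect_equal(ds$pairs[["129"]]$seq_a, c(1L, 1L, 0L))
  expect_equal(unname(covariate(ds, "ability")), c(3.5, 2.0))
  expect_equal(ds$label_a, "sc_")

  # roundtrip through write_dyads
  out <- withr::local_tempfile(fileext = ".csv")
  write_dyads(ds, out, a_prefix = "sc_", b_prefix = "dc_")
  ds2 <- read_dyads(out, a_prefix = "sc_", b_prefix = "dc_")
  expect_equal(lapply(ds2$pairs, `[[`, "seq_a"), lapply(ds$pairs, `[[`, "seq_a"))

  # internal gap in one stream
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dyad_id,sc_1,sc_2,sc_3,dc_1,dc_2,dc_3",
               "1,1,,0,0,1,1"), tmp2)
  expect_error(read_dyads(tmp2, a_prefix = "sc_", b_prefix = "dc_"),
               "unequal observed|non-terminal")

  # non-binary value reported with row and column
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dyad_id,sc_1,sc_2,dc_1,dc_2", "1,1,7,0,1"), tmp3)
  expect_error(read_dyads(tmp3, a_prefix = "sc_", b_prefix = "dc_"),
               "row 1.*sc_2")

  # unequal numbers of stream columns
  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dyad_id,sc_1,sc_2,dc_1", "1,1,0,1"), tmp4)
  expect_error(read_dyads(tmp4, a_prefix = "sc_", b_prefix = "dc_"), "schema")
})

test_that("state expansion maps code pairs to the fixed 4-state alphabet", {
  p <- dyad_pair("d", c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(as.character(expand_states(p)),
               c("both", "b_only", "a_only", "none"))
  # all-zero streams
  p0 <- dyad_pair("z", c(0, 0, 0), c(0, 0, 0))
  expect_equal(as.character(expand_states(p0)), rep("none", 3))
  # the 1-1-0 / 0-0-0 interval-sampling example
  p1 <- dyad_pair("e", c(1, 1, 0), c(0, 0, 0))
  expect_equal(as.character(expand_states(p1)), c("a_only", "a_only", "none"))
})

test_that("expand and collapse are mutual inverses on all sequences (T <= 6)", {
  for (T_obs in c(2L, 4L, 6L)) {
    grid <- as.matrix(expand.grid(rep(list(1:4), T_obs)))
    for (r in seq_len(nrow(grid))) {
      s <- as.integer(grid[r, ])
      p <- collapse_states(s, dyad_id = "x")
      expect_identical(as.integer(expand_states(p)), s)
    }
    # and pair -> states -> pair
    set.seed(T_obs)
    for (i in 1:20) {
      p <- random_pair("r", T_obs)
      p2 <- collapse_states(expand_states(p), dyad_id = "r")
      expect_identical(p2$seq_a, p$seq_a)
      expect_identical(p2$seq_b, p$seq_b)
    }
  }
})

test_that("describe: distributions, entropy and transition counts", {
  # two dyads, equal split between none and both at every interval
  ds <- dyad_dataset(list(dyad_pair("1", c(0, 0), c(0, 0)),
                          dyad_pair("2", c(1, 1), c(1, 1))))
  d <- describe(ds)
  expect_equal(colSums(d$state_distribution), c(1, 1))
  # (1/2, 0, 0, 1/2) distribution: entropy ln2/ln4 = 0.5 exactly
  expect_equal(d$entropy, c(0.5, 0.5))
  expect_equal(unname(d$transition_counts), c(0L, 0L))

  # all dyads in one state -> entropy 0
  ds0 <- dyad_dataset(list(dyad_pair("1", c(0, 0), c(0, 0)),
                           dyad_pair("2", c(0, 0), c(0, 0))))
  expect_equal(describe(ds0)$entropy, c(0, 0))

  # constant sequence of length 48 -> 0 transitions; alternating -> 47
  const48 <- dyad_pair("c", rep(1, 48), rep(1, 48))
  alt48 <- dyad_pair("a", rep(c(1, 0), 24), rep(0, 48))
  d2 <- describe(dyad_dataset(list(const48, alt48)))
  expect_equal(unname(d2$transition_counts), c(0L, 47L))

  # dropouts: per-interval denominators use only observed dyads
  ds3 <- dyad_dataset(list(dyad_pair("1", c(0, 0, 0), c(0, 0, 0)),
                           dyad_pair("2", c(1, 1, NA), c(1, 1, NA))))
  d3 <- describe(ds3)
  expect_equal(d3$n_observed, c(2L, 2L, 1L))
  expect_equal(d3$state_distribution[, 3], c(none = 1, a_only = 0, b_only = 0, both = 0))
})

test_that("transition counts are invariant under partner relabeling", {
  set.seed(7)
  for (i in 1:10) {
    p <- random_pair("p", 12)
    swapped <- dyad_pair("p", p$seq_b, p$seq_a)
    d1 <- describe(dyad_dataset(list(p, random_pair("q", 12))))
    d2 <- describe(dyad_dataset(list(swapped, random_pair("q2", 12))))
    expect_equal(d1$transition_counts[[1]], d2$transition_counts[[1]])
  }
})

test_that("frequency correlation matches the textbook formula and edge cases", {
  # hand-built: 5 dyads with known counts
  mk <- function(id, na, nb) {
    dyad_pair(id, c(rep(1, na), rep(0, 8 - na)), c(rep(1, nb), rep(0, 8 - nb)))
  }
  ds <- dyad_dataset(list(mk("1", 1, 2), mk("2", 3, 1), mk("3", 5, 4),
                          mk("4", 2, 6), mk("5", 7, 7)))
  fc <- frequency_correlation(ds)
  ca <- c(1, 3, 5, 2, 7); cb <- c(2, 1, 4, 6, 7)
  r_manual <- sum((ca - mean(ca)) * (cb - mean(cb))) /
    sqrt(sum((ca - mean(ca))^2) * sum((cb - mean(cb))^2))
  t_manual <- r_manual * sqrt(3 / (1 - r_manual^2))
  expect_equal(fc$r, r_manual, tolerance = 1e-12)
  expect_equal(fc$p, 2 * pt(-abs(t_manual), df = 3), tolerance = 1e-12)

  # perfect positive / negative association
  dsp <- dyad_dataset(list(mk("1", 1, 1), mk("2", 3, 3), mk("3", 5, 5)))
  expect_equal(frequency_correlation(dsp)$r, 1)
  dsn <- dyad_dataset(list(mk("1", 1, 7), mk("2", 3, 5), mk("3", 5, 3)))
  expect_equal(frequency_correlation(dsn)$r, -1)

  # zero variance -> undefined
  dsz <- dyad_dataset(list(mk("1", 2, 1), mk("2", 2, 3), mk("3", 2, 5)))
  expect_error(frequency_correlation(dsz), "zero variance")
  # unequal lengths -> warning
  dsu <- dyad_dataset(list(mk("1", 1, 2), mk("2", 3, 1),
                           dyad_pair("3", c(1, 0, NA), c(0, 1, NA))))
  expect_warning(frequency_correlation(dsu), "unequal")
})

test_that("plot builders return ggplot objects", {
  ds <- random_dataset(6, 10, seed = 1)
  d <- describe(ds)
  expect_s3_class(plot_state_distribution(d), "ggplot")
  expect_s3_class(plot_entropy(d), "ggplot")
  expect_s3_class(plot_transition_histogram(d), "ggplot")
  expect_s3_class(plot_state_distribution(ds, labels = rep(1:2, each = 3)), "ggplot")
})
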