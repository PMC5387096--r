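# ggplot2 graphics: state-distribution area plot, entropy profile, and the
# transition-count histogram; an optional grouping faceting for clusters.

describe_long <- function(desc) {
  dist <- desc$state_distribution
  Tm <- ncol(dist)
  lbl <- state_display(desc$label_a, desc$label_b)
  data.frame(
    interval = rep(seq_len(Tm), each = 4L),
    state = factor(rep(lbl, Tm), levels = lbl),
    share = as.numeric(dist)
  )
}

#' State-distribution area plot
#'
#' Relative frequency of each joint state per observation interval, over the
#' dyads still under observation.
#'
#' @param x A `dyad_describe` (from [describe()]) or a `dyad_dataset`.
#' @param labels Optional group labels (one per dyad) to facet by, e.g., a
#'   cluster assignment; only used when `x` is a dataset.
#' @return A ggplot object.
#' @export
plot_state_distribution <- function(x, labels = NULL) {
  if (inherits(x, "dyad_dataset") && !is.null(labels)) {
    stopifnot(length(labels) == n_dyads(x))
    groups <- split(seq_len(n_dyads(x)), labels)
    df <- do.call(rbind, lapply(names(groups), function(g) {
      sub <- dyad_dataset(x$pairs[groups[[g]]], x$label_a, x$label_b)
      cbind(describe_long(describe(sub)), group = g)
    }))
    p <- ggplot2::ggplot(df[!is.na(df$share), ],
                         ggplot2::aes(x = interval, y = share,
                                      fill = state)) +
      ggplot2::geom_area(position = "stack") +
      ggplot2::facet_wrap(~group)
  } else {
    desc <- if (inherits(x, "dyad_describe")) x else describe(x)
    df <- describe_long(desc)
    p <- ggplot2::ggplot(df[!is.na(df$share), ],
                         ggplot2::aes(x = interval, y = share,
                                      fill = state)) +
      ggplot2::geom_area(position = "stack")
  }
  p + ggplot2::labs(x = "observation interval", y = "relative frequency",
                    fill = "state") +
    ggplot2::theme_minimal()
}

#' Entropy profile plot
#'
#' Normalized Shannon entropy of the state distribution per interval
#' (0 = all dyads in the same state, 1 = uniform over the four states).
#'
#' @param desc A `dyad_describe` from [describe()].
#' @return A ggplot object.
#' @export
plot_entropy <- function(desc) {
  stopifnot(inherits(desc, "dyad_describe"))
  df <- data.frame(interval = seq_along(desc$entropy), entropy = desc$entropy)
  ggplot2::ggplot(df[!is.na(df$entropy), ],
                  ggplot2::aes(x = interval, y = entropy)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "observation interval", y = "normalized entropy") +
    ggplot2::theme_minimal()
}

#' Histogram of per-dyad state-transition counts
#'
#' @param desc A `dyad_describe` from [describe()].
#' @param binwidth Histogram bin width (default 2).
#' @return A ggplot object.
#' @export
plot_transition_histogram <- function(desc, binwidth = 2) {
  stopifnot(inherits(desc, "dyad_describe"))
  df <- data.frame(transitions = desc$transition_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = transitions)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40", color = "white") +
    ggplot2::labs(x = "state transitions per dyad", y = "dyads") +
    ggplot2::theme_minimal()
}

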