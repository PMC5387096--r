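# Optimal-matching sequence dissimilarities with transition-rate (TRATE)
# substitution costs, Ward clustering on the distance matrix, silhouette-based
# selection of the number of clusters, and cluster validation helpers.

#' Substitution costs from transition rates (TRATE)
#'
#' Builds the optimal-matching substitution-cost matrix from a fitted basic
#' Markov model: `cost(i, j) = 2 - p(j|i) - p(i|j)` for `i != j`, zero on the
#' diagonal. States that frequently follow one another are cheap to
#' substitute (cost 0 if each always follows the other); states never seen in
#' consecutive order cost the maximum of 2.
#'
#' @param x A fitted [markov_model()], or data accepted by [fit_markov()]
#'   (the model is then fitted first).
#' @param indel Insertion/deletion cost (default 1: one indel counts as one
#'   operation).
#' @return Object of class `om_costs` with elements `sub` (4 x 4 symmetric,
#'   zero diagonal) and `indel`.
#' @export
trate_costs <- function(x, indel = 1) {
  model <- if (inherits(x, "markov_model")) x else fit_markov(x)
  stopifnot(indel > 0)
  tm <- model$transition
  if (anyNA(tm)) {
    warning("undefined transition row(s); treating the missing rates as 0 ",
            "(maximal substitution cost)", call. = FALSE)
    tm[is.na(tm)] <- 0
  }
  sub <- 2 - tm - t(tm)
  diag(sub) <- 0
  dimnames(sub) <- dimnames(tm)
  structure(list(sub = sub, indel = indel), class = "om_costs")
}

#' Constant substitution costs
#'
#' @param sub Constant substitution cost between any two distinct states
#'   (default 2, the TRATE maximum).
#' @param indel Insertion/deletion cost.
#' @export
constant_costs <- function(sub = 2, indel = 1) {
  m <- matrix(sub, 4L, 4L, dimnames = list(STATES, STATES))
  diag(m) <- 0
  structure(list(sub = m, indel = indel), class = "om_costs")
}

#' @export
#' @method print om_costs
print.om_costs <- function(x, digits = 3, ...) {
  cat("<om_costs> indel =", x$indel, "\n")
  print(round(x$sub, digits))
  invisible(x)
}

#' Optimal-matching distance between two state sequences
#'
#' Minimal total cost of insertions, deletions (each costing `indel`) and
#' substitutions (costing `sub[i, j]`) transforming one sequence into the
#' other, computed by dynamic programming. Sequences of unequal length are
#' compared as-is; the length difference is absorbed by indels.
#'
#' @param s1,s2 State sequences (factors over the alphabet, state labels, or
#'   integer codes 1..4).
#' @param costs An `om_costs` object from [trate_costs()] or
#'   [constant_costs()].
#' @return Nonnegative distance.
#' @export
om_distance <- function(s1, s2, costs) {
  stopifnot(inherits(costs, "om_costs"))
  om_dist_cpp(states_to_codes(s1), states_to_codes(s2),
              costs$sub, costs$indel)
}

#' All pairwise optimal-matching distances for a dataset
#'
#' @param x A `dyad_dataset` or list of state sequences.
#' @param costs An `om_costs` object; by default TRATE costs from a basic
#'   Markov model fitted to the same data.
#' @param indel Indel cost used when `costs` is derived internally.
#' @return Symmetric n x n matrix with zero diagonal, dimnames = dyad ids.
#' @export
distance_matrix <- function(x, costs = NULL, indel = 1) {
  sl <- as_state_list(x)
  if (is.null(costs)) costs <- trate_costs(fit_markov(sl), indel = indel)
  n <- length(sl)
  D <- matrix(0, n, n, dimnames = list(names(sl), names(sl)))
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- om_dist_cpp(sl[[i]], sl[[j]], costs$sub, costs$indel)
    }
  }
  D
}

#' Ward agglomerative clustering of a distance matrix
#'
#' Hierarchical clustering by the Ward minimum-variance criterion via the
#' Lance-Williams recurrence on squared dissimilarities
#' (`stats::hclust(method = "ward.D")` on the squared matrix); merge heights
#' are reported on the squared scale and are non-decreasing.
#'
#' @param D Symmetric distance matrix (e.g., from [distance_matrix()]).
#' @return An [stats::hclust] tree.
#' @export
ward_cluster <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 2L, isTRUE(all.equal(D, t(D))))
  stats::hclust(stats::as.dist(D^2), method = "ward.D")
}

#' Choose the number of clusters by mean silhouette width
#'
#' Cuts the Ward tree at each `k` in `k_range`, computes per-dyad silhouette
#' widths `s(i) = (b(i) - a(i)) / max(a(i), b(i))` from the distance matrix
#' (singletons: `s(i) = 0`), and picks the `k` with the largest mean width.
#' A "reasonable structure" flag is set when the best mean silhouette
#' exceeds 0.51; weaker coefficients do not invalidate a solution but call
#' for corroboration by the dendrogram, the merge-height scree values, and
#' the classical MDS plot (all returned as diagnostics).
#'
#' @param D Distance matrix.
#' @param tree Optional precomputed [ward_cluster()] tree.
#' @param k_range Candidate cluster numbers (default `2:min(8, n - 1)`).
#' @return Object of class `cluster_solution`: `chosen_k`, `labels` (at the
#'   chosen k), `silhouette` (data frame k / mean width), `widths` (per-k
#'   per-dyad widths), `labels_k` (per-k label vectors), `tree`, `scree`
#'   (merge heights, largest first), `mds` (n x 2 coordinates),
#'   `reasonable_structure`.
#' @export
silhouette_select <- function(D, tree = NULL, k_range = NULL) {
  n <- nrow(D)
  if (is.null(k_range)) k_range <- 2:min(8L, n - 1L)
  stopifnot(n > max(k_range), min(k_range) >= 2L)
  if (is.null(tree)) tree <- ward_cluster(D)
  widths <- list()
  labels_k <- list()
  means <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    labs <- stats::cutree(tree, k = k)
    if (length(unique(labs)) < k) next  # degenerate cut: skip this k
    sil <- cluster::silhouette(labs, dmatrix = D)
    w <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, n)
    widths[[as.character(k)]] <- stats::setNames(w, rownames(D))
    labels_k[[as.character(k)]] <- labs
    means[i] <- mean(w)
  }
  if (all(is.na(means))) stop("no admissible k in k_range", call. = FALSE)
  chosen_k <- k_range[which.max(means)]
  mds <- tryCatch(stats::cmdscale(stats::as.dist(D), k = 2L),
                  error = function(e) NULL)
  structure(list(chosen_k = chosen_k,
                 labels = labels_k[[as.character(chosen_k)]],
                 silhouette = data.frame(k = k_range, mean_width = means),
                 widths = widths, labels_k = labels_k, tree = tree,
                 scree = rev(tree$height), mds = mds,
                 reasonable_structure = max(means, na.rm = TRUE) > 0.51),
            class = "cluster_solution")
}

#' @export
#' @method print cluster_solution
print.cluster_solution <- function(x, digits = 3, ...) {
  cat("<cluster_solution> chosen k =", x$chosen_k, "\n")
  print(transform(x$silhouette, mean_width = round(mean_width, digits)),
        row.names = FALSE)
  cat(if (x$reasonable_structure) "mean silhouette > 0.51: reasonable structure\n"
      else "mean silhouette <= 0.51: corroborate with dendrogram / scree / MDS\n")
  cat("cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' One-call optimal-matching sequence clustering
#'
#' Fits the basic Markov model for TRATE costs (unless costs are supplied),
#' computes all pairwise optimal-matching distances, clusters them with the
#' Ward criterion, and selects the number of clusters by mean silhouette.
#'
#' @inheritParams distance_matrix
#' @param k_range Candidate cluster numbers (default `2:min(8, n - 1)`).
#' @return A `cluster_solution` (see [silhouette_select()]) with the
#'   distance matrix attached as `$D` and the cost object as `$costs`.
#' @export
sequence_clusters <- function(x, costs = NULL, indel = 1, k_range = NULL) {
  sl <- as_state_list(x)
  if (is.null(costs)) costs <- trate_costs(fit_markov(sl), indel = indel)
  D <- distance_matrix(sl, costs = costs)
  sol <- silhouette_select(D, k_range = k_range)
  sol$D <- D
  sol$costs <- costs
  sol
}

# All permutations of 1..n (n <= 7) as a list.
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Best-matching percentage agreement between two labelings
#'
#' Maximal percentage of units assigned identically under the best
#' one-to-one matching of the two label sets (brute force over label
#' permutations; up to 6 groups).
#'
#' @param labels1,labels2 Label vectors of equal length (any types coercible
#'   to factors).
#' @return Percentage in \[0, 100\].
#' @export
agreement <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) {
    stop("labelings have different lengths", call. = FALSE)
  }
  f1 <- as.integer(factor(labels1))
  f2 <- as.integer(factor(labels2))
  g <- max(max(f1), max(f2))
  if (g > 6L) stop("more than 6 groups not supported", call. = FALSE)
  conf <- matrix(0L, g, g)
  for (i in seq_along(f1)) conf[f1[i], f2[i]] <- conf[f1[i], f2[i]] + 1L
  best <- 0L
  for (p in permutations_of(g)) {
    s <- sum(conf[cbind(seq_len(g), p)])
    if (s > best) best <- s
  }
  100 * best / length(f1)
}

#' Association between a two-group clustering and a dyad-level covariate
#'
#' Point-biserial correlation: Pearson correlation between the 0/1 group
#' dummy (second factor level = 1) and the covariate, with a two-tailed
#' p-value from the t distribution with n - 2 df.
#'
#' @param labels Two-group label vector (>= 3 dyads).
#' @param covariate Numeric covariate of the same length.
#' @return List with `r`, `p`, `n` and the underlying `htest`.
#' @export
covariate_association <- function(labels, covariate) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("exactly 2 groups required", call. = FALSE)
  keep <- !is.na(covariate)
  dummy <- as.integer(f)[keep] - 1L
  x <- covariate[keep]
  if (length(x) < 3L) stop("need at least 3 dyads", call. = FALSE)
  if (stats::var(dummy) == 0 || stats::var(x) == 0) {
    stop("zero variance: association undefined", call. = FALSE)
  }
  ct <- stats::cor.test(dummy, x, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), test = ct)
}
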