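#' Construct a single dyad's paired behavior sequences
#'
#' A dyad pair holds the two aligned binary streams observed for one dyad by
#' interval sampling: `seq_a` for partner A's behavior and `seq_b` for partner
#' B's behavior, coded 1 if the behavior occurred in an interval and 0
#' otherwise. Dropout (leaving the study before the last interval) appears as
#' a shared terminal run of `NA` values, which is trimmed; any other
#' missingness is rejected.
#'
#' @param dyad_id Identifier for the dyad (coerced to character).
#' @param seq_a,seq_b Numeric/integer vectors of 0/1 codes of equal length;
#'   a common terminal `NA` suffix marks dropout.
#' @param covariates Optional named list or vector of dyad-level covariates.
#' @return An object of class `dyad_pair` with elements `dyad_id`, `seq_a`,
#'   `seq_b` (trimmed to the observed length `T_obs >= 2`) and `covariates`.
#' @examples
#' dyad_pair("d1", c(1, 1, 0), c(0, 1, 1))
#' @export
dyad_pair <- function(dyad_id, seq_a, seq_b, covariates = NULL) {
  stopifnot(length(dyad_id) == 1L)
  dyad_id <- as.character(dyad_id)
  if (length(seq_a) != length(seq_b)) {
    stop("dyad ", dyad_id, ": partner streams have unequal length", call. = FALSE)
  }
  na_a <- is.na(seq_a)
  na_b <- is.na(seq_b)
  if (!identical(na_a, na_b)) {
    stop("dyad ", dyad_id, ": unequal observed lengths for the two partners ",
         "(missingness must be a shared terminal suffix)", call. = FALSE)
  }
  if (any(na_a)) {
    first_na <- which(na_a)[1L]
    if (!all(na_a[first_na:length(seq_a)])) {
      stop("dyad ", dyad_id, ": non-terminal missingness (internal gaps are invalid)",
           call. = FALSE)
    }
    seq_a <- seq_a[seq_len(first_na - 1L)]
    seq_b <- seq_b[seq_len(first_na - 1L)]
  }
  if (length(seq_a) < 2L) {
    stop("dyad ", dyad_id, ": fewer than 2 observed intervals", call. = FALSE)
  }
  check_binary <- function(x, which) {
    bad <- which(!(x %in% c(0, 1)))
    if (length(bad)) {
      stop("dyad ", dyad_id, ": non-binary code ", x[bad[1L]], " in ", which,
           " at interval ", bad[1L], call. = FALSE)
    }
    as.integer(x)
  }
  seq_a <- check_binary(seq_a, "seq_a")
  seq_b <- check_binary(seq_b, "seq_b")
  if (!is.null(covariates)) covariates <- as.list(covariates)
  structure(list(dyad_id = dyad_id, seq_a = seq_a, seq_b = seq_b,
                 covariates = covariates),
            class = "dyad_pair")
}

#' Bundle dyad pairs into a dataset
#'
#' @param pairs List of [dyad_pair()] objects with unique dyad ids.
#' @param label_a,label_b Display names for the two behavior streams
#'   (e.g., `"SC"` and `"DC"`).
#' @return Object of class `dyad_dataset`.
#' @export
dyad_dataset <- function(pairs, label_a = "A", label_b = "B") {
  stopifnot(length(pairs) >= 1L)
  if (!all(vapply(pairs, inherits, logical(1), "dyad_pair"))) {
    stop("all elements of `pairs` must be dyad_pair objects", call. = FALSE)
  }
  ids <- vapply(pairs, `[[`, character(1), "dyad_id")
  if (anyDuplicated(ids)) {
    stop("duplicate dyad ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(pairs) <- ids
  structure(list(pairs = pairs, label_a = label_a, label_b = label_b,
                 T_max = max(vapply(pairs, function(p) length(p$seq_a), integer(1)))),
            class = "dyad_dataset")
}

#' @export
#' @method print dyad_dataset
print.dyad_dataset <- function(x, ...) {
  lens <- seq_lengths(x)
  cat("<dyad_dataset> ", length(x$pairs), " dyads, streams '", x$label_a,
      "' / '", x$label_b, "'\n", sep = "")
  cat("  observed intervals: ", min(lens), "-", max(lens), "\n", sep = "")
  cv <- covariate_names(x)
  if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method print dyad_pair
print.dyad_pair <- function(x, ...) {
  cat("<dyad_pair> ", x$dyad_id, " (T_obs = ", length(x$seq_a), ")\n", sep = "")
  cat("  a:", paste(x$seq_a, collapse = ""), "\n")
  cat("  b:", paste(x$seq_b, collapse = ""), "\n")
  invisible(x)
}

#' Number of dyads in a dataset
#' @param dataset A `dyad_dataset`.
#' @export
n_dyads <- function(dataset) length(dataset$pairs)

#' Observed sequence lengths per dyad
#' @param dataset A `dyad_dataset`.
#' @return Named integer vector of `T_obs` per dyad.
#' @export
seq_lengths <- function(dataset) {
  vapply(dataset$pairs, function(p) length(p$seq_a), integer(1))
}

covariate_names <- function(dataset) {
  unique(unlist(lapply(dataset$pairs, function(p) names(p$covariates))))
}

#' Extract one dyad-level covariate as a vector
#' @param dataset A `dyad_dataset`.
#' @param name Covariate name.
#' @return Named numeric vector (NA where a dyad lacks the covariate).
#' @export
covariate <- function(dataset, name) {
  vapply(dataset$pairs, function(p) {
    v <- p$covariates[[name]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' Read dyadic sequences from a wide-format CSV/TSV file
#'
#' Expects one row per dyad with a dyad-id column, `T` columns for partner
#' A's behavior and `T` columns for partner B's behavior (identified by a
#' column-name prefix or an explicit column list), plus optional dyad-level
#' covariate columns. Dropout is encoded by empty/`NA` cells forming a
#' shared terminal suffix of both streams.
#'
#' @param path File path; the separator defaults to tab for `.tsv`/`.txt`,
#'   comma otherwise, unless `sep` is given.
#' @param a_prefix,b_prefix Column-name prefixes identifying the two streams
#'   (columns are ordered by their numeric suffix).
#' @param a_cols,b_cols Alternatively, explicit column-name vectors, in
#'   interval order.
#' @param id_col Name of the dyad-id column (default `"dyad_id"`); if absent,
#'   row numbers are used.
#' @param covariate_cols Names of covariate columns; default: every numeric
#'   column that is neither id nor sequence column.
#' @param label_a,label_b Display names for the streams; default the prefixes.
#' @param sep Field separator override.
#' @return A [dyad_dataset()].
#' @export
read_dyads <- function(path, a_prefix = NULL, b_prefix = NULL,
                       a_cols = NULL, b_cols = NULL, id_col = "dyad_id",
                       covariate_cols = NULL, label_a = NULL, label_b = NULL,
                       sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  prefix_cols <- function(prefix) {
    cols <- grep(paste0("^", prefix), names(df), value = TRUE)
    if (!length(cols)) stop("no columns match prefix '", prefix, "'", call. = FALSE)
    suff <- suppressWarnings(as.integer(sub(paste0("^", prefix), "", cols)))
    if (anyNA(suff)) cols else cols[order(suff)]
  }
  if (is.null(a_cols)) {
    if (is.null(a_prefix)) stop("supply `a_prefix` or `a_cols`", call. = FALSE)
    a_cols <- prefix_cols(a_prefix)
  }
  if (is.null(b_cols)) {
    if (is.null(b_prefix)) stop("supply `b_prefix` or `b_cols`", call. = FALSE)
    b_cols <- prefix_cols(b_prefix)
  }
  if (length(a_cols) != length(b_cols)) {
    stop("schema error: ", length(a_cols), " A-columns vs ", length(b_cols),
         " B-columns", call. = FALSE)
  }
  missing_cols <- setdiff(c(a_cols, b_cols), names(df))
  if (length(missing_cols)) {
    stop("columns not in file: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- if (id_col %in% names(df)) as.character(df[[id_col]]) else as.character(seq_len(nrow(df)))
  if (is.null(covariate_cols)) {
    rest <- setdiff(names(df), c(id_col, a_cols, b_cols))
    covariate_cols <- rest[vapply(df[rest], is.numeric, logical(1))]
  }
  # explicit cell check so errors can name the offending row and column
  for (col in c(a_cols, b_cols)) {
    v <- df[[col]]
    bad <- which(!(is.na(v) | v %in% c(0, 1)))
    if (length(bad)) {
      stop("non-binary code ", v[bad[1L]], " at row ", bad[1L], ", column '",
           col, "'", call. = FALSE)
    }
  }
  pairs <- lapply(seq_len(nrow(df)), function(i) {
    cov <- if (length(covariate_cols)) as.list(df[i, covariate_cols, drop = FALSE]) else NULL
    dyad_pair(ids[i],
              as.numeric(df[i, a_cols]),
              as.numeric(df[i, b_cols]),
              covariates = cov)
  })
  dyad_dataset(pairs,
               label_a = label_a %||% a_prefix %||% "A",
               label_b = label_b %||% b_prefix %||% "B")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset back to a wide-format CSV
#'
#' Inverse of [read_dyads()]; dropout is written as empty cells.
#'
#' @param dataset A `dyad_dataset`.
#' @param path Output file path.
#' @param a_prefix,b_prefix Column-name prefixes for the two streams.
#' @export
write_dyads <- function(dataset, path, a_prefix = "a_", b_prefix = "b_") {
  Tm <- dataset$T_max
  pad <- function(x) c(x, rep(NA_integer_, Tm - length(x)))
  a <- t(vapply(dataset$pairs, function(p) pad(p$seq_a), integer(Tm)))
  b <- t(vapply(dataset$pairs, function(p) pad(p$seq_b), integer(Tm)))
  colnames(a) <- paste0(a_prefix, seq_len(Tm))
  colnames(b) <- paste0(b_prefix, seq_len(Tm))
  out <- data.frame(dyad_id = names(dataset$pairs), a, b, check.names = FALSE)
  cn <- covariate_names(dataset)
  for (nm in cn) out[[nm]] <- covariate(dataset, nm)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Expand a dyad's two binary streams into the joint four-state sequence
#'
#' The state-expand step maps the pair of codes at each interval to one of
#' four joint states, in the fixed alphabet order none, A-only, B-only, both:
#' (0,0) -> none, (1,0) -> a_only, (0,1) -> b_only, (1,1) -> both.
#'
#' @param pair A [dyad_pair()].
#' @return A factor of length `T_obs` with levels
#'   `c("none", "a_only", "b_only", "both")` and attribute `dyad_id`.
#' @examples
#' expand_states(dyad_pair("d", c(1, 1, 0), c(0, 0, 0)))
#' @export
expand_states <- function(pair) {
  stopifnot(inherits(pair, "dyad_pair"))
  code <- 1L + pair$seq_a + 2L * pair$seq_b
  structure(factor(STATES[code], levels = STATES), dyad_id = pair$dyad_id)
}

#' Collapse a joint four-state sequence back into the two binary streams
#'
#' Exact inverse of [expand_states()].
#'
#' @param states Factor/character/integer vector over the four-state alphabet
#'   (integers are taken as codes 1..4 in alphabet order).
#' @param dyad_id Id for the resulting pair (default: taken from `states`'
#'   `dyad_id` attribute, else `"dyad"`).
#' @param covariates Optional covariates passed through.
#' @return A [dyad_pair()].
#' @export
collapse_states <- function(states, dyad_id = NULL, covariates = NULL) {
  code <- states_to_codes(states)
  dyad_id <- dyad_id %||% attr(states, "dyad_id") %||% "dyad"
  dyad_pair(dyad_id,
            as.integer(code %in% c(2L, 4L)),
            as.integer(code %in% c(3L, 4L)),
            covariates = covariates)
}

# Coerce a state sequence in any accepted representation to integer codes 1..4.
states_to_codes <- function(states) {
  if (is.factor(states)) states <- as.character(states)
  if (is.character(states)) {
    code <- match(states, STATES)
    if (anyNA(code)) stop("unknown state label(s): ",
                          paste(unique(states[is.na(code)]), collapse = ", "),
                          call. = FALSE)
    return(code)
  }
  code <- as.integer(states)
  if (any(is.na(code)) || any(code < 1L | code > 4L)) {
    stop("integer state codes must be in 1..4", call. = FALSE)
  }
  code
}

# List of integer state-code vectors (1..4), one per dyad, from a dataset or
# a list of state sequences.
as_state_list <- function(x) {
  if (inherits(x, "dyad_dataset")) {
    return(lapply(x$pairs, function(p) states_to_codes(expand_states(p))))
  }
  if (inherits(x, "dyad_pair")) {
    return(stats::setNames(list(states_to_codes(expand_states(x))), x$dyad_id))
  }
  if (is.list(x)) return(lapply(x, states_to_codes))
  stop("cannot interpret `x` as state sequences", call. = FALSE)
}

#' Descriptive statistics for a dyadic sequence dataset
#'
#' Computes, over the expanded four-state sequences: the per-interval state
#' distribution (shares over dyads still under observation), the normalized
#' Shannon entropy of that distribution, and the per-dyad number of state
#' transitions (intervals whose state differs from the previous one).
#'
#' @param dataset A `dyad_dataset` with at least one dyad.
#' @return Object of class `dyad_describe` with elements
#'   `state_distribution` (4 x T_max matrix; columns sum to 1),
#'   `entropy` (length T_max, in \[0, 1\], normalized by `log(4)`),
#'   `transition_counts` (named per-dyad integer vector),
#'   `n_observed` (dyads still observed per interval).
#' @export
describe <- function(dataset) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  sl <- as_state_list(dataset)
  if (!length(sl)) stop("empty dataset", call. = FALSE)
  Tm <- dataset$T_max
  lens <- lengths(sl)
  dist <- matrix(NA_real_, 4L, Tm, dimnames = list(STATES, NULL))
  n_obs <- integer(Tm)
  for (t in seq_len(Tm)) {
    obs <- lens >= t
    n_obs[t] <- sum(obs)
    if (n_obs[t] > 0L) {
      st <- vapply(sl[obs], `[[`, integer(1), t)
      dist[, t] <- tabulate(st, 4L) / n_obs[t]
    }
  }
  entropy <- apply(dist, 2L, function(p) {
    if (anyNA(p)) return(NA_real_)
    p <- p[p > 0]
    -sum(p * log(p)) / log(4)
  })
  trans <- vapply(sl, function(s) sum(diff(s) != 0L), integer(1))
  structure(list(state_distribution = dist, entropy = entropy,
                 transition_counts = trans, n_observed = n_obs,
                 label_a = dataset$label_a, label_b = dataset$label_b),
            class = "dyad_describe")
}

#' @export
#' @method print dyad_describe
print.dyad_describe <- function(x, ...) {
  Tm <- ncol(x$state_distribution)
  cat("<dyad_describe> ", length(x$transition_counts), " dyads x ", Tm,
      " intervals\n", sep = "")
  cat("  mean entropy:", round(mean(x$entropy, na.rm = TRUE), 3), "\n")
  cat("  transitions per dyad: median ",
      stats::median(x$transition_counts), " (range ",
      min(x$transition_counts), "-", max(x$transition_counts), ")\n", sep = "")
  invisible(x)
}

#' Correlation between the two partners' behavior frequencies
#'
#' Pearson correlation across dyads between the number of intervals in which
#' partner A showed the behavior and the number for partner B, with a
#' two-tailed p-value from the t distribution with n - 2 df.
#'
#' @param dataset A `dyad_dataset` with >= 3 dyads.
#' @return List with `r`, `p`, `n`, the per-dyad `counts_a`/`counts_b`, and
#'   the underlying `htest` object.
#' @export
frequency_correlation <- function(dataset) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  if (n_dyads(dataset) < 3L) stop("need at least 3 dyads", call. = FALSE)
  ca <- vapply(dataset$pairs, function(p) sum(p$seq_a), integer(1))
  cb <- vapply(dataset$pairs, function(p) sum(p$seq_b), integer(1))
  lens <- seq_lengths(dataset)
  if (length(unique(lens)) > 1L) {
    warning("sequences have unequal observed lengths; frequencies are raw ",
            "counts, not rates", call. = FALSE)
  }
  if (stats::var(ca) == 0 || stats::var(cb) == 0) {
    stop("undefined correlation: zero variance in a frequency vector", call. = FALSE)
  }
  ct <- stats::cor.test(ca, cb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ca),
       counts_a = ca, counts_b = cb, test = ct)
}
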