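# Dyadic multilevel logistic model: every interval t >= 2 contributes two
# long-format records per dyad (one per member); a member dummy crossed with
# the lagged effect-coded actor/partner predictors gives the eight fixed
# effects, and dyad-level random effects capture couple heterogeneity.

GAMMA_TERMS <- c("(Intercept)", "ae", "pe", "ae:pe",
                 "sex", "ae:sex", "pe:sex", "ae:pe:sex")

#' Build the long-format record table for the multilevel logistic model
#'
#' For each dyad and each interval `t = 2..T_obs` two records are emitted:
#' one for the reference member (sex = 0: outcome is partner B's behavior at
#' `t`, actor predictor is B's behavior at `t - 1`, partner predictor is A's
#' behavior at `t - 1`) and one for the other member (sex = 1: outcome A,
#' actor A, partner B). The outcome `dv` is coded occurrence = 1; the lagged
#' predictors `ae`/`pe` are effect-coded (occurrence = +1, non-occurrence =
#' -1). A dyad with T_obs intervals contributes `2 * (T_obs - 1)` records.
#'
#' @param dataset A `dyad_dataset`.
#' @return Data frame with columns `dyad_id`, `t`, `sex`, `dv`, `ae`, `pe`.
#' @export
build_long <- function(dataset) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  recs <- lapply(dataset$pairs, function(p) {
    a <- p$seq_a
    b <- p$seq_b
    Tn <- length(a)
    idx <- 2:Tn
    ea <- 2L * a - 1L
    eb <- 2L * b - 1L
    data.frame(
      dyad_id = p$dyad_id,
      t = rep(idx, 2L),
      sex = rep(c(0L, 1L), each = Tn - 1L),
      dv = c(b[idx], a[idx]),
      ae = c(eb[idx - 1L], ea[idx - 1L]),
      pe = c(ea[idx - 1L], eb[idx - 1L]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# Normalize a random-effect specification; "ae:pe" is the lagged product term.
normalize_random_spec <- function(random_spec) {
  if (is.null(random_spec) || !length(random_spec)) return(character(0))
  allowed <- c("intercept", "ae", "pe", "ae:pe", "sex", "ae:sex", "pe:sex",
               "ae:pe:sex")
  bad <- setdiff(random_spec, allowed)
  if (length(bad)) stop("unknown random terms: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  unique(random_spec)
}

spec_label <- function(random_spec) {
  if (!length(random_spec)) "none" else paste(random_spec, collapse = "+")
}

#' Fit the dyadic multilevel logistic model
#'
#' Maximizes the Laplace-approximated marginal likelihood of the mixed
#' logistic model `dv ~ ae * pe * sex` with dyad-level random effects for the
#' terms in `random_spec` (unstructured covariance), via [lme4::glmer()].
#' With an empty `random_spec` the model degenerates to ordinary pooled
#' logistic regression (fitted with [stats::glm()]).
#'
#' `BIC = -2 loglik + k log(n)` counts every free parameter (8 fixed effects
#' plus `q(q+1)/2` random-covariance entries) and, by default, uses the
#' number of dyads (the level-2 units) as `n`.
#'
#' @param records Long-format data frame from [build_long()].
#' @param random_spec Character vector drawn from `"intercept"`, `"ae"`,
#'   `"pe"`, `"ae:pe"`, `"sex"`, `"ae:sex"`, `"pe:sex"`, `"ae:pe:sex"`;
#'   default random intercept + actor + partner.
#' @param n_type BIC sample size: `"dyads"` (default) or `"records"`.
#' @param ... Passed to [lme4::glmer()] (e.g., `control`).
#' @return Object of class `dyad_glmm`: fixed-effect table (estimate, SE, z,
#'   p, indexed gamma0..gamma7), random-effect covariance and
#'   variance/correlation display matrices, `loglik`, `bic`, `n_obs`,
#'   `n_dyads`, `converged`, and the underlying fit object.
#' @export
fit_glmm <- function(records, random_spec = c("intercept", "ae", "pe"),
                     n_type = c("dyads", "records"), ...) {
  n_type <- match.arg(n_type)
  random_spec <- normalize_random_spec(random_spec)
  stopifnot(all(c("dyad_id", "dv", "ae", "pe", "sex") %in% names(records)))
  n_dy <- length(unique(records$dyad_id))
  if (n_dy < 2L) stop("need records from at least 2 dyads", call. = FALSE)
  if (length(random_spec)) {
    re_terms <- setdiff(random_spec, "intercept")
    re <- paste(c(if ("intercept" %in% random_spec) "1" else "0", re_terms),
                collapse = " + ")
    form <- stats::as.formula(paste0("dv ~ ae * pe * sex + (", re, " | dyad_id)"))
    fit <- lme4::glmer(form, data = records, family = stats::binomial(), ...)
    cf <- summary(fit)$coefficients
    ll <- as.numeric(stats::logLik(fit))
    vc <- lme4::VarCorr(fit)$dyad_id
    cov_m <- matrix(as.numeric(vc), nrow(vc), ncol(vc),
                    dimnames = dimnames(vc))
    sdv <- sqrt(diag(cov_m))
    disp <- diag(diag(cov_m), nrow(cov_m))
    if (nrow(cov_m) > 1L) {
      corr <- cov_m / tcrossprod(sdv)
      disp[lower.tri(disp)] <- corr[lower.tri(corr)]
      disp[upper.tri(disp)] <- corr[upper.tri(corr)]
    }
    dimnames(disp) <- dimnames(cov_m)
    q <- nrow(cov_m)
    k <- nrow(cf) + q * (q + 1L) / 2L
    conv_code <- fit@optinfo$conv$opt
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    converged <- isTRUE(conv_code == 0) &&
      !any(grepl("failed to converge", msgs, ignore.case = TRUE))
    if (any(diag(cov_m) < 1e-8)) {
      warning("random-effect variance at the boundary (< 1e-8) for: ",
              paste(rownames(cov_m)[diag(cov_m) < 1e-8], collapse = ", "),
              call. = FALSE)
    }
  } else {
    fit <- stats::glm(dv ~ ae * pe * sex, data = records,
                      family = stats::binomial())
    cf <- summary(fit)$coefficients
    ll <- as.numeric(stats::logLik(fit))
    cov_m <- NULL
    disp <- NULL
    k <- nrow(cf)
    converged <- isTRUE(fit$converged)
  }
  n_bic <- if (n_type == "dyads") n_dy else nrow(records)
  gamma_idx <- match(GAMMA_TERMS, rownames(cf))
  fixed <- data.frame(
    gamma = paste0("gamma", 0:7),
    term = GAMMA_TERMS,
    estimate = cf[gamma_idx, 1L],
    se = cf[gamma_idx, 2L],
    z = cf[gamma_idx, 3L],
    p = cf[gamma_idx, 4L],
    row.names = NULL
  )
  structure(list(fixed = fixed, random_spec = random_spec,
                 random_cov = cov_m, random_display = disp,
                 loglik = ll, bic = -2 * ll + k * log(n_bic),
                 k = k, n_type = n_type, n_obs = nrow(records),
                 n_dyads = n_dy, converged = converged, fit = fit),
            class = "dyad_glmm")
}

#' @export
#' @method print dyad_glmm
print.dyad_glmm <- function(x, digits = 3, ...) {
  cat("<dyad_glmm> random: ", spec_label(x$random_spec), "; ",
      x$n_obs, " records from ", x$n_dyads, " dyads\n", sep = "")
  if (!x$converged) cat("  ** fit did not converge **\n")
  out <- x$fixed
  out[3:6] <- lapply(out[3:6], function(v) round(v, digits))
  print(out, row.names = FALSE)
  if (!is.null(x$random_display)) {
    cat("random effects (variances on diagonal, correlations off):\n")
    print(round(x$random_display, digits))
  }
  cat("loglik = ", format(x$loglik), ", k = ", x$k, ", BIC(",
      x$n_type, ") = ", format(round(x$bic, 1)), "\n", sep = "")
  invisible(x)
}

#' Select the random-effect structure by BIC
#'
#' Fits the model under each candidate random-effect specification and
#' returns the candidate with the smallest BIC together with the full
#' comparison table. Candidates that fail to fit are excluded with their
#' error message recorded.
#'
#' @inheritParams fit_glmm
#' @param candidates List of random-effect specifications (character vectors
#'   as in [fit_glmm()]); the default ladder is none, intercept,
#'   intercept+ae, intercept+ae+pe, intercept+ae+pe+ae:pe.
#' @return List with `best` (the winning `dyad_glmm`), `table` (data frame of
#'   spec, loglik, k, bic, converged) and `fits` (all successful fits).
#' @export
select_random_structure <- function(records,
                                    candidates = list(
                                      character(0),
                                      "intercept",
                                      c("intercept", "ae"),
                                      c("intercept", "ae", "pe"),
                                      c("intercept", "ae", "pe", "ae:pe")),
                                    n_type = c("dyads", "records"), ...) {
  n_type <- match.arg(n_type)
  stopifnot(length(candidates) >= 1L)
  fits <- list()
  rows <- list()
  for (spec in candidates) {
    lab <- spec_label(spec)
    res <- tryCatch(fit_glmm(records, random_spec = spec, n_type = n_type, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[lab]] <- data.frame(spec = lab, loglik = NA_real_, k = NA_integer_,
                                bic = NA_real_, converged = FALSE,
                                note = conditionMessage(res))
    } else {
      fits[[lab]] <- res
      rows[[lab]] <- data.frame(spec = lab, loglik = res$loglik, k = res$k,
                                bic = res$bic, converged = res$converged,
                                note = "")
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!length(fits)) stop("all candidate random structures failed to fit",
                          call. = FALSE)
  ok <- tab$spec[!is.na(tab$bic)]
  best_lab <- ok[which.min(tab$bic[!is.na(tab$bic)])]
  list(best = fits[[best_lab]], table = tab, fits = fits)
}

#' Member-specific fixed effects from the fitted multilevel model
#'
#' The reference member's (sex = 0) intercept, actor, partner and interaction
#' effects are (gamma0, gamma1, gamma2, gamma3); the other member's (sex = 1)
#' are the sums (gamma0+gamma4, gamma1+gamma5, gamma2+gamma6, gamma3+gamma7).
#' Standard errors of the sums come from the fixed-effect covariance matrix
#' by the delta method.
#'
#' @param result A `dyad_glmm` from [fit_glmm()].
#' @return List with data frames `reference` and `other`, each with columns
#'   `effect`, `estimate`, `se`.
#' @export
sex_specific_effects <- function(result) {
  stopifnot(inherits(result, "dyad_glmm"))
  V <- as.matrix(stats::vcov(result$fit))
  est <- stats::setNames(result$fixed$estimate, result$fixed$term)
  base_terms <- GAMMA_TERMS[1:4]
  add_terms <- GAMMA_TERMS[5:8]
  effects <- c("intercept", "actor", "partner", "interaction")
  ref <- data.frame(effect = effects,
                    estimate = unname(est[base_terms]),
                    se = sqrt(diag(V)[base_terms]),
                    row.names = NULL)
  other_est <- est[base_terms] + est[add_terms]
  other_se <- vapply(seq_len(4L), function(j) {
    a <- base_terms[j]; b <- add_terms[j]
    sqrt(V[a, a] + V[b, b] + 2 * V[a, b])
  }, numeric(1))
  other <- data.frame(effect = effects, estimate = unname(other_est),
                      se = other_se, row.names = NULL)
  list(reference = ref, other = other)
}
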