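# Statistical core: Poisson likelihood over the five 30 bp bins of a
# 150 bp region, grouped into segments S1 = {bins 1,2}, S2 = {bin 3},
# S3 = {bins 4,5}. Each segment is either "background" (rate with a
# gamma prior fitted to the chromosome) or "enriched" (rate with a
# uniform prior on [0, lambda_max]). The eight background/enriched
# combinations define models M0..M7; M1 = (bg, en, bg) is the
# well-positioned-nucleosome profile.

MODEL_IDS <- paste0("M", 0:7)

# rows: model; columns: segment state (TRUE = enriched)
MODEL_STATES <- matrix(c(
  FALSE, FALSE, FALSE,  # M0 bg bg bg
  FALSE, TRUE,  FALSE,  # M1 bg en bg
  TRUE,  TRUE,  TRUE,   # M2 en en en
  TRUE,  FALSE, TRUE,   # M3 en bg en
  TRUE,  TRUE,  FALSE,  # M4 en en bg
  FALSE, TRUE,  TRUE,   # M5 bg en en
  TRUE,  FALSE, FALSE,  # M6 en bg bg
  FALSE, FALSE, TRUE    # M7 bg bg en
), nrow = 8, ncol = 3, byrow = TRUE,
  dimnames = list(MODEL_IDS, c("S1", "S2", "S3")))

#' Method-of-moments gamma hyperparameters for the background rate
#'
#' The background Poisson rate carries a Gamma(alpha, beta) prior whose
#' hyperparameters are fitted, chromosome by chromosome, to the marginal
#' (negative-binomial) distribution of the corrected bin counts: with
#' sample mean m and variance v, the moment equations `m = alpha/beta`
#' and `v = (alpha/beta) * (1 + 1/beta)` give `beta = m / (v - m)` and
#' `alpha = m * beta`. Because most of the genome shows little or no
#' positioning, these moments capture the background read distribution.
#'
#' @param counts Corrected bin counts of one chromosome (>= 2 bins).
#' @return List with `alpha`, `beta`.
#' @section Degenerate input: when the counts are not overdispersed
#'   (`v <= m`, impossible under the Poisson-gamma marginal) the moment
#'   equations have no solution; the fit falls back, with a warning, to
#'   the continuous limit of the estimator: as `v` decreases to `m`,
#'   `beta` diverges and the prior concentrates at `m`, so the fallback
#'   is a near-delta prior (`beta = 1e6`, `alpha = m * beta`), i.e. a
#'   plain Poisson background with rate `m`. An all-zero chromosome is
#'   an error.
#' @export
estimate_gamma_hyperparams <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 bins to estimate hyperparameters")
  m <- mean(counts)
  if (m == 0) stop("empty chromosome: all corrected counts are zero")
  v <- stats::var(counts)
  beta_cap <- 1e6
  if (v <= m || m / (v - m) > beta_cap) {
    if (v <= m) {
      warning("no overdispersion in bin counts (var <= mean); ",
              "using the concentrated-prior limit (plain Poisson background)")
    }
    return(list(alpha = m * beta_cap, beta = beta_cap))
  }
  beta <- m / (v - m)
  list(alpha = m * beta, beta = beta)
}

#' Log marginal likelihood of counts sharing one rate under a gamma prior
#'
#' Integrates the factorized Poisson likelihood of `counts` (all bins
#' sharing one rate lambda) against Gamma(alpha, beta). Conjugacy gives
#' the closed negative-binomial form
#' `sum(-log y_i!) + alpha*log(beta) - lgamma(alpha) + lgamma(alpha + S)
#'  - (alpha + S)*log(beta + n)` with `S = sum(y)`, `n = length(y)`.
#'
#' @param counts Non-negative integer vector (the bins of one segment).
#' @param alpha,beta Gamma shape and rate, both > 0.
#' @return Log marginal likelihood (scalar).
#' @export
log_marginal_gamma <- function(counts, alpha, beta) {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("invalid gamma hyperparameters")
  }
  S <- sum(counts)
  n <- length(counts)
  -sum(lfactorial(counts)) + lm_gamma_suff(S, n, alpha, beta)
}

# gamma-prior marginal minus the -sum(lfactorial(y)) term; vectorized over S
lm_gamma_suff <- function(S, n, alpha, beta) {
  alpha * log(beta) - lgamma(alpha) + lgamma(alpha + S) -
    (alpha + S) * log(beta + n)
}

#' Log marginal likelihood of counts sharing one rate under a uniform prior
#'
#' Integrates the shared-rate Poisson likelihood against
#' Uniform(0, lambda_max). Successive integration by parts expresses the
#' integral through the lower incomplete gamma function:
#' `-log(lambda_max) + sum(-log y_i!) - (S+1)*log(n)
#'  + log IncGamma_lower(S + 1, n * lambda_max)`,
#' evaluated in log space via `pgamma(..., log.p = TRUE)`.
#'
#' @param counts Non-negative integer vector.
#' @param lambda_max Upper bound of the uniform prior (> 0); per
#'   chromosome this is the maximum corrected bin count.
#' @return Log marginal likelihood (scalar).
#' @export
log_marginal_uniform <- function(counts, lambda_max) {
  stopifnot(length(counts) >= 1, all(counts >= 0))
  if (!is.finite(lambda_max) || lambda_max <= 0) stop("invalid lambda_max")
  S <- sum(counts)
  n <- length(counts)
  -sum(lfactorial(counts)) + lm_uniform_suff(S, n, lambda_max)
}

# uniform-prior marginal minus the factorial term; vectorized over S.
# log lower-incomplete-gamma(s, x) = lgamma(s) + pgamma(x, s, log.p = TRUE)
lm_uniform_suff <- function(S, n, lambda_max) {
  -log(lambda_max) - (S + 1) * log(n) + lgamma(S + 1) +
    stats::pgamma(n * lambda_max, shape = S + 1, log.p = TRUE)
}

#' Precompute the uniform-prior marginal for all segment sums
#'
#' The uniform-prior marginal depends on the data only through the
#' segment size n (1 for the centre bin, 2 for a flank) and the segment
#' sum S, apart from an additive `-sum(log y_i!)` term. Tabulating the
#' sufficient part once per chromosome avoids recomputing the incomplete
#' gamma function in every sliding window.
#'
#' @param lambda_max Uniform-prior upper bound.
#' @param max_total Largest tabulated segment sum.
#' @param max_bins Largest tabulated segment size (default 2).
#' @return Object of class `nf_uniform_table`; use [uniform_table_lookup()].
#' @export
precompute_uniform_table <- function(lambda_max, max_total, max_bins = 2L) {
  stopifnot(max_total >= 0, max_bins >= 1)
  S <- 0:max_total
  tab <- vapply(seq_len(max_bins),
                function(n) lm_uniform_suff(S, n, lambda_max),
                numeric(length(S)))
  structure(list(lambda_max = lambda_max, max_total = as.integer(max_total),
                 table = tab),  # [S + 1, n]
            class = "nf_uniform_table")
}

#' Look up tabulated uniform-prior marginals
#'
#' Returns the same sufficient value as [lm_uniform_suff] for vectors of
#' segment sums, falling back transparently to direct evaluation for
#' sums or sizes outside the table.
#'
#' @param tab An `nf_uniform_table`.
#' @param S Integer vector of segment sums.
#' @param n Segment size (scalar).
#' @return Numeric vector, `-sum(log y_i!)` term excluded.
#' @export
uniform_table_lookup <- function(tab, S, n) {
  out <- numeric(length(S))
  inside <- S <= tab$max_total & n <= ncol(tab$table)
  if (any(inside)) out[inside] <- tab$table[S[inside] + 1L, n]
  if (any(!inside)) out[!inside] <- lm_uniform_suff(S[!inside], n, tab$lambda_max)
  out
}

#' Evaluate the eight models on one 150 bp region
#'
#' Computes, for each model M0..M7, the log marginal likelihood as the
#' sum over the three segments of the segment marginal: a background
#' segment uses the gamma-prior marginal, an enriched segment the
#' uniform-prior marginal, each over its shared-rate bin group
#' ({y1,y2}, {y3}, {y4,y5}). The winner is the argmax; the score is the
#' log Bayes factor of M1 (positioned nucleosome) against M0
#' (all background).
#'
#' @param y Integer vector of 5 corrected bin counts.
#' @param hyper List with `alpha`, `beta` (background gamma prior).
#' @param lambda_max Uniform-prior upper bound (enriched state).
#' @return Object of class `nf_model_eval`: list with `log_marginals`
#'   (named, M0..M7), `winner`, `log_bayes_factor`, `winner_margin`
#'   (winning log marginal minus runner-up).
#' @export
evaluate_models <- function(y, hyper, lambda_max) {
  stopifnot(length(y) == 5, all(y >= 0))
  groups <- list(y[1:2], y[3], y[4:5])
  bg <- vapply(groups, log_marginal_gamma, numeric(1),
               alpha = hyper$alpha, beta = hyper$beta)
  en <- vapply(groups, log_marginal_uniform, numeric(1),
               lambda_max = lambda_max)
  lm <- vapply(seq_len(8L), function(k) {
    st <- MODEL_STATES[k, ]
    sum(ifelse(st, en, bg))
  }, numeric(1))
  names(lm) <- MODEL_IDS
  ord <- order(lm, decreasing = TRUE)
  structure(list(
    log_marginals = lm,
    winner = MODEL_IDS[ord[1L]],
    log_bayes_factor = unname(lm["M1"] - lm["M0"]),
    winner_margin = unname(lm[ord[1L]] - lm[ord[2L]])
  ), class = "nf_model_eval")
}

#' @export
print.nf_model_eval <- function(x, ...) {
  cat("Model evaluation of one 150 bp region\n")
  print(round(x$log_marginals, 4))
  cat("winner:", x$winner,
      " log BF(M1:M0):", format(x$log_bayes_factor, digits = 4), "\n")
  invisible(x)
}

#' Is a region a well-positioned nucleosome?
#'
#' True iff M1 (flanks background, centre enriched) attains the strictly
#' largest log marginal likelihood. Ties resolve to "not a nucleosome"
#' (conservative calling).
#'
#' @param evaluation An `nf_model_eval` from [evaluate_models()].
#' @return Logical scalar.
#' @export
is_nucleosome <- function(evaluation) {
  lm <- evaluation$log_marginals
  lm[["M1"]] > max(lm[setdiff(names(lm), "M1")])
}
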