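# Independent numerical oracle for the marginal likelihoods: adaptive
# quadrature of the raw integrand, rescaled by its mode so narrow
# posteriors do not starve the quadrature of mass.
quad_log_marginal <- function(y, log_prior, upper = Inf) {
  logf <- function(l) {
    vapply(l, function(li) {
      if (li <= 0) return(-Inf)
      sum(stats::dpois(y, li, log = TRUE)) + log_prior(li)
    }, numeric(1))
  }
  hi <- if (is.finite(upper)) upper else max(1, 3 * sum(y) + 50)
  opt <- stats::optimize(logf, c(1e-12, hi), maximum = TRUE)
  M <- opt$objective
  val <- stats::integrate(function(l) exp(logf(l) - M), 0, upper,
                          rel.tol = 1e-11, abs.tol = 0)$value
  M + log(val)
}

oracle_gamma <- function(y, alpha, beta) {
  quad_log_marginal(y, function(l) stats::dgamma(l, alpha, rate = beta, log = TRUE))
}

oracle_uniform <- function(y, lambda_max) {
  quad_log_marginal(y, function(l) -log(lambda_max), upper = lambda_max)
}

# Eight-model oracle built purely on the quadrature marginals
oracle_evaluate <- function(y, alpha, beta, lambda_max) {
  groups <- list(y[1:2], y[3], y[4:5])
  bg <- vapply(groups, oracle_gamma, numeric(1), alpha = alpha, beta = beta)
  en <- vapply(groups, oracle_uniform, numeric(1), lambda_max = lambda_max)
  states <- list(M0 = c(F, F, F), M1 = c(F, T, F), M2 = c(T, T, T),
                 M3 = c(T, F, T), M4 = c(T, T, F), M5 = c(F, T, T),
                 M6 = c(T, F, F), M7 = c(F, F, T))
  vapply(states, function(st) sum(ifelse(st, en, bg)), numeric(1))
}

# Minimal call table for a vector of call-centre midpoints
calls_from_centers <- function(centers, chrom = "chrT", bf = 1) {
  data.table::data.table(
    chrom = chrom,
    start = as.integer(centers) - 75L,
    end = as.integer(centers) + 75L,
    center_start = as.integer(centers) - 15L,
    center_end = as.integer(centers) + 15L,
    log_bayes_factor = bf,
    winner_margin = bf)
}

write_temp_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}
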