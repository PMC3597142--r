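test_that("gamma-prior marginal matches elementary closed forms", {
  # single zero count, alpha = beta = 1: int e^-l e^-l dl = 1/2
  expect_equal(log_marginal_gamma(0L, 1, 1), log(0.5), tolerance = 1e-12)
  # two zero counts: int e^-2l e^-l dl = 1/3
  expect_equal(log_marginal_gamma(c(0L, 0L), 1, 1), log(1 / 3), tolerance = 1e-12)
})

test_that("uniform-prior marginal matches elementary closed forms", {
  # single zero count, Uniform(0,1): int_0^1 e^-l dl = 1 - e^-1
  expect_equal(log_marginal_uniform(0L, 1), log(1 - exp(-1)), tolerance = 1e-12)
  # growing lambda_max dilutes the prior mass: marginal -> 0
  vals <- vapply(c(10, 1e3, 1e6), function(lm) log_marginal_uniform(3L, lm),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("both marginals agree with adaptive quadrature on random segments", {
  set.seed(23)
  for (i in 1:40) {
    y <- sample(0:50, sample(1:2, 1), replace = TRUE)
    a <- runif(1, 0.2, 5); b <- runif(1, 0.1, 3); lmax <- runif(1, 1, 60)
    eg <- oracle_gamma(y, a, b)
    eu <- oracle_uniform(y, lmax)
    expect_equal(log_marginal_gamma(y, a, b), eg, tolerance = 1e-8)
    expect_equal(log_marginal_uniform(y, lmax), eu, tolerance = 1e-8)
  }
})

test_that("method of moments solves the marginal moment equations", {
  # sample mean 2 and variance 4 solve to beta = 1, alpha = 2
  counts <- c(0, 0, 2, 4, 4)
  expect_equal(mean(counts), 2)
  expect_equal(var(counts), 4)
  h <- estimate_gamma_hyperparams(counts)
  expect_equal(h$beta, 1)
  expect_equal(h$alpha, 2)
})

test_that("hyperparameter recovery from the Poisson-gamma marginal", {
  set.seed(11)
  # NB with size = alpha, prob = beta/(1+beta) is the Poisson-gamma marginal
  counts <- rnbinom(1e5, size = 2, prob = 1 / 2)
  h <- estimate_gamma_hyperparams(counts)
  expect_lt(abs(h$alpha - 2) / 2, 0.05)
  expect_lt(abs(h$beta - 1) / 1, 0.05)
})

test_that("degenerate tracks fall back to the concentrated-prior limit", {
  expect_warning(h <- estimate_gamma_hyperparams(rep(3L, 10)), "overdispersion")
  expect_equal(h$alpha / h$beta, 3)      # prior mean equals the sample mean
  expect_gt(h$beta, 1e5)                 # near-delta prior
  expect_error(estimate_gamma_hyperparams(integer(10)), "empty chromosome")
  expect_error(estimate_gamma_hyperparams(3L), "at least 2")
})

test_that("uniform-marginal table lookups are bit-identical to direct calls", {
  tab <- precompute_uniform_table(lambda_max = 21, max_total = 60)
  for (n in 1:2) {
    S <- c(0L, 1L, 7L, 60L)
    direct <- vapply(S, function(s) nucleofinder:::lm_uniform_suff(s, n, 21),
                     numeric(1))
    expect_identical(uniform_table_lookup(tab, S, n), direct)
  }
  # consistency with the public marginal: add back the factorial term
  expect_identical(uniform_table_lookup(tab, 0L, 1L),
                   log_marginal_uniform(0L, 21))
  # outside the table: transparent direct evaluation
  expect_equal(uniform_table_lookup(tab, 100L, 2L),
               nucleofinder:::lm_uniform_suff(100L, 2L, 21))
})

test_that("model selection matches the quadrature oracle on canonical regions", {
  h <- list(alpha = 1, beta = 1)
  cases <- list(
    list(y = c(0, 0, 20, 0, 0), lmax = 20),
    list(y = c(20, 20, 20, 20, 20), lmax = 20),
    list(y = c(0, 0, 0, 0, 0), lmax = 10),
    list(y = c(9, 7, 2, 8, 10), lmax = 15))
  for (cs in cases) {
    ev <- evaluate_models(cs$y, h, cs$lmax)
    orc <- oracle_evaluate(cs$y, 1, 1, cs$lmax)
    expect_equal(ev$log_marginals, orc, tolerance = 1e-8)
    expect_equal(ev$winner, names(which.max(orc)))
    expect_equal(ev$log_bayes_factor, unname(orc["M1"] - orc["M0"]),
                 tolerance = 1e-8)
  }
})

test_that("a central spike is a nucleosome; flat or empty regions are not", {
  h <- list(alpha = 1, beta = 1)
  spike <- evaluate_models(c(0, 0, 20, 0, 0), h, 20)
  expect_equal(spike$winner, "M1")
  expect_true(is_nucleosome(spike))
  flat <- evaluate_models(c(20, 20, 20, 20, 20), h, 20)
  expect_false(is_nucleosome(flat))
  zero <- evaluate_models(c(0, 0, 0, 0, 0), h, 10)
  expect_equal(zero$winner, "M0")
  expect_lt(zero$log_bayes_factor, 0)
})

test_that("ties never count as nucleosomes", {
  tie <- structure(list(log_marginals = c(M0 = -1, M1 = -1, M2 = -5, M3 = -5,
                                          M4 = -5, M5 = -5, M6 = -5, M7 = -5),
                        winner = "M0", log_bayes_factor = 0,
                        winner_margin = 0),
                   class = "nf_model_eval")
  expect_false(is_nucleosome(tie))
})

test_that("within-segment bin swaps leave all marginals unchanged", {
  h <- list(alpha = 0.8, beta = 0.3)
  set.seed(3)
  for (i in 1:10) {
    y <- sample(0:25, 5, replace = TRUE)
    base <- evaluate_models(y, h, 30)$log_marginals
    expect_equal(evaluate_models(y[c(2, 1, 3, 4, 5)], h, 30)$log_marginals, base)
    expect_equal(evaluate_models(y[c(1, 2, 3, 5, 4)], h, 30)$log_marginals, base)
  }
})

test_that("region reversal swaps M4 with M5 and M6 with M7", {
  h <- list(alpha = 0.8, beta = 0.3)
  set.seed(4)
  for (i in 1:10) {
    y <- sample(0:25, 5, replace = TRUE)
    fwd <- evaluate_models(y, h, 30)$log_marginals
    rev <- evaluate_models(y[5:1], h, 30)$log_marginals
    expect_equal(rev[["M4"]], fwd[["M5"]])
    expect_equal(rev[["M5"]], fwd[["M4"]])
    expect_equal(rev[["M6"]], fwd[["M7"]])
    expect_equal(rev[["M7"]], fwd[["M6"]])
    for (m in c("M0", "M1", "M2", "M3")) expect_equal(rev[[m]], fwd[[m]])
  }
})

test_that("the Bayes factor is non-decreasing in the centre count", {
  # on the model's domain every bin count is bounded by lambda_max
  # (the chromosome maximum), so monotonicity is asserted up to it
  h <- list(alpha = 1.5, beta = 0.7)
  bf <- vapply(0:100, function(y3) {
    evaluate_models(c(0, 0, y3, 0, 0), h, 100)$log_bayes_factor
  }, numeric(1))
  expect_true(all(diff(bf) >= 0))
})
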