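test_that("analytic three-subject fixture gives beta = log(sqrt(2))", {
  sv <- data.frame(sample = c("a", "b", "c"), time = c(1, 2, 3),
                   event = c(1, 1, 1))
  fit <- fit_cox_univariate(c(0, 1, 0), sv)
  expect_equal(fit$beta, log(sqrt(2)), tolerance = 1e-6)
  expect_equal(fit$hr, sqrt(2), tolerance = 1e-6)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
})

test_that("symmetric two-group data give beta near 0 and p near 1", {
  sv <- data.frame(sample = letters[1:4], time = c(1, 1, 2, 2),
                   event = rep(1, 4))
  fit <- fit_cox_univariate(c(0, 1, 0, 1), sv)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$wald_p, 1, tolerance = 1e-6)
})

test_that("Newton-Raphson agrees with a 1-D partial-likelihood search", {
  set.seed(515)
  for (i in 1:20) {
    n <- 30
    x <- rnorm(n)
    time <- rexp(n, exp(0.4 * x))
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) next
    sv <- data.frame(sample = paste0("s", 1:n), time = time, event = event)
    for (ties in c("efron", "breslow")) {
      fit <- fit_cox_univariate(x, sv, ties = ties)
      expect_equal(fit$beta, grid_cox_beta(time, event, x, ties = ties),
                   tolerance = 1e-6)
      # oracle: the fitted beta maximises the hand-written partial likelihood
      ll <- partial_loglik(fit$beta, time, event, x, ties)
      expect_gte(ll, partial_loglik(fit$beta + 0.01, time, event, x, ties))
      expect_gte(ll, partial_loglik(fit$beta - 0.01, time, event, x, ties))
    }
  }
})

test_that("Efron and Breslow coincide when event times are unique", {
  set.seed(16)
  n <- 40
  x <- rnorm(n)
  sv <- data.frame(sample = paste0("s", 1:n), time = rexp(n),
                   event = rbinom(n, 1, 0.7))
  fe <- fit_cox_univariate(x, sv, ties = "efron")
  fb <- fit_cox_univariate(x, sv, ties = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
  expect_equal(fe$se, fb$se, tolerance = 1e-10)
})

test_that("beta and se are scale-equivariant, the p-value scale-invariant", {
  set.seed(17)
  n <- 60
  x <- rnorm(n)
  sv <- data.frame(sample = paste0("s", 1:n), time = rexp(n, exp(0.5 * x)),
                   event = rbinom(n, 1, 0.8))
  f1 <- fit_cox_univariate(x, sv)
  f2 <- fit_cox_univariate(3.7 * x, sv)
  expect_equal(f2$beta, f1$beta / 3.7, tolerance = 1e-8)
  expect_equal(f2$se, f1$se / 3.7, tolerance = 1e-8)
  expect_equal(f2$wald_p, f1$wald_p, tolerance = 1e-8)
})

test_that("large-sample fit recovers a true hazard ratio of 2", {
  set.seed(18)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  sv <- data.frame(sample = paste0("s", 1:n), time = rexp(n, 0.1 * 2^x),
                   event = rep(1, n))
  fit <- fit_cox_univariate(x, sv)
  expect_lt(abs(fit$beta - log(2)), 3 * fit$se)
})

test_that("degenerate inputs are rejected", {
  sv <- data.frame(sample = c("a", "b", "c"), time = 1:3, event = c(0, 0, 0))
  expect_error(fit_cox_univariate(c(0, 1, 0), sv), "2 events")
  sv$event <- c(1, 1, 1)
  expect_error(fit_cox_univariate(c(1, 1, 1), sv), "constant")
})

test_that("screen_gene_sets labels a planted risk set and enforces contracts", {
  set.seed(19)
  sim <- generate_bulk(n_samples = 150, n_genes = 400,
                       sets = make_gene_sets(400, n_sets = 6, set_size = 20),
                       effects = c(SET01 = 1.2), censor_rate = 0.25,
                       seed = 19)
  enr <- score_all(sim$expression, make_gene_sets(400, n_sets = 6,
                                                  set_size = 20))
  res <- screen_gene_sets(enr, sim$survival)
  expect_identical(res$set, rownames(enr$nes))
  expect_identical(res$direction[res$set == "SET01"], "risk")
  expect_equal(res$hr, exp(res$beta), tolerance = 1e-12)
  retained <- res$direction != "dropped"
  expect_true(all(res$wald_p[retained] < 0.05))

  expect_error(screen_gene_sets(enr, sim$survival, p_threshold = 0,
                                require_retained = TRUE),
               "no gene set passed")
  expect_error(screen_gene_sets(enr, sim$survival[1:5, ]), "shared")
})
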