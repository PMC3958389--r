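# Mixture likelihood and EM estimation.

test_that("mixture log-likelihood matches brute-force enumeration", {
  set.seed(21)
  y <- c(9.8, 11.2, 10.4)
  direction <- c("F", "Fprime", "F")
  P <- matrix(runif(12), 3, 4)
  P <- P / rowSums(P)
  beta <- c(mu = 10, c = 0.5, a = 1, d = 0.4, i = 0.2, ica = 0.3)
  ll <- mixture_loglik(y, P, direction, beta, sigma2 = 1.3)
  expect_equal(ll, oracle_mixture_loglik(y, P, direction, beta, 1.3),
               tolerance = 1e-10)
})

test_that("mixture log-likelihood is translation invariant and errors on bad sigma2", {
  set.seed(22)
  y <- rnorm(10, 10)
  P <- matrix(1 / 4, 10, 4)
  direction <- rep(c("F", "Fprime"), 5)
  beta <- c(mu = 10, a = 0.5)
  ll1 <- mixture_loglik(y, P, direction, beta, 1)
  ll2 <- mixture_loglik(y + 3, P, direction, c(mu = 13, a = 0.5), 1)
  expect_equal(ll1, ll2, tolerance = 1e-10)
  # degenerate posterior at the component mean: plain normal density
  expect_equal(
    mixture_loglik(12.6, matrix(c(1, 0, 0, 0), 1), "Fprime",
                   c(mu = 10, c = 1, a = 1, ica = 0.6), 2),
    dnorm(0, sd = sqrt(2), log = TRUE))
  expect_error(mixture_loglik(y, P, direction, beta, 0), "positive")
})

test_that("EM with degenerate posteriors reproduces ordinary least squares", {
  dat <- make_degenerate_f2()
  fit <- em_fit(dat$y, dat$P, dat$direction)
  ols <- lm.fit(dat$X, dat$y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-10)
  expect_equal(fit$sigma2, mean(ols$residuals^2), tolerance = 1e-10)
  expect_true(fit$converged)
  # responsibilities stay degenerate
  expect_equal(fit$posterior_weights, dat$P, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the all-effects-zero constraint gives the intercept-only MLE", {
  dat <- make_degenerate_f2()
  fit <- em_fit(dat$y, dat$P, dat$direction,
                constraint = c("c", "a", "d", "i", "ica", "icd", "ici"))
  expect_equal(fit$beta[["mu"]], mean(dat$y), tolerance = 1e-10)
  expect_equal(fit$sigma2, mean((dat$y - mean(dat$y))^2), tolerance = 1e-10)
})

test_that("EM log-likelihood ascends and the compiled loop matches the R loop", {
  scen <- table_scenarios("table2", n = 200, h2 = 0.25)
  pop <- simulate_population(scen, seed = 5)
  grid <- posteriors_at_grid(pop$cross, pop$map, step = 50)
  P <- grid$posterior[[2]]
  fit <- em_fit(pop$cross$phenotype, P, pop$cross$direction)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_equal(fit$loglik,
               mixture_loglik(pop$cross$phenotype, P, pop$cross$direction,
                              fit$beta, fit$sigma2),
               tolerance = 1e-8)
  rfit <- cnimap:::em_core_r(pop$cross$phenotype, P,
                             cnimap:::build_design_blocks(pop$cross$direction),
                             1:8)
  expect_equal(fit$beta, rfit$beta, tolerance = 1e-6)
  expect_equal(fit$loglik, rfit$loglik, tolerance = 1e-6)
  # responsibilities are proper distributions
  expect_equal(rowSums(fit$posterior_weights), rep(1, 200), tolerance = 1e-9)
})

test_that("estimates are equivariant under phenotype scaling", {
  scen <- table_scenarios("table2", n = 200, h2 = 0.25)
  pop <- simulate_population(scen, seed = 9)
  grid <- posteriors_at_grid(pop$cross, pop$map, step = 50)
  P <- grid$posterior[[2]]
  f1 <- em_fit(pop$cross$phenotype, P, pop$cross$direction)
  f2 <- em_fit(3 * pop$cross$phenotype, P, pop$cross$direction)
  expect_equal(f2$beta, 3 * f1$beta, tolerance = 1e-5)
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-5)
})

test_that("confounded designs raise an informative rank error", {
  dat <- make_degenerate_f2()
  one_dir <- rep("F", length(dat$y))   # cytoplasm column = -intercept
  expect_error(em_fit(dat$y, dat$P, one_dir), "confounded|singular")
  expect_error(em_fit(dat$y[1:5], dat$P[1:5, ], dat$direction[1:5]),
               "fewer individuals")
  expect_error(em_fit(dat$y, dat$P, dat$direction, constraint = "mu"),
               "cannot constrain")
})

test_that("likelihood-ratio bookkeeping: nesting, zero and LOD conversion", {
  dat <- make_degenerate_f2()
  full <- em_fit(dat$y, dat$P, dat$direction)
  null <- em_fit(dat$y, dat$P, dat$direction, constraint = c("c", "ica"))
  expect_gte(lr_statistic(full, null), 0)
  expect_equal(lr_statistic(full, full), 0)
  expect_equal(lr_statistic(full, null),
               2 * (full$loglik - null$loglik), tolerance = 1e-9)
  expect_error(lr_statistic(null, full), "not nested")
  expect_equal(lr_to_lod(2 * log(10)), 1)
  expect_equal(lr_to_lod(4.605170185988091), 1, tolerance = 1e-12)
})

test_that("tidy and glance summarise fits in model order", {
  dat <- make_degenerate_f2()
  fit <- em_fit(dat$y, dat$P, dat$direction, constraint = "ici")
  td <- tidy(fit)
  expect_equal(td$term, c("mu", "c", "a", "d", "i", "ica", "icd", "ici"))
  expect_true(td$constrained[td$term == "ici"])
  expect_equal(td$estimate[td$term == "ici"], 0)
  # F2 fits flag the imprinting terms as sign-unidentified
  expect_equal(td$estimable, !td$term %in% c("i", "ici"))
  gl <- glance(fit)
  expect_equal(gl$n, length(dat$y))
  expect_true(gl$converged)
})
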