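# Monte Carlo simulator of reciprocal crosses.

test_that("the same seed reproduces a population exactly", {
  scen <- table_scenarios("table2", n = 100, h2 = 0.25)
  p1 <- simulate_population(scen, seed = 123)
  p2 <- simulate_population(scen, seed = 123)
  expect_identical(p1$cross, p2$cross)
  expect_identical(p1$truth$qtl_genotype, p2$truth$qtl_genotype)
  p3 <- simulate_population(scen, seed = 124)
  expect_false(identical(p1$cross$phenotype, p3$cross$phenotype))
})

test_that("noiseless simulation yields exact genotypic class means", {
  beta <- c(mu = 10, c = 1, a = 1, d = 0.8, ica = 0.6, icd = 0.5)
  scen <- sim_scenario(n = 200, beta = beta, sigma2 = 0)
  pop <- simulate_population(scen, seed = 2)
  mm <- genotypic_means(beta, "F2")
  key <- paste(mm$direction, mm$genotype)
  expected <- mm$mean[match(paste(pop$cross$direction,
                                  pop$truth$qtl_genotype), key)]
  expect_equal(pop$cross$phenotype, expected)
})

test_that("ordered QTL genotypes segregate 1:1:1:1 within each direction", {
  scen <- table_scenarios("table2", n = 40000, h2 = 0.4)
  pop <- simulate_population(scen, seed = 77)
  for (d in c("F", "Fprime")) {
    tab <- table(pop$truth$qtl_genotype[pop$cross$direction == d])
    expect_equal(sort(names(tab)), c("AmAf", "AmBf", "BmAf", "BmBf"))
    expect_gt(chisq.test(tab)$p.value, 1e-4)
  }
})

test_that("gamete switch frequencies follow the sex-specific Haldane fractions", {
  set.seed(55)
  n <- 50000
  pos <- c(0, 20)
  fem <- cnimap:::simulate_gametes(n, pos, "female", lambda = 1.25)
  mal <- cnimap:::simulate_gametes(n, pos, "male", lambda = 1.25)
  r_f <- haldane_r(sex_split(20, 1.25)$female)
  r_m <- haldane_r(sex_split(20, 1.25)$male)
  emp_f <- mean(fem[, 1] != fem[, 2])
  emp_m <- mean(mal[, 1] != mal[, 2])
  se <- sqrt(r_f * (1 - r_f) / n)
  expect_lt(abs(emp_f - r_f), 3 * se)
  expect_lt(abs(emp_m - r_m), 3 * se)
  expect_gt(emp_f, emp_m)  # lambda > 1: females recombine more
  # zero-length interval: complete linkage
  g <- cnimap:::simulate_gametes(200, c(5, 5), "female", 1.25)
  expect_true(all(g[, 1] == g[, 2]))
})

test_that("heritability calibration matches the enumerated genetic variance", {
  beta <- effect_vector(c(c = 1, a = 1, d = 0.8, ica = 0.6, icd = 0.5))
  mm <- genotypic_means(beta, "F2")$mean
  var_g <- mean((mm - mean(mm))^2)
  expect_equal(heritability_to_sigma2(beta, 0.5), var_g)
  expect_equal(heritability_to_sigma2(beta, 0.4), var_g * 0.6 / 0.4)
  expect_error(heritability_to_sigma2(c(mu = 10), 0.4), "zero genetic variance")
  expect_error(heritability_to_sigma2(beta, 1.2), "in \\(0, 1\\)")
})

test_that("phenotypic variance decomposes into genetic plus residual variance", {
  scen <- table_scenarios("table3", n = 50000, h2 = 0.4,
                          effect = "cytoplasmic", gamma = 0.05)
  pop <- simulate_population(scen, seed = 6)
  mm <- genotypic_means(scen$beta, "F2")$mean
  var_g <- mean((mm - mean(mm))^2)
  total <- var_g + scen$sigma2
  emp <- var(pop$cross$phenotype)
  expect_lt(abs(emp - total) / total, 0.03)
  # the preset hits the requested broad-sense heritability
  expect_equal(var_g / total, 0.4, tolerance = 1e-12)
})

test_that("study presets carry the published truths", {
  s2 <- table_scenarios("table2", n = 800, h2 = 0.4)
  expect_equal(s2$sigma2, 1.26)
  expect_equal(s2$qtl_position, 48)
  expect_equal(s2$n_markers, 6L)
  expect_equal(unname(s2$beta),
               c(10, 1, 1, 0.8, 0, 0.6, 0.5, 0))
  expect_equal(table_scenarios("table2", h2 = 0.1)$sigma2, 3.81)
  expect_equal(table_scenarios("table2", h2 = 0.25)$sigma2, 2.04)

  t3c <- table_scenarios("table3", n = 800, h2 = 0.4,
                         effect = "cytoplasmic", gamma = 0.05)
  expect_equal(t3c$beta[["c"]], 0.461)
  expect_equal(unname(t3c$beta[c("a", "d", "i", "ica", "icd", "ici")]),
               rep(0.8, 6))
  t3i <- table_scenarios("table3", n = 800, h2 = 0.4,
                         effect = "imprinting", gamma = 0.10)
  expect_equal(t3i$beta[["i"]], 1.020)
  # null scenarios set the varied effect exactly to zero
  expect_equal(table_scenarios("table3", effect = "cytoplasmic",
                               gamma = 0)$beta[["c"]], 0)
  expect_equal(table_scenarios("table3", effect = "imprinting",
                               gamma = 0)$beta[["i"]], 0)
  expect_error(table_scenarios("table3", gamma = 0.2), "gamma")
  expect_error(table_scenarios("table2", h2 = 0.3), "h2")
})

test_that("backcross populations segregate the two genotypes of each type", {
  beta <- effect_vector(c(mu = 5, c = 0.5, a = 1, d = 0.5, i = 0.4,
                          ica = 0.2, icd = 0.2, ici = 0.1))
  scen <- sim_scenario(n = 400, beta = beta, sigma2 = 0.5, design = "BC")
  pop <- simulate_population(scen, seed = 12)
  for (bc in c("BC1", "BC2", "BC3", "BC4")) {
    g <- unique(pop$truth$qtl_genotype[pop$cross$direction == bc])
    expect_setequal(g, backcross_genotypes(bc))
  }
  # marker codes consistent with the recurrent father
  m1 <- pop$cross$M1[pop$cross$direction == "BC1"]
  expect_true(all(m1 %in% c("AA", "AB")))
  m1b <- pop$cross$M1[pop$cross$direction == "BC4"]
  expect_true(all(m1b %in% c("AB", "BB")))
})

test_that("scenario validation enforces its invariants", {
  beta <- c(mu = 10, a = 1)
  expect_error(sim_scenario(100, beta), "exactly one")
  expect_error(sim_scenario(100, beta, sigma2 = 1, h2 = 0.4), "exactly one")
  expect_error(sim_scenario(100, beta, sigma2 = 1, qtl_position = 150),
               "linkage group")
  s <- sim_scenario(100, beta, h2 = 0.4)
  expect_equal(s$sigma2, heritability_to_sigma2(effect_vector(beta), 0.4))
})
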