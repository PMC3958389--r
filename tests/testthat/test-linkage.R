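# Map arithmetic and marker-conditional QTL genotype posteriors.

test_that("Haldane map function behaves at its limits and is additive", {
  expect_equal(haldane_r(0), 0)
  expect_lt(abs(haldane_r(1e6) - 0.5), 1e-12)
  expect_error(haldane_r(-1), "nonnegative")
  # two-interval composition: r13 = r12 + r23 - 2 r12 r23
  for (d in list(c(5, 10), c(20, 33), c(0.5, 80))) {
    r1 <- haldane_r(d[1]); r2 <- haldane_r(d[2])
    expect_equal(haldane_r(sum(d)), r1 + r2 - 2 * r1 * r2, tolerance = 1e-12)
  }
})

test_that("sex_split preserves the average and the female:male ratio", {
  sp <- sex_split(20, 1.25)
  expect_equal(sp$female, 200 / 9)
  expect_equal(sp$male, 160 / 9)
  expect_equal(sex_split(13, 1), list(female = 13, male = 13))
  set.seed(4)
  for (k in 1:10) {
    d <- runif(1, 0, 80); lam <- runif(1, 0.5, 2)
    sp <- sex_split(d, lam)
    expect_equal((sp$female + sp$male) / 2, d)
    expect_equal(sp$female / sp$male, lam)
  }
  expect_error(sex_split(10, 0), "positive")
})

test_that("three-point gamete rule gives the closed-form conditionals", {
  expect_equal(gamete_allele_prob("A", "A", 0, 0), 1)
  expect_equal(gamete_allele_prob("A", "B", 0.1, 0.1), 0.5)
  expect_equal(gamete_allele_prob("A", "A", 0.08, 0.12),
               0.8096 / 0.8192, tolerance = 1e-12)
  expect_equal(gamete_allele_prob("B", "B", 0.08, 0.12),
               0.08 * 0.12 / 0.8192, tolerance = 1e-12)
  expect_error(gamete_allele_prob("A", "B", 0, 0), "impossible")
})

test_that("posteriors are proper distributions and match exhaustive enumeration", {
  codes <- c("AA", "AB", "BB", NA)
  cases <- expand.grid(left = codes, right = codes,
                       d1 = c(2, 8), lambda = c(1, 1.25, 1.6),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    p <- qtl_genotype_posterior(cs$left, cs$right, cs$d1, 20 - cs$d1,
                                lambda = cs$lambda)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    o <- oracle_posterior(cs$left, cs$right, cs$d1, 20 - cs$d1, cs$lambda)
    expect_equal(p, o, tolerance = 1e-10,
                 info = paste(cs$left, cs$right, cs$d1, cs$lambda))
  }
})

test_that("tight linkage to homozygous flanks pins the posterior", {
  p <- qtl_genotype_posterior("AA", "AA", 0.01, 0.01, lambda = 1.25)
  expect_gt(p["AmAf"], 1 - 1e-3)
  expect_lt(max(p[-1]), 1e-3)
})

test_that("reciprocal heterozygotes are equiprobable only when the sexes are exchangeable", {
  # lambda = 1: equal for every flank pattern
  for (fl in list(c("AB", "AB"), c("AB", "AA"), c("AA", "AB"))) {
    p1 <- qtl_genotype_posterior(fl[1], fl[2], 5, 15, lambda = 1)
    expect_equal(p1[["AmBf"]], p1[["BmAf"]], tolerance = 1e-12)
  }
  # lambda = 1.25 separates them when the flank information is asymmetric
  p2 <- qtl_genotype_posterior("AB", "AA", 5, 15, lambda = 1.25)
  expect_gt(abs(p2[["AmBf"]] - p2[["BmAf"]]), 0.01)
  # double-heterozygote flanks stay symmetric by allele complementation
  p3 <- qtl_genotype_posterior("AB", "AB", 5, 15, lambda = 1.25)
  expect_equal(p3[["AmBf"]], p3[["BmAf"]], tolerance = 1e-12)
})

test_that("the scan grid covers first to last marker at the requested step", {
  map <- tibble::tibble(chromosome = "1", marker = paste0("M", 1:6),
                        position_cM = seq(0, 100, 20))
  cross <- tibble::tibble(direction = c("F", "Fprime"),
                          M1 = c("AA", "AB"), M2 = c("AA", "AB"),
                          M3 = c("AA", "BB"), M4 = c("AA", "AB"),
                          M5 = c("AA", "AB"), M6 = c("AA", "AB"))
  grid <- posteriors_at_grid(cross, map, step = 2)
  expect_equal(nrow(grid), 51L)
  expect_equal(grid$position_cM, seq(0, 100, 2))
  for (k in seq_len(nrow(grid))) {
    expect_equal(rowSums(grid$posterior[[k]]), rep(1, 2), tolerance = 1e-12)
  }
  # at a fully informative homozygous marker the posterior is degenerate
  at40 <- grid$posterior[[which(grid$position_cM == 40)]]
  expect_equal(at40[1, ], c(AmAf = 1, AmBf = 0, BmAf = 0, BmBf = 0))
  at40b <- at40[2, ]
  expect_equal(at40b[["BmBf"]], 1)
})

test_that("backcross posteriors use the maternal gamete only", {
  # BC1: father is P1, so marker code AB means the maternal allele is B
  map <- tibble::tibble(chromosome = "1", marker = c("M1", "M2"),
                        position_cM = c(0, 20))
  cross <- tibble::tibble(direction = rep("BC1", 2),
                          M1 = c("AA", "AB"), M2 = c("AA", "AB"))
  grid <- posteriors_at_grid(cross, map, step = 10)
  mid <- grid$posterior[[2]]
  expect_equal(sum(mid[, c("AmBf", "BmBf")]), 0)  # paternal allele fixed A
  expect_gt(mid[1, "AmAf"], 0.95)
  expect_gt(mid[2, "BmAf"], 0.95)
  # the non-recombinant class probability matches the female-map fraction
  rf <- haldane_r(sex_split(10, 1.25)$female)
  expect_equal(unname(mid[1, "AmAf"]),
               (1 - rf)^2 / ((1 - rf)^2 + rf^2), tolerance = 1e-12)
})

test_that("map validation rejects malformed maps", {
  bad <- tibble::tibble(chromosome = "1", marker = c("M1", "M2"),
                        position_cM = c(10, 5))
  cross <- tibble::tibble(direction = "F", M1 = "AA", M2 = "AA")
  expect_error(posteriors_at_grid(cross, bad, step = 2),
               "strictly increasing")
  expect_error(posteriors_at_grid(cross, bad[0, ], step = 2), "empty|columns")
})
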