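# Independent oracles used across test files.

# Exhaustive-enumeration oracle for the F2 QTL-genotype posterior on a
# two-marker interval: enumerates every ordered three-locus haplotype
# (left marker, QTL, right marker) of the maternal gamete (female
# recombination fractions) and the paternal gamete (male fractions),
# conditions exactly on the observed unordered marker codes, and
# marginalises to the four ordered QTL genotypes.
oracle_posterior <- function(left_code, right_code, d_left, d_right, lambda) {
  hap_prob <- function(h, r1, r2) {
    0.5 * (if (h[1] == h[2]) 1 - r1 else r1) *
      (if (h[2] == h[3]) 1 - r2 else r2)
  }
  sp1 <- sex_split(d_left, lambda)
  sp2 <- sex_split(d_right, lambda)
  haps <- expand.grid(l = c("A", "B"), q = c("A", "B"), r = c("A", "B"),
                      stringsAsFactors = FALSE)
  code_of <- function(x, y) paste(sort(c(x, y)), collapse = "")
  matches <- function(code, obs) is.na(obs) || code == obs
  post <- setNames(numeric(4),
                   c("AmAf", "AmBf", "BmAf", "BmBf"))
  for (im in seq_len(nrow(haps))) {
    hm <- unlist(haps[im, ])
    pm <- hap_prob(hm, haldane_r(sp1$female), haldane_r(sp2$female))
    for (ip in seq_len(nrow(haps))) {
      hp <- unlist(haps[ip, ])
      pp <- hap_prob(hp, haldane_r(sp1$male), haldane_r(sp2$male))
      if (!matches(code_of(hm[1], hp[1]), left_code)) next
      if (!matches(code_of(hm[3], hp[3]), right_code)) next
      g <- paste0(hm[2], "m", hp[2], "f")
      post[g] <- post[g] + pm * pp
    }
  }
  post / sum(post)
}

# Brute-force mixture log-likelihood: sums the joint density over all
# genotype assignments (4^n terms), then logs.
oracle_mixture_loglik <- function(y, P, direction, beta, sigma2) {
  n <- length(y)
  gtys <- c("AmAf", "AmBf", "BmAf", "BmBf")
  assignments <- expand.grid(rep(list(1:4), n))
  total <- 0
  for (k in seq_len(nrow(assignments))) {
    j <- as.integer(assignments[k, ])
    term <- 1
    for (i in seq_len(n)) {
      row <- f2_design_row(direction[i], gtys[j[i]])
      term <- term * P[i, j[i]] *
        dnorm(y[i], sum(row * effect_vector(beta)), sqrt(sigma2))
    }
    total <- total + term
  }
  log(total)
}

# A small deterministic F2 population with degenerate genotype knowledge
# (used for the OLS-oracle checks).
make_degenerate_f2 <- function(n = 60, beta = c(mu = 10, c = 1, a = 1, d = 0.5,
                                                ica = 0.3, icd = 0.2),
                               sigma2 = 0.5, seed = 7) {
  set.seed(seed)
  gtys <- c("AmAf", "AmBf", "BmAf", "BmBf")
  direction <- rep(c("F", "Fprime"), each = n / 2)
  # cycle genotypes so every (direction, genotype) class is represented
  genotype <- rep(gtys, length.out = n)
  X <- t(mapply(f2_design_row, direction, genotype))
  y <- as.numeric(X %*% effect_vector(beta)) + rnorm(n, 0, sqrt(sigma2))
  P <- matrix(0, n, 4)
  P[cbind(seq_len(n), match(genotype, gtys))] <- 1
  list(y = y, P = P, direction = direction, X = X)
}
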