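## Four-component Gaussian mixture with design-constrained means, maximised
## by EM.  Components are the four ordered QTL genotypes; an individual's
## mixture proportions are its marker-conditional genotype posteriors, and
## its component means are design rows (direction x genotype) times the
## effect vector.  Backcross individuals simply carry zero proportions on
## the two genotypes that do not segregate in their cross.

## internal: per-direction 4 x 8 design-row matrices for the directions
## present, plus the stacked matrix and class index per individual.
build_design_blocks <- function(direction) {
  lv <- sort(unique(as.character(direction)))
  X <- lapply(lv, function(d) {
    t(vapply(GENOTYPES, function(g) design_row_impl(d, g), numeric(8L)))
  })
  names(X) <- lv
  Xall <- do.call(rbind, X)                      # (4 * L) x 8
  cls <- factor(as.character(direction), levels = lv)
  ## 0/1 class-indicator matrix: crossprod(G, W) aggregates weights by class
  G <- matrix(0, length(cls), length(lv))
  G[cbind(seq_along(cls), as.integer(cls))] <- 1
  list(levels = lv, X = X, Xall = Xall, cls = cls, G = G)
}

#' Log-likelihood of the genotype-mixture model
#'
#' Evaluates the observed-data log-likelihood
#' `sum_i log sum_j pi_ij Normal(y_i; x_ij' beta, sigma2)` where `pi_ij`
#' are the marker-conditional posteriors over the four ordered QTL
#' genotypes and `x_ij` the design row of genotype `j` in individual `i`'s
#' cross direction.
#'
#' @param y Numeric phenotype vector.
#' @param posteriors n x 4 matrix of mixture proportions (rows sum to 1).
#' @param direction Character vector of cross directions per individual.
#' @param beta Effect vector (see [effect_vector()]).
#' @param sigma2 Residual variance, `> 0`.
#' @return Log-likelihood in nats.
#' @export
mixture_loglik <- function(y, posteriors, direction, beta, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  beta <- effect_vector(beta)
  blk <- build_design_blocks(direction)
  mu <- matrix(blk$Xall %*% beta, ncol = 4L, byrow = TRUE)  # L x 4
  M <- mu[as.integer(blk$cls), , drop = FALSE]              # n x 4
  dens <- posteriors * stats::dnorm(y, M, sqrt(sigma2))
  sum(log(rowSums(dens)))
}

## internal EM core shared by em_fit and the scan.  The iteration loop is
## compiled (src/em_core.cpp); em_core_r below is the reference R
## implementation, kept for cross-checking and for the descriptive error
## on singular normal equations.
em_core <- function(y, P, blk, free, tol = 1e-8, max_iter = 500L,
                    init = NULL) {
  fit <- .em_core_cpp(y, P, blk$Xall, as.integer(blk$cls) - 1L,
                      as.integer(free), tol, as.integer(max_iter),
                      !is.null(init),
                      if (is.null(init)) numeric(8L) else effect_vector(init$beta),
                      if (is.null(init)) 0 else init$sigma2)
  if (isTRUE(fit$singular)) {
    ## refit in R purely to raise the error naming the confounded effects
    return(em_core_r(y, P, blk, free, tol, max_iter, init))
  }
  list(beta = stats::setNames(as.numeric(fit$beta), EFFECTS),
       sigma2 = fit$sigma2, loglik = fit$loglik, n_iter = fit$n_iter,
       converged = fit$converged, weights = fit$weights,
       loglik_trace = as.numeric(fit$loglik_trace))
}

## reference R implementation of the same iteration (used in tests as a
## consistency check of the compiled loop)
em_core_r <- function(y, P, blk, free, tol = 1e-8, max_iter = 500L,
                      init = NULL) {
  n <- length(y)
  Xall <- blk$Xall
  Xf <- Xall[, free, drop = FALSE]
  icls <- as.integer(blk$cls)
  G <- blk$G
  y2 <- y^2

  mstep <- function(W) {
    Wy <- W * y
    avec <- as.vector(t(crossprod(G, W)))      # sum of weights, Xall row order
    bvec <- as.vector(t(crossprod(G, Wy)))     # sum of w * y
    XtWX <- crossprod(Xf, avec * Xf)
    XtWy <- crossprod(Xf, bvec)
    beta_f <- tryCatch(solve(XtWX, XtWy), error = function(e) {
      bad <- confounded_effects(XtWX)
      stop("weighted normal equations are singular; confounded effects: ",
           paste(bad, collapse = ", "), call. = FALSE)
    })
    beta <- numeric(8L)
    beta[free] <- beta_f
    muv <- as.vector(Xall %*% beta)            # length 4L
    cvec <- as.vector(t(crossprod(G, W * y2)))
    sigma2 <- sum(cvec - 2 * muv * bvec + muv^2 * avec) / n
    list(beta = beta, sigma2 = sigma2, mu = muv)
  }

  estep <- function(beta, sigma2, muv = NULL) {
    if (is.null(muv)) muv <- as.vector(Xall %*% beta)
    mu <- matrix(muv, ncol = 4L, byrow = TRUE)
    M <- mu[icls, , drop = FALSE]
    dens <- P * exp((y * M - 0.5 * M^2 - 0.5 * y2) / sigma2)
    rs <- rowSums(dens)
    list(ll = sum(log(rs)) - 0.5 * n * log(2 * pi * sigma2), W = dens / rs)
  }

  ## deterministic initialisation: weighted least squares with the prior
  ## mixture proportions as weights
  if (is.null(init)) {
    ms <- mstep(P)
    beta <- ms$beta
    sigma2 <- max(ms$sigma2, 1e-12)
    muv <- ms$mu
  } else {
    beta <- effect_vector(init$beta)
    sigma2 <- init$sigma2
    muv <- NULL
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  es <- estep(beta, sigma2, muv)
  ll <- es$ll
  ll_trace <- ll
  repeat {
    iter <- iter + 1L
    ms <- mstep(es$W)
    beta <- ms$beta
    sigma2 <- max(ms$sigma2, 1e-12)
    es <- estep(beta, sigma2, ms$mu)
    ll_new <- es$ll
    ll_trace <- c(ll_trace, ll_new)
    if (is.finite(ll_new) && ll_new - ll < tol) {
      converged <- ll_new - ll > -1e-6  # tiny decreases = numerical noise
      ll <- ll_new
      break
    }
    ll <- ll_new
    if (iter >= max_iter) break
  }

  list(beta = stats::setNames(beta, EFFECTS), sigma2 = sigma2, loglik = ll,
       n_iter = iter, converged = converged, weights = es$W,
       loglik_trace = ll_trace)
}

confounded_effects <- function(XtWX) {
  q <- qr(XtWX)
  if (q$rank == ncol(XtWX)) return(character(0))
  colnames(XtWX)[q$pivot[seq.int(q$rank + 1L, ncol(XtWX))]]
}

#' Fit the genotype-mixture model by EM
#'
#' Maximum-likelihood estimation of the effect vector and residual variance
#' under the four-component Gaussian mixture with design-constrained means.
#' The E-step computes responsibilities proportional to
#' `pi_ij * Normal(y_i; x_ij' beta, sigma2)`; the M-step solves the
#' responsibility-weighted least-squares problem for the free effects
#' (columns named in `constraint` are held at zero) and updates the common
#' residual variance.  The observed-data log-likelihood is nondecreasing
#' across iterations.
#'
#' Under the F2 design the imprinting effect and the
#' cytoplasm-by-imprinting interaction are fitted (they parameterise the
#' reciprocal-heterozygote mean split used by the hypothesis tests) but
#' their sign is only weakly identified through the sex difference in
#' recombination; they are flagged as sign-unidentified in tidied output.
#'
#' @param y Numeric phenotype vector.
#' @param posteriors n x 4 matrix of prior mixture proportions over the
#'   ordered genotypes (e.g. from [posteriors_at_grid()]).
#' @param direction Character vector of cross directions per individual.
#' @param constraint Character vector of effects constrained to zero, a
#'   subset of `c("c","a","d","i","ica","icd","ici")` (the overall mean is
#'   never constrained).
#' @param tol Absolute log-likelihood increment below which EM stops.
#' @param max_iter Maximum EM iterations; non-convergence is flagged, not
#'   an error.
#' @param init Optional list with `beta` and `sigma2` starting values; by
#'   default a deterministic weighted-least-squares initialisation with the
#'   prior proportions as weights is used.
#' @return An object of class `cnimap_fit`: a list with elements `beta`
#'   (named length-8 vector; constrained entries exactly 0), `sigma2`,
#'   `loglik`, `n_iter`, `converged`, `constraint`, `posterior_weights`
#'   (n x 4 responsibilities), `loglik_trace`, `family` (`"F2"`, `"BC"` or
#'   `"mixed"`) and `n`.
#' @export
em_fit <- function(y, posteriors, direction, constraint = character(0),
                   tol = 1e-8, max_iter = 500L, init = NULL) {
  y <- as.numeric(y)
  posteriors <- as.matrix(posteriors)
  stopifnot(nrow(posteriors) == length(y), ncol(posteriors) == 4L)
  bad <- setdiff(constraint, EFFECTS[-1])
  if (length(bad) > 0) {
    stop("cannot constrain: ", paste(bad, collapse = ", "),
         " (only the seven effects other than mu may be zeroed)",
         call. = FALSE)
  }
  free <- which(!EFFECTS %in% constraint)
  if (length(y) < length(free) + 1L) {
    stop("fewer individuals than free parameters", call. = FALSE)
  }
  blk <- build_design_blocks(direction)
  fit <- em_core(y, posteriors, blk, free, tol = tol, max_iter = max_iter,
                 init = init)
  fam <- direction_family(direction)
  structure(
    c(fit[c("beta", "sigma2", "loglik", "n_iter", "converged")],
      list(constraint = sort(constraint),
           posterior_weights = fit$weights,
           loglik_trace = fit$loglik_trace,
           family = fam, n = length(y))),
    class = "cnimap_fit"
  )
}

direction_family <- function(direction) {
  u <- unique(as.character(direction))
  f2 <- u %in% F2_DIRECTIONS
  if (all(f2)) "F2" else if (!any(f2)) "BC" else "mixed"
}

#' @export
print.cnimap_fit <- function(x, ...) {
  cat("Genotype-mixture model fit (", x$family, " design)\n", sep = "")
  cat("  n =", x$n, " loglik =", format(x$loglik, digits = 8),
      " sigma2 =", format(x$sigma2, digits = 5), "\n")
  if (length(x$constraint)) {
    cat("  constrained to zero:", paste(x$constraint, collapse = ", "), "\n")
  }
  cat("  EM iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Likelihood-ratio statistic between two nested mixture fits
#'
#' `LR = 2 (loglik_full - loglik_null)`, clipped at zero (tiny negative
#' values can arise from finite EM convergence tolerance).  The null fit's
#' constraint set must contain the full fit's.
#'
#' @param full,null `cnimap_fit` objects from [em_fit()].
#' @return Nonnegative LR statistic.  Divide by `2 * log(10)` for a LOD
#'   score, see [lr_to_lod()].
#' @export
lr_statistic <- function(full, null) {
  stopifnot(inherits(full, "cnimap_fit"), inherits(null, "cnimap_fit"))
  if (!all(full$constraint %in% null$constraint)) {
    stop("models are not nested: the null constraint set must contain the full one",
         call. = FALSE)
  }
  max(0, 2 * (full$loglik - null$loglik))
}

#' Convert a likelihood-ratio statistic to a LOD score
#'
#' @param lr Nonnegative LR statistic(s).
#' @return `lr / (2 * log(10))`.
#' @export
lr_to_lod <- function(lr) lr / (2 * log(10))
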