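## Genome-wide grid scan, LOD profile, permutation thresholds and the
## four-test battery at a detected QTL.

## Closed-form fit of the no-QTL null y = mu + c * m + e.  The cytoplasmic
## effect is estimable without any QTL (it is carried by the cross
## direction), so the scan null retains it; with a single direction in the
## data it degenerates to the intercept-only model.
null_fit_cyto <- function(y, direction) {
  m <- cytoplasm_indicator(direction)
  X <- if (length(unique(m)) > 1L) cbind(mu = 1, c = m) else cbind(mu = rep(1, length(y)))
  cf <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% cf
  sigma2 <- sum(res^2) / length(y)
  beta <- stats::setNames(numeric(8L), EFFECTS)
  beta[rownames(cf)] <- cf
  list(beta = beta, sigma2 = sigma2,
       loglik = sum(stats::dnorm(y, X %*% cf, sqrt(sigma2), log = TRUE)))
}

## Precompute everything about a scan that does not depend on the
## phenotype: the posterior grid, design blocks and class index.  Reused
## across permutations.
prepare_scan <- function(cross, map, step = 2, lambda = 1.25) {
  validate_map(map)
  direction <- as.character(cross$direction)
  geno <- genotype_matrix(cross, map)
  chroms <- unique(map$chromosome)
  grids <- list()
  for (ch in chroms) {
    m <- map[map$chromosome == ch, , drop = FALSE]
    g_ch <- geno[, m$marker, drop = FALSE]
    if (all(is.na(g_ch))) {
      warning("chromosome ", ch, " has no genotype data; skipped",
              call. = FALSE)
      next
    }
    pos <- scan_grid(m$position_cM, step)
    grids[[as.character(ch)]] <- list(
      chromosome = ch,
      positions = pos,
      posteriors = lapply(pos, function(p) {
        posteriors_at_position(g_ch, m$position_cM, p, direction, lambda)
      })
    )
  }
  if (length(grids) == 0) stop("no chromosome with genotype data", call. = FALSE)
  list(grids = grids, direction = direction,
       blk = build_design_blocks(direction), step = step, lambda = lambda)
}

## Fit the full model at every grid position (warm-started along each
## chromosome) and return the profile plus per-position estimates.  In a
## pure F2 population the scan fits the estimable parameterisation: the
## imprinting effect and its cytoplasm interaction only split the two
## reciprocal-heterozygote means, a split the F2 design cannot sign, so
## they are held at zero along the profile (as they are reported in this
## design); backcross scans fit all eight effects.
scan_core <- function(y, prep, tol = 1e-8, max_iter = 500L,
                      effects = c("estimable", "all")) {
  effects <- match.arg(effects)
  null <- null_fit_cyto(y, prep$direction)
  free <- if (effects == "estimable" &&
              direction_family(prep$direction) == "F2") {
    which(!EFFECTS %in% c("i", "ici"))
  } else {
    seq_len(8L)
  }
  rows <- list()
  for (gr in prep$grids) {
    init <- NULL
    for (k in seq_along(gr$positions)) {
      fit <- em_core(y, gr$posteriors[[k]], prep$blk, free,
                     tol = tol, max_iter = max_iter, init = init)
      init <- list(beta = fit$beta, sigma2 = fit$sigma2)
      rows[[length(rows) + 1L]] <- c(
        list(chromosome = gr$chromosome, position_cM = gr$positions[k],
             lr = max(0, 2 * (fit$loglik - null$loglik)),
             loglik = fit$loglik, sigma2 = fit$sigma2,
             n_iter = fit$n_iter, converged = fit$converged),
        as.list(fit$beta)
      )
    }
  }
  list(profile = dplyr::bind_rows(rows), null = null)
}

#' Genome scan for cyto-nuclear imprinting QTL
#'
#' Scans each linkage group on a cM grid.  At every position the full
#' eight-parameter mixture model is fitted by EM against the
#' marker-conditional genotype posteriors, and compared by likelihood ratio
#' with the no-QTL null `y = mu + c m + e` (fitted once in closed form).
#' The position of the profile maximum (leftmost in case of ties) is the
#' maximum-likelihood estimate of the QTL location.
#'
#' @param cross Data frame with columns `id` (optional), `direction`,
#'   `phenotype`, and one column per marker (codes `"AA"`, `"AB"`, `"BB"`,
#'   `NA`).
#' @param map Data frame with columns `chromosome`, `marker`,
#'   `position_cM`.
#' @param step Grid increment in cM.
#' @param lambda Female:male map-expansion ratio.
#' @param phenotype Name of the phenotype column.
#' @param tol,max_iter EM convergence controls, see [em_fit()].
#' @param effects `"estimable"` (default) fits the F2 scan in the
#'   estimable parameterisation, holding the sign-unidentified imprinting
#'   terms at zero along the profile; `"all"` frees all eight effects.
#'   Backcross scans always fit all eight.
#' @return A `cnimap_scan` object: a tibble with columns `chromosome`,
#'   `position_cM`, `lr`, `lod`, `sigma2`, the eight effect estimates and
#'   convergence diagnostics, with the null fit, peak and scan settings in
#'   attributes.  Use [scan_peak()], [generics::tidy()] or
#'   [ggplot2::autoplot()] on it.
#' @export
genome_scan <- function(cross, map, step = 2, lambda = 1.25,
                        phenotype = "phenotype", tol = 1e-8,
                        max_iter = 500L,
                        effects = c("estimable", "all")) {
  y <- as.numeric(cross[[phenotype]])
  if (anyNA(y)) stop("phenotype contains missing values", call. = FALSE)
  prep <- prepare_scan(cross, map, step, lambda)
  sc <- scan_core(y, prep, tol = tol, max_iter = max_iter, effects = effects)
  out <- sc$profile
  out$lod <- lr_to_lod(out$lr)
  out <- dplyr::relocate(out, "lod", .after = "lr")
  peak <- out[which.max(out$lr), c("chromosome", "position_cM", "lr", "lod")]
  structure(out,
            class = c("cnimap_scan", class(out)),
            null = sc$null, peak = peak, step = step, lambda = lambda,
            family = direction_family(prep$direction))
}

#' Peak of a genome scan
#'
#' @param scan A `cnimap_scan` object.
#' @return One-row tibble with `chromosome`, `position_cM`, `lr`, `lod` at
#'   the profile maximum (leftmost position on ties).
#' @export
scan_peak <- function(scan) {
  stopifnot(inherits(scan, "cnimap_scan"))
  attr(scan, "peak")
}

#' @export
print.cnimap_scan <- function(x, ...) {
  pk <- attr(x, "peak")
  cat("Genome scan (", attr(x, "family"), " design), step ",
      attr(x, "step"), " cM, lambda ", attr(x, "lambda"), "\n", sep = "")
  cat("  peak: chromosome ", as.character(pk$chromosome), " at ",
      pk$position_cM, " cM, LR = ", format(pk$lr, digits = 5),
      ", LOD = ", format(pk$lod, digits = 4), "\n", sep = "")
  NextMethod()
}

#' Permutation threshold for the genome-wide scan statistic
#'
#' Recomputes the genome scan on permuted phenotypes and records the
#' genome-wide maximum LR of each permutation; the threshold at level
#' `alpha` is the empirical `(1 - alpha)` quantile of those maxima.  By
#' default phenotypes are permuted within cross-direction strata, which
#' preserves the cytoplasmic structure under the no-QTL null.
#'
#' @inheritParams genome_scan
#' @param n_perm Number of permutations (values below 100 trigger a
#'   warning but are honoured).
#' @param alpha Genome-wide significance level.
#' @param seed Optional integer seed; permutations are reproducible given
#'   the seed.
#' @param stratified Permute within cross-direction strata (default) or
#'   freely.
#' @return A `cnimap_perm` object: list with `threshold`, `alpha`,
#'   `null_max_stats` (LR scale), `n_perm`, `seed`, `stratified`.
#' @export
permutation_threshold <- function(cross, map, n_perm = 1000, alpha = 0.05,
                                  step = 2, lambda = 1.25,
                                  phenotype = "phenotype", seed = NULL,
                                  stratified = TRUE, tol = 1e-8,
                                  max_iter = 500L) {
  if (n_perm < 100) {
    warning("n_perm < 100 gives a coarse threshold estimate", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(cross[[phenotype]])
  prep <- prepare_scan(cross, map, step, lambda)
  strata <- if (stratified) as.character(cross$direction) else rep("all", length(y))
  idx <- split(seq_along(y), strata)
  maxlr <- vapply(seq_len(n_perm), function(p) {
    yp <- y
    for (s in idx) yp[s] <- y[sample(s)]
    sc <- scan_core(yp, prep, tol = tol, max_iter = max_iter)
    max(sc$profile$lr)
  }, numeric(1L))
  structure(
    list(threshold = unname(stats::quantile(maxlr, 1 - alpha, type = 1)),
         alpha = alpha, null_max_stats = maxlr, n_perm = n_perm,
         seed = seed, stratified = stratified),
    class = "cnimap_perm"
  )
}

#' @export
print.cnimap_perm <- function(x, ...) {
  cat("Permutation threshold:", format(x$threshold, digits = 5),
      "(LR scale; LOD", format(lr_to_lod(x$threshold), digits = 4), ")\n")
  cat("  ", x$n_perm, " permutations, alpha = ", x$alpha,
      if (x$stratified) ", stratified by direction" else "", "\n", sep = "")
  invisible(x)
}

BATTERY_CONSTRAINTS <- function(imprinting = c("single", "joint")) {
  imprinting <- match.arg(imprinting)
  list(
    cytoplasmic = "c",
    imprinting = if (imprinting == "single") "i" else c("i", "ici"),
    interaction = c("ica", "icd", "ici"),
    adddom = c("a", "d")
  )
}

#' Hypothesis-test battery at a QTL position
#'
#' At a fixed genome position, fits the full model and four nested nulls
#' and reports the likelihood-ratio tests: (1) cytoplasmic effect
#' (`c = 0`, 1 df), (2) imprinting (`i = 0`, 1 df by default; set
#' `imprinting = "joint"` to also zero the cytoplasm-by-imprinting
#' interaction, 2 df), (3) all cyto-nuclear interactions
#' (`ica = icd = ici = 0`, 3 df), (4) additive and dominance
#' (`a = d = 0`, 2 df).  P-values come from the chi-square reference with
#' degrees of freedom equal to the number of zeroed effects; when `n_perm`
#' is given, position-fixed permutation p-values are added.
#'
#' @inheritParams genome_scan
#' @param position Genome position (cM) to test, inside the map of
#'   `chromosome`.
#' @param chromosome Chromosome of `position`; defaults to the only one in
#'   the map.
#' @param imprinting `"single"` (`i = 0`) or `"joint"` (`i = ici = 0`).
#' @param n_perm Optional number of phenotype permutations for empirical
#'   p-values.
#' @param seed Optional seed for the permutations.
#' @param stratified Permute within cross-direction strata; default
#'   `FALSE` (full exchange enforces the complete null of each sub-test).
#' @return A `cnimap_battery` tibble with columns `test`, `constraint`,
#'   `df`, `lr`, `p_chisq` (and `p_perm` when permutations are requested)
#'   and the full fit in attribute `fit`.
#' @export
test_battery <- function(cross, map, position, chromosome = NULL,
                         lambda = 1.25, phenotype = "phenotype",
                         imprinting = c("single", "joint"), n_perm = NULL,
                         seed = NULL, stratified = FALSE, tol = 1e-8,
                         max_iter = 500L) {
  validate_map(map)
  imprinting <- match.arg(imprinting)
  if (is.null(chromosome)) {
    chroms <- unique(map$chromosome)
    if (length(chroms) > 1L) {
      stop("specify `chromosome` when the map has several", call. = FALSE)
    }
    chromosome <- chroms
  }
  m <- map[map$chromosome == chromosome, , drop = FALSE]
  if (position < min(m$position_cM) - 1e-8 ||
      position > max(m$position_cM) + 1e-8) {
    stop("position is outside the marker map of chromosome ", chromosome,
         call. = FALSE)
  }
  y <- as.numeric(cross[[phenotype]])
  direction <- as.character(cross$direction)
  geno <- genotype_matrix(cross, map)[, m$marker, drop = FALSE]
  P <- posteriors_at_position(geno, m$position_cM, position, direction, lambda)
  constraints <- BATTERY_CONSTRAINTS(imprinting)

  fit_all <- function(yy, init_full = NULL) {
    full <- em_fit(yy, P, direction, tol = tol, max_iter = max_iter,
                   init = init_full)
    lrs <- vapply(constraints, function(cs) {
      null <- em_fit(yy, P, direction, constraint = cs, tol = tol,
                     max_iter = max_iter)
      lr_statistic(full, null)
    }, numeric(1L))
    list(full = full, lrs = lrs)
  }

  obs <- fit_all(y)
  df <- lengths(constraints)
  out <- tibble::tibble(
    test = names(constraints),
    constraint = vapply(constraints, paste, "", collapse = ","),
    df = unname(df),
    lr = unname(obs$lrs),
    p_chisq = stats::pchisq(unname(obs$lrs), df = unname(df),
                            lower.tail = FALSE)
  )

  if (!is.null(n_perm)) {
    if (!is.null(seed)) set.seed(seed)
    strata <- if (stratified) direction else rep("all", length(y))
    idx <- split(seq_along(y), strata)
    exceed <- numeric(length(constraints))
    for (p in seq_len(n_perm)) {
      yp <- y
      for (s in idx) yp[s] <- y[sample(s)]
      perm <- fit_all(yp)
      exceed <- exceed + (perm$lrs >= obs$lrs - 1e-12)
    }
    out$p_perm <- (1 + exceed) / (1 + n_perm)
  }

  structure(out, class = c("cnimap_battery", class(out)), fit = obs$full,
            position = position, chromosome = chromosome,
            converged = obs$full$converged)
}
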