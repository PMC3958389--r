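## Seeded Monte Carlo simulator of reciprocal F2 and backcross populations
## under sex-specific recombination, with scenario presets matching the
## package's simulation study.

#' Build a simulation scenario
#'
#' Describes a reciprocal-cross population to simulate: one linkage group
#' of equidistant markers, one QTL, an effect vector, and a residual
#' variance given either directly or through a broad-sense heritability.
#'
#' @param n Number of offspring.
#' @param beta True effect vector (see [effect_vector()]).
#' @param sigma2 Residual variance (trait units squared); give exactly one
#'   of `sigma2` and `h2`.
#' @param h2 Broad-sense heritability in (0, 1); converted to `sigma2` via
#'   [heritability_to_sigma2()].
#' @param map_length Length of the linkage group in cM.
#' @param n_markers Number of equidistant markers spanning the group.
#' @param qtl_position QTL position in cM from the first marker.
#' @param lambda Female:male map-expansion ratio.
#' @param design `"F2"` (offspring split between the two reciprocal
#'   directions) or `"BC"` (split between the four backcross types).
#' @param direction_split For F2, the fraction of offspring from direction
#'   `"F"` (P1 maternal cytoplasm).
#' @return A `cnimap_scenario` list.
#' @export
sim_scenario <- function(n, beta, sigma2 = NULL, h2 = NULL,
                         map_length = 100, n_markers = 6, qtl_position = 48,
                         lambda = 1.25, design = c("F2", "BC"),
                         direction_split = 0.5) {
  design <- match.arg(design)
  beta <- effect_vector(beta)
  if (is.null(sigma2) == is.null(h2)) {
    stop("give exactly one of sigma2 and h2", call. = FALSE)
  }
  if (!is.null(h2)) sigma2 <- heritability_to_sigma2(beta, h2, design)
  if (sigma2 < 0) stop("sigma2 must be nonnegative", call. = FALSE)
  if (qtl_position < 0 || qtl_position > map_length) {
    stop("qtl_position must lie on the linkage group", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), beta = beta, sigma2 = sigma2,
         map_length = map_length, n_markers = as.integer(n_markers),
         qtl_position = qtl_position, lambda = lambda, design = design,
         direction_split = direction_split, h2 = h2),
    class = "cnimap_scenario"
  )
}

#' Residual variance implied by a broad-sense heritability
#'
#' The genetic variance is taken as the variance of the eight genotypic
#' class means under equal class probabilities (balanced directions,
#' Mendelian segregation), and the residual variance solves
#' `h2 = var_g / (var_g + sigma2)`.
#'
#' @param beta True effect vector.
#' @param h2 Broad-sense heritability, in (0, 1).
#' @param design `"F2"` or `"BC"`.
#' @return Residual variance `sigma2 = var_g (1 - h2) / h2`.
#' @export
heritability_to_sigma2 <- function(beta, h2, design = c("F2", "BC")) {
  design <- match.arg(design)
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 >= 1) {
    stop("h2 must be a single value in (0, 1)", call. = FALSE)
  }
  mm <- genotypic_means(beta, design)$mean
  var_g <- mean((mm - mean(mm))^2)
  if (var_g == 0) {
    stop("all genotypic means are equal (zero genetic variance); ",
         "the residual variance is undefined at any h2", call. = FALSE)
  }
  var_g * (1 - h2) / h2
}

#' Scenario presets of the package's simulation study
#'
#' Two families of presets. `"table2"` is the parameter-recovery study: a
#' 100 cM group with 6 equidistant markers, QTL at 48 cM, true effects
#' `mu = 10`, `c = 1`, `a = 1`, `d = 0.8`, interactions `ica = 0.6`,
#' `icd = 0.5`, imprinting terms 0, and residual variance 3.81, 2.04 or
#' 1.26 at nominal heritability 0.1, 0.25 or 0.4.  `"table3"` is the
#' test-power study: all effects fixed at 0.8 except the varied one — the
#' cytoplasmic effect takes 0, 0.461 or 0.679 and the imprinting effect 0,
#' 0.680 or 1.020 as its variance share `gamma` is 0, 5 or 10% — with the
#' residual variance set from the heritability via
#' [heritability_to_sigma2()].
#'
#' @param name `"table2"` or `"table3"`.
#' @param n Number of offspring (the study used 400 and 800).
#' @param h2 Heritability level: one of 0.1, 0.25, 0.4.
#' @param effect For `"table3"`: which effect is varied, `"cytoplasmic"`
#'   or `"imprinting"`.
#' @param gamma For `"table3"`: variance share of the varied effect, one
#'   of 0, 0.05, 0.10 (0 gives the null scenario used for test size).
#' @return A `cnimap_scenario`.
#' @examples
#' table_scenarios("table2", n = 800, h2 = 0.4)
#' table_scenarios("table3", n = 800, h2 = 0.4, effect = "cytoplasmic", gamma = 0)
#' @export
table_scenarios <- function(name = c("table2", "table3"), n = 800, h2 = 0.4,
                            effect = c("cytoplasmic", "imprinting"),
                            gamma = 0) {
  name <- match.arg(name)
  h2_levels <- c(`0.1` = 0.1, `0.25` = 0.25, `0.4` = 0.4)
  if (!any(abs(h2 - h2_levels) < 1e-12)) {
    stop("h2 must be one of 0.1, 0.25, 0.4", call. = FALSE)
  }
  if (name == "table2") {
    sigma2 <- c(3.81, 2.04, 1.26)[which(abs(h2 - h2_levels) < 1e-12)]
    beta <- effect_vector(c(mu = 10, c = 1, a = 1, d = 0.8,
                            ica = 0.6, icd = 0.5))
    sim_scenario(n = n, beta = beta, sigma2 = sigma2)
  } else {
    effect <- match.arg(effect)
    glev <- c(0, 0.05, 0.10)
    k <- which(abs(gamma - glev) < 1e-12)
    if (length(k) == 0) stop("gamma must be one of 0, 0.05, 0.10", call. = FALSE)
    beta <- effect_vector(c(mu = 10, c = 0.8, a = 0.8, d = 0.8, i = 0.8,
                            ica = 0.8, icd = 0.8, ici = 0.8))
    if (effect == "cytoplasmic") {
      beta["c"] <- c(0, 0.461, 0.679)[k]
    } else {
      beta["i"] <- c(0, 0.680, 1.020)[k]
    }
    sim_scenario(n = n, beta = beta, h2 = h2)
  }
}

#' @export
print.cnimap_scenario <- function(x, ...) {
  cat("Simulation scenario (", x$design, "): n = ", x$n, ", ",
      x$n_markers, " markers over ", x$map_length, " cM, QTL at ",
      x$qtl_position, " cM, lambda = ", x$lambda, "\n", sep = "")
  cat("  sigma2 =", format(x$sigma2, digits = 5),
      if (!is.null(x$h2)) paste0("(h2 = ", x$h2, ")"), "\n")
  print(round(x$beta, 4))
  invisible(x)
}

## n gametes from F1 parents of the given sex over ordered loci: first
## allele uniform, successive loci switch with the sex-specific Haldane
## fraction of each interval.  Returns an n x L 0/1 matrix (0 = A, 1 = B).
simulate_gametes <- function(n, positions, sex = c("female", "male"),
                             lambda = 1.25) {
  sex <- match.arg(sex)
  L <- length(positions)
  d <- diff(positions)
  r <- haldane_r(sex_split(d, lambda)[[sex]])
  al <- matrix(0L, n, L)
  al[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (k in seq_along(r)) {
    sw <- stats::rbinom(n, 1L, r[k])
    al[, k + 1L] <- (al[, k] + sw) %% 2L
  }
  al
}

#' Simulate one F1 gamete
#'
#' A single meiotic product of an F1 parent (heterozygous at every locus
#' in coupling phase): the allele at the first locus is uniform on
#' `{A, B}` and successive loci switch with the sex-specific Haldane
#' recombination fraction of each interval (Markov crossovers, no
#' interference).
#'
#' @param positions Ordered locus positions in cM (sex-averaged map).
#' @param sex `"female"` or `"male"`: the sex of the transmitting parent.
#' @param lambda Female:male map-expansion ratio.
#' @return Character vector of alleles (`"A"`/`"B"`), one per locus.
#' @export
simulate_gamete <- function(positions, sex = c("female", "male"),
                            lambda = 1.25) {
  c("A", "B")[simulate_gametes(1L, positions, sex, lambda)[1L, ] + 1L]
}

#' Simulate a reciprocal-cross population
#'
#' Draws a population under `scenario`: each offspring receives one
#' maternal gamete (female recombination fractions) and one paternal
#' gamete — from the F1 father under male fractions in the F2 design, or
#' the constant recurrent-line allele in a backcross — at the markers and
#' the QTL jointly, so marker and QTL states are consistent with the
#' generating gametes.  Phenotypes are the genotypic class mean (design
#' row times the true effect vector) plus Gaussian noise.
#'
#' @param scenario A `cnimap_scenario`, e.g. from [table_scenarios()].
#' @param seed Optional integer seed; the same seed reproduces the
#'   population exactly.
#' @return A `cnimap_pop` list with elements `cross` (tibble: `id`,
#'   `direction`, `phenotype`, one column per marker with unordered codes
#'   `"AA"/"AB"/"BB"`), `map` (tibble: `chromosome`, `marker`,
#'   `position_cM`) and `truth` (true QTL genotypes, position, effects,
#'   residual variance, seed).
#' @export
simulate_population <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "cnimap_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n
  mk_pos <- seq(0, scenario$map_length, length.out = scenario$n_markers)
  loci <- sort(unique(c(mk_pos, scenario$qtl_position)))
  qtl_idx <- match(scenario$qtl_position, loci)
  mk_idx <- match(mk_pos, loci)

  if (scenario$design == "F2") {
    n_F <- round(n * scenario$direction_split)
    direction <- rep(c("F", "Fprime"), times = c(n_F, n - n_F))
    mat <- simulate_gametes(n, loci, "female", scenario$lambda)
    pat <- simulate_gametes(n, loci, "male", scenario$lambda)
  } else {
    direction <- rep(BC_TYPES, length.out = n)
    direction <- direction[order(direction)]
    mat <- simulate_gametes(n, loci, "female", scenario$lambda)
    ## recurrent father: P1 (allele A = 0) for BC1/BC2, P2 (B = 1) otherwise
    pat <- matrix(rep(ifelse(direction %in% c("BC1", "BC2"), 0L, 1L),
                      length(loci)), n, length(loci))
  }

  qtl_geno <- GENOTYPES[2L * mat[, qtl_idx] + pat[, qtl_idx] + 1L]
  means_tbl <- genotypic_means(scenario$beta,
                               if (scenario$design == "F2") "F2" else "BC")
  key <- paste(means_tbl$direction, means_tbl$genotype)
  mu_i <- means_tbl$mean[match(paste(direction, qtl_geno), key)]
  phenotype <- mu_i + stats::rnorm(n, 0, sqrt(scenario$sigma2))

  codes <- c("AA", "AB", "BB")
  geno <- matrix(codes[mat[, mk_idx, drop = FALSE] +
                         pat[, mk_idx, drop = FALSE] + 1L],
                 n, length(mk_idx))
  marker_names <- sprintf("M%d", seq_along(mk_pos))
  colnames(geno) <- marker_names

  cross <- tibble::tibble(
    id = sprintf("ind%04d", seq_len(n)),
    direction = direction,
    phenotype = phenotype
  )
  cross <- dplyr::bind_cols(cross, tibble::as_tibble(geno))
  map <- tibble::tibble(chromosome = "1", marker = marker_names,
                        position_cM = mk_pos)
  structure(
    list(cross = cross, map = map,
         truth = list(qtl_genotype = qtl_geno,
                      qtl_position = scenario$qtl_position,
                      beta = scenario$beta, sigma2 = scenario$sigma2,
                      scenario = scenario, seed = seed)),
    class = "cnimap_pop"
  )
}

#' @export
print.cnimap_pop <- function(x, ...) {
  cat("Simulated population: n =", nrow(x$cross), "(",
      paste(names(table(x$cross$direction)), table(x$cross$direction),
            collapse = ", "), ")\n")
  cat("  QTL at", x$truth$qtl_position, "cM; sigma2 =",
      format(x$truth$sigma2, digits = 5), "\n")
  invisible(x)
}
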