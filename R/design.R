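#' @keywords internal
#' @useDynLib cnimap, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Canonical orderings used throughout the package.  The four ordered QTL
## genotypes list the maternally inherited allele first; the two reciprocal
## heterozygotes AmBf and BmAf are distinct states.
GENOTYPES <- c("AmAf", "AmBf", "BmAf", "BmBf")

## Effect names in model order: overall mean, cytoplasmic effect, additive,
## dominance, imprinting, and the cytoplasm-by-{additive,dominance,imprinting}
## interactions.
EFFECTS <- c("mu", "c", "a", "d", "i", "ica", "icd", "ici")

F2_DIRECTIONS <- c("F", "Fprime")
BC_TYPES <- c("BC1", "BC2", "BC3", "BC4")
DIRECTIONS <- c(F2_DIRECTIONS, BC_TYPES)

## Indicator coding of the nuclear terms for the four ordered genotypes
## (rows AmAf, AmBf, BmAf, BmBf): x_a additive, x_d dominance, x_i imprinting.
## The reciprocal heterozygotes differ only in the sign of x_i.
F2_INDICATORS <- matrix(
  c( 1, 0, 0,
     0, 1, 1,
     0, 1, -1,
    -1, 0, 0),
  nrow = 4, byrow = TRUE,
  dimnames = list(GENOTYPES, c("x_a", "x_d", "x_i"))
)

#' Cytoplasm indicator of a cross direction
#'
#' The cytoplasm of an offspring is inherited through its mother.  With the
#' P1 line (the `A`-allele line) taken as the reference, the indicator is
#' `-1` when the maternal cytoplasm descends from P1 and `+1` when it
#' descends from P2 (the `B`-allele line).  In the reciprocal F2 design,
#' direction `"F"` (P1 grandmother) gives `-1` and `"Fprime"` gives `+1`;
#' among the four backcrosses, `BC2` and `BC3` carry the P2 cytoplasm.
#'
#' @param direction Character vector with values in
#'   `c("F", "Fprime", "BC1", "BC2", "BC3", "BC4")`.
#' @return Integer vector of `-1`/`+1` values, one per element.
#' @examples
#' cytoplasm_indicator(c("F", "Fprime", "BC2"))
#' @export
cytoplasm_indicator <- function(direction) {
  direction <- as.character(direction)
  bad <- setdiff(unique(direction), DIRECTIONS)
  if (length(bad) > 0) {
    stop("unknown cross direction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ifelse(direction %in% c("Fprime", "BC2", "BC3"), 1L, -1L)
}

#' Offspring QTL genotypes segregating in a backcross
#'
#' Each backcross uses an F1 mother, so the maternal allele segregates while
#' the paternal allele is fixed by the recurrent father: P1 fathers (`BC1`,
#' `BC2`) give `AmAf`/`BmAf`, P2 fathers (`BC3`, `BC4`) give `AmBf`/`BmBf`.
#'
#' @param bc One of `"BC1"`, `"BC2"`, `"BC3"`, `"BC4"`.
#' @return Character vector of the two segregating ordered genotypes.
#' @export
backcross_genotypes <- function(bc) {
  bc <- match.arg(bc, BC_TYPES)
  if (bc %in% c("BC1", "BC2")) c("AmAf", "BmAf") else c("AmBf", "BmBf")
}

## Unified design row for any (direction, ordered genotype) pair:
## (1, m, x_a, x_d, x_i, m*x_a, m*x_d, m*x_i).  The backcross rows of the
## reciprocal-backcross design and the F2 rows share this single coding.
design_row_impl <- function(direction, genotype) {
  m <- cytoplasm_indicator(direction)
  x <- F2_INDICATORS[genotype, ]
  row <- c(1, m, x, m * x)
  names(row) <- EFFECTS
  row
}

#' Design row of an ordered genotype in a reciprocal F2
#'
#' Returns the coefficients `(1, m, x_a, x_d, x_i, m*x_a, m*x_d, m*x_i)`
#' mapping the effect vector `(mu, c, a, d, i, ica, icd, ici)` to the
#' genotypic mean of `genotype` in direction `direction`.
#'
#' @param direction `"F"` or `"Fprime"`.
#' @param genotype One of `"AmAf"`, `"AmBf"`, `"BmAf"`, `"BmBf"`.
#' @return Named numeric vector of length 8.
#' @examples
#' f2_design_row("Fprime", "AmAf")
#' @export
f2_design_row <- function(direction, genotype) {
  direction <- match.arg(direction, F2_DIRECTIONS)
  genotype <- match.arg(genotype, GENOTYPES)
  design_row_impl(direction, genotype)
}

#' Design row of an ordered genotype in a reciprocal backcross
#'
#' @param bc One of `"BC1"`, `"BC2"`, `"BC3"`, `"BC4"`.
#' @param genotype One of the two ordered genotypes segregating in `bc`
#'   (see [backcross_genotypes()]).
#' @return Named numeric vector of length 8.
#' @export
backcross_design_row <- function(bc, genotype) {
  bc <- match.arg(bc, BC_TYPES)
  genotype <- match.arg(genotype, GENOTYPES)
  if (!genotype %in% backcross_genotypes(bc)) {
    stop("genotype ", genotype, " does not segregate in ", bc, call. = FALSE)
  }
  design_row_impl(bc, genotype)
}

#' Full design matrix of a reciprocal cross family
#'
#' Stacks the eight design rows of a design family: for `"F2"` the two
#' reciprocal directions times the four ordered genotypes; for `"BC"` the
#' four backcrosses times their two segregating genotypes.  Both matrices
#' are invertible, so the eight genotypic means and the eight effects are in
#' one-to-one correspondence.
#'
#' @param design `"F2"` or `"BC"`.
#' @return An 8 x 8 numeric matrix with informative dimnames.
#' @examples
#' design_matrix("BC")
#' solve(design_matrix("F2"))
#' @export
design_matrix <- function(design = c("F2", "BC")) {
  design <- match.arg(design)
  rows <- design_classes(design)
  out <- t(mapply(design_row_impl, rows$direction, rows$genotype))
  rownames(out) <- paste(rows$direction, rows$genotype, sep = ":")
  colnames(out) <- EFFECTS
  out
}

## The (direction, genotype) pairs, in canonical row order, of a family.
design_classes <- function(design = c("F2", "BC")) {
  design <- match.arg(design)
  if (design == "F2") {
    tibble::tibble(
      direction = rep(F2_DIRECTIONS, each = 4L),
      genotype = rep(GENOTYPES, times = 2L)
    )
  } else {
    tibble::tibble(
      direction = rep(BC_TYPES, each = 2L),
      genotype = unlist(lapply(BC_TYPES, backcross_genotypes))
    )
  }
}

#' Validate and name an effect vector
#'
#' Accepts a numeric vector of length 8 (taken in model order
#' `mu, c, a, d, i, ica, icd, ici`), possibly partially named, and returns a
#' fully named vector in model order.  Unspecified named entries default
#' to 0.
#'
#' @param beta Numeric vector: either length 8 (model order) or a named
#'   vector whose names are a subset of the effect names.
#' @return Named numeric vector of length 8 in model order.
#' @examples
#' effect_vector(c(mu = 10, a = 1))
#' @export
effect_vector <- function(beta) {
  if (is.null(names(beta)) || all(names(beta) == "")) {
    if (length(beta) != 8L) {
      stop("unnamed effect vectors must have length 8", call. = FALSE)
    }
    beta <- stats::setNames(as.numeric(beta), EFFECTS)
    return(beta)
  }
  bad <- setdiff(names(beta), EFFECTS)
  if (length(bad) > 0) {
    stop("unknown effect name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- stats::setNames(numeric(8L), EFFECTS)
  out[names(beta)] <- as.numeric(beta)
  out
}

#' Genotypic means implied by an effect vector
#'
#' Computes the eight class means (design row times effect vector) of a
#' design family.
#'
#' @param beta Effect vector, see [effect_vector()].
#' @param design `"F2"` or `"BC"`.
#' @return A tibble with columns `direction`, `genotype`, `mean`.
#' @examples
#' genotypic_means(c(mu = 10, c = 1, a = 1, ica = 0.6))
#' @export
genotypic_means <- function(beta, design = c("F2", "BC")) {
  design <- match.arg(design)
  beta <- effect_vector(beta)
  cls <- design_classes(design)
  cls$mean <- as.numeric(design_matrix(design) %*% beta)
  cls
}

#' Effects recovered from the eight genotypic means
#'
#' Inverts the design relation: given the eight class means of a family (in
#' the canonical row order of [design_matrix()], or as the tibble produced
#' by [genotypic_means()]), solves for the effect vector.
#'
#' @param means Numeric vector of length 8, or a data frame with a `mean`
#'   column in canonical row order.
#' @param design `"F2"` or `"BC"`.
#' @return Named numeric effect vector of length 8.
#' @export
effects_from_means <- function(means, design = c("F2", "BC")) {
  design <- match.arg(design)
  if (is.data.frame(means)) means <- means$mean
  means <- as.numeric(means)
  if (length(means) != 8L) stop("need exactly 8 genotypic means", call. = FALSE)
  stats::setNames(as.numeric(solve(design_matrix(design), means)), EFFECTS)
}
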