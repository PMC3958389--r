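## Genetic-map arithmetic and QTL genotype posteriors given flanking
## markers, with sex-specific recombination fractions.

#' Haldane map function
#'
#' Converts a map distance in centiMorgans to a recombination fraction
#' assuming no crossover interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d Numeric vector of map distances (cM), all `>= 0`.
#' @return Recombination fractions in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 20, 1000))
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distances must be nonnegative", call. = FALSE)
  (1 - exp(-2 * d / 100)) / 2
}

#' Split a sex-averaged distance into female and male distances
#'
#' Female and male genetic maps differ in length; with a female:male
#' map-expansion ratio `lambda` (about 1.25 genome-wide in the mouse), a
#' sex-averaged distance `d` splits into `d_f = 2 lambda d / (1 + lambda)`
#' and `d_m = 2 d / (1 + lambda)`, so that their mean is `d` and their
#' ratio is `lambda`.
#'
#' @param d Sex-averaged distance(s) in cM, `>= 0`.
#' @param lambda Female:male map-expansion ratio, `> 0`.
#' @return A list with numeric components `female` and `male` (cM).
#' @examples
#' sex_split(20, 1.25)
#' @export
sex_split <- function(d, lambda = 1.25) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("lambda must be a single positive number", call. = FALSE)
  }
  if (any(d < 0)) stop("map distances must be nonnegative", call. = FALSE)
  list(female = 2 * lambda * d / (1 + lambda), male = 2 * d / (1 + lambda))
}

## Two-locus transmission: probability that a gamete carries allele y at the
## second locus given allele x at the first, for recombination fraction r.
trans_prob <- function(same, r) ifelse(same, 1 - r, r)

#' Probability that a gamete carries allele A at the QTL
#'
#' Three-point transmission rule for one gamete: given the alleles carried
#' at the two markers flanking a putative QTL and the recombination
#' fractions `r1` (left marker to QTL) and `r2` (QTL to right marker), with
#' the marker-marker fraction `r12 = r1 + r2 - 2 r1 r2` (no interference),
#' returns the conditional probability that the gamete carries allele `A`
#' at the QTL.
#'
#' @param left,right Flanking-marker alleles of the gamete, `"A"` or `"B"`.
#' @param r1,r2 Recombination fractions in `[0, 0.5)` for the two
#'   sub-intervals, on the map of the transmitting parent's sex.
#' @return Probability in `[0, 1]`.
#' @examples
#' gamete_allele_prob("A", "A", 0.08, 0.12)
#' @export
gamete_allele_prob <- function(left, right, r1, r2) {
  stopifnot(r1 >= 0, r1 < 0.5, r2 >= 0, r2 < 0.5)
  r12 <- r1 + r2 - 2 * r1 * r2
  if (left == right) {
    if (r12 == 0) return(if (left == "A") 1 else 0)
    if (left == "A") (1 - r1) * (1 - r2) / (1 - r12) else r1 * r2 / (1 - r12)
  } else {
    if (r12 == 0) {
      stop("discordant flanking alleles with zero recombination: impossible configuration",
           call. = FALSE)
    }
    if (left == "A") (1 - r1) * r2 / r12 else r1 * (1 - r2) / r12
  }
}

## Ordered (maternal, paternal) marker-allele configurations consistent with
## an unordered F2 marker code.  Codes: "AA", "AB", "BB", NA (missing).
marker_configs <- function(code) {
  if (is.na(code)) {
    list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B"))
  } else {
    switch(code,
      AA = list(c("A", "A")),
      AB = list(c("A", "B"), c("B", "A")),
      BB = list(c("B", "B")),
      stop("unknown marker code: ", code, call. = FALSE)
    )
  }
}

#' Posterior over ordered QTL genotypes given two flanking markers (F2)
#'
#' For an F2 individual, both gametes come from F1 parents heterozygous at
#' every locus in full coupling phase, the maternal gamete under female
#' recombination fractions and the paternal gamete under male fractions.
#' This function enumerates all ordered (maternal allele, paternal allele)
#' configurations of the two flanking markers consistent with the observed
#' unordered codes, weighs each by its gamete-pair probability, applies the
#' three-point rule [gamete_allele_prob()] per gamete, marginalises to the
#' four ordered QTL genotypes and normalises.  Missing codes (`NA`) are
#' summed over all states of that marker.  The sex difference
#' (`lambda != 1`) is what renders the two reciprocal heterozygotes
#' distinguishable.
#'
#' When `d_left` and `d_right` are both zero the putative position
#' coincides with a single fully typed marker and the posterior conditions
#' on that marker alone (pass the same code twice).
#'
#' @param left_code,right_code Unordered marker codes: `"AA"` (P1
#'   homozygote), `"AB"`, `"BB"`, or `NA` for missing.
#' @param d_left,d_right Sex-averaged distances (cM) from the left marker
#'   to the position and from the position to the right marker.
#' @param lambda Female:male map-expansion ratio.
#' @return Named numeric vector of posterior probabilities over
#'   `c("AmAf", "AmBf", "BmAf", "BmBf")`, summing to 1.
#' @examples
#' qtl_genotype_posterior("AB", "AB", 8, 12, lambda = 1.25)
#' @export
qtl_genotype_posterior <- function(left_code, right_code, d_left, d_right,
                                   lambda = 1.25) {
  if (d_left < 0 || d_right < 0) {
    stop("distances to flanking markers must be nonnegative", call. = FALSE)
  }
  sp1 <- sex_split(d_left, lambda)
  sp2 <- sex_split(d_right, lambda)
  r1 <- list(female = haldane_r(sp1$female), male = haldane_r(sp1$male))
  r2 <- list(female = haldane_r(sp2$female), male = haldane_r(sp2$male))
  r12 <- list(
    female = r1$female + r2$female - 2 * r1$female * r2$female,
    male   = r1$male + r2$male - 2 * r1$male * r2$male
  )

  ## per-gamete contribution: weight of the flank configuration times the
  ## probability the gamete carries A at the QTL
  gamete_terms <- function(code_pairs, sex) {
    lapply(code_pairs, function(al) {
      w <- 0.5 * trans_prob(al[1] == al[2], r12[[sex]])
      if (w == 0) return(NULL)
      list(w = w, pA = gamete_allele_prob(al[1], al[2], r1[[sex]], r2[[sex]]))
    })
  }

  left_cfg <- marker_configs(left_code)
  right_cfg <- marker_configs(right_code)
  ## maternal flank alleles are position 1 of each config, paternal position 2
  post <- stats::setNames(numeric(4L), GENOTYPES)
  for (lc in left_cfg) {
    for (rc in right_cfg) {
      mat <- gamete_terms(list(c(lc[1], rc[1])), "female")[[1]]
      if (is.null(mat)) next
      pat <- gamete_terms(list(c(lc[2], rc[2])), "male")[[1]]
      if (is.null(pat)) next
      w <- mat$w * pat$w
      pm <- mat$pA
      pp <- pat$pA
      post <- post + w * c(pm * pp, pm * (1 - pp), (1 - pm) * pp,
                           (1 - pm) * (1 - pp))
    }
  }
  s <- sum(post)
  if (s <= 0) {
    stop("marker configuration has zero probability under the map", call. = FALSE)
  }
  post / s
}

## Backcross posterior over the two segregating genotypes, expanded onto the
## four ordered genotypes (zeros elsewhere).  Only the maternal (F1) gamete
## segregates; the paternal allele is fixed by the recurrent father.  Marker
## codes determine the maternal allele exactly: with a P1 father (BC1/BC2)
## "AA" -> maternal A, "AB" -> maternal B; with a P2 father (BC3/BC4)
## "AB" -> maternal A, "BB" -> maternal B.
bc_maternal_allele <- function(code, bc) {
  if (is.na(code)) return(NA_character_)
  if (bc %in% c("BC1", "BC2")) {
    switch(code, AA = "A", AB = "B",
           stop("marker code ", code, " impossible in ", bc, call. = FALSE))
  } else {
    switch(code, AB = "A", BB = "B",
           stop("marker code ", code, " impossible in ", bc, call. = FALSE))
  }
}

bc_genotype_posterior <- function(left_code, right_code, d_left, d_right,
                                  lambda, bc) {
  sp1 <- sex_split(d_left, lambda)
  sp2 <- sex_split(d_right, lambda)
  r1 <- haldane_r(sp1$female)
  r2 <- haldane_r(sp2$female)
  r12 <- r1 + r2 - 2 * r1 * r2
  la <- bc_maternal_allele(left_code, bc)
  ra <- bc_maternal_allele(right_code, bc)
  lefts <- if (is.na(la)) c("A", "B") else la
  rights <- if (is.na(ra)) c("A", "B") else ra
  pA <- 0
  wsum <- 0
  for (l in lefts) {
    for (r in rights) {
      w <- 0.5 * trans_prob(l == r, r12)
      if (w == 0) next
      pA <- pA + w * gamete_allele_prob(l, r, r1, r2)
      wsum <- wsum + w
    }
  }
  pA <- pA / wsum
  post <- stats::setNames(numeric(4L), GENOTYPES)
  gtys <- backcross_genotypes(bc)   # first has maternal A, second maternal B
  post[gtys[1]] <- pA
  post[gtys[2]] <- 1 - pA
  post
}

## Scan grid over one linkage group: positions from the first to the last
## marker inclusive, in `step` cM increments (the last marker is always
## included).
scan_grid <- function(positions, step) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  lo <- positions[1]
  hi <- positions[length(positions)]
  g <- seq(lo, hi, by = step)
  if (g[length(g)] < hi - 1e-9) g <- c(g, hi)
  g
}

## Flanking-interval bookkeeping for one grid position: indices of the left
## and right flanking markers and distances to each.  A position that
## coincides with a marker (to 1e-8 cM) degenerates to that marker alone.
flanking_interval <- function(pos, marker_pos) {
  hit <- which(abs(marker_pos - pos) < 1e-8)
  if (length(hit) > 0) {
    k <- hit[1]
    return(list(left = k, right = k, d_left = 0, d_right = 0))
  }
  k <- findInterval(pos, marker_pos)
  if (k < 1 || k >= length(marker_pos)) {
    stop("position ", pos, " outside the marker map", call. = FALSE)
  }
  list(left = k, right = k + 1L,
       d_left = pos - marker_pos[k], d_right = marker_pos[k + 1L] - pos)
}

## Posterior matrix (individuals x 4 ordered genotypes) at one position.
## geno: character matrix n x M of codes "AA"/"AB"/"BB"/NA; directions give
## the design class per individual.  F2 posteriors depend only on the two
## flanking codes, so a 16-entry lookup is computed once per position.
posteriors_at_position <- function(geno, marker_pos, pos, direction,
                                   lambda = 1.25) {
  fl <- flanking_interval(pos, marker_pos)
  n <- nrow(geno)
  codes <- c("AA", "AB", "BB")
  iL <- match(geno[, fl$left], codes, nomatch = 4L)
  iR <- match(geno[, fl$right], codes, nomatch = 4L)
  out <- matrix(0, n, 4L, dimnames = list(NULL, GENOTYPES))
  dirs <- unique(direction)
  code_of <- function(k) if (k == 4L) NA_character_ else codes[k]
  for (d in dirs) {
    in_d <- which(direction == d)
    combos <- unique((iL[in_d] - 1L) * 4L + iR[in_d])
    for (cb in combos) {
      kL <- (cb - 1L) %/% 4L + 1L
      kR <- (cb - 1L) %% 4L + 1L
      p <- if (d %in% F2_DIRECTIONS) {
        qtl_genotype_posterior(code_of(kL), code_of(kR),
                               fl$d_left, fl$d_right, lambda)
      } else {
        bc_genotype_posterior(code_of(kL), code_of(kR),
                              fl$d_left, fl$d_right, lambda, d)
      }
      rows <- in_d[(iL[in_d] - 1L) * 4L + iR[in_d] == cb]
      out[rows, ] <- matrix(p, length(rows), 4L, byrow = TRUE)
    }
  }
  out
}

#' QTL genotype posteriors on a genome-scan grid
#'
#' Computes, for every individual and every grid position along each
#' linkage group, the posterior distribution over the four ordered QTL
#' genotypes given the flanking markers.
#'
#' @param cross Data frame with columns `direction` and one column per
#'   marker (codes `"AA"`, `"AB"`, `"BB"`, `NA`), marker columns named as
#'   in `map`.
#' @param map Data frame with columns `chromosome`, `marker`,
#'   `position_cM` (strictly increasing within chromosome).
#' @param step Grid increment in cM (default 2, as in a standard interval
#'   mapping scan).
#' @param lambda Female:male map-expansion ratio.
#' @return A tibble with one row per (chromosome, position) and a
#'   list-column `posterior` holding the n x 4 posterior matrix.
#' @export
posteriors_at_grid <- function(cross, map, step = 2, lambda = 1.25) {
  validate_map(map)
  geno <- genotype_matrix(cross, map)
  direction <- as.character(cross$direction)
  out <- lapply(split(map, map$chromosome), function(m) {
    g <- scan_grid(m$position_cM, step)
    tibble::tibble(
      chromosome = m$chromosome[1],
      position_cM = g,
      posterior = lapply(g, function(p) {
        posteriors_at_position(geno[, m$marker, drop = FALSE],
                               m$position_cM, p, direction, lambda)
      })
    )
  })
  dplyr::bind_rows(out)
}

## Genotype codes of `cross` as a character matrix in map-marker order.
genotype_matrix <- function(cross, map) {
  missing_mk <- setdiff(map$marker, names(cross))
  if (length(missing_mk) > 0) {
    stop("markers in map but not in cross data: ",
         paste(missing_mk, collapse = ", "), call. = FALSE)
  }
  geno <- as.matrix(as.data.frame(cross)[, map$marker, drop = FALSE])
  mode(geno) <- "character"
  geno
}

validate_map <- function(map) {
  req <- c("chromosome", "marker", "position_cM")
  if (!all(req %in% names(map))) {
    stop("map must have columns chromosome, marker, position_cM", call. = FALSE)
  }
  if (nrow(map) == 0) stop("map is empty", call. = FALSE)
  ok <- tapply(map$position_cM, map$chromosome,
               function(p) all(diff(p) > 0))
  if (!all(ok)) {
    stop("marker positions must be strictly increasing within chromosome",
         call. = FALSE)
  }
  invisible(map)
}
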