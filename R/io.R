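## CSV input/output for cross data and genetic maps, plus the Box-Cox
## phenotype transform.

VALID_CODES <- c("AA", "AB", "BB")

#' Read a cross from CSV files
#'
#' Reads a population file (columns `id`, `direction`, one or more
#' phenotype columns, then one column per marker with codes
#' `"AA"`/`"AB"`/`"BB"`, missing as the `na` token) and a map file
#' (columns `chromosome`, `marker`, `position_cM`).  Marker columns must
#' match the map's marker set; unknown genotype tokens are converted to
#' missing with a message; cross directions must all belong to one design
#' family (F2 or backcross).
#'
#' @param cross_file,map_file Paths to the two CSV files.
#' @param na Token representing missing values.
#' @return A `cnimap_pop`-style list with elements `cross` and `map`.
#' @export
read_cross <- function(cross_file, map_file, na = "NA") {
  map <- readr::read_csv(map_file, show_col_types = FALSE, na = na,
                         col_types = readr::cols(
                           chromosome = readr::col_character(),
                           marker = readr::col_character(),
                           position_cM = readr::col_double()))
  validate_map(map)
  cross <- readr::read_csv(cross_file, show_col_types = FALSE, na = na,
                           col_types = readr::cols(.default = readr::col_character()))
  req <- c("direction", "phenotype")
  if (!all(req %in% names(cross))) {
    stop("cross file must have columns 'direction' and 'phenotype'",
         call. = FALSE)
  }
  missing_mk <- setdiff(map$marker, names(cross))
  if (length(missing_mk) > 0) {
    stop("markers in map but absent from cross file: ",
         paste(missing_mk, collapse = ", "), call. = FALSE)
  }
  cross$phenotype <- suppressWarnings(as.numeric(cross$phenotype))
  if (anyNA(cross$phenotype)) {
    stop("non-numeric or missing phenotype values", call. = FALSE)
  }
  dirs <- unique(cross$direction)
  bad <- setdiff(dirs, DIRECTIONS)
  if (length(bad) > 0) {
    stop("unknown cross direction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (direction_family(dirs) == "mixed") {
    stop("cross mixes F2 and backcross directions", call. = FALSE)
  }
  n_unknown <- 0L
  for (mk in map$marker) {
    v <- cross[[mk]]
    unk <- !is.na(v) & !v %in% VALID_CODES
    n_unknown <- n_unknown + sum(unk)
    v[unk] <- NA_character_
    cross[[mk]] <- v
  }
  if (n_unknown > 0) {
    message(n_unknown, " unknown genotype code(s) set to missing")
  }
  structure(list(cross = cross, map = map), class = "cnimap_pop")
}

#' Write a cross to CSV files
#'
#' Inverse of [read_cross()]: writes the population and map tibbles of a
#' `cnimap_pop` (or a plain list with `cross` and `map`) to CSV.
#'
#' @param pop List with elements `cross` and `map`.
#' @param cross_file,map_file Output paths.
#' @return `pop`, invisibly.
#' @export
write_cross <- function(pop, cross_file, map_file) {
  readr::write_csv(pop$cross, cross_file, na = "NA")
  readr::write_csv(pop$map, map_file, na = "NA")
  invisible(pop)
}

#' Box-Cox transform of a phenotype
#'
#' Applies the Box-Cox power transform `(y^l - 1) / l` (natural log at
#' `l = 0`).  When `lambda_bc` is not supplied it is chosen by profile
#' likelihood on a fixed grid via [MASS::boxcox()].  Values must be
#' positive; with `shift = TRUE` nonpositive data are shifted above zero
#' first (with a message).
#'
#' @param y Positive numeric vector.
#' @param lambda_bc Optional transform exponent; estimated when `NULL`.
#' @param shift Shift nonpositive data above zero instead of erroring.
#' @return List with `y` (transformed values), `lambda_bc` (the exponent
#'   used) and `shift` (the additive shift applied, 0 if none).
#' @examples
#' boxcox_transform(rlnorm(50), lambda_bc = 0)
#' @export
boxcox_transform <- function(y, lambda_bc = NULL, shift = FALSE) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("phenotype contains missing values", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant phenotype cannot be transformed", call. = FALSE)
  applied_shift <- 0
  if (any(y <= 0)) {
    if (!shift) {
      stop("nonpositive values; use shift = TRUE to shift above zero",
           call. = FALSE)
    }
    applied_shift <- -min(y) + 1e-3 * diff(range(y))
    message("shifting phenotype by ", format(applied_shift, digits = 4),
            " before Box-Cox transform")
    y <- y + applied_shift
  }
  if (is.null(lambda_bc)) {
    prof <- MASS::boxcox(y_ ~ 1, data = data.frame(y_ = y),
                         lambda = seq(-2, 2, 0.05), plotit = FALSE)
    lambda_bc <- prof$x[which.max(prof$y)]
  }
  z <- if (abs(lambda_bc) < 1e-12) log(y) else (y^lambda_bc - 1) / lambda_bc
  list(y = z, lambda_bc = lambda_bc, shift = applied_shift)
}
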