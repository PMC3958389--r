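## broom-style tidiers for fitted objects and scan results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture-model fit
#'
#' One row per effect with its constrained status.  Under the F2 design
#' the imprinting effect and the cytoplasm-by-imprinting interaction are
#' reported with `estimable = FALSE`: the design cannot infer the
#' imprinting direction, so their sign is not identified (their presence
#' is still testable, see [test_battery()]).
#'
#' @param x A `cnimap_fit` from [em_fit()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `constrained`,
#'   `estimable`.
#' @method tidy cnimap_fit
#' @export
tidy.cnimap_fit <- function(x, ...) {
  tibble::tibble(
    term = EFFECTS,
    estimate = unname(x$beta),
    constrained = EFFECTS %in% x$constraint,
    estimable = !(x$family == "F2" & EFFECTS %in% c("i", "ici"))
  )
}

#' Glance at a mixture-model fit
#'
#' @param x A `cnimap_fit`.
#' @param ... Unused.
#' @return One-row tibble: `loglik`, `sigma2`, `n`, `n_iter`, `converged`,
#'   `df_free`.
#' @method glance cnimap_fit
#' @export
glance.cnimap_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, sigma2 = x$sigma2, n = x$n, n_iter = x$n_iter,
    converged = x$converged, df_free = 9L - length(x$constraint)
  )
}

#' Tidy a genome scan
#'
#' @param x A `cnimap_scan`.
#' @param ... Unused.
#' @return The scan profile as a plain tibble.
#' @method tidy cnimap_scan
#' @export
tidy.cnimap_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at a genome scan
#'
#' @param x A `cnimap_scan`.
#' @param ... Unused.
#' @return One-row tibble with the peak chromosome/position and the
#'   maximum LR and LOD.
#' @method glance cnimap_scan
#' @export
glance.cnimap_scan <- function(x, ...) {
  pk <- attr(x, "peak")
  tibble::tibble(
    chromosome = pk$chromosome, position_cM = pk$position_cM,
    max_lr = pk$lr, max_lod = pk$lod,
    null_loglik = attr(x, "null")$loglik,
    n_positions = nrow(x)
  )
}
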