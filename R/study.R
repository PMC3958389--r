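## Replicated simulation studies: simulate, scan, and summarise at the
## per-replicate peak.  This is the driver behind the package's
## parameter-recovery and test-calibration experiments.

#' Run a replicated simulation study
#'
#' Simulates `n_rep` populations under `scenario`, scans each at `step`
#' cM, and records the peak position with the full-model estimates there;
#' optionally runs the hypothesis-test battery at each peak.
#'
#' @param scenario A `cnimap_scenario`, e.g. from [table_scenarios()].
#' @param n_rep Number of replicates.
#' @param step Scan grid increment in cM.
#' @param seed Optional seed for the whole study (one stream across
#'   replicates).
#' @param battery Also run [test_battery()] at each replicate's peak and
#'   record the chi-square p-values.
#' @param imprinting Imprinting-test form passed to [test_battery()].
#' @return Tibble with one row per replicate: `position_cM`, the eight
#'   effect estimates, `sigma2`, `max_lr`, `max_lod`, `converged`, and
#'   when `battery = TRUE` the columns `p_cytoplasmic`, `p_imprinting`,
#'   `p_interaction`, `p_adddom`.
#' @examples
#' \donttest{
#' scen <- table_scenarios("table2", n = 400, h2 = 0.4)
#' run_simulation_study(scen, n_rep = 3, seed = 1)
#' }
#' @export
run_simulation_study <- function(scenario, n_rep, step = 2, seed = NULL,
                                 battery = FALSE,
                                 imprinting = c("single", "joint")) {
  stopifnot(inherits(scenario, "cnimap_scenario"))
  imprinting <- match.arg(imprinting)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    pop <- simulate_population(scenario)
    sc <- genome_scan(pop$cross, pop$map, step = step,
                      lambda = scenario$lambda)
    pk <- scan_peak(sc)
    at <- sc[sc$chromosome == pk$chromosome &
               sc$position_cM == pk$position_cM, ]
    out <- tibble::tibble(
      replicate = r, position_cM = pk$position_cM,
      mu = at$mu, c = at$c, a = at$a, d = at$d, i = at$i,
      ica = at$ica, icd = at$icd, ici = at$ici,
      sigma2 = at$sigma2, max_lr = pk$lr, max_lod = pk$lod,
      converged = at$converged
    )
    if (battery) {
      tb <- test_battery(pop$cross, pop$map, position = pk$position_cM,
                         chromosome = pk$chromosome,
                         lambda = scenario$lambda, imprinting = imprinting)
      out$p_cytoplasmic <- tb$p_chisq[tb$test == "cytoplasmic"]
      out$p_imprinting <- tb$p_chisq[tb$test == "imprinting"]
      out$p_interaction <- tb$p_chisq[tb$test == "interaction"]
      out$p_adddom <- tb$p_chisq[tb$test == "adddom"]
    }
    rows[[r]] <- out
  }
  dplyr::bind_rows(rows)
}
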