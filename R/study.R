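# One-call in-silico block study: calibrated heterogeneous population,
# no-block reference, and the full channel x block-level sweep with paired
# percent-change features. This is the computation behind the simulation
# tables and the classifier validation.

#' Run the full in-silico ion-channel-block study
#'
#' Calibrates the conductance heterogeneity so the no-block population's
#' APD80 coefficient of variation is about 0.10, draws a population, runs
#' the no-block reference and every channel x remaining-fraction scenario on
#' the same conductance draws (20 beats at CL 2000 ms, metrics from the
#' penultimate beat), and assembles the per-cell paired percent-change
#' feature table.
#'
#' @param nCells population size per scenario (default 100).
#' @param seed RNG seed controlling calibration, draws and downstream
#'   splits.
#' @param calibrate calibrate the conductance cv (default TRUE); when FALSE
#'   \code{cv} is used as given.
#' @param cv conductance coefficient of variation when \code{calibrate} is
#'   FALSE (default 0.15).
#' @param nPilot pilot size for calibration.
#' @param channels,levels sweep layout (defaults: the six modeled channel
#'   families at remaining fractions 0.75, 0.50, 0.25).
#' @param ... passed to \code{\link{runScenario}} (integration controls,
#'   MAS configuration).
#' @return list: \code{cv} (calibrated or given), \code{population},
#'   \code{reference} (no-block per-cell metrics), \code{features}
#'   (percent-change table with channel/level labels), \code{scenarios}
#'   (raw per-scenario metrics).
#' @export
simulateBlockStudy <- function(nCells = 100, seed = 1, calibrate = TRUE,
                               cv = 0.15, nPilot = 40,
                               channels = c("INa", "Ito", "ICa", "IKr",
                                            "IKs", "IK1"),
                               levels = c(0.75, 0.5, 0.25), ...) {
  if (calibrate) {
    cal <- calibrateHeterogeneity(nPilot = nPilot, seed = seed, ...)
    cv <- cal$cv
  }
  population <- samplePopulation(nCells, cv = cv, seed = seed)
  sweep <- blockSweep(population, channels = channels, levels = levels, ...)
  list(cv = cv, population = population, reference = sweep$reference,
       features = sweep$features, scenarios = sweep$scenarios)
}

#' Percent change of scenario means against the no-block reference
#'
#' The simulation tables report metric changes as the percent change of the
#' population mean under block relative to the no-block population mean
#' (excluded cells dropped from both).
#'
#' @param scenario per-cell metrics of a blocked scenario
#'   (\code{\link{runScenario}} output).
#' @param reference per-cell no-block metrics.
#' @return named numeric vector of percent changes per metric.
#' @export
meanPercentChange <- function(scenario, reference) {
  cols <- c("rise_ms", "apd30_ms", "apd50_ms", "apd80_ms", "apd_mxr_ms",
            "apd_tri_ms")
  mb <- colMeans(scenario[!scenario$excluded, cols, drop = FALSE])
  mr <- colMeans(reference[!reference$excluded, cols, drop = FALSE])
  100 * (mb - mr) / mr
}
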