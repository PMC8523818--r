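.msg <- function(verbose, ...) if (verbose) message(...)

#' Tabulate MR estimates in report layout
#'
#' Collects estimates into the conventional results layout: method, OR with
#' 95\% CI, association p, Cochran's Q with its p, and the Egger-intercept
#' p. Display rounding follows the usual reporting convention (OR/CI to 2
#' dp, Q to 2 dp, p to 3 dp) when \code{rounded = TRUE}; full precision is
#' retained otherwise.
#'
#' @param estimates list of \linkS4class{MREstimate}s.
#' @param het optional \linkS4class{MRHeterogeneity} attached to the first
#'   row.
#' @param rounded apply display rounding.
#' @return data.frame, one row per estimate.
#' @export
mrReport <- function(estimates, het = NULL, rounded = FALSE) {
  rows <- lapply(estimates, as.data.frame)
  out <- do.call(rbind, rows)
  out$q <- out$p_het <- out$p_intercept <- NA_real_
  if (!is.null(het)) {
    out$q[1] <- het@q
    out$p_het[1] <- het@pQ
    egg <- which(out$method == "egger_slope")
    if (length(egg)) out$p_intercept[egg[1]] <- het@pIntercept
  }
  if (rounded) {
    for (col in c("or", "ci_low", "ci_high", "q"))
      out[[col]] <- round(out[[col]], 2)
    for (col in c("pval", "p_het", "p_intercept"))
      out[[col]] <- round(out[[col]], 3)
  }
  rownames(out) <- NULL
  out
}

#' Run the full two-sample MR pipeline
#'
#' Read (or accept) exposure and outcome summary tables, harmonize them,
#' apply LD pruning and list-based confounder exclusion, compute the
#' instrument-strength report, fit IVW / weighted-median / MR-Egger /
#' MR-PRESSO, run heterogeneity diagnostics, leave-one-out sensitivity and
#' E-values, and optionally write every table to \code{outDir}. The run is
#' deterministic given the seed; every removed SNP appears exactly once in
#' the exclusion log with a machine-readable reason.
#'
#' @param exposure,outcome \linkS4class{SummaryTable}s or file paths.
#' @param ld optional LD data.frame (\code{\link{readLdTable}}) or path.
#' @param exclusions optional named rsid -> reason vector
#'   (\code{\link{readExclusions}}) or path.
#' @param r2Threshold,windowKb LD pruning parameters.
#' @param nExposure fallback exposure sample size for the strength report.
#' @param fThreshold weak-instrument threshold.
#' @param nBoot weighted-median bootstrap replicates.
#' @param nSim MR-PRESSO simulations.
#' @param alpha MR-PRESSO outlier threshold (before Bonferroni).
#' @param seed seed for the stochastic components (WM bootstrap, PRESSO).
#' @param rareOutcome passed to \code{\link{eValue}}.
#' @param outDir optional directory; when given, delimited result tables
#'   and a run log are written there.
#' @param verbose emit per-stage progress messages.
#' @return list with elements \code{instruments}, \code{strength},
#'   \code{estimates} (data.frame in report layout), \code{heterogeneity},
#'   \code{loo}, \code{presso}, \code{evalue}, \code{log}.
#' @export
runPipeline <- function(exposure, outcome, ld = NULL, exclusions = NULL,
                        r2Threshold = 0.05, windowKb = 5000,
                        nExposure = 78592, fThreshold = 10,
                        nBoot = 1000, nSim = 1000, alpha = 0.05, seed = 2021,
                        rareOutcome = TRUE, outDir = NULL, verbose = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.character(exposure))
    exposure <- stage("read_exposure", readSummary(exposure, trait = "exposure"))
  if (is.character(outcome))
    outcome <- stage("read_outcome", readSummary(outcome, trait = "outcome"))
  if (is.character(ld)) ld <- stage("read_ld", readLdTable(ld))
  if (is.character(exclusions) && is.null(names(exclusions)) &&
      length(exclusions) == 1L)
    exclusions <- stage("read_exclusions", readExclusions(exclusions))

  .msg(verbose, "harmonizing ", nRecords(exposure), " exposure vs ",
       nRecords(outcome), " outcome records")
  inst <- stage("harmonize", harmonize(exposure, outcome))
  counts <- nInstruments(inst)
  if (!is.null(ld)) {
    inst <- stage("prune_ld", pruneLd(inst, ld, r2Threshold, windowKb))
    counts <- c(counts, nInstruments(inst))
  }
  if (!is.null(exclusions) && length(exclusions)) {
    inst <- stage("exclude_by_list", excludeByList(inst, exclusions))
    counts <- c(counts, nInstruments(inst))
  }
  .msg(verbose, "instrument accounting: ", paste(counts, collapse = " -> "))

  strength <- stage("strength", weakInstrumentReport(inst, n = nExposure,
                                                     threshold = fThreshold))
  if (any(!strength$pass))
    warning("weak instruments (F < ", fThreshold, "): ",
            paste(strength$rsid[!strength$pass], collapse = ", "))

  ivw <- stage("ivw", mrIVW(inst))
  wm <- stage("wm", mrWeightedMedian(inst, nBoot = nBoot, seed = seed))
  egger <- stage("egger", mrEgger(inst))
  het <- stage("cochran_q", mrCochranQ(inst))
  loo <- stage("leave_one_out", leaveOneOut(inst))
  presso <- stage("presso", mrPresso(inst, nSim = nSim, seed = seed,
                                     alpha = alpha))
  ev <- stage("evalue", eValue(ivw@or, ivw@ciLow, ivw@ciHigh,
                               rareOutcome = rareOutcome))

  estimates <- mrReport(list(ivw, wm, egger$slope, presso@raw), het = het)
  log <- c(inst@log,
           sprintf("final instrument count: %d", nInstruments(inst)),
           sprintf("seed: %d; nBoot: %d; nSim: %d", seed, nBoot, nSim))

  res <- list(instruments = inst, strength = strength, estimates = estimates,
              heterogeneity = het, egger_intercept = egger$intercept,
              loo = loo, presso = presso, evalue = ev, log = log)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f)
      utils::write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    wt(instrumentData(inst), "instruments.tsv")
    wt(removedInstruments(inst), "excluded.tsv")
    wt(strength, "strength.tsv")
    wt(estimates, "estimates.tsv")
    wt(loo, "leave_one_out.tsv")
    wt(data.frame(rsid = names(presso@outlierP), p = presso@outlierP),
       "presso_outlier_p.tsv")
    wt(data.frame(e_point = ev$e_point,
                  e_ci = if (is.null(ev$e_ci)) NA_real_ else ev$e_ci),
       "evalue.tsv")
    writeLines(log, file.path(outDir, "run_log.txt"))
  }
  res
}

#' Reproduce the telomere-length / total-osteoarthritis analysis
#'
#' Runs the full pipeline on the packaged instrument panel with the
#' documented quality-control inputs: LD pruning at r-squared > 0.05 in a
#' 5,000-kb window (removing rs2853677) and the confounder exclusion list
#' (removing rs73624724), leaving 18 instruments; then IVW,
#' weighted-median, MR-Egger and MR-PRESSO estimation with heterogeneity,
#' leave-one-out and E-value sensitivity analyses.
#'
#' @inheritParams runPipeline
#' @return the \code{\link{runPipeline}} result list.
#' @examples
#' res <- reproduceTelomereOA(nBoot = 200, nSim = 200, verbose = FALSE)
#' res$estimates[, c("method", "or", "ci_low", "ci_high")]
#' @export
reproduceTelomereOA <- function(seed = 2021, nBoot = 1000, nSim = 1000,
                                outDir = NULL, verbose = TRUE) {
  panel <- loadTelomereOA()
  ld <- readLdTable(system.file("extdata", "telomere_ld_synthetic.tsv",
                                package = "mrsummary"))
  excl <- readExclusions(system.file("extdata", "telomere_exclusions.tsv",
                                     package = "mrsummary"))
  runPipeline(panel$exposure, panel$outcome, ld = ld, exclusions = excl,
              r2Threshold = 0.05, windowKb = 5000, nExposure = 78592,
              nBoot = nBoot, nSim = nSim, seed = seed, rareOutcome = TRUE,
              outDir = outDir, verbose = verbose)
}
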