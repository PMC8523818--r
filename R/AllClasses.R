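#' @import methods
NULL

.NUCLEOTIDES <- c("A", "C", "G", "T")

.INSTRUMENT_FLAGS <- c("flipped", "palindromic", "proxy",
                       "excluded_ld", "excluded_confounder")

#' SummaryTable: GWAS summary statistics for one trait
#'
#' One row per SNP of a single-trait GWAS: rsID, chromosome, 1-based
#' position, effect and other allele, effect-allele frequency, additive
#' per-allele effect (SD units for a quantitative exposure, log-odds for a
#' binary outcome), its standard error, association p-value and sample size.
#' p-value and sample size may be \code{NA}; operations that need them
#' (e.g. the F-statistic needs N) fail explicitly rather than silently.
#'
#' @slot trait single character label for the trait.
#' @slot data data.frame with columns \code{rsid}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#'   \code{se}, \code{pval}, \code{n}, in file order, rsids unique.
#' @export
setClass("SummaryTable",
         representation(trait = "character", data = "data.frame"))

.summaryColumns <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n")

setValidity("SummaryTable", function(object) {
  d <- object@data
  msgs <- character()
  if (length(object@trait) != 1L)
    msgs <- c(msgs, "trait must be a single string")
  missing_cols <- setdiff(.summaryColumns, names(d))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(d$rsid))
    msgs <- c(msgs, paste("duplicate rsid:",
                          paste(unique(d$rsid[duplicated(d$rsid)]), collapse = ", ")))
  if (nrow(d)) {
    if (any(!d$effect_allele %in% .NUCLEOTIDES) ||
        any(!d$other_allele %in% .NUCLEOTIDES))
      msgs <- c(msgs, "alleles must be single nucleotide codes A/C/G/T")
    if (any(d$effect_allele == d$other_allele))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
    if (any(!is.finite(d$se)) || any(d$se <= 0))
      msgs <- c(msgs, "se must be finite and > 0")
    if (any(!is.finite(d$eaf)) || any(d$eaf <= 0) || any(d$eaf >= 1))
      msgs <- c(msgs, "eaf must lie strictly in (0, 1)")
    nn <- d$n[!is.na(d$n)]
    if (any(nn < 2))
      msgs <- c(msgs, "n must be >= 2")
    pp <- d$pval[!is.na(d$pval)]
    if (any(pp <= 0) || any(pp > 1))
      msgs <- c(msgs, "pval must lie in (0, 1]")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SummaryTable
#'
#' @param data data.frame with the columns documented in
#'   \linkS4class{SummaryTable}; \code{pval} and \code{n} are optional and
#'   filled with \code{NA} when absent.
#' @param trait trait label.
#' @return A \linkS4class{SummaryTable}.
#' @export
SummaryTable <- function(data, trait = "trait") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("pval", "n"))
    if (is.null(data[[col]])) data[[col]] <- NA_real_
  if (is.null(data$chrom)) data$chrom <- NA_character_
  if (is.null(data$pos)) data$pos <- NA_real_
  data$chrom <- as.character(data$chrom)
  rownames(data) <- NULL
  new("SummaryTable", trait = trait, data = data[, .summaryColumns])
}

#' @describeIn SummaryTable number of SNP records.
#' @param x,object a \code{SummaryTable}.
#' @export
nRecords <- function(x) nrow(x@data)

#' @describeIn SummaryTable trait label.
#' @export
traitLabel <- function(x) x@trait

#' @describeIn SummaryTable the underlying per-SNP data.frame.
#' @export
summaryData <- function(x) x@data

setMethod("show", "SummaryTable", function(object) {
  cat("SummaryTable:", object@trait, "-", nrow(object@data), "SNP records\n")
  if (nrow(object@data))
    print(utils::head(object@data, 5L), row.names = FALSE)
  if (nrow(object@data) > 5L) cat("...\n")
})

#' MRInstruments: harmonized instrument set
#'
#' The analysis-ready pairing of exposure and outcome effects per SNP,
#' aligned to a shared effect allele. Instruments removed by quality control
#' (LD pruning, confounder exclusion, allele mismatch) are retained in the
#' \code{removed} slot with their reason so that every exclusion is
#' accounted for exactly once.
#'
#' @slot data data.frame of active instruments with columns \code{rsid},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf_exposure}, \code{beta_exposure}, \code{se_exposure},
#'   \code{pval_exposure}, \code{n_exposure}, \code{beta_outcome},
#'   \code{se_outcome}, \code{flags} (comma-joined tokens among
#'   flipped/palindromic/proxy/excluded_ld/excluded_confounder).
#' @slot removed data.frame with columns \code{rsid}, \code{reason},
#'   \code{stage}, one row per excluded SNP.
#' @slot log character vector of processing messages, in order.
#' @export
setClass("MRInstruments",
         representation(data = "data.frame", removed = "data.frame",
                        log = "character"))

setValidity("MRInstruments", function(object) {
  d <- object@data
  need <- c("rsid", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome", "flags")
  if (length(setdiff(need, names(d))))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(d$rsid)) msgs <- c(msgs, "duplicate instrument rsid")
  if (nrow(d) && (any(d$se_exposure <= 0) || any(d$se_outcome <= 0)))
    msgs <- c(msgs, "standard errors must be > 0")
  toks <- setdiff(unlist(strsplit(d$flags[nzchar(d$flags)], ",")), .INSTRUMENT_FLAGS)
  if (length(toks))
    msgs <- c(msgs, paste("unknown flag:", paste(toks, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn MRInstruments number of active instruments.
#' @param x,object an \code{MRInstruments} object.
#' @export
nInstruments <- function(x) nrow(x@data)

#' @describeIn MRInstruments data.frame of active instruments.
#' @export
instrumentData <- function(x) x@data

#' @describeIn MRInstruments data.frame of removed SNPs with reasons.
#' @export
removedInstruments <- function(x) x@removed

#' @describeIn MRInstruments processing log, one message per event.
#' @export
exclusionLog <- function(x) x@log

#' @describeIn MRInstruments test whether instruments carry a given flag.
#' @param flag one of \code{"flipped"}, \code{"palindromic"}, \code{"proxy"},
#'   \code{"excluded_ld"}, \code{"excluded_confounder"}.
#' @export
hasFlag <- function(x, flag) {
  flag <- match.arg(flag, .INSTRUMENT_FLAGS)
  vapply(strsplit(x@data$flags, ","), function(t) flag %in% t, logical(1))
}

setMethod("show", "MRInstruments", function(object) {
  cat("MRInstruments:", nrow(object@data), "active instruments,",
      nrow(object@removed), "removed\n")
  if (nrow(object@data))
    print(utils::head(object@data[, c("rsid", "beta_exposure", "se_exposure",
                                      "beta_outcome", "se_outcome", "flags")], 5L),
          row.names = FALSE)
  if (nrow(object@data) > 5L) cat("...\n")
})

#' MREstimate: one method's causal-effect estimate
#'
#' Causal log-odds of outcome per SD of exposure, with normal-theory
#' 95\% confidence interval on the odds-ratio scale.
#'
#' @slot method label: one of wald, ivw_fe, ivw_mre, wm, egger_slope,
#'   egger_intercept, presso_raw, presso_corrected.
#' @slot beta causal estimate (log-odds per SD of exposure).
#' @slot se its standard error.
#' @slot or exp(beta).
#' @slot ciLow,ciHigh exp(beta -/+ 1.96 se).
#' @slot pval two-sided p-value.
#' @slot nSNP number of instruments used.
#' @export
setClass("MREstimate",
         representation(method = "character", beta = "numeric", se = "numeric",
                        or = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pval = "numeric", nSNP = "integer"))

.Z95 <- 1.96

.MREstimate <- function(method, beta, se, pval, nSNP) {
  new("MREstimate", method = method, beta = beta, se = se,
      or = exp(beta), ciLow = exp(beta - .Z95 * se),
      ciHigh = exp(beta + .Z95 * se), pval = pval, nSNP = as.integer(nSNP))
}

setValidity("MREstimate", function(object) {
  ok <- isTRUE(all.equal(object@or, exp(object@beta))) &&
    !isTRUE(object@ciLow > object@or) && !isTRUE(object@or > object@ciHigh)
  if (ok) TRUE else "inconsistent OR / CI"
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s], %d SNPs\n", object@method, object@nSNP))
  cat(sprintf("  beta = %.4f (SE %.4f); OR = %.2f (95%% CI %.2f, %.2f); p = %.3g\n",
              object@beta, object@se, object@or, object@ciLow, object@ciHigh,
              object@pval))
})

#' @describeIn MREstimate one-row data.frame representation.
#' @param x an \code{MREstimate}.
#' @param row.names,optional,... passed through for generic consistency.
#' @export
as.data.frame.MREstimate <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(method = x@method, beta = x@beta, se = x@se, or = x@or,
             ci_low = x@ciLow, ci_high = x@ciHigh, pval = x@pval,
             n_snp = x@nSNP, stringsAsFactors = FALSE)
}

#' @describeIn MREstimate the odds ratio exp(beta).
#' @export
mrOR <- function(x) x@or

#' @describeIn MREstimate the two-sided p-value.
#' @export
mrPval <- function(x) x@pval

#' MRHeterogeneity: Cochran's Q and Egger-intercept diagnostics
#'
#' @slot q Cochran's Q statistic over per-SNP Wald ratios.
#' @slot df degrees of freedom, nSNP - 1.
#' @slot pQ chi-square upper-tail p at \code{q}.
#' @slot eggerIntercept average directional pleiotropy (Egger intercept);
#'   NA when fewer than 3 instruments.
#' @slot eggerInterceptSE its standard error.
#' @slot pIntercept two-sided t-test p-value for the intercept (k - 2 df).
#' @export
setClass("MRHeterogeneity",
         representation(q = "numeric", df = "integer", pQ = "numeric",
                        eggerIntercept = "numeric", eggerInterceptSE = "numeric",
                        pIntercept = "numeric"))

setMethod("show", "MRHeterogeneity", function(object) {
  cat(sprintf("Cochran's Q = %.2f on %d df (p = %.3f)\n",
              object@q, object@df, object@pQ))
  if (!is.na(object@eggerIntercept))
    cat(sprintf("Egger intercept = %.4f (SE %.4f), p = %.3f\n",
                object@eggerIntercept, object@eggerInterceptSE, object@pIntercept))
})

#' MRPresso: MR-PRESSO test results
#'
#' @slot rssObs observed leave-one-out residual sum of squares.
#' @slot pGlobal smoothed empirical p of the global heterogeneity test.
#' @slot outlierP named per-SNP outlier p-values.
#' @slot outliers rsids declared outliers at the Bonferroni threshold.
#' @slot pDistortion distortion-test p (NA when no outliers).
#' @slot raw IVW estimate on all instruments.
#' @slot corrected IVW estimate on the non-outlier subset (NULL when no
#'   outliers; stored in a list slot).
#' @slot nSim number of parametric simulations used.
#' @export
setClass("MRPresso",
         representation(rssObs = "numeric", pGlobal = "numeric",
                        outlierP = "numeric", outliers = "character",
                        pDistortion = "numeric", raw = "MREstimate",
                        corrected = "list", nSim = "integer"))

setMethod("show", "MRPresso", function(object) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.3f, global p = %.4g (%d simulations)\n",
              object@rssObs, object@pGlobal, object@nSim))
  if (length(object@outliers)) {
    cat("Outliers:", paste(object@outliers, collapse = ", "), "\n")
    cat(sprintf("Distortion p = %.3g\n", object@pDistortion))
    cat("Corrected: "); show(object@corrected[[1]])
  } else cat("No outliers detected.\n")
  cat("Raw: "); show(object@raw)
})
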