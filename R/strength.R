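#' Per-SNP variance in the exposure explained by an instrument
#'
#' For an additive per-allele effect \code{beta} with standard error
#' \code{se}, effect-allele frequency \code{eaf} and GWAS sample size
#' \code{n}, the proportion of exposure variance explained is
#' \deqn{R^2 = \frac{2\,EAF(1-EAF)\,\beta^2}
#'   {2\,EAF(1-EAF)\,\beta^2 + 2\,EAF(1-EAF)\,N\,SE^2}.}
#' The common factor cancels, so this equals
#' \eqn{\beta^2 / (\beta^2 + N\,SE^2)}; the full expression is evaluated as
#' written for transparency.
#'
#' @param eaf effect-allele frequency, strictly in (0, 1). Vectorized.
#' @param beta per-allele effect on the exposure.
#' @param se its standard error, > 0.
#' @param n exposure-GWAS sample size, >= 3.
#' @return r-squared in [0, 1).
#' @examples
#' varianceExplained(0.24, -0.086, 0.006, 78592)  # ~0.0026
#' @export
varianceExplained <- function(eaf, beta, se, n) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1))
    stop("eaf must lie strictly in (0, 1)")
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be > 0")
  if (any(!is.finite(n)) || any(n < 3)) stop("n must be >= 3")
  v <- 2 * eaf * (1 - eaf)
  (v * beta^2) / ((v * beta^2) + (v * n * se^2))
}

#' Instrument F-statistic from variance explained
#'
#' \deqn{F = R^2 (N - 2) / (1 - R^2)} — the single-instrument strength
#' statistic; values above 10 are conventionally taken to indicate a strong
#' instrument. For small \eqn{R^2}, \eqn{F \approx (\beta/SE)^2 (1 - 2/N)}.
#'
#' @param r2 variance explained, in [0, 1). Vectorized.
#' @param n sample size, >= 3.
#' @return F-statistic >= 0.
#' @examples
#' fStatistic(varianceExplained(0.24, -0.086, 0.006, 78592), 78592)  # ~205
#' @export
fStatistic <- function(r2, n) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1))
    stop("r2 must lie in [0, 1)")
  if (any(!is.finite(n)) || any(n < 3)) stop("n must be >= 3")
  r2 * (n - 2) / (1 - r2)
}

#' Weak-instrument report for a harmonized instrument set
#'
#' Computes per-SNP variance explained and F-statistic on the exposure side
#' and flags instruments below the conventional strength threshold. Per-SNP
#' sample sizes from the exposure table are used where present; otherwise
#' \code{n} applies to every SNP. The default \code{n} is the headline size
#' of the telomere-length GWAS meta-analysis (78,592), which the packaged
#' panel was estimated in.
#'
#' @param instruments an \linkS4class{MRInstruments} object (or a
#'   \linkS4class{SummaryTable} of exposure records).
#' @param n fallback sample size when the records carry none.
#' @param threshold F threshold for the pass flag; default 10.
#' @return data.frame with columns \code{rsid}, \code{r2}, \code{f_stat},
#'   \code{pass}; zero rows for an empty instrument set.
#' @examples
#' panel <- loadTelomereOA()
#' inst <- harmonize(panel$exposure, panel$outcome)
#' head(weakInstrumentReport(inst))
#' @export
weakInstrumentReport <- function(instruments, n = 78592, threshold = 10) {
  if (is(instruments, "SummaryTable")) {
    d <- instruments@data
    d <- data.frame(rsid = d$rsid, eaf_exposure = d$eaf, beta_exposure = d$beta,
                    se_exposure = d$se, n_exposure = d$n,
                    stringsAsFactors = FALSE)
  } else {
    stopifnot(is(instruments, "MRInstruments"))
    d <- instruments@data
  }
  if (!nrow(d))
    return(data.frame(rsid = character(), r2 = numeric(), f_stat = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  nn <- d$n_exposure
  nn[is.na(nn)] <- n
  if (any(is.na(nn))) stop("sample size unavailable; supply n")
  r2 <- varianceExplained(d$eaf_exposure, d$beta_exposure, d$se_exposure, nn)
  f <- fStatistic(r2, nn)
  data.frame(rsid = d$rsid, r2 = r2, f_stat = f, pass = f >= threshold,
             stringsAsFactors = FALSE)
}
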