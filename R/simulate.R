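#' Configuration for the two-sample summary-statistic generator
#'
#' Defaults mirror the telomere-length / osteoarthritis setting the packaged
#' panel comes from: 18 instruments, an exposure GWAS of 78,592 individuals
#' on the SD scale, a case-control outcome GWAS of 50,508 individuals with
#' case fraction 0.1996 on the log-odds scale, effect-allele frequencies
#' between 0.1 and 0.9, and true exposure effects |N(0, 0.05)| + 0.02 per
#' allele (spanning roughly 0.03-0.14, the realistic instrument range for a
#' polygenic quantitative trait).
#'
#' @param k number of instruments, >= 2.
#' @param theta true causal effect, log-odds of outcome per SD of exposure.
#' @param pleiotropyMode \code{"none"}, \code{"balanced"} (pleiotropy
#'   intercepts centred on zero) or \code{"directional"}.
#' @param alphaMean,alphaSd mean and SD of the per-SNP pleiotropy intercept
#'   for invalid instruments (log-odds scale); \code{"balanced"} requires
#'   \code{alphaMean = 0}.
#' @param invalidFrac fraction of instruments receiving pleiotropy, in
#'   [0, 1].
#' @param nExposure,nOutcome effective GWAS sample sizes.
#' @param caseFraction outcome case fraction used for the log-odds SE.
#' @param eafRange interval within (0, 1) for effect-allele frequencies.
#' @param betaSd,betaMin exposure-effect distribution |N(0, betaSd)| +
#'   betaMin.
#' @param noiseScale multiplier on observation noise; 0 gives noiseless
#'   summary statistics (estimators then recover theta exactly).
#' @param allowPalindromic draw allele pairs that may be palindromic.
#' @param seed RNG seed used by \code{\link{simulateSummary}}.
#' @return a \code{simConfig} list.
#' @export
simConfig <- function(k = 18, theta = 0, pleiotropyMode = c("none", "balanced",
                                                            "directional"),
                      alphaMean = 0, alphaSd = 0.01, invalidFrac = 0,
                      nExposure = 78592, nOutcome = 50508,
                      caseFraction = 0.1996, eafRange = c(0.1, 0.9),
                      betaSd = 0.05, betaMin = 0.02, noiseScale = 1,
                      allowPalindromic = FALSE, seed = 1) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  stopifnot(k >= 2, invalidFrac >= 0, invalidFrac <= 1, alphaSd >= 0,
            length(eafRange) == 2, eafRange[1] > 0, eafRange[2] < 1,
            eafRange[1] < eafRange[2], nExposure >= 3, nOutcome >= 3,
            caseFraction > 0, caseFraction < 1, noiseScale >= 0)
  if (pleiotropyMode == "balanced" && alphaMean != 0)
    stop("balanced pleiotropy requires alphaMean = 0")
  structure(list(k = as.integer(k), theta = theta,
                 pleiotropyMode = pleiotropyMode, alphaMean = alphaMean,
                 alphaSd = alphaSd, invalidFrac = invalidFrac,
                 nExposure = nExposure, nOutcome = nOutcome,
                 caseFraction = caseFraction, eafRange = eafRange,
                 betaSd = betaSd, betaMin = betaMin, noiseScale = noiseScale,
                 allowPalindromic = allowPalindromic, seed = seed),
            class = "simConfig")
}

.NONPALINDROMIC_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                                  "G","A", "G","T", "T","C", "T","G"),
                                ncol = 2, byrow = TRUE)
.ALL_PAIRS <- rbind(.NONPALINDROMIC_PAIRS,
                    matrix(c("A","T", "T","A", "C","G", "G","C"),
                           ncol = 2, byrow = TRUE))

#' Simulate two-sample MR summary statistics with known ground truth
#'
#' Per SNP: an effect-allele frequency uniform on the configured range; a
#' true exposure effect |N(0, betaSd)| + betaMin with random sign; the
#' exposure SE \eqn{1/\sqrt{2\,eaf(1-eaf)\,n_{exp}}} (per-allele effect on a
#' standardized trait); the outcome SE
#' \eqn{1/\sqrt{2\,eaf(1-eaf)\,n_{out}\,\phi(1-\phi)}} (log-odds scale with
#' case fraction \eqn{\phi}); a pleiotropy intercept of 0 for valid SNPs
#' and N(alphaMean, alphaSd) for the configured invalid fraction; the true
#' outcome effect \eqn{\theta\,\beta_X^{true} + \alpha}; and observed betas
#' equal to the true values plus normal noise at the reported SEs (scaled
#' by \code{noiseScale}). Outcome effects are generated directly on the
#' log-odds scale — no individual-level case-control sampling — since the
#' estimators consume summary statistics only.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{exposure} and \code{outcome}
#'   (\linkS4class{SummaryTable}s sharing rsids and alleles) and
#'   \code{truth}: a data.frame of per-SNP true effects, pleiotropy
#'   intercepts and validity, with attributes \code{theta} and \code{seed}.
#' @examples
#' sim <- simulateSummary(simConfig(k = 10, theta = 0.2, seed = 42))
#' attr(sim$truth, "theta")
#' @export
simulateSummary <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  old <- .Random.seed_exists(); on.exit(old$restore(), add = TRUE)
  set.seed(config$seed)
  k <- config$k
  eaf <- stats::runif(k, config$eafRange[1], config$eafRange[2])
  # effect alleles are oriented to the exposure-increasing direction, the
  # usual convention for instrument panels; estimators are invariant to
  # jointly negating any (beta_X, beta_Y) pair
  bx_true <- abs(stats::rnorm(k, 0, config$betaSd)) + config$betaMin
  sx <- 1 / sqrt(2 * eaf * (1 - eaf) * config$nExposure)
  phi <- config$caseFraction
  sy <- 1 / sqrt(2 * eaf * (1 - eaf) * config$nOutcome * phi * (1 - phi))

  n_invalid <- round(config$invalidFrac * k)
  invalid <- rep(FALSE, k)
  if (config$pleiotropyMode != "none" && n_invalid > 0)
    invalid[sample(k, n_invalid)] <- TRUE
  alpha <- ifelse(invalid,
                  stats::rnorm(k, config$alphaMean, config$alphaSd), 0)
  by_true <- config$theta * bx_true + alpha

  ns <- config$noiseScale
  bx_obs <- bx_true + stats::rnorm(k, 0, sx) * ns
  by_obs <- by_true + stats::rnorm(k, 0, sy) * ns

  pairs <- if (config$allowPalindromic) .ALL_PAIRS else .NONPALINDROMIC_PAIRS
  pick <- sample(nrow(pairs), k, replace = TRUE)
  rsid <- sprintf("snp%04d", seq_len(k))
  base <- data.frame(rsid = rsid,
                     chrom = as.character(rep_len(1:22, k)),
                     pos = seq_len(k) * 1e6,
                     effect_allele = pairs[pick, 1],
                     other_allele = pairs[pick, 2],
                     eaf = eaf, stringsAsFactors = FALSE)
  expo <- base
  expo$beta <- bx_obs; expo$se <- sx
  expo$pval <- pmax(2 * stats::pnorm(-abs(bx_obs) / sx), 1e-300)
  expo$n <- config$nExposure
  outc <- base
  outc$beta <- by_obs; outc$se <- sy
  outc$pval <- pmax(2 * stats::pnorm(-abs(by_obs) / sy), 1e-300)
  outc$n <- config$nOutcome

  truth <- data.frame(rsid = rsid, beta_exposure_true = bx_true,
                      beta_outcome_true = by_true, alpha = alpha,
                      valid = !invalid, stringsAsFactors = FALSE)
  attr(truth, "theta") <- config$theta
  attr(truth, "seed") <- config$seed
  list(exposure = SummaryTable(expo, trait = "simulated exposure (SD)"),
       outcome = SummaryTable(outc, trait = "simulated outcome (log-odds)"),
       truth = truth)
}

#' Simulate a panel at the scale of the telomere-length instrument set
#'
#' Emits 20 genome-wide-significant instruments whose marginal ranges match
#' the packaged telomere-length panel: exposure |beta| roughly 0.03-0.14
#' (SD units) with SEs 0.006-0.023, and outcome SEs roughly 0.016-0.053 on
#' the log-odds scale. Effect-allele frequencies and exposure effects are
#' rejection-sampled so every SNP's recomputed exposure p-value clears
#' genome-wide significance (p < 5e-8). Useful for fuzzing I/O and the
#' estimators at realistic scale.
#'
#' @param seed RNG seed; identical seeds give identical tables.
#' @param theta true causal effect used for the outcome betas; default 0.
#' @return list with \code{exposure} and \code{outcome}
#'   \linkS4class{SummaryTable}s of 20 SNPs sharing rsids and alleles.
#' @export
simulateTelomerePanel <- function(seed = 1, theta = 0) {
  old <- .Random.seed_exists(); on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  k <- 20L
  n_exp <- 78592; n_out <- 50508; phi <- 0.1996
  z_gw <- stats::qnorm(2.5e-8, lower.tail = FALSE)
  eaf <- beta <- se <- numeric(k)
  for (j in seq_len(k)) {
    repeat {
      e <- stats::runif(1, 0.02, 0.96)
      s <- 1 / sqrt(2 * e * (1 - e) * n_exp)
      b <- (abs(stats::rnorm(1, 0, 0.05)) + 0.02) * sample(c(-1, 1), 1)
      b_obs <- b + stats::rnorm(1, 0, s)
      if (abs(b_obs) / s > z_gw && abs(b_obs) <= 0.14 && abs(b_obs) >= 0.029) {
        eaf[j] <- e; beta[j] <- b_obs; se[j] <- s
        break
      }
    }
  }
  sy <- 1 / sqrt(2 * eaf * (1 - eaf) * n_out * phi * (1 - phi))
  by <- theta * beta + stats::rnorm(k, 0, sy)
  pick <- sample(nrow(.NONPALINDROMIC_PAIRS), k, replace = TRUE)
  rsid <- sprintf("rs%07d", sample(1e7, k))
  base <- data.frame(rsid = rsid, chrom = as.character(rep_len(1:22, k)),
                     pos = sort(sample(1e8, k)),
                     effect_allele = .NONPALINDROMIC_PAIRS[pick, 1],
                     other_allele = .NONPALINDROMIC_PAIRS[pick, 2],
                     eaf = eaf, stringsAsFactors = FALSE)
  expo <- base
  expo$beta <- beta; expo$se <- se
  expo$pval <- pmax(2 * stats::pnorm(-abs(beta) / se), 1e-300)
  expo$n <- n_exp
  outc <- base
  outc$beta <- by; outc$se <- sy
  outc$pval <- pmax(2 * stats::pnorm(-abs(by) / sy), 1e-300)
  outc$n <- n_out
  list(exposure = SummaryTable(expo, trait = "simulated telomere-scale exposure"),
       outcome = SummaryTable(outc, trait = "simulated telomere-scale outcome"))
}
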