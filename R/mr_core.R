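# Shared extraction: estimators accept the MRInstruments container or a plain
# data.frame carrying the same columns (convenient for simulation studies).
.xy <- function(instruments) {
  d <- if (is(instruments, "MRInstruments")) instruments@data else
    as.data.frame(instruments)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (length(setdiff(need, names(d))))
    stop("instrument data must carry columns ",
         paste(need, collapse = ", "))
  list(rsid = if (!is.null(d$rsid)) d$rsid else
         sprintf("snp%03d", seq_len(nrow(d))),
       bx = d$beta_exposure, sx = d$se_exposure,
       by = d$beta_outcome, sy = d$se_outcome, k = nrow(d))
}

#' Wald ratio for a single instrument
#'
#' Per-SNP causal estimate \eqn{\beta_Y / \beta_X} with first-order
#' delta-method standard error \eqn{|SE_Y / \beta_X|} (outcome uncertainty
#' only). With \code{secondOrder = TRUE} the exposure uncertainty is added:
#' \eqn{SE^2 = SE_Y^2/\beta_X^2 + \beta_Y^2 SE_X^2/\beta_X^4}.
#'
#' @param inst a one-row instrument (an \linkS4class{MRInstruments} object
#'   or data.frame with one active instrument).
#' @param secondOrder include the exposure-side variance term.
#' @return An \linkS4class{MREstimate} with method \code{"wald"}.
#' @export
waldRatio <- function(inst, secondOrder = FALSE) {
  v <- .xy(inst)
  if (v$k != 1L) stop("waldRatio expects exactly one instrument")
  if (v$bx == 0) stop("null instrument: beta_exposure is zero")
  beta <- v$by / v$bx
  se <- if (secondOrder)
    sqrt(v$sy^2 / v$bx^2 + v$by^2 * v$sx^2 / v$bx^4)
  else abs(v$sy / v$bx)
  .MREstimate("wald", beta, se, 2 * stats::pnorm(-abs(beta / se)), 1L)
}

.ivwCore <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fe <- sqrt(1 / sxx)
  q <- sum(w * (by - beta * bx)^2)     # equals ratio-scale Q with these weights
  list(beta = beta, se_fe = se_fe, q = q)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights \eqn{1/SE_Y^2} — algebraically, the inverse-variance
#' pooling of per-SNP Wald ratios. The point estimate is identical in both
#' modes; \code{"fixed"} uses the model-based standard error, the default
#' \code{"multiplicative_random"} scales it by
#' \eqn{\max(1, \sqrt{Q/(k-1)})} so overdispersion widens the interval but
#' homogeneous data reduce to the fixed-effect answer. With a single
#' instrument the estimate reduces algebraically to that instrument's Wald
#' ratio.
#'
#' @param instruments \linkS4class{MRInstruments} or equivalent data.frame
#'   with at least one instrument.
#' @param mode \code{"multiplicative_random"} (default) or \code{"fixed"}.
#' @return An \linkS4class{MREstimate} (method \code{ivw_mre} or
#'   \code{ivw_fe}).
#' @examples
#' panel <- loadTelomereOA()
#' inst <- harmonize(panel$exposure, panel$outcome)
#' mrIVW(inst)
#' @export
mrIVW <- function(instruments, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  v <- .xy(instruments)
  if (v$k < 1L) stop("no instruments")
  if (v$k == 1L)
    message("single instrument: IVW reduces to the Wald ratio (see waldRatio)")
  fit <- .ivwCore(v$bx, v$by, v$sy)
  phi <- if (mode == "multiplicative_random" && v$k > 1L)
    max(1, sqrt(fit$q / (v$k - 1))) else 1
  se <- fit$se_fe * phi
  p <- 2 * stats::pnorm(-abs(fit$beta / se))
  .MREstimate(if (mode == "fixed") "ivw_fe" else "ivw_mre",
              fit$beta, se, p, v$k)
}

.weightedMedian <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2                   # midpoint cumulative weights
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(v)])
  stats::approx(s, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Orders the per-SNP Wald ratios, weights them by the inverse squared
#' delta-method ratio SE (normalized to sum to one), and interpolates the
#' piecewise-linear cumulative-weight function at 0.5 using midpoint
#' cumulative sums. Consistent when at least half the weight comes from
#' valid instruments. The standard error comes from a parametric bootstrap:
#' \code{nBoot} resamples of \eqn{(\beta_X, \beta_Y)} from normal
#' distributions centred on the observed betas with the reported SEs, the
#' estimator recomputed on each, and the SD of the resampled estimates
#' taken. Deterministic under a fixed \code{seed}; the point estimate does
#' not depend on the bootstrap.
#'
#' @param instruments \linkS4class{MRInstruments} or equivalent data.frame,
#'   at least 3 instruments.
#' @param nBoot bootstrap replicates for the SE; default 1000.
#'   \code{nBoot = 0} skips the bootstrap and reports an NA standard error
#'   (point estimate only).
#' @param seed RNG seed for the bootstrap; default 2021.
#' @return An \linkS4class{MREstimate} with method \code{"wm"}.
#' @export
mrWeightedMedian <- function(instruments, nBoot = 1000, seed = 2021) {
  v <- .xy(instruments)
  if (v$k < 3L) stop("weighted median needs at least 3 instruments")
  ratio <- v$by / v$bx
  w <- (v$bx / v$sy)^2                      # 1 / se(ratio)^2, first-order
  beta <- .weightedMedian(ratio, w)
  if (nBoot < 2)
    return(.MREstimate("wm", beta, NA_real_, NA_real_, v$k))
  old <- .Random.seed_exists()
  on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  bb <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    bxs <- stats::rnorm(v$k, v$bx, v$sx)
    bys <- stats::rnorm(v$k, v$by, v$sy)
    bb[b] <- .weightedMedian(bys / bxs, (bxs / v$sy)^2)
  }
  se <- stats::sd(bb)
  .MREstimate("wm", beta, se, 2 * stats::pnorm(-abs(beta / se)), v$k)
}

# Save/restore the global RNG state so seeded estimators do not perturb the
# caller's random stream.
.Random.seed_exists <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  list(restore = function() {
    if (had) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' unconstrained intercept, weights \eqn{1/SE_Y^2}, after orienting every
#' instrument to a non-negative exposure beta (jointly negating each
#' \eqn{(\beta_X, \beta_Y)} pair as needed). The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy. Standard errors use multiplicative residual
#' scaling floored at 1; p-values use the t distribution with k - 2 df.
#'
#' @param instruments \linkS4class{MRInstruments} or equivalent data.frame,
#'   at least 3 instruments.
#' @return list with elements \code{slope} and \code{intercept}, both
#'   \linkS4class{MREstimate}s (methods \code{egger_slope},
#'   \code{egger_intercept}).
#' @export
mrEgger <- function(instruments) {
  v <- .xy(instruments)
  if (v$k < 3L) stop("MR-Egger needs at least 3 instruments")
  s <- ifelse(v$bx < 0, -1, 1)
  bx <- s * v$bx
  by <- s * v$by
  w <- 1 / v$sy^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) stop("degenerate design: exposure betas are collinear")
  a <- (swxx * swy - swx * swxy) / det
  b <- (sw * swxy - swx * swy) / det
  resid <- by - a - b * bx
  df <- v$k - 2L
  sigma2 <- sum(w * resid^2) / df
  scale2 <- max(1, sigma2)                  # multiplicative scaling, floored
  se_a <- sqrt(scale2 * swxx / det)
  se_b <- sqrt(scale2 * sw / det)
  p_b <- 2 * stats::pt(-abs(b / se_b), df)
  p_a <- 2 * stats::pt(-abs(a / se_a), df)
  list(slope = .MREstimate("egger_slope", b, se_b, p_b, v$k),
       intercept = .MREstimate("egger_intercept", a, se_a, p_a, v$k))
}

#' Cochran's Q heterogeneity and Egger-intercept diagnostics
#'
#' \eqn{Q = \sum_i w_i (r_i - \beta_{IVW})^2} over per-SNP Wald ratios
#' \eqn{r_i} with weights \eqn{w_i = 1/se(r_i)^2}, compared to a chi-square
#' with k - 1 df. With at least 3 instruments the Egger intercept and its
#' two-sided t-test (k - 2 df) are reported alongside as the directional
#' pleiotropy diagnostic.
#'
#' @param instruments \linkS4class{MRInstruments} or equivalent data.frame,
#'   at least 2 instruments.
#' @return An \linkS4class{MRHeterogeneity} object.
#' @export
mrCochranQ <- function(instruments) {
  v <- .xy(instruments)
  if (v$k < 2L) stop("heterogeneity needs at least 2 instruments")
  fit <- .ivwCore(v$bx, v$by, v$sy)
  df <- v$k - 1L
  pq <- stats::pchisq(fit$q, df, lower.tail = FALSE)
  if (v$k >= 3L) {
    eg <- mrEgger(instruments)$intercept
    new("MRHeterogeneity", q = fit$q, df = df, pQ = pq,
        eggerIntercept = eg@beta, eggerInterceptSE = eg@se, pIntercept = eg@pval)
  } else {
    new("MRHeterogeneity", q = fit$q, df = df, pQ = pq,
        eggerIntercept = NA_real_, eggerInterceptSE = NA_real_,
        pIntercept = NA_real_)
  }
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Refits the IVW estimator k times, omitting each instrument in turn, and
#' flags omissions that flip the sign of the pooled log-OR or move the 95\%
#' CI across the null (relative to the full-sample fit).
#'
#' @param instruments \linkS4class{MRInstruments} or equivalent data.frame,
#'   at least 3 instruments (each refit needs k >= 2).
#' @param mode IVW mode passed through to \code{\link{mrIVW}}.
#' @return data.frame with one row per omitted rsid: \code{beta}, \code{se},
#'   \code{or}, \code{ci_low}, \code{ci_high}, \code{pval},
#'   \code{sign_flip}, \code{crosses_null}.
#' @export
leaveOneOut <- function(instruments, mode = "multiplicative_random") {
  v <- .xy(instruments)
  if (v$k < 3L) stop("leave-one-out needs at least 3 instruments")
  d <- if (is(instruments, "MRInstruments")) instruments@data else
    as.data.frame(instruments)
  full <- mrIVW(d, mode = mode)
  full_sig <- full@ciLow > 1 || full@ciHigh < 1
  rows <- lapply(seq_len(v$k), function(i) {
    est <- mrIVW(d[-i, ], mode = mode)
    sig <- est@ciLow > 1 || est@ciHigh < 1
    data.frame(rsid = v$rsid[i], beta = est@beta, se = est@se, or = est@or,
               ci_low = est@ciLow, ci_high = est@ciHigh, pval = est@pval,
               sign_flip = sign(est@beta) != sign(full@beta) &&
                 est@beta != 0 && full@beta != 0,
               crosses_null = sig != full_sig,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' E-value for unmeasured confounding
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to fully
#' explain away an observed association. The observed OR is converted to an
#' approximate risk ratio (\code{RR = OR} for a rare outcome, otherwise
#' \code{RR = sqrt(OR)}), inverted if protective, and
#' \deqn{E = RR + \sqrt{RR (RR - 1)}.}
#' The CI E-value applies the same formula to the confidence limit closer
#' to the null and is 1 when the interval crosses 1 (no confounding needed
#' to explain a null-compatible interval). The lowest possible E-value is 1.
#'
#' @param or observed odds ratio, > 0.
#' @param ciLow,ciHigh optional 95\% CI bounds on the OR scale.
#' @param rareOutcome if \code{TRUE} (default) the OR approximates the RR
#'   directly; otherwise the square-root transform is used.
#' @return list with \code{e_point} and (when a CI is given) \code{e_ci}.
#' @examples
#' eValue(2)                 # 2 + sqrt(2) = 3.41
#' eValue(1.00, 0.83, 1.21)  # CI crosses 1 -> e_ci = 1
#' @export
eValue <- function(or, ciLow = NA_real_, ciHigh = NA_real_, rareOutcome = TRUE) {
  if (!is.finite(or) || or <= 0) stop("or must be positive")
  toRR <- function(x) if (rareOutcome) x else sqrt(x)
  evalOne <- function(x) {
    rr <- toRR(x)
    if (rr < 1) rr <- 1 / rr
    rr + sqrt(rr * (rr - 1))
  }
  out <- list(e_point = evalOne(or))
  if (is.finite(ciLow) && is.finite(ciHigh)) {
    if (any(c(ciLow, ciHigh) <= 0)) stop("CI bounds must be positive")
    out$e_ci <- if (ciLow <= 1 && ciHigh >= 1) 1
    else evalOne(if (or >= 1) ciLow else ciHigh)
  }
  out
}
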