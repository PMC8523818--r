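# Simulation engine shared by the global and outlier tests. Residuals are
# defined against leave-one-out IVW slopes (each SNP's fitted value uses the
# slope estimated without it), with weights 1/SE_Y^2. The null distribution
# is parametric: beta_X* ~ N(beta_X, SE_X), beta_Y* ~ N(loo_slope * beta_X,
# SE_Y), with leave-one-out slopes recomputed on each simulated dataset.
.pressoEngine <- function(bx, sx, by, sy, nSim) {
  k <- length(bx)
  w <- 1 / sy^2
  looSlopes <- function(BX, BY) {
    WXY <- sweep(BX * BY, 2, w, "*")
    WXX <- sweep(BX * BX, 2, w, "*")
    (rowSums(WXY) - WXY) / (rowSums(WXX) - WXX)
  }
  obs_bx <- matrix(bx, 1); obs_by <- matrix(by, 1)
  L_obs <- looSlopes(obs_bx, obs_by)
  res_obs <- as.numeric(sweep((obs_by - L_obs * obs_bx)^2, 2, w, "*"))
  mu_y <- as.numeric(L_obs) * bx

  BX <- matrix(stats::rnorm(nSim * k, rep(bx, each = nSim), rep(sx, each = nSim)),
               nSim, k)
  BY <- matrix(stats::rnorm(nSim * k, rep(mu_y, each = nSim), rep(sy, each = nSim)),
               nSim, k)
  L <- looSlopes(BX, BY)
  RES <- sweep((BY - L * BX)^2, 2, w, "*")
  list(res_obs = res_obs, rss_obs = sum(res_obs), RES = RES,
       RSS = rowSums(RES))
}

.pressoCheck <- function(v) {
  if (v$k < 4L) stop("MR-PRESSO needs at least 4 instruments")
}

#' MR-PRESSO global heterogeneity test
#'
#' Observed residual sum of squares
#' \eqn{RSS = \sum_i w_i (\beta_{Y_i} - \hat\beta_{-i} \beta_{X_i})^2}
#' (leave-one-out IVW slopes, weights \eqn{1/SE_Y^2}) compared against a
#' parametric null built from \code{nSim} simulated datasets; the p-value is
#' the smoothed exceedance fraction \eqn{(r + 1)/(n_{sim} + 1)}.
#'
#' @param instruments \linkS4class{MRInstruments} or equivalent data.frame,
#'   at least 4 instruments.
#' @param nSim simulated datasets; default 1000.
#' @param seed RNG seed; default 2021.
#' @return list with \code{rss_obs} and \code{p_global}.
#' @export
pressoGlobal <- function(instruments, nSim = 1000, seed = 2021) {
  v <- .xy(instruments)
  .pressoCheck(v)
  old <- .Random.seed_exists(); on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  eng <- .pressoEngine(v$bx, v$sx, v$by, v$sy, nSim)
  list(rss_obs = eng$rss_obs,
       p_global = (sum(eng$RSS >= eng$rss_obs) + 1) / (nSim + 1))
}

#' MR-PRESSO per-SNP outlier test
#'
#' Each SNP's observed weighted squared residual is compared to its own
#' simulated null distribution, giving a smoothed empirical p-value per
#' SNP; outliers are SNPs with p below the Bonferroni-adjusted threshold
#' \code{alpha / k}.
#'
#' @inheritParams pressoGlobal
#' @param alpha family-wise outlier threshold before Bonferroni adjustment;
#'   default 0.05. \code{alpha = 0} declares nothing by construction.
#' @return list with \code{outlier_p} (named numeric) and \code{outliers}
#'   (character).
#' @export
pressoOutlier <- function(instruments, nSim = 1000, seed = 2021, alpha = 0.05) {
  v <- .xy(instruments)
  .pressoCheck(v)
  old <- .Random.seed_exists(); on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  eng <- .pressoEngine(v$bx, v$sx, v$by, v$sy, nSim)
  pv <- (colSums(sweep(eng$RES, 2, eng$res_obs, ">=")) + 1) / (nSim + 1)
  names(pv) <- v$rsid
  list(outlier_p = pv, outliers = v$rsid[pv < alpha / v$k])
}

#' MR-PRESSO distortion test and outlier-corrected estimate
#'
#' With declared outliers, compares the raw IVW estimate with the IVW
#' estimate on the retained set through the distortion statistic
#' \eqn{D = 100 (\beta_{raw} - \beta_{corrected}) / |\beta_{corrected}|},
#' and derives its null by re-estimating after removing random subsets of
#' the same size. With no outliers the raw estimate is passed through and
#' no distortion test is run.
#'
#' @inheritParams pressoGlobal
#' @param outliers character vector of outlier rsids (possibly empty), as
#'   returned by \code{\link{pressoOutlier}}.
#' @param mode IVW mode for the raw/corrected estimates.
#' @return list with \code{raw} (\linkS4class{MREstimate}),
#'   \code{corrected} (\linkS4class{MREstimate} or \code{NULL}) and
#'   \code{p_distortion} (\code{NA} when no outliers).
#' @export
pressoDistortion <- function(instruments, outliers, nSim = 1000, seed = 2021,
                             mode = "multiplicative_random") {
  v <- .xy(instruments)
  .pressoCheck(v)
  d <- if (is(instruments, "MRInstruments")) instruments@data else
    as.data.frame(instruments)
  raw <- mrIVW(d, mode = mode)
  if (!length(outliers))
    return(list(raw = raw, corrected = NULL, p_distortion = NA_real_))
  is_out <- v$rsid %in% outliers
  if (all(is_out)) stop("all instruments declared outliers")
  corrected <- mrIVW(d[!is_out, ], mode = mode)
  if (corrected@beta == 0) stop("corrected estimate is exactly zero")
  d_obs <- 100 * (raw@beta - corrected@beta) / abs(corrected@beta)
  m <- sum(is_out)
  old <- .Random.seed_exists(); on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  d_null <- numeric(nSim)
  for (b in seq_len(nSim)) {
    drop <- sample(v$k, m)
    fit <- .ivwCore(v$bx[-drop], v$by[-drop], v$sy[-drop])
    d_null[b] <- 100 * (raw@beta - fit$beta) / abs(fit$beta)
  }
  p <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (nSim + 1)
  corrected@method <- "presso_corrected"
  list(raw = raw, corrected = corrected, p_distortion = p)
}

#' Run the full MR-PRESSO procedure
#'
#' Global heterogeneity test, per-SNP outlier test at the Bonferroni
#' threshold, and — when outliers are found — the distortion test and
#' outlier-corrected IVW estimate. When no outliers are found the reported
#' estimate is exactly the raw IVW estimate.
#'
#' @inheritParams pressoOutlier
#' @param mode IVW mode for the raw/corrected estimates.
#' @return An \linkS4class{MRPresso} object.
#' @examples
#' panel <- loadTelomereOA()
#' inst <- harmonize(panel$exposure, panel$outcome)
#' mrPresso(inst, nSim = 200, seed = 7)
#' @export
mrPresso <- function(instruments, nSim = 1000, seed = 2021, alpha = 0.05,
                     mode = "multiplicative_random") {
  v <- .xy(instruments)
  .pressoCheck(v)
  old <- .Random.seed_exists(); on.exit(old$restore(), add = TRUE)
  set.seed(seed)
  eng <- .pressoEngine(v$bx, v$sx, v$by, v$sy, nSim)
  p_global <- (sum(eng$RSS >= eng$rss_obs) + 1) / (nSim + 1)
  pv <- (colSums(sweep(eng$RES, 2, eng$res_obs, ">=")) + 1) / (nSim + 1)
  names(pv) <- v$rsid
  outliers <- v$rsid[pv < alpha / v$k]
  dist <- pressoDistortion(instruments, outliers, nSim = nSim, seed = seed + 1L,
                           mode = mode)
  raw <- dist$raw
  raw@method <- "presso_raw"
  new("MRPresso", rssObs = eng$rss_obs, pGlobal = p_global, outlierP = pv,
      outliers = outliers, pDistortion = dist$p_distortion, raw = raw,
      corrected = if (is.null(dist$corrected)) list() else list(dist$corrected),
      nSim = as.integer(nSim))
}
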