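.complement <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effect of every SNP shared between the two tables to
#' the exposure's effect allele. If the outcome alleles match as given the
#' record is kept unchanged; if they are swapped (effect and other allele
#' exchanged) the outcome beta is negated exactly once and the instrument is
#' flagged \code{flipped}; strand-complement representations of the same
#' pair are resolved the same way. Palindromic SNPs (A/T or C/G) cannot be
#' strand-resolved from alleles alone: they are retained and flagged
#' \code{palindromic}. With \code{inferStrand = TRUE} a palindromic SNP
#' whose exposure and outcome allele frequencies sit on opposite sides of
#' 0.5 is additionally flipped (off by default; frequency-based inference is
#' unreliable near 0.5). Irreconcilable allele pairs are dropped with a
#' logged reason.
#'
#' @param exposure,outcome \linkS4class{SummaryTable}s sharing at least one
#'   rsid.
#' @param inferStrand use allele frequencies to orient palindromic SNPs.
#' @param proxies optional data.frame with columns \code{target},
#'   \code{proxy}, \code{r2}, \code{proxy_effect_allele}: before matching,
#'   an outcome record for \code{proxy} stands in for the missing
#'   \code{target} when \code{r2 > 0.8}; the proxied instrument is flagged
#'   \code{proxy}. No reference-panel lookup is performed — the table is a
#'   data contract supplied by the caller.
#' @return An \linkS4class{MRInstruments} object in exposure-table order.
#' @examples
#' panel <- loadTelomereOA()
#' inst <- harmonize(panel$exposure, panel$outcome)
#' nInstruments(inst)
#' @export
harmonize <- function(exposure, outcome, inferStrand = FALSE, proxies = NULL) {
  stopifnot(is(exposure, "SummaryTable"), is(outcome, "SummaryTable"))
  ed <- exposure@data
  od <- outcome@data

  if (!is.null(proxies) && nrow(proxies)) {
    for (i in seq_len(nrow(proxies))) {
      tgt <- proxies$target[i]; prx <- proxies$proxy[i]
      if (tgt %in% od$rsid || !prx %in% od$rsid) next
      if (proxies$r2[i] <= 0.8) next
      row <- od[od$rsid == prx, ]
      row$rsid <- tgt
      # re-express the proxy's effect for the target's effect allele
      if (!is.null(proxies$proxy_effect_allele) &&
          !is.na(proxies$proxy_effect_allele[i]) &&
          proxies$proxy_effect_allele[i] != row$effect_allele) {
        row$beta <- -row$beta
        row$eaf <- 1 - row$eaf
        tmp <- row$effect_allele
        row$effect_allele <- row$other_allele
        row$other_allele <- tmp
      }
      ea <- ed$effect_allele[ed$rsid == tgt]
      oa <- ed$other_allele[ed$rsid == tgt]
      row$effect_allele <- ea; row$other_allele <- oa
      attr(row, "is_proxy") <- TRUE
      od <- rbind(od, row)
      attr(od, "proxied") <- c(attr(od, "proxied"), tgt)
    }
  }
  proxied <- attr(od, "proxied")

  shared <- ed$rsid[ed$rsid %in% od$rsid]
  if (!length(shared))
    stop("exposure and outcome tables share no rsid")
  omap <- od[match(shared, od$rsid), ]
  emap <- ed[match(shared, ed$rsid), ]

  log <- character()
  keep <- logical(length(shared))
  flip <- logical(length(shared))
  pal <- logical(length(shared))
  for (i in seq_along(shared)) {
    ea <- emap$effect_allele[i]; oa <- emap$other_allele[i]
    yb <- omap$effect_allele[i]; ya <- omap$other_allele[i]
    pal[i] <- .isPalindromic(ea, oa)
    if (yb == ea && ya == oa) {
      keep[i] <- TRUE
    } else if (yb == oa && ya == ea) {
      keep[i] <- TRUE; flip[i] <- TRUE
    } else if (!pal[i] && yb == .complement[ea] && ya == .complement[oa]) {
      keep[i] <- TRUE                      # same pair on the other strand
    } else if (!pal[i] && yb == .complement[oa] && ya == .complement[ea]) {
      keep[i] <- TRUE; flip[i] <- TRUE
    } else {
      log <- c(log, sprintf("dropped %s: allele mismatch (%s/%s vs %s/%s)",
                            shared[i], ea, oa, yb, ya))
    }
  }
  if (inferStrand) {
    amb <- keep & pal & !is.na(omap$eaf) &
      (emap$eaf - 0.5) * (omap$eaf - 0.5) < 0 &
      pmin(emap$eaf, 1 - emap$eaf) < 0.42
    flip <- xor(flip, amb)
    if (any(amb))
      log <- c(log, sprintf("strand-flipped palindromic %s by allele frequency",
                            shared[amb]))
  }

  flags <- character(length(shared))
  addFlag <- function(flags, on, token)
    ifelse(on, ifelse(nzchar(flags), paste(flags, token, sep = ","), token), flags)
  flags <- addFlag(flags, flip, "flipped")
  flags <- addFlag(flags, pal, "palindromic")
  flags <- addFlag(flags, shared %in% proxied, "proxy")

  d <- data.frame(rsid = shared, chrom = emap$chrom, pos = emap$pos,
                  effect_allele = emap$effect_allele,
                  other_allele = emap$other_allele,
                  eaf_exposure = emap$eaf,
                  beta_exposure = emap$beta, se_exposure = emap$se,
                  pval_exposure = emap$pval, n_exposure = emap$n,
                  beta_outcome = ifelse(flip, -omap$beta, omap$beta),
                  se_outcome = omap$se,
                  flags = flags, stringsAsFactors = FALSE)[keep, ]
  rownames(d) <- NULL

  removed <- data.frame(rsid = shared[!keep],
                        reason = rep("allele mismatch", sum(!keep)),
                        stage = rep("harmonize", sum(!keep)),
                        stringsAsFactors = FALSE)
  log <- c(sprintf("harmonize: %d shared rsids, %d kept, %d flipped, %d palindromic",
                   length(shared), sum(keep), sum(flip & keep), sum(pal & keep)),
           log)
  new("MRInstruments", data = d, removed = removed, log = log)
}

.ldLookup <- function(ld, a, b) {
  if (a == b) return(1)
  hit <- (ld$rsid_a == a & ld$rsid_b == b) | (ld$rsid_a == b & ld$rsid_b == a)
  if (any(hit)) ld$r2[hit][1] else NA_real_
}

#' Greedy LD pruning of an instrument set
#'
#' Standard clumping: instruments are ranked by exposure p-value ascending
#' (ties broken by |beta|/SE descending, then rsid), and each is kept unless
#' its r-squared with an already-kept SNP on the same chromosome within
#' \code{windowKb} exceeds \code{r2Threshold}. SNPs on different chromosomes
#' or beyond the window are treated as independent. A pair inside the window
#' with no LD entry is treated as r2 = 0 with a warning. The kept set is a
#' function of the instrument set, LD table and threshold only — input order
#' does not matter.
#'
#' @param instruments an \linkS4class{MRInstruments} object.
#' @param ld LD data.frame from \code{\link{readLdTable}} (columns
#'   \code{rsid_a}, \code{rsid_b}, \code{r2}).
#' @param r2Threshold pruning threshold in (0, 1); default 0.05.
#' @param windowKb window in kilobases within which the r2 rule applies;
#'   default 5000.
#' @return An \linkS4class{MRInstruments} with pruned SNPs moved to the
#'   removed slot (reason \code{excluded_ld}).
#' @export
pruneLd <- function(instruments, ld, r2Threshold = 0.05, windowKb = 5000) {
  stopifnot(is(instruments, "MRInstruments"))
  if (!(r2Threshold > 0 && r2Threshold < 1))
    stop("r2Threshold must lie in (0, 1)")
  d <- instruments@data
  if (!nrow(d)) return(instruments)

  z <- abs(d$beta_exposure) / d$se_exposure
  pv <- d$pval_exposure
  pv[is.na(pv)] <- 2 * stats::pnorm(-z[is.na(pv)])
  ord <- order(pv, -z, d$rsid)

  kept <- integer(0)
  missing_pairs <- character(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      same_chr <- !is.na(d$chrom[i]) && !is.na(d$chrom[j]) &&
        d$chrom[i] == d$chrom[j]
      within <- same_chr && !is.na(d$pos[i]) && !is.na(d$pos[j]) &&
        abs(d$pos[i] - d$pos[j]) <= windowKb * 1000
      if (!within) next
      r2 <- .ldLookup(ld, d$rsid[i], d$rsid[j])
      if (is.na(r2)) {
        missing_pairs <- c(missing_pairs,
                           paste(d$rsid[i], d$rsid[j], sep = "/"))
        r2 <- 0
      }
      if (r2 > r2Threshold) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, i)
  }
  if (length(missing_pairs))
    warning("no LD entry for in-window pair(s) ",
            paste(unique(missing_pairs), collapse = ", "),
            "; treated as r2 = 0")

  dropped <- setdiff(seq_len(nrow(d)), kept)
  removed <- rbind(instruments@removed,
                   data.frame(rsid = d$rsid[dropped],
                              reason = sprintf("r2 > %g with retained SNP",
                                               r2Threshold)[rep(1, length(dropped))],
                              stage = rep("prune_ld", length(dropped)),
                              stringsAsFactors = FALSE))
  out <- d[sort(kept), ]
  rownames(out) <- NULL
  log <- c(instruments@log,
           sprintf("prune_ld: %d -> %d instruments (r2 > %g within %d kb)%s",
                   nrow(d), length(kept), r2Threshold, windowKb,
                   if (length(dropped))
                     paste0("; removed ", paste(d$rsid[dropped], collapse = ", "))
                   else ""))
  new("MRInstruments", data = out, removed = removed, log = log)
}

#' Remove instruments named on an exclusion list
#'
#' Removes listed rsids (typically SNPs associated with confounders in a
#' manual database screen) with their reasons logged; rsids not present in
#' the active set produce a warning, not an error.
#'
#' @param instruments an \linkS4class{MRInstruments} object.
#' @param exclusions named character vector, rsid -> reason (as returned by
#'   \code{\link{readExclusions}}); may be empty.
#' @return An \linkS4class{MRInstruments} with listed SNPs moved to the
#'   removed slot (reason prefixed \code{confounder:}).
#' @export
excludeByList <- function(instruments, exclusions) {
  stopifnot(is(instruments, "MRInstruments"))
  if (!length(exclusions)) return(instruments)
  d <- instruments@data
  hit <- names(exclusions) %in% d$rsid
  if (any(!hit))
    warning("exclusion-list rsid(s) not among active instruments: ",
            paste(names(exclusions)[!hit], collapse = ", "))
  drop <- d$rsid %in% names(exclusions)
  reasons <- if (any(drop)) paste0("confounder: ", exclusions[d$rsid[drop]])
             else character(0)
  removed <- rbind(instruments@removed,
                   data.frame(rsid = d$rsid[drop],
                              reason = reasons,
                              stage = rep("exclude_by_list", sum(drop)),
                              stringsAsFactors = FALSE))
  log <- c(instruments@log,
           sprintf("exclude_by_list: %d -> %d instruments%s",
                   nrow(d), sum(!drop),
                   if (any(drop))
                     paste0("; removed ",
                            paste(sprintf("%s (%s)", d$rsid[drop],
                                          exclusions[d$rsid[drop]]),
                                  collapse = ", "))
                   else ""))
  out <- d[!drop, ]
  rownames(out) <- NULL
  new("MRInstruments", data = out, removed = removed, log = log)
}
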