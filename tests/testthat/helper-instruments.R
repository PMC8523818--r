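# Build a plain instrument data.frame for estimator tests.
makeInstruments <- function(bx, by, sy, sx = rep(0.005, length(bx)),
                            rsid = sprintf("rs%03d", seq_along(bx))) {
  data.frame(rsid = rsid, beta_exposure = bx, se_exposure = sx,
             beta_outcome = by, se_outcome = sy, flags = rep("", length(bx)),
             stringsAsFactors = FALSE)
}

# Wrap an instrument data.frame in the S4 container (adds required columns).
asMRInstruments <- function(d) {
  new("MRInstruments", data = d,
      removed = data.frame(rsid = character(), reason = character(),
                           stage = character(), stringsAsFactors = FALSE),
      log = character())
}

# Minimal SummaryTable data.frame with defaults, for io/harmonize tests.
makeSummaryDf <- function(rsid, a1, a2, beta, se, eaf = 0.3, chrom = "1",
                          pos = seq_along(rsid) * 1e6, pval = NA, n = NA) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, effect_allele = a1,
             other_allele = a2, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, stringsAsFactors = FALSE)
}

# The 18-instrument analysis set used throughout: packaged panel after LD
# pruning and confounder exclusion.
fixtureInstruments <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- loadTelomereOA()
      inst <- harmonize(panel$exposure, panel$outcome)
      ld <- readLdTable(system.file("extdata", "telomere_ld_synthetic.tsv",
                                    package = "mrsummary"))
      inst <- pruneLd(inst, ld)
      excl <- readExclusions(system.file("extdata", "telomere_exclusions.tsv",
                                         package = "mrsummary"))
      cache <<- excludeByList(inst, excl)
    }
    cache
  }
})

# Instrument data.frame straight from paired simulated tables (shared
# alleles, no flips needed), bypassing the allele-matching path for speed
# in replicate loops.
simInstruments <- function(sim) {
  e <- summaryData(sim$exposure)
  o <- summaryData(sim$outcome)
  makeInstruments(e$beta, o$beta, o$se, sx = e$se, rsid = e$rsid)
}
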