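test_that("matching, swapped, strand-complement and mismatched alleles", {
  expo <- SummaryTable(makeSummaryDf(
    c("rs_keep", "rs_swap", "rs_strand", "rs_bad"),
    a1 = c("C", "A", "A", "A"), a2 = c("A", "G", "G", "G"),
    beta = c(0.05, 0.04, 0.03, 0.02), se = 0.006), "exposure")
  outc <- SummaryTable(makeSummaryDf(
    c("rs_keep", "rs_swap", "rs_strand", "rs_bad"),
    a1 = c("C", "G", "T", "A"), a2 = c("A", "A", "C", "C"),
    beta = c(-0.033, 0.02, 0.01, 0.01), se = 0.02), "outcome")
  inst <- harmonize(expo, outc)
  d <- instrumentData(inst)
  expect_equal(d$rsid, c("rs_keep", "rs_swap", "rs_strand"))
  expect_equal(d$beta_outcome[d$rsid == "rs_keep"], -0.033)  # unchanged
  expect_equal(d$beta_outcome[d$rsid == "rs_swap"], -0.02)   # negated once
  expect_equal(d$beta_outcome[d$rsid == "rs_strand"], 0.01)  # other strand
  expect_true(hasFlag(inst, "flipped")[d$rsid == "rs_swap"])
  expect_false(any(hasFlag(inst, "flipped")[d$rsid != "rs_swap"]))
  rem <- removedInstruments(inst)
  expect_equal(rem$rsid, "rs_bad")
  expect_match(rem$reason, "allele mismatch")
})

test_that("palindromic SNPs are retained and flagged, not dropped", {
  expo <- SummaryTable(makeSummaryDf(c("rs_at", "rs_cg"),
                                     a1 = c("A", "C"), a2 = c("T", "G"),
                                     beta = c(0.05, 0.04), se = 0.006))
  outc <- SummaryTable(makeSummaryDf(c("rs_at", "rs_cg"),
                                     a1 = c("A", "C"), a2 = c("T", "G"),
                                     beta = c(0.01, 0.02), se = 0.02))
  inst <- harmonize(expo, outc)
  expect_equal(nInstruments(inst), 2L)
  expect_true(all(hasFlag(inst, "palindromic")))
  expect_false(any(hasFlag(inst, "flipped")))
})

test_that("empty rsid intersection errors", {
  a <- SummaryTable(makeSummaryDf("rs1", "A", "G", 0.1, 0.01))
  b <- SummaryTable(makeSummaryDf("rs2", "A", "G", 0.1, 0.01))
  expect_error(harmonize(a, b), "share no rsid")
})

test_that("harmonization is involution-safe under pre-swapped outcome alleles", {
  sim <- simulateTelomerePanel(seed = 5, theta = 0.1)
  swapped <- summaryData(sim$outcome)
  tmp <- swapped$effect_allele
  swapped$effect_allele <- swapped$other_allele
  swapped$other_allele <- tmp
  swapped$beta <- -swapped$beta
  swapped$eaf <- 1 - swapped$eaf
  outc2 <- SummaryTable(swapped, "pre-swapped outcome")

  i1 <- harmonize(sim$exposure, sim$outcome)
  i2 <- harmonize(sim$exposure, outc2)
  expect_true(all(hasFlag(i2, "flipped")))
  # betas equal in magnitude, opposite sign relative to the swapped source,
  # identical to the unswapped harmonization
  expect_equal(instrumentData(i2)$beta_outcome, instrumentData(i1)$beta_outcome)
  expect_equal(mrIVW(i2)@beta, mrIVW(i1)@beta)
  expect_equal(mrEgger(i2)$slope@beta, mrEgger(i1)$slope@beta)
})

test_that("proxy substitution stands in for missing outcome SNPs above r2 0.8", {
  expo <- SummaryTable(makeSummaryDf(c("rs_t", "rs_o"), "A", "G",
                                     beta = c(0.05, 0.04), se = 0.006))
  # outcome lacks rs_t but has its proxy rs_p
  outc <- SummaryTable(makeSummaryDf(c("rs_p", "rs_o"), c("C", "A"),
                                     c("T", "G"), beta = c(0.02, 0.01),
                                     se = 0.02))
  proxies <- data.frame(target = "rs_t", proxy = "rs_p", r2 = 0.9,
                        proxy_effect_allele = "C", stringsAsFactors = FALSE)
  inst <- harmonize(expo, outc, proxies = proxies)
  d <- instrumentData(inst)
  expect_setequal(d$rsid, c("rs_t", "rs_o"))
  expect_equal(d$beta_outcome[d$rsid == "rs_t"], 0.02)
  expect_true(hasFlag(inst, "proxy")[d$rsid == "rs_t"])
  # below the r2 bar the proxy is not used
  proxies$r2 <- 0.5
  inst2 <- harmonize(expo, outc, proxies = proxies)
  expect_equal(instrumentData(inst2)$rsid, "rs_o")
})

test_that("LD pruning removes rs2853677 from the packaged panel", {
  panel <- loadTelomereOA()
  inst <- harmonize(panel$exposure, panel$outcome)
  ld <- readLdTable(system.file("extdata", "telomere_ld_synthetic.tsv",
                                package = "mrsummary"))
  pruned <- pruneLd(inst, ld, r2Threshold = 0.05, windowKb = 5000)
  expect_equal(nInstruments(pruned), 19L)
  rem <- removedInstruments(pruned)
  expect_equal(rem$rsid[rem$stage == "prune_ld"], "rs2853677")
  expect_true("rs7705526" %in% instrumentData(pruned)$rsid)
})

test_that("pruning ignores pairs on different chromosomes or beyond the window", {
  d <- makeInstruments(c(0.05, 0.04), c(0.01, 0.02), c(0.02, 0.02))
  d$chrom <- c("1", "2"); d$pos <- c(1e6, 1e6)
  d$eaf_exposure <- 0.3; d$pval_exposure <- c(1e-10, 1e-8); d$n_exposure <- NA
  ld <- data.frame(rsid_a = "rs001", rsid_b = "rs002", r2 = 0.99)
  pruned <- pruneLd(asMRInstruments(d), ld)
  expect_equal(nInstruments(pruned), 2L)
  # same chromosome, 10 Mb apart, 5 Mb window: still independent
  d$chrom <- c("1", "1"); d$pos <- c(1e6, 11e6)
  expect_equal(nInstruments(pruneLd(asMRInstruments(d), ld)), 2L)
  # inside the window the r2 rule bites
  d$pos <- c(1e6, 2e6)
  expect_equal(nInstruments(pruneLd(asMRInstruments(d), ld)), 1L)
})

test_that("greedy pruning keeps the feasible set a brute-force search selects", {
  # three mutually linked SNPs: only singletons are feasible; the oracle
  # maximizes the kept count and breaks ties by smallest exposure p
  d <- makeInstruments(c(0.05, 0.06, 0.04), c(0.01, 0.02, 0.01),
                       c(0.02, 0.02, 0.02))
  d$chrom <- "1"; d$pos <- c(1e6, 1.1e6, 1.2e6)
  d$eaf_exposure <- 0.3
  d$pval_exposure <- c(1e-9, 1e-15, 1e-8)
  d$n_exposure <- NA
  ld <- data.frame(rsid_a = c("rs001", "rs001", "rs002"),
                   rsid_b = c("rs002", "rs003", "rs003"),
                   r2 = c(1, 1, 1))
  subsets <- lapply(seq_len(2^3 - 1), function(m) which(bitwAnd(m, 2^(0:2)) > 0))
  feasible <- Filter(function(s) {
    all(apply(expand.grid(s, s), 1, function(pr) {
      if (pr[1] >= pr[2]) return(TRUE)
      r2 <- ld$r2[(ld$rsid_a == d$rsid[pr[1]] & ld$rsid_b == d$rsid[pr[2]]) |
                  (ld$rsid_a == d$rsid[pr[2]] & ld$rsid_b == d$rsid[pr[1]])]
      length(r2) == 0 || r2 <= 0.05
    }))
  }, subsets)
  sizes <- lengths(feasible)
  best <- feasible[sizes == max(sizes)]
  minp <- vapply(best, function(s) min(d$pval_exposure[s]), numeric(1))
  oracle <- d$rsid[best[[which.min(minp)]]]

  pruned <- pruneLd(asMRInstruments(d), ld)
  expect_identical(instrumentData(pruned)$rsid, oracle)
  expect_identical(oracle, "rs002")  # the smallest-p SNP
})

test_that("pruning outcome does not depend on input row order", {
  sim <- simulateTelomerePanel(seed = 9)
  inst <- harmonize(sim$exposure, sim$outcome)
  d <- instrumentData(inst)
  set.seed(2)
  ld <- data.frame(rsid_a = d$rsid[1:6], rsid_b = d$rsid[7:12],
                   r2 = runif(6))
  kept1 <- sort(instrumentData(pruneLd(inst, ld))$rsid)
  for (rep in 1:5) {
    shuf <- asMRInstruments(d[sample(nrow(d)), ])
    expect_equal(sort(instrumentData(pruneLd(shuf, ld))$rsid), kept1)
  }
})

test_that("exclusion list removes named instruments and warns on absentees", {
  inst18 <- fixtureInstruments()
  expect_equal(nInstruments(inst18), 18L)
  rem <- removedInstruments(inst18)
  expect_equal(rem$rsid[rem$stage == "exclude_by_list"], "rs73624724")
  expect_match(rem$reason[rem$rsid == "rs73624724"], "body fat")
  # identity on an empty map
  expect_equal(nInstruments(excludeByList(inst18, character())), 18L)
  # absent rsid warns, count unchanged
  expect_warning(out <- excludeByList(inst18, c(rs2853677 = "already pruned")),
                 "rs2853677")
  expect_equal(nInstruments(out), 18L)
})
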