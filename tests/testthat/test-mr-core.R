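test_that("Wald ratio: unit case, hand division, null outcome effect", {
  unit <- makeInstruments(0.05, 0.05, 0.05)
  est <- waldRatio(unit)
  expect_equal(est@beta, 1)
  expect_equal(est@se, 1)

  snp <- makeInstruments(-0.039, -0.050, 0.021)
  expect_equal(waldRatio(snp)@beta, -0.050 / -0.039)  # ~1.282
  expect_equal(round(waldRatio(snp)@beta, 3), 1.282)

  null <- makeInstruments(0.05, 0, 0.02)
  expect_equal(waldRatio(null)@beta, 0)
  expect_equal(mrOR(waldRatio(null)), 1)

  expect_error(waldRatio(makeInstruments(0, 0.01, 0.02)), "null instrument")
  expect_error(waldRatio(makeInstruments(c(.1, .2), c(.1, .2), c(.1, .1))),
               "one instrument")
})

test_that("IVW equals independently computed weighted sums and exact cases", {
  d <- makeInstruments(c(0.05, -0.08, 0.03), c(0.01, -0.02, 0.005),
                       c(0.02, 0.015, 0.03))
  est <- mrIVW(d)
  w <- 1 / d$se_outcome^2
  oracle <- sum(w * d$beta_exposure * d$beta_outcome) /
    sum(w * d$beta_exposure^2)
  expect_equal(est@beta, oracle)
  # fixed vs multiplicative-random: identical point estimate
  expect_equal(mrIVW(d, "fixed")@beta, est@beta)
  # cross-check against lm through the origin
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = d, weights = w)
  expect_equal(est@beta, unname(coef(fit)))

  # exact proportionality: slope c, Q = 0, both modes give the same SE
  prop <- makeInstruments(c(0.05, -0.08, 0.03), 0.4 * c(0.05, -0.08, 0.03),
                          c(0.02, 0.015, 0.03))
  expect_equal(mrIVW(prop)@beta, 0.4)
  expect_equal(mrCochranQ(prop)@q, 0)
  expect_equal(mrIVW(prop)@se, mrIVW(prop, "fixed")@se)
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  one <- makeInstruments(0.06, 0.02, 0.015)
  expect_message(est <- mrIVW(one), "Wald")
  wald <- waldRatio(one)
  expect_equal(est@beta, wald@beta)
  expect_equal(est@se, wald@se)
})

test_that("IVW and Egger are invariant to jointly negating instruments, and
           scale-equivariant in the exposure", {
  set.seed(21)
  d <- makeInstruments(runif(8, 0.03, 0.1), rnorm(8, 0.02, 0.02),
                       runif(8, 0.01, 0.03))
  flip <- d
  idx <- c(2, 5)
  flip$beta_exposure[idx] <- -flip$beta_exposure[idx]
  flip$beta_outcome[idx] <- -flip$beta_outcome[idx]
  expect_equal(mrIVW(flip)@beta, mrIVW(d)@beta)
  expect_equal(mrEgger(flip)$slope@beta, mrEgger(d)$slope@beta)
  expect_equal(mrEgger(flip)$intercept@beta, mrEgger(d)$intercept@beta)

  for (c_scale in c(0.5, 2, 10)) {
    scaled <- d
    scaled$beta_exposure <- d$beta_exposure * c_scale
    scaled$se_exposure <- d$se_exposure * c_scale
    expect_equal(mrIVW(scaled)@beta, mrIVW(d)@beta / c_scale)
    expect_equal(mrEgger(scaled)$slope@beta, mrEgger(d)$slope@beta / c_scale)
    expect_equal(mrWeightedMedian(scaled, nBoot = 10)@beta,
                 mrWeightedMedian(d, nBoot = 10)@beta / c_scale)
  }
})

test_that("weighted median interpolates the cumulative-weight function", {
  # constant ratios: estimate equals the constant whatever the weights
  const <- makeInstruments(c(0.05, 0.1, 0.02), 0.7 * c(0.05, 0.1, 0.02),
                           c(0.02, 0.01, 0.05))
  expect_equal(mrWeightedMedian(const, nBoot = 10)@beta, 0.7)

  # five instruments with hand-picked weights vs a brute-force evaluation
  # of the piecewise-linear cumulative-weight function
  bx <- c(0.05, 0.05, 0.05, 0.05, 0.05)
  ratios <- c(0.1, 0.3, 0.5, 0.9, 1.5)
  w_target <- c(1, 2, 3, 1, 1)
  sy <- bx[1] / sqrt(w_target)             # gives weights w = (bx/sy)^2
  d <- makeInstruments(bx, ratios * bx, sy)
  est <- mrWeightedMedian(d, nBoot = 10)@beta
  wn <- w_target / sum(w_target)
  s <- cumsum(wn) - wn / 2
  i <- max(which(s < 0.5)); j <- i + 1
  oracle <- ratios[i] + (ratios[j] - ratios[i]) * (0.5 - s[i]) / (s[j] - s[i])
  expect_equal(est, oracle)

  # bootstrap SE is deterministic under a fixed seed
  set.seed(999)  # outer RNG state must not leak in
  e1 <- mrWeightedMedian(d, nBoot = 200, seed = 7)
  e2 <- mrWeightedMedian(d, nBoot = 200, seed = 7)
  expect_identical(e1@se, e2@se)
  e3 <- mrWeightedMedian(d, nBoot = 200, seed = 8)
  expect_false(identical(e1@se, e3@se))

  expect_error(mrWeightedMedian(makeInstruments(c(.1, .2), c(.1, .2),
                                                c(.1, .1))), "3 instruments")
})

test_that("Egger matches the weighted normal equations and recovers
           noiseless intercept/slope exactly", {
  # noiseless data with a planted intercept and slope
  bx <- c(0.04, 0.06, 0.08, 0.11)
  d <- makeInstruments(bx, 0.015 + 0.6 * bx, c(0.02, 0.015, 0.025, 0.01))
  fit <- mrEgger(d)
  expect_equal(fit$slope@beta, 0.6)
  expect_equal(fit$intercept@beta, 0.015)

  # noisy 4-instrument case vs an independent 2x2 linear solve
  set.seed(8)
  d$beta_outcome <- d$beta_outcome + rnorm(4, 0, d$se_outcome)
  fit <- mrEgger(d)
  w <- 1 / d$se_outcome^2
  X <- cbind(1, d$beta_exposure)
  ab <- solve(t(X) %*% (w * X), t(X) %*% (w * d$beta_outcome))
  expect_equal(fit$intercept@beta, ab[1])
  expect_equal(fit$slope@beta, ab[2])
  # and against lm with weights
  lmfit <- lm(beta_outcome ~ beta_exposure, data = d, weights = w)
  expect_equal(fit$slope@beta, unname(coef(lmfit)[2]))

  expect_error(mrEgger(makeInstruments(c(.1, .2), c(.1, .2), c(.1, .1))),
               "3 instruments")
})

test_that("Cochran's Q equals the brute-force sum over ratio terms", {
  d <- makeInstruments(c(0.05, -0.08, 0.03), c(0.012, -0.018, 0.002),
                       c(0.02, 0.015, 0.03))
  het <- mrCochranQ(d)
  ratio <- d$beta_outcome / d$beta_exposure
  w <- (d$beta_exposure / d$se_outcome)^2
  b_ivw <- sum(w * ratio) / sum(w)
  q_oracle <- w[1] * (ratio[1] - b_ivw)^2 + w[2] * (ratio[2] - b_ivw)^2 +
    w[3] * (ratio[3] - b_ivw)^2
  expect_equal(het@q, q_oracle)
  expect_equal(het@df, 2L)
  expect_equal(het@pQ, pchisq(q_oracle, 2, lower.tail = FALSE))

  prop <- makeInstruments(c(0.05, 0.08), 0.3 * c(0.05, 0.08), c(0.02, 0.015))
  het0 <- mrCochranQ(prop)
  expect_equal(het0@q, 0)
  expect_equal(het0@pQ, 1)
})

test_that("leave-one-out rows equal IVW refits on the complementary subsets", {
  d <- makeInstruments(c(0.05, -0.08, 0.03), c(0.012, -0.018, 0.002),
                       c(0.02, 0.015, 0.03))
  loo <- leaveOneOut(d)
  expect_equal(nrow(loo), 3L)
  for (i in 1:3)
    expect_equal(loo$beta[i], mrIVW(d[-i, ])@beta)
  expect_error(leaveOneOut(d[1:2, ]), "3 instruments")
})

test_that("leave-one-out on the panel leaves the null conclusion intact", {
  loo <- leaveOneOut(fixtureInstruments())
  expect_equal(nrow(loo), 18L)
  expect_false(any(loo$crosses_null))
  expect_true(all(loo$ci_low < 1 & loo$ci_high > 1))
})

test_that("E-value closed forms and the null-crossing rule", {
  expect_equal(eValue(1)$e_point, 1)
  expect_equal(eValue(2)$e_point, 2 + sqrt(2))
  # protective ORs are inverted first
  expect_equal(eValue(0.5)$e_point, 2 + sqrt(2))
  # common-outcome square-root transform
  expect_equal(eValue(4, rareOutcome = FALSE)$e_point, 2 + sqrt(2))
  # CI crossing the null gives e_ci = 1
  expect_equal(eValue(1.00, 0.83, 1.21)$e_ci, 1)
  # CI limit closer to the null drives e_ci otherwise
  ev <- eValue(2, 1.5, 2.7)
  expect_equal(ev$e_ci, 1.5 + sqrt(1.5 * 0.5))
  expect_error(eValue(0), "positive")
  expect_error(eValue(-1), "positive")
})
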