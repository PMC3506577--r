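decoyCloud <- function(mass, score, charge = 2L) {
  n <- length(mass)
  data.frame(spectrum_id = sprintf("d%s_%04d", charge, seq_len(n)),
             peptide = strrep("G", 8), charge = as.integer(charge),
             mass = mass, score = score, is_decoy = TRUE, proteins = "",
             stringsAsFactors = FALSE)
}

test_that("per-charge OLS recovers an exact line and the closed form", {
  mass <- seq(800, 2600, length.out = 12)
  exact <- PsmSet(decoyCloud(mass, 0.01 * mass + 5))
  m <- fitDecoyRegression(exact, nMin = 10L)
  l <- regressionLines(m)
  expect_equal(l$slope, 0.01, tolerance = 1e-12)
  expect_equal(l$intercept, 5, tolerance = 1e-10)
  expect_equal(l$r, 1, tolerance = 1e-12)
  expect_equal(l$flag, "fitted")

  # three-point fixture against the analytic two-pass formula
  three <- PsmSet(decoyCloud(c(1000, 2000, 3000), c(15, 25, 38)))
  fit3 <- regressionLines(fitDecoyRegression(three, nMin = 3L))
  expect_equal(fit3$slope, 0.0115, tolerance = 1e-12)
  expect_equal(fit3$intercept, 3.0, tolerance = 1e-10)
  oracle <- twoPassOls(c(1000, 2000, 3000), c(15, 25, 38))
  expect_equal(fit3$slope, unname(oracle["slope"]), tolerance = 1e-12)
})

test_that("sparse charges fall back to the pooled slope, then to zero", {
  set.seed(5)
  cloud2 <- decoyCloud(runif(40, 800, 2600), rnorm(40, 30, 2), charge = 2L)
  cloud5 <- decoyCloud(runif(2, 800, 2600), rnorm(2, 40, 2), charge = 5L)
  m <- fitDecoyRegression(PsmSet(rbind(cloud2, cloud5)), nMin = 10L)
  l <- regressionLines(m)
  expect_equal(l$flag[l$charge == 5], "pooled_fallback")
  expect_equal(l$slope[l$charge == 5], m@pooledSlope)

  # no decoys at all: zero slopes everywhere, with a warning
  targets_only <- PsmSet(psmRow("s1", "AAAK", 2, 1000, 50, FALSE))
  expect_warning(m0 <- fitDecoyRegression(targets_only), "no decoy")
  expect_equal(regressionLines(m0)$slope, 0)
  expect_equal(regressionLines(m0)$flag, "zero_fallback")

  # all masses identical within the only charge: slope undefined -> zero
  flat <- PsmSet(decoyCloud(rep(1500, 12), rnorm(12, 30, 2)))
  mf <- regressionLines(fitDecoyRegression(flat, nMin = 10L))
  expect_equal(mf$flag, "zero_fallback")
  expect_equal(mf$slope, 0)

  expect_error(fitDecoyRegression(flat, nMin = 2L),
               class = "flexifdr_config_error")
})

test_that("the FlexiScore is the intercept of the parallel line", {
  mkModel <- function(slope) {
    new("ChargeRegressionModel",
        lines = data.frame(charge = 2L, slope = slope, intercept = 5,
                           n = 10L, r = NA_real_, flag = "fitted",
                           stringsAsFactors = FALSE),
        pooledSlope = slope, pooledIntercept = 5, nMin = 3L)
  }
  expect_equal(flexiScore(37.5, 1800, 2, mkModel(0)), 37.5)   # identity
  expect_equal(flexiScore(50, 1000, 2, mkModel(0.01)), 40)
  expect_equal(flexiScore(30, 2000, 2, mkModel(-0.005)), 40)  # negative slope
  expect_error(flexiScore(10, 1000, 3, mkModel(0.01)),
               class = "flexifdr_config_error")
})

test_that("every PSM's flexiscore equals score minus slope times mass", {
  gen <- defaultFixture()
  filt <- filterDecoys(gen$result)
  model <- fitDecoyRegression(filt)
  scored <- psmTable(applyFlexiScore(filt, model))
  l <- regressionLines(model)
  slope <- l$slope[match(scored$charge, l$charge)]
  expect_equal(scored$flexiscore, scored$score - slope * scored$mass)
})

test_that("zero slopes make FlexiFDR coincide with classical FDR PSM-for-PSM", {
  gen <- defaultFixture()
  filt <- filterDecoys(gen$result)
  zero <- fitDecoyRegression(filt)
  zero@lines$slope <- 0
  zero@lines$flag <- "zero_fallback"
  scored <- applyFlexiScore(filt, zero)
  flexi <- acceptAtAlpha(scored, 0.01, scoreColumn = "flexiscore")
  simple <- acceptAtAlpha(filt, 0.01, scoreColumn = "score")
  expect_identical(psmTable(flexi)$accepted, psmTable(simple)$accepted)
  expect_setequal(acceptedSpectra(flexi), acceptedSpectra(simple))
})

test_that("fitted slopes recover the injected per-charge mass bias", {
  gen <- defaultFixture()
  d <- psmTable(filterDecoys(gen$result))
  d <- d[d$is_decoy, ]
  injected <- c(`2` = 0.008, `3` = 0.012)
  for (z in c(2L, 3L)) {
    dz <- d[d$charge == z, ]
    expect_gte(nrow(dz), 500L)
    fit <- summary(stats::lm(score ~ mass, dz))$coefficients
    expect_lt(abs(fit["mass", "Estimate"] - injected[as.character(z)]),
              3 * fit["mass", "Std. Error"])
  }
})

test_that("rescoring removes the decoy mass trend (detrending idempotence)", {
  gen <- defaultFixture()
  filt <- filterDecoys(gen$result)
  scored <- psmTable(applyFlexiScore(filt, fitDecoyRegression(filt)))
  d <- scored[scored$is_decoy, ]
  for (z in c(2L, 3L)) {
    dz <- d[d$charge == z, ]
    refit <- summary(stats::lm(flexiscore ~ mass, dz))$coefficients
    expect_lt(abs(refit["mass", "Estimate"]),
              3 * refit["mass", "Std. Error"])
    expect_lt(abs(refit["mass", "Estimate"]), 1e-4)
  }
})

test_that("negating the injected slopes leaves sensitivity unchanged", {
  counts <- vapply(1:6, function(s) {
    pos <- generatePsmData(generatorConfig(nSpectra = 600L), seed = 100 + s)
    neg <- generatePsmData(generatorConfig(nSpectra = 600L,
                                           decoySlope = c(-0.008, -0.012)),
                           seed = 100 + s)
    c(pos = length(acceptedSpectra(runFlexiFdr(pos$result, 0.01)$outcome)),
      neg = length(acceptedSpectra(runFlexiFdr(neg$result, 0.01)$outcome)))
  }, numeric(2))
  rel <- abs(mean(counts["pos", ]) - mean(counts["neg", ])) /
    mean(counts["pos", ])
  expect_lt(rel, 0.05)
})

test_that("the full pipeline reports both the outcome and the model", {
  gen <- defaultFixture()
  fit <- runFlexiFdr(gen$result, alpha = 0.01)
  expect_s4_class(fit$outcome, "FdrOutcome")
  expect_s4_class(fit$model, "ChargeRegressionModel")
  expect_equal(fit$outcome@scoreColumn, "flexiscore")
  expect_equal(fit$outcome@decoysRemoved, 200L)
  # acceptance never admits a decoy, and respects alpha on q-values
  tab <- psmTable(fit$outcome)
  expect_false(any(tab$accepted & tab$is_decoy))
  expect_true(all(tab$q_value[tab$accepted] <= 0.01))
})
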