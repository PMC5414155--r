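# The CV-scaled deviation objective, GA fitting and cross-validation.

simpleDatasets <- function(values, preds = NULL, cv = 0.5) {
  ds <- mutantDataset("d1", NULL,
                      data.frame(quantity = "yield",
                                 target = paste0("t", seq_along(values)),
                                 value = values, cv = cv))
  list(ds)
}

test_that("an exact fit scores zero everywhere", {
  ds <- simpleDatasets(c(1, 2, 3))
  rep0 <- relativeDeviation(list(d1 = c(1, 2, 3)), ds)
  expect_equal(rep0@overall, 0)
  expect_equal(unname(rep0@perDataset), 0)
  expect_true(all(rep0@residuals$scaled == 0))
})

test_that("the hand-evaluated two-measurement case gives exactly 1", {
  # M = 1, N = 2, CV = 0.5 each, measured (1, 2), predicted (1.5, 1):
  # (1/2) * [ (1/0.5)|0.5|/1 + (1/0.5)|-1|/2 ] = (1/2)(1 + 1) = 1
  ds <- simpleDatasets(c(1, 2))
  rep0 <- relativeDeviation(list(d1 = c(1.5, 1)), ds)
  expect_equal(rep0@overall, 1)
})

test_that("doubling every CV halves the reported deviation", {
  ds1 <- simpleDatasets(c(1, 2, 4), cv = 0.5)
  ds2 <- simpleDatasets(c(1, 2, 4), cv = 1)
  pred <- list(d1 = c(1.2, 1.7, 5))
  expect_equal(relativeDeviation(pred, ds1)@overall,
               2 * relativeDeviation(pred, ds2)@overall)
})

test_that("deviation is invariant to dataset and measurement ordering", {
  dsA <- mutantDataset("A", NULL, data.frame(quantity = "yield",
                                             target = c("x", "y"),
                                             value = c(1, 2), cv = 0.5))
  dsB <- mutantDataset("B", NULL, data.frame(quantity = "yield",
                                             target = "z", value = 3,
                                             cv = 0.3))
  predA <- c(1.1, 2.3); predB <- 2.5
  r1 <- relativeDeviation(list(A = predA, B = predB), list(dsA, dsB))
  r2 <- relativeDeviation(list(B = predB, A = predA), list(dsB, dsA))
  expect_equal(r1@overall, r2@overall)
  dsA2 <- mutantDataset("A", NULL, dsA@measurements[2:1, ])
  r3 <- relativeDeviation(list(A = predA[2:1], B = predB), list(dsA2, dsB))
  expect_equal(r1@overall, r3@overall)
})

test_that("zero measured values fall back to CV-scaled absolute residuals", {
  ds <- simpleDatasets(c(0, 2))
  rep0 <- relativeDeviation(list(d1 = c(0.1, 2)), ds)
  expect_true(rep0@residuals$zeroMeasured[1])
  expect_equal(rep0@overall, (0.1 / 0.5) / 2)
})

test_that("the signed variant lets residuals cancel where magnitudes add", {
  ds <- simpleDatasets(c(1, 1))
  overshoot <- list(d1 = c(1.5, 0.5))
  expect_equal(relativeDeviation(overshoot, ds, signed = TRUE)@overall, 0)
  # unsigned: mean of (1/0.5)*0.5/1 over the two measurements = 1
  expect_equal(relativeDeviation(overshoot, ds)@overall, 1)
})

test_that("GA with the truth in the pool recovers it on noise-free data", {
  fit <- noiseFreeFit()
  expect_lt(fit$report@overall, 1e-6)
  tr <- truth2()
  # parameters are identifiable only where flux flows; zero-flux reactions
  # (the ammonium exchange has no consumer in the 2-branch network) leave
  # the objective blind to the choice
  active <- names(tr@referenceFlux)[abs(tr@referenceFlux) > 1e-9]
  expect_equal(fit$params@kf[active], tr@trueParams@kf[active])
})

test_that("GA best fitness is monotone non-increasing (elitism)", {
  expect_true(all(diff(noiseFreeFit()$trace) <= 1e-12))
  expect_true(all(diff(noisyFit()$trace) <= 1e-12))
})

test_that("GA runs are deterministic for a fixed seed", {
  tr <- truth2()
  cfg <- gaConfig(population = 8, generations = 4, seed = 77)
  ds <- noiseFreeDatasets()[1:2]
  f1 <- gaFit(recoveryPool(), tr@mechanisms, ds, cfg)
  f2 <- gaFit(recoveryPool(), tr@mechanisms, ds, cfg)
  expect_identical(f1$indices, f2$indices)
  expect_identical(f1$trace, f2$trace)
})

test_that("fitted yields fall within twice the measurement CV of the truth", {
  fit <- noisyFit()
  lib <- recoveryLibrary()
  tr <- truth2()
  hits <- 0; total <- 0
  for (nm in names(lib$datasets)) {
    pred <- emkin:::.predictDataset(tr@mechanisms, fit$params,
                                    lib$datasets[[nm]])
    truthY <- as.numeric(lib$trueYields[[nm]])
    ok <- abs(pred - truthY) <= 2 * 0.2 * pmax(abs(truthY), 1e-9) |
      abs(pred - truthY) < 1e-6
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.9)
})

test_that("leaving out a duplicated dataset costs no accuracy", {
  tr <- truth2()
  ds <- noiseFreeDatasets()[c("m1", "m2", "m3")]
  ds$m1dup <- ds$m1
  ds$m1dup@name <- "m1dup"
  cfg <- gaConfig(population = 12, generations = 10, stagnation = 6,
                  seed = 21)
  cv <- crossValidate(recoveryPool(), tr@mechanisms, ds, cfg)
  red <- cv$reduction[cv$dataset == "m1dup"]
  expect_lt(abs(red), 0.05)
  # held-out accuracy is never better than the full fit beyond tolerance
  expect_true(all(cv$reduction > -1e-6))
})

test_that("a fold exercising a unique pathway shows the largest reduction", {
  tr <- truth2()
  lib <- recoveryLibrary()
  # m4 knocks out the NADH hydrogenase: the only mutant whose data probe the
  # rerouting of reducing equivalents through the transhydrogenase loop
  ds <- noiseFreeDatasets()[c("m1", "m2", "m4")]
  ds$m1b <- ds$m1; ds$m1b@name <- "m1b"      # m1's information is backed up
  cfg <- gaConfig(population = 12, generations = 10, stagnation = 6,
                  seed = 33)
  cv <- crossValidate(recoveryPool(), tr@mechanisms, ds, cfg)
  expect_equal(cv$dataset[which.max(cv$reduction)], "m4")
})

test_that("an all-divergent generation 0 aborts with an anchoring diagnostic", {
  tr <- truth2()
  ds <- noiseFreeDatasets()[1]
  brokenPool <- recoveryPool()
  for (k in seq_along(brokenPool)) {
    for (rid in names(brokenPool[[k]]@kf))
      brokenPool[[k]]@kf[[rid]] <- brokenPool[[k]]@kf[[rid]] * NA_real_
  }
  expect_error(gaFit(brokenPool, tr@mechanisms, ds,
                     gaConfig(population = 4, generations = 2, seed = 1)),
               "anchoring")
})
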