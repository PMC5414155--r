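# Elementary decomposition, ensemble anchoring, Michaelis-Menten
# derivation, steady states and genotype semantics.

test_that("decomposition produces the ordered-mechanism step counts", {
  net <- metabolicNetwork(
    data.frame(id = c("a", "b", "c", "d", "i")),
    data.frame(id = c("UNI", "BIBI"), lb = -1, ub = 1),
    list(UNI = c(a = -1, b = 1), BIBI = c(a = -1, b = -1, c = 1, d = 1)))
  mech <- decomposeNetwork(net)
  expect_equal(nrow(mech@mechanisms$UNI$steps), 3)   # bind, convert, release
  expect_equal(nrow(mech@mechanisms$BIBI$steps), 5)  # ordered bi-bi
  # one competitive inhibitor adds exactly one dead-end step on free enzyme
  mechR <- decomposeNetwork(net, data.frame(effector = "i", target = "UNI",
                                            type = "competitive"))
  expect_equal(nrow(mechR@mechanisms$UNI$steps), 4)
  reg <- mechR@mechanisms$UNI$steps[4, ]
  expect_equal(reg$type, "regulatory")
  expect_equal(reg$from, "E")
  # uncompetitive inhibition binds the loaded complex instead
  mechU <- decomposeNetwork(net, data.frame(effector = "i", target = "BIBI",
                                            type = "uncompetitive"))
  expect_equal(mechU@mechanisms$BIBI$steps$from[6], "F2")
})

test_that("oversized stoichiometries are refused with a lumping hint", {
  net <- metabolicNetwork(
    data.frame(id = paste0("m", 1:6)),
    data.frame(id = "BIG", lb = 0, ub = 1),
    list(BIG = setNames(c(-1, -1, -1, -1, -1, 5), paste0("m", 1:6))))
  expect_error(decomposeNetwork(net), "lump")
})

test_that("every sampled member reproduces the reference flux at e_tot = 1", {
  tr <- truth2()
  ens <- sampleEnsemble(tr@mechanisms, tr@referenceFlux, 20, seed = 8)
  for (ps in ens) {
    model <- kineticModel(tr@mechanisms, ps)
    sim <- emkin:::.buildSim(model)
    expect_lt(max(abs(emkin:::.simRHS(sim, sim$x0))), 1e-10)
    rates <- emkin:::.simRates(sim, sim$x0)
    flux <- rates$net[sim$firstStep]
    expect_equal(unname(flux), unname(tr@referenceFlux[sim$active]),
                 tolerance = 1e-8)
  }
})

test_that("sampling is bit-identical for a fixed seed and leaves no trace", {
  tr <- truth2()
  seedBefore <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  e1 <- sampleEnsemble(tr@mechanisms, tr@referenceFlux, 3, seed = 123)
  e2 <- sampleEnsemble(tr@mechanisms, tr@referenceFlux, 3, seed = 123)
  expect_identical(lapply(e1, function(p) p@kf), lapply(e2, function(p) p@kf))
  expect_identical(lapply(e1, function(p) p@fractions),
                   lapply(e2, function(p) p@fractions))
  seedAfter <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  expect_identical(seedBefore, seedAfter)
})

test_that("an inconsistent reference flux is rejected", {
  tr <- truth2()
  bad <- tr@referenceFlux; bad["GLYC"] <- bad["GLYC"] + 1
  expect_error(sampleEnsemble(tr@mechanisms, bad, 1, seed = 1), "S v = 0")
})

test_that("derived Km and kcat reproduce the closed-form uni-uni constants", {
  net <- metabolicNetwork(
    data.frame(id = c("s", "p")),
    data.frame(id = "R", lb = -1, ub = 1), list(R = c(s = -1, p = 1)))
  mech <- decomposeNetwork(net)
  # planted elementary constants kf = (10, 5, 8), kr = (2, 1, 0):
  # King-Altman gives kcat = k2 k3 / (k2 + k-2 + k3) = 40/14 and
  # Km = (k-1 k-2 + k-1 k3 + k2 k3) / (k1 (k2 + k-2 + k3)) = 58/140
  ps <- new("ElementaryParameterSet",
            fractions = list(R = c(E = 1/3, F1 = 1/3, G1 = 1/3)),
            reversibilities = list(R = c(0.5, 0.5, 0.5)),
            kf = list(R = c(10, 5, 8)), kr = list(R = c(2, 1, 0)),
            referenceFlux = c(R = 1))
  kk <- deriveKmKcat(ps, "R", mech)
  expect_equal(kk$kcat, 40 / 14, tolerance = 1e-8)
  expect_equal(unname(kk$km["s"]), 58 / 140, tolerance = 1e-6)
  # independent oracle: nonlinear Michaelis-Menten fit to the simulated
  # saturation curve
  S <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 20, 100)
  v <- vapply(S, function(s)
    emkin:::.qssRate(mech@mechanisms$R, c(10, 5, 8), c(2, 1, 0),
                     c(s = s, p = 0)), numeric(1))
  # scaleOffset keeps the convergence test meaningful on this (numerically
  # zero-residual) artificial dataset
  fit <- stats::nls(v ~ vm * S / (km + S), start = list(vm = 2, km = 0.5),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1))
  expect_equal(unname(coef(fit)["vm"]), kk$kcat, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["km"]), unname(kk$km["s"]), tolerance = 1e-6)
  # irreversible release (kr = 0) still leaves Km defined
  expect_true(is.finite(kk$km["s"]))
})

test_that("symmetric elementary constants give symmetric Km and kcat", {
  net <- metabolicNetwork(
    data.frame(id = c("s", "p")),
    data.frame(id = "R", lb = -1, ub = 1), list(R = c(s = -1, p = 1)))
  mech <- decomposeNetwork(net)
  ps <- new("ElementaryParameterSet",
            fractions = list(R = c(E = 1/3, F1 = 1/3, G1 = 1/3)),
            reversibilities = list(R = c(0.5, 0.5, 0.5)),
            kf = list(R = c(2, 3, 4)), kr = list(R = c(4, 3, 2)),
            referenceFlux = c(R = 0))
  kk <- deriveKmKcat(ps, "R", mech)
  expect_equal(kk$kcat, kk$kcatRev, tolerance = 1e-9)
  expect_equal(unname(kk$km["s"]), unname(kk$kmRev["p"]), tolerance = 1e-6)
})

test_that("ensemble members all obey the Michaelis-Menten curve shape", {
  net <- metabolicNetwork(
    data.frame(id = c("s", "p")),
    data.frame(id = c("EX_s", "R", "EX_p"), lb = c(-2, -2, 0), ub = c(0, 2, 5)),
    list(EX_s = c(s = -1), R = c(s = -1, p = 1), EX_p = c(p = -1)))
  mech <- decomposeNetwork(net)
  ens <- sampleEnsemble(mech, c(EX_s = -1, R = 1, EX_p = 1), 500, seed = 4)
  S <- c(0.05, 0.1, 0.3, 0.6, 1, 1.5, 3, 6, 15, 60)
  worst <- 0
  for (ps in ens) {
    kk <- deriveKmKcat(ps, "R", mech)
    v <- vapply(S, function(s)
      emkin:::.qssRate(mech@mechanisms$R, ps@kf$R, ps@kr$R, c(s = s, p = 0)),
      numeric(1))
    mm <- kk$kcat * S / (kk$km[["s"]] + S)
    worst <- max(worst, max(abs(v - mm) / pmax(abs(mm), 1e-12)))
  }
  expect_lt(worst, 1e-6)
})

test_that("steady state at reference levels returns the reference unchanged", {
  tr <- truth2()
  model <- kineticModel(tr@mechanisms, tr@trueParams)
  ss <- steadyState(model)
  expect_true(ss@converged)
  expect_equal(unname(ss@fluxes), unname(tr@referenceFlux[names(ss@fluxes)]),
               tolerance = 1e-8)
  mets <- metaboliteIds(tr@network)
  expect_equal(unname(ss@concentrations[mets]), rep(1, length(mets)),
               tolerance = 1e-8)
})

test_that("knockout zeroes its flux and reroutes a balanced distribution", {
  tr <- truth2()
  model <- kineticModel(tr@mechanisms, tr@trueParams)
  ss <- steadyState(model, enzymeLevels = c(PFL = 0), method = "dynamic")
  expect_true(ss@converged)
  expect_equal(ss@fluxes[["PFL"]], 0)
  resid <- as.numeric(stoichMatrix(tr@network) %*% ss@fluxes)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("a two-step chain matches its independent quasi-steady-state oracle", {
  # uptake (clamped reservoir) -> conversion -> export; at steady state the
  # enzyme forms are stationary, so each reaction follows its exact QSS rate
  # law and the internal pool solves rate1(b) = rate2(b)
  net <- metabolicNetwork(
    data.frame(id = c("a", "b")),
    data.frame(id = c("EX_a", "R1", "EX_b"), lb = c(-5, -5, 0), ub = c(0, 5, 5)),
    list(EX_a = c(a = -1), R1 = c(a = -1, b = 1), EX_b = c(b = -1)))
  mech <- decomposeNetwork(net)
  ps <- sampleEnsemble(mech, c(EX_a = -1, R1 = 1, EX_b = 1), 1, seed = 6)[[1]]
  # clamping a and silencing its transporter leaves the two-step chain
  model <- kineticModel(mech, ps, enzymeLevels = c(EX_a = 0))
  model@clampedPools <- c(a = 1.3)
  ss <- steadyState(model, enzymeLevels = c(R1 = 0.7), method = "dynamic")
  expect_true(ss@converged)
  rate1 <- function(b) 0.7 * emkin:::.qssRate(mech@mechanisms$R1, ps@kf$R1,
                                              ps@kr$R1, c(a = 1.3, b = b))
  rate2 <- function(b) emkin:::.qssRate(mech@mechanisms$EX_b, ps@kf$EX_b,
                                        ps@kr$EX_b, c(b = b))
  bstar <- stats::uniroot(function(b) rate1(b) - rate2(b), c(1e-6, 1e3),
                          tol = 1e-12)$root
  expect_equal(ss@concentrations[["b"]], bstar, tolerance = 1e-6)
  expect_equal(ss@fluxes[["R1"]], rate1(bstar), tolerance = 1e-6)
})

test_that("sampleEnsemble rejects a flux state violating mass balance", {
  net <- metabolicNetwork(
    data.frame(id = c("a", "b")),
    data.frame(id = c("EX_a", "R1", "EX_b"), lb = c(-5, -5, 0), ub = c(0, 5, 5)),
    list(EX_a = c(a = -1), R1 = c(a = -1, b = 1), EX_b = c(b = -1)))
  mech <- decomposeNetwork(net)
  expect_error(sampleEnsemble(mech, c(EX_a = -1, R1 = 1, EX_b = 2), 1,
                              seed = 1),
               "S v = 0")
})

test_that("enzyme totals are conserved along integrated trajectories", {
  tr <- truth2()
  model <- kineticModel(tr@mechanisms, tr@trueParams)
  sim <- emkin:::.buildSim(model, enzymeLevels = c(ALCD = 0.4))
  x <- sim$x0 * stats::setNames(rep(1, length(sim$x0)), names(sim$x0))
  x[sim$dynMets] <- x[sim$dynMets] * seq(0.9, 1.1,
                                         length.out = length(sim$dynMets))
  out <- deSolve::lsoda(y = x, times = c(0, 1, 10, 100),
                        func = function(t, y, p) list(emkin:::.simRHS(sim, y)),
                        rtol = 1e-10, atol = 1e-12)
  for (rid in sim$active) {
    sl <- sim$formSlices[[rid]]
    tot0 <- sum(x[sl])
    for (row in seq_len(nrow(out)))
      expect_lt(abs(sum(out[row, 1 + sl]) - tot0), 1e-10)
  }
})

test_that("flux is monotone non-decreasing in a reaction's own enzyme level", {
  tr <- truth2()
  model <- kineticModel(tr@mechanisms, tr@trueParams)
  levels <- c(0.1, 0.25, 0.5, 1, 2, 4, 10)
  fl <- vapply(levels, function(lv)
    steadyState(model, enzymeLevels = c(ALCD = lv),
                method = "newton")@fluxes[["ALCD"]], numeric(1))
  expect_true(all(diff(fl) > -1e-8))
})

test_that("genotype directives set, bound and free enzyme levels correctly", {
  tr <- truth2()
  model <- kineticModel(tr@mechanisms, tr@trueParams)
  m1 <- applyGenotype(model, data.frame(reaction = "ALCD",
                                        directive = "knockout", level = NA))
  expect_equal(m1@enzymeLevels[["ALCD"]], 0)
  m2 <- applyGenotype(model, data.frame(reaction = "ALCD",
                                        directive = "down", level = 0.5))
  expect_equal(m2@enzymeLevels[["ALCD"]], 0.5)
  m3 <- applyGenotype(model, data.frame(reaction = "ALCD",
                                        directive = "up", level = NA))
  expect_true(is.na(m3@enzymeLevels[["ALCD"]]))
  expect_equal(m3@freeLevels$lo, 1)
  expect_equal(m3@freeLevels$hi, 10)
  expect_error(applyGenotype(model, data.frame(reaction = "ALCD",
                                               directive = "down",
                                               level = 5)),
               "band")
  m4 <- applyGenotype(model, data.frame(reaction = character(0),
                                        directive = character(0),
                                        level = numeric(0)))
  expect_identical(m4@enzymeLevels, model@enzymeLevels)
  expect_error(steadyState(m3), "free enzyme level")
})
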