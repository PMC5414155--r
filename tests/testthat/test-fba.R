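# FBA, FVA, infeasible-cycle detection and the cycle-elimination
# constraint.

test_that("single-pathway FBA reaches the uptake-limited optimum", {
  s <- fba(chainNetwork(), "EX_b")
  expect_equal(s@status, "optimal")
  expect_equal(s@objectiveValue, 1)
  expect_lt(max(abs(as.matrix(stoichMatrix(chainNetwork())) %*% s@fluxes)),
            1e-6)
})

test_that("FBA optimum equals the brute-force vertex oracle on random nets", {
  set.seed(31)
  for (t in 1:20) {
    nm <- 3; nr <- 6
    repeat {
      A <- matrix(sample(-1:1, nm * nr, TRUE), nm, nr)
      if (all(colSums(A != 0) > 0) && qr(A)$rank == nm) break
    }
    lb <- round(runif(nr, -2, 0), 1); ub <- round(runif(nr, 0.5, 3), 1)
    net <- metabolicNetwork(
      data.frame(id = paste0("m", 1:nm)),
      data.frame(id = paste0("r", 1:nr), lb = lb, ub = ub),
      setNames(lapply(1:nr, function(j) setNames(A[, j], paste0("m", 1:nm))[A[, j] != 0]),
               paste0("r", 1:nr)))
    oracle <- bruteLP(c(1, numeric(nr - 1)), A, rep(0, nm), lb, ub, TRUE)
    s <- fba(net, "r1", "max")
    if (is.na(oracle)) expect_false(s@status == "optimal")
    else expect_equal(s@objectiveValue, oracle, tolerance = 1e-7)
  }
})

test_that("FVA collapses to a point for a fully determined network", {
  rng <- fva(chainNetwork(), extraBounds = list(EX_a = c(-1, -1)))
  expect_equal(rng$min, rng$max, tolerance = 1e-9)
  expect_equal(rng$max[rng$id == "EX_b"], 1)
})

test_that("an unconstrained loop hits the big-M truncation in FVA", {
  net <- metabolicNetwork(
    data.frame(id = c("a", "b")),
    data.frame(id = c("R1", "R2"), lb = c(0, 0), ub = c(1e9, 1e9)),
    list(R1 = c(a = -1, b = 1), R2 = c(b = -1, a = 1)))
  rng <- fva(net)
  expect_true(all(rng$max >= 1000 - 1e-6))
  expect_true(all(rng$truncated))
})

test_that("findTICs reports the canonical 2-cycle and the planted 3-cycle", {
  net <- metabolicNetwork(
    data.frame(id = c("a", "b")),
    data.frame(id = c("R1", "R2", "EX_a"), lb = c(0, 0, -5), ub = c(10, 10, 5)),
    list(R1 = c(a = -1, b = 1), R2 = c(b = -1, a = 1), EX_a = c(a = -1)))
  tics <- findTICs(net)
  expect_length(tics, 1)
  expect_setequal(tics[[1]]$reactions, c("R1", "R2"))
  tics2 <- findTICs(truth2()@network)
  expect_length(tics2, 1)
  expect_setequal(tics2[[1]]$reactions, truth2()@plantedCycle)
})

test_that("loop-free random DAG networks yield no cycles", {
  set.seed(17)
  for (t in 1:50) {
    nm <- sample(3:6, 1)
    stoich <- list()
    # chain + random skip edges always pointing forward: acyclic
    for (i in seq_len(nm - 1)) {
      tgt <- if (i + 1 == nm) nm else sample((i + 1):nm, 1)
      stoich[[paste0("r", i)]] <- setNames(c(-1, 1), paste0("m", c(i, tgt)))
    }
    stoich[["in1"]] <- c(m1 = 1)
    stoich[[paste0("out", nm)]] <- setNames(-1, paste0("m", nm))
    net <- metabolicNetwork(
      data.frame(id = paste0("m", 1:nm)),
      data.frame(id = names(stoich), lb = 0, ub = 10),
      stoich)
    expect_length(findTICs(net), 0)
  }
})

test_that("findTICs membership equals nonzero closed-exchange FVA by definition", {
  net <- truth2()@network
  tics <- findTICs(net)
  members <- unlist(lapply(tics, `[[`, "reactions"))
  closed <- setNames(rep(list(c(0, 0)), length(exchangeIds(net))),
                     exchangeIds(net))
  rng <- fva(net, extraBounds = closed)
  byDef <- rng$id[rng$min < -1e-6 | rng$max > 1e-6]
  expect_setequal(members, byDef)
})

test_that("an empty cycle spec leaves FVA ranges untouched", {
  net <- truth2()@network
  cm <- applyCycleConstraint(net, cycleSpec(character(0), list()))
  r1 <- fva(net, targets = c("ALCD", "HYDR1"))
  r2 <- fva(cm, targets = c("ALCD", "HYDR1"))
  expect_equal(r1$min, r2$min, tolerance = 1e-7)
  expect_equal(r1$max, r2$max, tolerance = 1e-7)
})

test_that("the cycle constraint kills closed loops yet allows co-activity", {
  tr <- truth2()
  net <- tr@network
  cm <- applyCycleConstraint(net, tr@cycleSpec)
  closed <- setNames(rep(list(c(0, 0)), length(exchangeIds(net))),
                     exchangeIds(net))
  rng <- fva(cm, targets = c("HYDR1", "HYDR2"), extraBounds = closed)
  expect_equal(rng$min, c(0, 0), tolerance = 1e-6)
  expect_equal(rng$max, c(0, 0), tolerance = 1e-6)
  # with exchanges open both alternate-cofactor hydrogenases can run at once
  s <- fba(cm, "EXCH_h2(e)", "max",
           extraBounds = list(HYDR1 = c(0.2, 1000), HYDR2 = c(0.2, 1000)))
  expect_equal(s@status, "optimal")
  expect_gte(s@fluxes[["HYDR1"]], 0.2)
  expect_gte(s@fluxes[["HYDR2"]], 0.2)
})

test_that("LP with direction hints equals the enumerated MILP optimum", {
  set.seed(53)
  for (t in 1:10) {
    # 8-reaction instance: planted 2-loop through marker metabolite plus a
    # random acyclic remainder
    stoich <- list(L1 = c(h = 1, x1 = -1), L2 = c(h = -1, x1 = 1),
                   EXh = c(h = -1),
                   S1 = c(x1 = 1), S2 = c(x1 = -1, x2 = 1),
                   S3 = c(x2 = -1, x3 = 1), S4 = c(x3 = -1),
                   EX1 = c(x1 = -1))
    lb <- c(-4, -4, 0, 0, 0, 0, 0, round(runif(1, -3, 0), 1))
    ub <- round(runif(8, 1, 5), 1)
    net <- metabolicNetwork(
      data.frame(id = c("h", "x1", "x2", "x3")),
      data.frame(id = names(stoich), lb = lb, ub = ub), stoich)
    spec <- cycleSpec("h", list(h = c("L1", "L2")))
    milp <- fba(applyCycleConstraint(net, spec), "S4", "max")
    hinted <- fba(applyCycleConstraint(net, spec,
                                       directionHints = c(EXh = 1)),
                  "S4", "max")
    expect_equal(hinted@objectiveValue, milp@objectiveValue, tolerance = 1e-7)
  }
})

test_that("hints contradicting bounds are rejected", {
  tr <- truth2()
  expect_error(applyCycleConstraint(tr@network, tr@cycleSpec,
                                    directionHints = c("EXCH_h2(e)" = -1)),
               "contradicts")
})

test_that("marker suggestion picks the metabolite unique to the cycle", {
  tr <- truth2()
  sg <- suggestCycleMarkers(tr@network)
  expect_true("h2(c)" %in% names(sg))
  expect_setequal(sg[["h2(c)"]],
                  intersect(tr@plantedCycle, c("HYDR1", "HYDR2")))
})

test_that("yield ranges: stoichiometric forcing and measurement boxes", {
  # 1 substrate -> 2 product chain forces yield exactly 2
  net <- metabolicNetwork(
    data.frame(id = c("s", "p")),
    data.frame(id = c("EX_s", "CONV", "EX_p"), lb = c(-5, 0, 0), ub = c(0, 10, 20)),
    list(EX_s = c(s = -1), CONV = c(s = -1, p = 2), EX_p = c(p = -1)))
  yr <- yieldRange(net, "EX_p", "EX_s")
  expect_equal(yr@minYield, 2, tolerance = 1e-9)
  expect_equal(yr@maxYield, 2, tolerance = 1e-9)

  # random feasible measurement boxes always contain the FBA optimum yield
  tr <- truth2()
  net2 <- tr@network
  set.seed(11)
  for (t in 1:20) {
    free <- fva(net2, targets = c("EXCH_etoh(c)", "EXCH_ac(c)"),
                extraBounds = list("EXCH_cellb(e)" = c(-1, -1)))
    box <- list()
    lo <- runif(1, 0, free$min[2] + 0.6 * (free$max[2] - free$min[2]))
    hi <- runif(1, lo, free$max[2])
    box[["EXCH_ac(c)"]] <- c(lo, hi)
    yr2 <- yieldRange(net2, "EXCH_etoh(c)", "EXCH_cellb(e)",
                      measurementBounds = box)
    opt <- fba(net2, "EXCH_etoh(c)", "max",
               extraBounds = c(list("EXCH_cellb(e)" = c(-1, -1)), box))
    expect_lte(yr2@minYield, opt@objectiveValue + 1e-7)
    expect_gte(yr2@maxYield, opt@objectiveValue - 1e-7)
  }
})

test_that("infeasible measurement sets raise a mass-imbalance diagnostic", {
  net <- truth2()@network
  expect_error(
    yieldRange(net, "EXCH_etoh(c)", "EXCH_cellb(e)",
               measurementBounds = list("EXCH_ac(c)" = c(50, 60))),
    "mass-imbalanced")
})

test_that("FVA bounds are monotone under bound relaxation", {
  net <- truth2()@network
  tight <- fva(net, targets = "EXCH_etoh(c)",
               extraBounds = list("EXCH_cellb(e)" = c(-1, 0),
                                  "ALCD" = c(0, 1)))
  relaxed <- fva(net, targets = "EXCH_etoh(c)",
                 extraBounds = list("EXCH_cellb(e)" = c(-2, 0),
                                    "ALCD" = c(0, 5)))
  expect_lte(relaxed$min, tight$min + 1e-9)
  expect_gte(relaxed$max, tight$max - 1e-9)
})
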