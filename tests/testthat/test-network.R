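# Network construction, balance checking and core extraction.

test_that("construction validates ids, bounds and exchange flags", {
  net <- chainNetwork()
  expect_equal(nrow(net@reactions), 3)
  expect_equal(exchangeIds(net), c("EX_a", "EX_b"))
  expect_error(metabolicNetwork(data.frame(id = c("a", "a")),
                                data.frame(id = "R1"),
                                list(R1 = c(a = 1))),
               "duplicated")
  expect_error(metabolicNetwork(data.frame(id = "a"),
                                data.frame(id = "R1"),
                                list(R1 = c(z = 1))),
               "unknown metabolite")
  expect_error(metabolicNetwork(data.frame(id = "a"),
                                data.frame(id = "R1", lb = 2, ub = 1),
                                list(R1 = c(a = 1))),
               "lb > ub")
})

test_that("reversibility is defined by the bounds", {
  net <- metabolicNetwork(data.frame(id = "a"),
                          data.frame(id = c("R1", "R2", "R3"),
                                     lb = c(-1, 0, -1), ub = c(1, 1, 0)),
                          list(R1 = c(a = 1), R2 = c(a = 1), R3 = c(a = 1)))
  expect_equal(unname(isReversible(net)), c(TRUE, FALSE, FALSE))
})

test_that("balanced reactions give an empty report, imbalances are itemized", {
  net <- metabolicNetwork(
    data.frame(id = c("h", "o2", "h2o", "a", "b"),
               formula = c("H", "O2", "H2O", "C6H12O6", "C6H11O6"),
               charge = c(0L, 0L, 0L, 0L, -1L)),
    data.frame(id = c("WATER", "AB", "EX_a"), lb = 0, ub = 10),
    list(WATER = c(h = -2, o2 = -0.5, h2o = 1),
         AB = c(a = -1, b = 1),
         EX_a = c(a = -1)))
  r <- checkBalance(net, "WATER")
  expect_true(r$balanced)
  expect_length(r$elements, 0)
  expect_equal(r$charge, 0)
  # a -> b loses one H and one unit of charge (hand-summed)
  r2 <- checkBalance(net, "AB")
  expect_false(isTRUE(r2$balanced))
  expect_equal(r2$elements[["H"]], -1)
  expect_equal(r2$charge, -1)
  # exchange reactions are exempt and reported skipped
  r3 <- checkBalance(net, "EX_a")
  expect_true(r3$skipped)
})

test_that("perturbing any coefficient of a balanced reaction breaks balance", {
  set.seed(7)
  for (i in 1:100) {
    coefA <- sample(1:3, 1)
    net <- metabolicNetwork(
      data.frame(id = c("x", "y"), formula = c("C2H4", paste0("C", 2 * coefA, "H", 4 * coefA)),
                 charge = 0L),
      data.frame(id = "R", lb = 0, ub = 1),
      list(R = c(x = -coefA, y = 1)))
    expect_true(checkBalance(net, "R")$balanced)
    # perturb one coefficient
    delta <- sample(c(-1, 1), 1) * sample(1:2, 1)
    net2 <- metabolicNetwork(
      data.frame(id = c("x", "y"), formula = c("C2H4", paste0("C", 2 * coefA, "H", 4 * coefA)),
                 charge = 0L),
      data.frame(id = "R", lb = 0, ub = 1),
      list(R = c(x = -coefA - delta, y = 1)))
    expect_false(isTRUE(checkBalance(net2, "R")$balanced))
  }
})

test_that("balance report is linear in the reaction scaling", {
  net <- function(k) metabolicNetwork(
    data.frame(id = c("a", "b"), formula = c("C6H12O6", "C6H11O6"),
               charge = c(0L, -1L)),
    data.frame(id = "R", lb = 0, ub = 1),
    list(R = c(a = -k, b = k)))
  r1 <- checkBalance(net(1), "R"); r3 <- checkBalance(net(3), "R")
  expect_equal(r3$elements, 3 * r1$elements)
  expect_equal(r3$charge, 3 * r1$charge)
})

test_that("missing formulas mark a reaction unverifiable with a warning entry", {
  net <- metabolicNetwork(
    data.frame(id = c("a", "b"), formula = c("C6H12O6", NA), charge = 0L),
    data.frame(id = "R", lb = 0, ub = 1), list(R = c(a = -1, b = 1)))
  r <- checkBalance(net, "R")
  expect_true(is.na(r$balanced))
  expect_equal(r$unverifiable, "b")
})

test_that("extractCore with the full keep list is the identity", {
  net <- truth2()@network
  core <- extractCore(net, reactionIds(net))
  expect_setequal(reactionIds(core), reactionIds(net))
  expect_equal(as.matrix(core@S[metaboliteIds(net), reactionIds(net)]),
               as.matrix(net@S))
})

test_that("lumping parallel cofactor variants preserves the FBA optimum", {
  # two parallel conversions a -> b with different cofactor pairs; lump into
  # one and check the optimum against the parent (LP oracle on both)
  net <- metabolicNetwork(
    data.frame(id = c("a", "b", "c1", "c2", "d1", "d2")),
    data.frame(id = c("EX_a", "P1", "P2", "REG1", "REG2", "EX_b"),
               lb = c(-1, 0, 0, -10, -10, 0), ub = c(0, 10, 10, 10, 10, 10)),
    list(EX_a = c(a = -1),
         P1 = c(a = -1, c1 = -1, b = 1, d1 = 1),
         P2 = c(a = -1, c2 = -1, b = 1, d2 = 1),
         REG1 = c(d1 = -1, c1 = 1), REG2 = c(d2 = -1, c2 = 1),
         EX_b = c(b = -1)))
  parent <- fba(net, "EX_b")
  core <- extractCore(net, c("EX_a", "EX_b", "REG1"),
                      lumpingRules = list(list(
                        remove = c("P1", "P2"),
                        replacement = list(id = "P", lb = 0, ub = 20,
                                           stoichiometry = c(a = -1, c1 = -1,
                                                             b = 1, d1 = 1)))))
  expect_equal(fba(core, "EX_b")@objectiveValue, parent@objectiveValue,
               tolerance = 1e-9)
  expect_false("P2" %in% reactionIds(core))
})

test_that("cut-boundary metabolites receive exchanges, orphans are dropped", {
  net <- truth2()@network
  keep <- setdiff(reactionIds(net), c("THD", "HYDR2", "EXCH_h2(e)", "HYDR1"))
  core <- extractCore(net, keep)
  # nadh/nad were also touched by the dropped reactions -> exchanges appear
  expect_true(any(grepl("^EXCH_nad", reactionIds(core))))
  expect_false("h2(c)" %in% metaboliteIds(core))   # orphaned by the cut
  s <- fba(core, "EXCH_etoh(c)")
  expect_equal(s@status, "optimal")
})
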