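# Shared fixtures, memoized so expensive objects (GA fits, ground truths)
# are built once per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# tiny linear chain network: uptake -> conversion -> export
chainNetwork <- function() {
  metabolicNetwork(
    data.frame(id = c("a", "b")),
    data.frame(id = c("EX_a", "AB", "EX_b"), lb = c(-1, 0, 0),
               ub = c(0, 10, 10)),
    list(EX_a = c(a = -1), AB = c(a = -1, b = 1), EX_b = c(b = -1)))
}

# hydrogenase-pair network with a planted 3-reaction infeasible cycle
hydLoopNetwork <- function() {
  metabolicNetwork(
    data.frame(id = c("nadh", "nad", "nadph", "nadp", "h2")),
    data.frame(id = c("HYD1", "HYD2", "THD", "EX_h2", "SRC1", "SRC2"),
               lb = c(-10, -10, -10, 0, -10, -10), ub = rep(10, 6)),
    list(HYD1 = c(nadh = -1, nad = 1, h2 = 1),
         HYD2 = c(nadph = -1, nadp = 1, h2 = 1),
         THD = c(nadh = -1, nadp = -1, nad = 1, nadph = 1),
         EX_h2 = c(h2 = -1),
         SRC1 = c(nad = -1, nadh = 1), SRC2 = c(nadp = -1, nadph = 1)))
}

# brute-force LP oracle: enumerate basic solutions over nonbasic bound
# combinations; returns the optimum or NA if nothing feasible was found
bruteLP <- function(cc, A, b, lb, ub, maximize = TRUE) {
  n <- length(cc); m <- nrow(A)
  best <- NA_real_
  combs <- utils::combn(n, m)
  for (ci in seq_len(ncol(combs))) {
    Bidx <- combs[, ci]; Nidx <- setdiff(seq_len(n), Bidx)
    B <- A[, Bidx, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nn <- length(Nidx)
    for (mask in 0:(2^nn - 1)) {
      xN <- ifelse(bitwAnd(mask, 2^(seq_len(nn) - 1)) > 0, ub[Nidx], lb[Nidx])
      xB <- solve(B, b - A[, Nidx, drop = FALSE] %*% xN)
      x <- numeric(n); x[Nidx] <- xN; x[Bidx] <- xB
      if (all(x >= lb - 1e-7) && all(x <= ub + 1e-7)) {
        v <- sum(cc * x)
        if (is.na(best) || (maximize && v > best) || (!maximize && v < best))
          best <- v
      }
    }
  }
  best
}

truth2 <- function() memo("truth2", generateToyNetwork(nBranches = 2, seed = 3))
truth7 <- function() memo("truth7", generateToyNetwork(nBranches = 7, seed = 7))

recoveryGenotypes <- function() {
  list(
    m1 = data.frame(reaction = "PFL", directive = "knockout", level = NA),
    m2 = data.frame(reaction = "ALCD", directive = "down", level = 0.5),
    m3 = data.frame(reaction = "THD", directive = "down", level = 0.5),
    m4 = data.frame(reaction = "HYDR1", directive = "knockout", level = NA),
    m5 = data.frame(reaction = "HYDR2", directive = "up", level = 2))
}

recoveryLibrary <- function() memo("recoveryLibrary", {
  generateMutantLibrary(truth2(), genotypes = recoveryGenotypes(), cv = 0.2,
                        seed = 5, concentrationDataset = FALSE,
                        kineticDataset = FALSE)
})

noiseFreeDatasets <- function() memo("noiseFreeDatasets", {
  lib <- recoveryLibrary()
  ds <- lapply(names(lib$datasets), function(nm) {
    d <- lib$datasets[[nm]]
    d@measurements$value <- as.numeric(lib$trueYields[[nm]])
    d
  })
  stats::setNames(ds, names(lib$datasets))
})

recoveryPool <- function() memo("recoveryPool", {
  tr <- truth2()
  pool <- sampleEnsemble(tr@mechanisms, tr@referenceFlux, 4, seed = 42)
  pool[[3]] <- tr@trueParams
  pool
})

# the two GA runs at the heart of the ground-truth recovery surface
noiseFreeFit <- function() memo("noiseFreeFit", {
  tr <- truth2()
  gaFit(recoveryPool(), tr@mechanisms, noiseFreeDatasets(),
        gaConfig(population = 24, generations = 100, stagnation = 40,
                 seed = 9))
})

noisyFit <- function() memo("noisyFit", {
  tr <- truth2()
  gaFit(recoveryPool(), tr@mechanisms, recoveryLibrary()$datasets,
        gaConfig(population = 24, generations = 60, stagnation = 25,
                 seed = 9))
})

# planted-saturation kinetic micro-model: constant producer feeding a
# capacity-limited consumer (vmax = 1/(0.95 * 0.8) ~ 1.316 reference units)
saturationModel <- function() memo("saturationModel", {
  net <- metabolicNetwork(
    data.frame(id = c("s", "a")),
    data.frame(id = c("EX_s", "P1", "CONS"), lb = c(-10, 0, 0),
               ub = c(0, 10, 10)),
    list(EX_s = c(s = -1), P1 = c(s = -1, a = 1), CONS = c(a = -1)))
  mech <- decomposeNetwork(net)
  vref <- c(EX_s = -1, P1 = 1, CONS = 1)
  ps <- sampleEnsemble(mech, vref, 1, seed = 2)[[1]]
  plant <- function(ps, rid, fracs, Rs, v) {
    m <- mech@mechanisms[[rid]]
    ps@fractions[[rid]] <- fracs
    ps@reversibilities[[rid]] <- Rs
    kf <- kr <- numeric(nrow(m$steps))
    for (s in seq_len(nrow(m$steps))) {
      st <- m$steps[s, ]
      vf <- v / (1 - Rs[s]); vr <- v * Rs[s] / (1 - Rs[s])
      kf[s] <- vf / fracs[[st$from]]; kr[s] <- vr / fracs[[st$to]]
    }
    ps@kf[[rid]] <- kf; ps@kr[[rid]] <- kr
    ps
  }
  ps <- plant(ps, "P1", c(E = 0.45, F1 = 0.45, G1 = 0.1), rep(1e-8, 3), 1)
  ps <- plant(ps, "CONS", c(E = 0.2, F1 = 0.8), c(0.5, 0.05), 1)
  model <- kineticModel(mech, ps, enzymeLevels = c(EX_s = 0))
  model@clampedPools <- c(s = 1)
  model
})
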