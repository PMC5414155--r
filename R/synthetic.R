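# Synthetic ground truth: branched fermentation networks with known
# kinetics, plus noisy mutant libraries with the statistical structure of
# multi-mutant fermentation training data.
#
# The generated topology emulates anaerobic hexose fermentation: substrate
# uptake feeding a lumped glycolysis that produces pyruvate and NADH, a set
# of competing terminal branches (ethanol-, acetate/formate-, lactate- and
# amino-acid-analog sinks) coupled through two redox cofactor pairs
# (NAD(H), NADP(H)), a transhydrogenase bridging them, and two hydrogenases
# with alternate cofactors that deliberately close a thermodynamically
# infeasible cycle with the transhydrogenase (marker metabolite: hydrogen).
# All metabolite formulas are synthetic (pseudo-elements R and Q label the
# cofactor backbones) and every internal reaction is elementally balanced
# by construction.

.toyBranchCatalog <- function() {
  list(
    list(id = "ALCD", stoich = c("pyr(c)" = -1, "nadh(c)" = -1,
                                 "etoh(c)" = 1, "co2(c)" = 1, "nad(c)" = 1),
         pyrUse = 1, products = "etoh(c)"),
    list(id = "PFL", stoich = c("pyr(c)" = -2, "nadp(c)" = -1, "ac(c)" = 1,
                                "fmt(c)" = 1, "co2(c)" = 1, "nadph(c)" = 1),
         pyrUse = 2, products = c("ac(c)", "fmt(c)")),
    list(id = "LDH", stoich = c("pyr(c)" = -1, "nadh(c)" = -1,
                                "lac(c)" = 1, "nad(c)" = 1),
         pyrUse = 1, products = "lac(c)"),
    list(id = "GLUDy", stoich = c("pyr(c)" = -1, "nh4(e)" = -1,
                                  "nadph(c)" = -1, "glu(c)" = 1,
                                  "ala(c)" = 1, "nadp(c)" = 1),
         pyrUse = 1, products = c("glu(c)", "ala(c)")),
    list(id = "VALS", stoich = c("pyr(c)" = -1, "nh4(e)" = -1,
                                 "nadph(c)" = -1, "val(c)" = 1,
                                 "abu(c)" = 1, "nadp(c)" = 1),
         pyrUse = 1, products = c("val(c)", "abu(c)")),
    list(id = "LEUS", stoich = c("pyr(c)" = -1, "nh4(e)" = -1,
                                 "nadph(c)" = -1, "leu(c)" = 1,
                                 "ival(c)" = 1, "gly(c)" = 1, "nadp(c)" = 1),
         pyrUse = 1, products = c("leu(c)", "ival(c)", "gly(c)")),
    list(id = "SERS", stoich = c("pyr(c)" = -1, "nh4(e)" = -1,
                                 "nadph(c)" = -1, "ser(c)" = 1,
                                 "cys(c)" = 1, "thr(c)" = 1, "nadp(c)" = 1),
         pyrUse = 1, products = c("ser(c)", "cys(c)", "thr(c)")))
}

.toyFormulas <- c(
  "cellb(e)" = "C6H12O6", "pyr(c)" = "C3H4O3", "nh4(e)" = "NH3",
  "co2(c)" = "CO2", "h2(c)" = "H2",
  "nad(c)" = "R", "nadh(c)" = "RH2", "nadp(c)" = "Q", "nadph(c)" = "QH2",
  "etoh(c)" = "C2H6O", "ac(c)" = "C2H2O", "fmt(c)" = "C3H4O3",
  "lac(c)" = "C3H6O3",
  "glu(c)" = "C2H7O2N", "ala(c)" = "CH2O",
  "val(c)" = "C2H7O2N", "abu(c)" = "CH2O",
  "leu(c)" = "CH5ON", "ival(c)" = "CH2O", "gly(c)" = "CH2O",
  "ser(c)" = "CH5ON", "cys(c)" = "CH2O", "thr(c)" = "CH2O")

#' Generate a ground-truth fermentation network with known kinetics
#'
#' Builds the branched topology described above with \code{nBranches}
#' terminal branches (2 to 7, drawn in a fixed order: ethanol,
#' acetate+formate, lactate, then amino-acid families), assigns a reference
#' flux distribution with seeded branch weights, plants a hydrogenase/
#' transhydrogenase infeasible cycle, samples the true elementary kinetics
#' anchored to the reference state, and verifies that the reference state
#' is dynamically stable.
#'
#' @param nBranches number of terminal product branches (2..7; 7 gives 30
#'   reactions and 19 measured exchange metabolites, the shape of a
#'   19-mutant fermentation panel).
#' @param seed integer seed; fully determines topology weights, kinetics
#'   and nothing else (no global state is consumed).
#' @return a [GroundTruth-class].
#' @export
generateToyNetwork <- function(nBranches = 7, seed = 1) {
  if (nBranches < 2 || nBranches > 7)
    stop("nBranches must be in 2..7")
  catalog <- .toyBranchCatalog()[seq_len(nBranches)]
  branchIds <- vapply(catalog, `[[`, "", "id")
  products <- unlist(lapply(catalog, `[[`, "products"))

  stoich <- list(
    "GLYC" = c("cellb(e)" = -1, "nad(c)" = -2, "pyr(c)" = 2, "nadh(c)" = 2),
    "HYDR1" = c("nadh(c)" = -1, "nad(c)" = 1, "h2(c)" = 1),
    "HYDR2" = c("nadph(c)" = -1, "nadp(c)" = 1, "h2(c)" = 1),
    "THD" = c("nadh(c)" = -1, "nadp(c)" = -1, "nad(c)" = 1, "nadph(c)" = 1))
  for (b in catalog) stoich[[b$id]] <- b$stoich
  stoich[["EXCH_cellb(e)"]] <- c("cellb(e)" = -1)
  stoich[["EXCH_nh4(e)"]] <- c("nh4(e)" = -1)
  stoich[["EXCH_co2(e)"]] <- c("co2(c)" = -1)
  stoich[["EXCH_h2(e)"]] <- c("h2(c)" = -1)
  stoich[["EXCH_pyr(e)"]] <- c("pyr(c)" = -1)
  for (p in products) stoich[[paste0("EXCH_", p)]] <- stats::setNames(-1, p)

  rids <- names(stoich)
  rxn <- data.frame(id = rids,
                    lb = ifelse(rids %in% c("HYDR1", "HYDR2", "THD"), -.LP_BIG,
                         ifelse(rids %in% c("EXCH_cellb(e)", "EXCH_nh4(e)"),
                                -10, 0)),
                    ub = ifelse(rids %in% c("EXCH_cellb(e)", "EXCH_nh4(e)"),
                                0, .LP_BIG))
  mets <- unique(unlist(lapply(stoich, names)))
  met <- data.frame(id = mets, formula = .toyFormulas[mets],
                    charge = 0L)
  net <- metabolicNetwork(met, rxn, stoich)

  .withSeed(seed, {
    w <- stats::runif(nBranches + 1, 0.5, 1.5)      # branch + pyruvate export
    pyrUse <- c(vapply(catalog, `[[`, numeric(1), "pyrUse"), 1)
    share <- 2 * w / sum(w)                         # 2 pyruvate per substrate
    fluxB <- share / pyrUse                         # branch reaction fluxes
    names(fluxB) <- c(branchIds, "EXCH_pyr(e)")
    nadhUse <- sum(fluxB[intersect(c("ALCD", "LDH"), branchIds)])
    Erh <- 2 - nadhUse                              # spare NADH at reference
    h1 <- 0.6 * Erh; tTHD <- 0.4 * Erh
    aaIds <- intersect(c("GLUDy", "VALS", "LEUS", "SERS"), branchIds)
    qUse <- sum(fluxB[aaIds])
    qProd <- if ("PFL" %in% branchIds) fluxB[["PFL"]] else 0
    h2f <- qProd + tTHD - qUse                      # NADPH hydrogenase flux
    vref <- stats::setNames(numeric(length(rids)), rids)
    vref["GLYC"] <- 1
    vref["HYDR1"] <- h1; vref["HYDR2"] <- h2f; vref["THD"] <- tTHD
    vref[branchIds] <- fluxB[branchIds]
    vref["EXCH_pyr(e)"] <- fluxB[["EXCH_pyr(e)"]]
    vref["EXCH_cellb(e)"] <- -1
    vref["EXCH_nh4(e)"] <- -qUse
    vref["EXCH_co2(e)"] <- sum(fluxB[intersect(c("ALCD", "PFL"), branchIds)])
    vref["EXCH_h2(e)"] <- h1 + h2f
    for (b in catalog)
      for (p in b$products) vref[paste0("EXCH_", p)] <- fluxB[[b$id]]
    resid <- max(abs(as.numeric(net@S %*% vref)))
    if (resid > 1e-9)
      stop("internal error: generated reference flux violates S v = 0")

    regs <- data.frame(effector = c("nadh(c)", "nadph(c)", "glu(c)"),
                       target = c("ALCD", "THD", "GLUDy"),
                       type = c("uncompetitive", "product-inhibition",
                                "product-inhibition"))
    regs <- regs[regs$target %in% branchIds | regs$target == "THD", ,
                 drop = FALSE]
    mech <- decomposeNetwork(net, regs)

    truth <- NULL
    for (attempt in 1:10) {
      cand <- sampleEnsemble(mech, vref, 1,
                             seed = stats::runif(1, 1, 2^30))[[1]]
      model <- kineticModel(mech, cand)
      sim <- .buildSim(model)
      if (max(abs(.simRHS(sim, sim$x0))) > 1e-10) next
      J <- .simJac(sim, sim$x0)
      ev <- Re(eigen(J, only.values = TRUE)$values)
      if (max(ev) < 1e-8) { truth <- cand; break }  # stable up to conserved modes
    }
    if (is.null(truth))
      stop("could not sample a dynamically stable ground truth; try ",
           "another seed")

    measured <- c("EXCH_cellb(e)", "EXCH_nh4(e)", "EXCH_co2(e)",
                  "EXCH_h2(e)", "EXCH_pyr(e)", paste0("EXCH_", products))
    spec <- cycleSpec("h2(c)", list("h2(c)" = c("HYDR1", "HYDR2")))
    new("GroundTruth", network = net, mechanisms = mech, trueParams = truth,
        referenceFlux = vref, cycleSpec = spec,
        plantedCycle = c("HYDR1", "HYDR2", "THD"),
        measuredExchanges = measured,
        substrateExchange = "EXCH_cellb(e)")
  })
}

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@network@reactions), "reactions,",
      length(object@measuredExchanges), "measured exchanges, planted cycle:",
      paste(object@plantedCycle, collapse = "+"), "\n")
})

#' The default 19-genotype mutant panel
#'
#' Single and multiple knockouts plus up/downregulations concentrated
#' around the pyruvate node, including two unique-phenotype genotypes
#' (knockouts of the transhydrogenase and of the NADH hydrogenase) whose
#' information no other mutant replicates.
#'
#' @param truth a [GroundTruth-class] built with the default 7 branches.
#' @return named list of genotype data.frames.
#' @export
defaultGenotypes <- function(truth) {
  g <- function(...) {
    rows <- list(...)
    data.frame(reaction = vapply(rows, `[[`, "", 1),
               directive = vapply(rows, `[[`, "", 2),
               level = vapply(rows, function(r)
                 if (length(r) > 2) as.numeric(r[[3]]) else NA_real_, 0))
  }
  need <- c("LDH", "PFL", "ALCD", "GLUDy", "VALS", "LEUS", "SERS",
            "HYDR1", "HYDR2", "THD")
  missing <- setdiff(need, reactionIds(truth@network))
  if (length(missing))
    stop("default genotype panel needs the 7-branch network (missing: ",
         paste(missing, collapse = ", "), ")")
  list(
    mut01 = g(list("LDH", "knockout")),
    mut02 = g(list("PFL", "knockout")),
    mut03 = g(list("LDH", "knockout"), list("PFL", "knockout")),
    mut04 = g(list("VALS", "knockout")),
    mut05 = g(list("SERS", "knockout")),
    mut06 = g(list("LEUS", "knockout")),
    mut07 = g(list("LDH", "down", 0.5)),
    mut08 = g(list("PFL", "down", 0.5)),
    mut09 = g(list("ALCD", "up", 2)),
    mut10 = g(list("HYDR2", "knockout")),
    mut11 = g(list("THD", "down", 0.5)),
    mut12 = g(list("LDH", "knockout"), list("ALCD", "up", 2)),
    mut13 = g(list("THD", "knockout")),
    mut14 = g(list("HYDR1", "down", 0.5)),
    mut15 = g(list("VALS", "knockout"), list("LEUS", "knockout")),
    mut16 = g(list("EXCH_nh4(e)", "down", 0.5)),
    mut17 = g(list("HYDR1", "knockout")),
    mut18 = g(list("EXCH_pyr(e)", "up", 2)),
    mut19 = g(list("GLUDy", "knockout")))
}

#' Simulate a noisy mutant library from a ground truth
#'
#' Simulates every genotype's true steady state, converts fluxes to yields
#' on the substrate uptake, applies multiplicative lognormal noise with the
#' given coefficient of variation (unbiased in log space), and tags each
#' measurement with that CV. Optionally also emits one
#' intracellular-concentration dataset (an amino-acid-pathway knockout
#' analog) and one noisy Km/kcat dataset.
#'
#' @param truth a [GroundTruth-class].
#' @param genotypes named list of genotype data.frames; default
#'   [defaultGenotypes()]. Up/down entries may carry explicit levels; the
#'   recorded dataset hides levels whose \code{hide} marker is set via
#'   \code{hideLevels}.
#' @param cv measurement coefficient of variation (default 0.5, an
#'   "average 50 percent error in measurement").
#' @param seed integer seed for the noise draws.
#' @param concentrationDataset also emit a concentration-fold dataset for a
#'   knockout mutant (up to 18 metabolites).
#' @param kineticDataset also emit a Km/kcat dataset (up to 10 parameters,
#'   CV \code{kineticCv}).
#' @param kineticCv coefficient of variation of the kinetic-parameter
#'   "measurements".
#' @param hideLevels record up/down levels as unknown (NA) in the emitted
#'   genotypes, leaving them free for fitting, as in panels where enzyme
#'   levels were not quantified.
#' @return list(datasets, trueStates, trueYields); datasets is a list of
#'   [MutantDataset-class].
#' @export
generateMutantLibrary <- function(truth, genotypes = NULL, cv = 0.5,
                                  seed = 1, concentrationDataset = TRUE,
                                  kineticDataset = TRUE, kineticCv = 0.3,
                                  hideLevels = FALSE) {
  if (cv <= 0) stop("cv must be > 0")
  if (is.null(genotypes)) genotypes <- defaultGenotypes(truth)
  mech <- truth@mechanisms
  sdlog <- sqrt(log(1 + cv^2))
  datasets <- list(); trueStates <- list(); trueYields <- list()
  .withSeed(seed, {
    for (nm in names(genotypes)) {
      gt <- genotypes[[nm]]
      model <- kineticModel(mech, truth@trueParams)
      model <- applyGenotype(model, gt)
      if (anyNA(model@enzymeLevels))
        stop("genotype '", nm, "' has free levels; give explicit levels ",
             "when simulating truth")
      ss <- steadyState(model, method = "dynamic",
                        normalizeBy = truth@substrateExchange)
      if (!ss@converged)
        stop("true steady state for genotype '", nm, "' did not converge")
      trueStates[[nm]] <- ss
      y <- ss@yields[truth@measuredExchanges]
      y[abs(y) < 1e-9] <- 0                    # numerically silent exchanges
      trueYields[[nm]] <- y
      noisy <- y * exp(stats::rnorm(length(y), 0, sdlog))
      emitted <- gt
      if (hideLevels && nrow(emitted))
        emitted$level[emitted$directive %in% c("down", "up")] <- NA_real_
      datasets[[nm]] <- mutantDataset(nm, emitted,
        data.frame(quantity = "yield", target = names(y),
                   value = as.numeric(noisy), cv = cv))
    }
    if (concentrationDataset) {
      koCand <- intersect(c("GLUDy", "VALS", "LDH"),
                          reactionIds(truth@network))
      if (length(koCand)) {
        ko <- koCand[1]
        gt <- data.frame(reaction = ko, directive = "knockout",
                         level = NA_real_)
        model <- applyGenotype(kineticModel(mech, truth@trueParams), gt)
        ss <- steadyState(model, method = "dynamic",
                          normalizeBy = truth@substrateExchange)
        if (ss@converged) {
          mets <- grep("\\(c\\)$", metaboliteIds(truth@network), value = TRUE)
          mets <- utils::head(mets, 18)
          cvals <- ss@concentrations[mets]
          noisyc <- cvals * exp(stats::rnorm(length(cvals), 0, sdlog))
          datasets[[paste0("conc_d", tolower(ko))]] <-
            mutantDataset(paste0("conc_d", tolower(ko)), gt,
              data.frame(quantity = "concentration-fold", target = mets,
                         value = as.numeric(noisyc), cv = cv))
          trueStates[[paste0("conc_d", tolower(ko))]] <- ss
        }
      }
    }
    if (kineticDataset) {
      sdk <- sqrt(log(1 + kineticCv^2))
      cand <- intersect(c("GLYC", "LDH", "ALCD", "PFL", "THD"),
                        reactionIds(truth@network))
      rows <- list()
      for (rid in cand) {
        kk <- deriveKmKcat(truth@trueParams, rid, mech)
        if (is.finite(kk$kcat))
          rows[[length(rows) + 1L]] <-
            data.frame(quantity = "kcat", target = rid, value = kk$kcat)
        if (length(kk$km))
          rows[[length(rows) + 1L]] <-
            data.frame(quantity = "km",
                       target = paste(rid, names(kk$km)[1], sep = ":"),
                       value = as.numeric(kk$km[1]))
      }
      tab <- utils::head(do.call(rbind, rows), 10)
      tab$value <- tab$value * exp(stats::rnorm(nrow(tab), 0, sdk))
      tab$cv <- kineticCv
      datasets[["kinetic_params"]] <-
        mutantDataset("kinetic_params",
                      data.frame(reaction = character(0),
                                 directive = character(0),
                                 level = numeric(0)),
                      tab)
    }
  })
  list(datasets = datasets, trueStates = trueStates,
       trueYields = trueYields)
}
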