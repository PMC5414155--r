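# Mass-action kinetic models: assembly, genotype application, and steady
# states.
#
# State variables are the (normalized) metabolite pools plus every enzyme
# form of every active reaction. Rates are bilinear (at most one form and
# one metabolite per side of an elementary step), so the system has an
# analytic Jacobian. Conserved totals (enzyme per reaction, cofactor
# moieties) make the Jacobian structurally singular; steady-state polishing
# therefore solves the Newton system stacked with the conservation
# relations in a least-squares sense.

.KIN_SS_TOL <- 1e-9       # steady-state residual (|dC/dt| max-norm)
.KIN_DIV_HI <- 1e6        # divergence: pool above this
.KIN_DIV_LO <- 1e-9       # divergence: pool below this with monotone decay
.KIN_TMAX <- 1e6          # integration horizon (normalized time)

#' Assemble a solvable kinetic model
#'
#' @param mechanisms a [ReactionMechanisms-class].
#' @param params an [ElementaryParameterSet-class] sampled for those
#'   mechanisms.
#' @param enzymeLevels optional named numeric of total enzyme levels
#'   (e_tot, 1 = wild type); defaults to 1 for every reaction.
#' @return a [KineticModel-class].
#' @export
kineticModel <- function(mechanisms, params, enzymeLevels = NULL) {
  rids <- reactionIds(mechanisms@network)
  lev <- stats::setNames(rep(1, length(rids)), rids)
  if (!is.null(enzymeLevels)) {
    bad <- setdiff(names(enzymeLevels), rids)
    if (length(bad)) stop("enzyme level for unknown reaction(s): ",
                          paste(bad, collapse = ", "))
    lev[names(enzymeLevels)] <- enzymeLevels
  }
  new("KineticModel", mechanisms = mechanisms, params = params,
      enzymeLevels = lev,
      freeLevels = data.frame(reaction = character(0), lo = numeric(0),
                              hi = numeric(0)),
      clampedPools = stats::setNames(numeric(0), character(0)))
}

#' @export
setMethod("show", "KineticModel", function(object) {
  lev <- object@enzymeLevels
  cat("KineticModel:", length(lev), "reactions;",
      sum(!is.na(lev) & lev == 0), "knocked out,",
      sum(is.na(lev)), "free level(s),",
      length(object@clampedPools), "clamped pool(s)\n")
})

#' Apply a mutant genotype to a kinetic model
#'
#' Knockouts set the enzyme level to zero. Down- or upregulation with an
#' explicit level fixes e_tot at it (validated against the band 0.1..1 for
#' down, 1..10 for up); without a level the e_tot stays free in its band as
#' a decision variable for fitting.
#'
#' @param model a [KineticModel-class].
#' @param genotype data.frame(reaction, directive, level); directive in
#'   "knockout", "down", "up"; level may be NA.
#' @return the modified model.
#' @export
applyGenotype <- function(model, genotype) {
  if (is.null(genotype) || nrow(genotype) == 0) return(model)
  rids <- names(model@enzymeLevels)
  for (i in seq_len(nrow(genotype))) {
    rid <- genotype$reaction[i]
    if (!(rid %in% rids)) stop("genotype references unknown reaction '", rid, "'")
    dir <- genotype$directive[i]
    lev <- if ("level" %in% names(genotype)) genotype$level[i] else NA_real_
    if (dir == "knockout") {
      model@enzymeLevels[rid] <- 0
    } else if (dir %in% c("down", "up")) {
      band <- if (dir == "down") c(0.1, 1) else c(1, 10)
      if (is.na(lev)) {
        model@enzymeLevels[rid] <- NA_real_
        model@freeLevels <- rbind(model@freeLevels,
                                  data.frame(reaction = rid, lo = band[1],
                                             hi = band[2]))
      } else {
        if (lev < band[1] - 1e-12 || lev > band[2] + 1e-12)
          stop("level ", lev, " outside the ", dir, " band [",
               band[1], ", ", band[2], "] for '", rid, "'")
        model@enzymeLevels[rid] <- lev
      }
    } else stop("unknown directive '", dir, "'")
  }
  model
}

# ---- simulation assembly ----------------------------------------------------

# Structural part of the assembly: everything that depends only on the
# mechanisms, the set of active (nonzero-level) reactions and the clamped
# pools -- index maps, step stoichiometry, conservation basis, Jacobian
# sparsity pattern. Memoized on the mechanisms' cache environment.
.simStructure <- function(mech, active, clampedNames) {
  key <- paste(paste(active, collapse = "|"),
               paste(clampedNames, collapse = "|"), sep = "#")
  hit <- mech@cache[[key]]
  if (!is.null(hit)) return(hit)
  net <- mech@network
  dynMets <- setdiff(metaboliteIds(net), clampedNames)
  formNames <- unlist(lapply(active, function(rid)
    paste0(rid, ":", mech@mechanisms[[rid]]$forms)))
  stateNames <- c(dynMets, formNames)
  nd <- length(stateNames)
  ONE <- nd + length(clampedNames) + 1L
  metIdx <- function(nm) {
    i <- match(nm, stateNames)
    j <- match(nm, clampedNames)
    out <- ifelse(is.na(i), nd + j, i)
    out[is.na(nm)] <- ONE
    out
  }
  # flatten steps over active reactions
  rid <- from <- to <- met <- type <- character(0); side <- numeric(0)
  nsteps <- vapply(active, function(r) nrow(mech@mechanisms[[r]]$steps),
                   numeric(1))
  rid <- rep(active, nsteps)
  from <- unlist(lapply(active, function(r) mech@mechanisms[[r]]$steps$from))
  to <- unlist(lapply(active, function(r) mech@mechanisms[[r]]$steps$to))
  met <- unlist(lapply(active, function(r) mech@mechanisms[[r]]$steps$met))
  side <- unlist(lapply(active, function(r) mech@mechanisms[[r]]$steps$metSide))
  type <- unlist(lapply(active, function(r) mech@mechanisms[[r]]$steps$type))
  ns <- length(rid)
  iA <- match(paste0(rid, ":", from), stateNames)
  iC <- match(paste0(rid, ":", to), stateNames)
  consumed <- !is.na(met) & side < 0
  produced <- !is.na(met) & side > 0
  iB <- rep(ONE, ns); iB[consumed] <- metIdx(met[consumed])
  iD <- rep(ONE, ns); iD[produced] <- metIdx(met[produced])
  firstStep <- stats::setNames(cumsum(c(1, utils::head(nsteps, -1))), active)
  # step stoichiometry over dynamic states
  ti <- c(iA, iC, iB, iD)
  tj <- rep(seq_len(ns), 4)
  tx <- rep(c(-1, 1, -1, 1), each = ns)
  keep <- ti <= nd
  Tm <- Matrix::sparseMatrix(i = ti[keep], j = tj[keep], x = tx[keep],
                             dims = c(nd, ns))
  Td <- as.matrix(Tm)
  L <- t(.nullspace(t(Td)))
  if (nrow(L)) L[abs(L) < 1e-12] <- 0
  # Jacobian pattern: d(net rate_s)/d(state): four candidate entries per step
  jRow <- c(seq_len(ns), seq_len(ns), seq_len(ns), seq_len(ns))
  jCol <- c(iA, iB, iC, iD)
  jXX <- c(iB, iA, iD, iC)
  jSign <- rep(c(1, 1, -1, -1), each = ns)
  jIsF <- rep(c(TRUE, TRUE, FALSE, FALSE), each = ns)
  jK <- rep(seq_len(ns), 4)
  jkeep <- jCol <= nd
  jRow <- jRow[jkeep]; jCol <- jCol[jkeep]; jXX <- jXX[jkeep]
  jSign <- jSign[jkeep]; jIsF <- jIsF[jkeep]; jK <- jK[jkeep]
  str <- list(stateNames = stateNames, nd = nd, ONE = ONE,
              dynMets = dynMets, clampedNames = clampedNames,
              iA = iA, iB = iB, iC = iC, iD = iD,
              stepRxn = rid, stepType = type, stepMet = met,
              firstStep = firstStep, active = active,
              Tm = Tm, Td = Td, L = L,
              jRow = jRow, jCol = jCol, jXX = jXX, jSign = jSign,
              jIsF = jIsF, jK = jK, ns = ns, net = net,
              formSlices = lapply(active, function(r)
                match(paste0(r, ":", mech@mechanisms[[r]]$forms), stateNames)))
  names(str$formSlices) <- active
  mech@cache[[key]] <- str
  str
}

.buildSim <- function(model, enzymeLevels = NULL) {
  mech <- model@mechanisms
  lev <- model@enzymeLevels
  if (!is.null(enzymeLevels)) lev[names(enzymeLevels)] <- enzymeLevels
  if (anyNA(lev))
    stop("unresolved free enzyme level(s): ",
         paste(names(lev)[is.na(lev)], collapse = ", "),
         " (supply them or fit them)")
  if (any(lev < 0)) stop("enzyme levels must be >= 0")
  active <- names(lev)[lev > 0]
  clamped <- model@clampedPools
  str <- .simStructure(mech, active, names(clamped))
  kf <- unlist(lapply(active, function(r) model@params@kf[[r]]),
               use.names = FALSE)
  kr <- unlist(lapply(active, function(r) model@params@kr[[r]]),
               use.names = FALSE)
  x0 <- stats::setNames(rep(1, str$nd), str$stateNames)
  for (r in active) {
    frac <- model@params@fractions[[r]]
    x0[str$formSlices[[r]]] <-
      lev[[r]] * frac[mech@mechanisms[[r]]$forms]
  }
  c(str, list(kf = kf, kr = kr, x0 = x0,
              fixedVals = if (length(clamped)) clamped else numeric(0),
              lev = lev))
}

.simRates <- function(sim, x) {
  xx <- c(x, sim$fixedVals, 1)
  rf <- sim$kf * xx[sim$iA] * xx[sim$iB]
  rr <- sim$kr * xx[sim$iC] * xx[sim$iD]
  list(rf = rf, rr = rr, net = rf - rr)
}

.simRHS <- function(sim, x) {
  as.numeric(sim$Tm %*% .simRates(sim, x)$net)
}

.simJac <- function(sim, x) {
  xx <- c(x, sim$fixedVals, 1)
  k <- ifelse(sim$jIsF, sim$kf[sim$jK], sim$kr[sim$jK])
  vals <- sim$jSign * k * xx[sim$jXX]
  D <- matrix(0, sim$ns, sim$nd)
  D[cbind(sim$jRow, sim$jCol)] <- vals
  sim$Td %*% D
}

# Damped Newton with conservation augmentation. Returns list(x, ok).
.newtonPolish <- function(sim, x, tol = .KIN_SS_TOL, maxit = 60L) {
  L <- sim$L
  x0 <- sim$x0
  g0 <- if (nrow(L)) as.numeric(L %*% x0) else numeric(0)
  resid <- function(x) {
    f <- .simRHS(sim, x)
    g <- if (nrow(L)) as.numeric(L %*% x) - g0 else numeric(0)
    c(f, g)
  }
  r <- resid(x)
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) return(list(x = x, ok = TRUE))
    J <- .simJac(sim, x)
    A <- if (nrow(L)) rbind(J, L) else J
    dx <- tryCatch(qr.solve(A, -r), error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, ok = FALSE))
    t <- 1
    repeat {
      xn <- x + t * dx
      if (all(xn > -1e-12)) {
        xn[xn < 0] <- 0
        rn <- resid(xn)
        if (max(abs(rn)) < max(abs(r)) || t < 1e-4) break
      }
      t <- t / 2
      if (t < 1e-6) return(list(x = x, ok = max(abs(r)) < tol * 100))
    }
    x <- xn; r <- rn
  }
  list(x = x, ok = max(abs(resid(x))) < tol * 100)
}

.divergent <- function(sim, x, xPrev) {
  up <- x > .KIN_DIV_HI & x > xPrev * (1 + 1e-9)
  dn <- x < .KIN_DIV_LO & x < xPrev * (1 - 1e-9)
  sim$stateNames[which(up | dn)]
}

.integrateToSS <- function(sim, x, tmax = .KIN_TMAX, tol = .KIN_SS_TOL,
                           rtol = 1e-8, atol = 1e-12) {
  times <- c(1, 10, 100, 1e3, 1e4, 1e5, 1e6)
  times <- times[times <= tmax]
  if (!length(times) || times[length(times)] < tmax) times <- c(times, tmax)
  tPrev <- 0
  xPrev <- x
  for (tEnd in times) {
    out <- tryCatch(
      deSolve::lsoda(y = x, times = c(tPrev, tEnd),
                     func = function(t, y, p) list(.simRHS(sim, y)),
                     jacfunc = function(t, y, p) .simJac(sim, y),
                     jactype = "fullusr", rtol = rtol, atol = atol),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(out) || nrow(out) < 2) {
      # one retry with tighter tolerances before surfacing the failure
      out <- tryCatch(
        deSolve::lsoda(y = x, times = c(tPrev, tEnd),
                       func = function(t, y, p) list(.simRHS(sim, y)),
                       jacfunc = function(t, y, p) .simJac(sim, y),
                       jactype = "fullusr", rtol = rtol * 1e-2,
                       atol = atol * 1e-2, maxsteps = 50000),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(out) || nrow(out) < 2)
        return(list(x = x, converged = FALSE,
                    divergent = .divergent(sim, x, xPrev)))
    }
    xNew <- stats::setNames(as.numeric(out[nrow(out), -1]), sim$stateNames)
    if (max(abs(.simRHS(sim, xNew))) < tol)
      return(list(x = xNew, converged = TRUE, divergent = character(0)))
    div <- .divergent(sim, xNew, x)
    if (length(div))
      return(list(x = xNew, converged = FALSE, divergent = div))
    xPrev <- x; x <- xNew; tPrev <- tEnd
  }
  conv <- max(abs(.simRHS(sim, x))) < tol * 100
  div <- character(0)
  if (!conv) {
    # at the horizon: species still moving monotonically away from the
    # reference over the last decade of time are classified divergent
    growth <- x / pmax(xPrev, 1e-300)
    div <- sim$stateNames[(x > 100 & growth > 1.05) |
                            (x < 1e-6 & growth < 0.95)]
  }
  list(x = x, converged = conv, divergent = div)
}

#' Solve a kinetic model to steady state
#'
#' The default route integrates the mass-action ODE system from the
#' reference state until the residual drops below tolerance (or the horizon
#' is reached), then polishes with a damped Newton solve; per-species
#' divergence (monotone unbounded accumulation or depletion) is reported
#' rather than raised, because it is the signal robustness analysis feeds
#' on. \code{method = "newton"} tries the polish directly from the start
#' state and falls back to integration -- much faster inside fitting loops.
#'
#' @param model a [KineticModel-class].
#' @param enzymeLevels optional named numeric overriding levels per reaction.
#' @param method "dynamic" (integrate then polish) or "newton".
#' @param normalizeBy reaction id used as the yield denominator; default is
#'   the exchange with the most negative reference flux (the substrate
#'   uptake).
#' @param x0 optional start state (a previous solution, for continuation).
#' @param tmax integration horizon in normalized time units.
#' @return a [KineticSteadyState-class].
#' @export
steadyState <- function(model, enzymeLevels = NULL,
                        method = c("dynamic", "newton"),
                        normalizeBy = NULL, x0 = NULL, tmax = .KIN_TMAX) {
  method <- match.arg(method)
  sim <- .buildSim(model, enzymeLevels)
  x <- sim$x0
  if (!is.null(x0)) {
    shared <- intersect(names(x0), sim$stateNames)
    x[shared] <- x0[shared]
  }
  divergent <- character(0)
  converged <- FALSE
  if (method == "newton") {
    np <- .newtonPolish(sim, x)
    if (np$ok && all(np$x > -1e-9) && all(np$x < .KIN_DIV_HI)) {
      x <- np$x; converged <- TRUE
    } else {
      method <- "dynamic"
    }
  }
  if (method == "dynamic") {
    r <- .integrateToSS(sim, x, tmax = tmax)
    x <- r$x; divergent <- r$divergent
    if (r$converged || length(divergent) == 0) {
      np <- .newtonPolish(sim, x)
      if (np$ok) { x <- np$x; converged <- TRUE }
      else converged <- r$converged
    }
  }
  .makeSteadyState(model, sim, x, converged, divergent, normalizeBy)
}

.defaultNormalization <- function(model) {
  net <- model@mechanisms@network
  vref <- model@params@referenceFlux
  ex <- exchangeIds(net)
  ex <- ex[!is.na(vref[ex])]
  if (!length(ex)) return(NA_character_)
  ex[which.min(vref[ex])]
}

.makeSteadyState <- function(model, sim, x, converged, divergent,
                             normalizeBy = NULL) {
  net <- model@mechanisms@network
  rates <- .simRates(sim, x)
  flux <- stats::setNames(rep(0, nrow(net@reactions)), reactionIds(net))
  for (rid in sim$active) flux[rid] <- rates$net[sim$firstStep[[rid]]]
  conc <- stats::setNames(rep(NA_real_, nrow(net@metabolites)),
                          metaboliteIds(net))
  conc[sim$dynMets] <- x[sim$dynMets]
  if (length(sim$fixedVals)) conc[names(sim$fixedVals)] <- sim$fixedVals
  if (is.null(normalizeBy)) normalizeBy <- .defaultNormalization(model)
  yields <- if (!is.na(normalizeBy) && abs(flux[[normalizeBy]]) > 1e-12)
    flux / abs(flux[[normalizeBy]]) else flux * NA_real_
  new("KineticSteadyState", concentrations = conc, fluxes = flux,
      yields = yields, converged = converged && length(divergent) == 0,
      divergentSpecies = divergent, state = x)
}

#' @export
setMethod("show", "KineticSteadyState", function(object) {
  cat("KineticSteadyState:", if (object@converged) "converged" else "NOT converged")
  if (length(object@divergentSpecies))
    cat(" (divergent:", paste(object@divergentSpecies, collapse = ", "), ")")
  cat("\n")
})
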