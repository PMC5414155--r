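# Steady-state LP analysis: FBA, FVA, yield ranges, and detection plus
# elimination of thermodynamically infeasible cycles (TICs).
#
# The cycle-elimination constraint demands, for each cycle marker metabolite
# i and each alternate-cofactor reaction j* in its cycle set J_i, that
#   | sum_{j not in J_i} S_ij v_j |  >=  | v_j* | .
# The absolute value on the left is disjunctive; it is realized either as an
# exact enumeration over the sign of the non-cycle sum (one binary decision
# per cycle -- the MILP route) or as a single LP when direction hints pin
# that sign down.

.lpData <- function(network, extraBounds = NULL) {
  rxn <- network@reactions
  lb <- rxn$lb; ub <- rxn$ub
  names(lb) <- names(ub) <- rxn$id
  if (!is.null(extraBounds)) {
    for (id in names(extraBounds)) {
      i <- match(id, rxn$id)
      if (is.na(i)) stop("extra bound references unknown reaction '", id, "'")
      lb[i] <- extraBounds[[id]][1]; ub[i] <- extraBounds[[id]][2]
    }
  }
  list(A = as.matrix(network@S), lb = pmax(lb, -.LP_BIG), ub = pmin(ub, .LP_BIG))
}

# Build the inequality block for the cycle constraints under a fixed sign
# assignment. Variables are c(v, w) with one auxiliary w_i >= 0 per cycle.
.cycleIneq <- function(network, spec, signs) {
  n <- nrow(network@reactions)
  nc <- length(spec@markers)
  Ain <- NULL; bin <- numeric(0)
  for (ci in seq_len(nc)) {
    mk <- spec@markers[ci]
    J <- spec@cycleReactions[[mk]]
    jIdx <- match(J, network@reactions$id)
    srow <- as.numeric(network@S[mk, ])
    srow[jIdx] <- 0                          # non-cycle sum only
    # |v_j*| <= w_i
    for (j in jIdx) {
      r1 <- numeric(n + nc); r1[j] <- 1; r1[n + ci] <- -1
      r2 <- numeric(n + nc); r2[j] <- -1; r2[n + ci] <- -1
      Ain <- rbind(Ain, r1, r2); bin <- c(bin, 0, 0)
    }
    # sign * (non-cycle sum) >= w_i
    r3 <- numeric(n + nc); r3[seq_len(n)] <- -signs[ci] * srow; r3[n + ci] <- 1
    Ain <- rbind(Ain, r3); bin <- c(bin, 0)
  }
  list(Ain = Ain, bin = bin)
}

.solveConstrained <- function(network, spec, signs, cc, lpd, maximize) {
  n <- length(cc)
  nc <- length(spec@markers)
  free <- which(is.na(signs))
  combos <- if (length(free))
    as.matrix(expand.grid(rep(list(c(-1, 1)), length(free)))) else
    matrix(numeric(0), 1, 0)
  best <- list(status = "infeasible", x = NULL, objective = NA_real_)
  for (k in seq_len(nrow(combos))) {
    sg <- signs
    if (length(free)) sg[free] <- combos[k, ]
    iq <- .cycleIneq(network, spec, sg)
    res <- .lpSolve(c(cc, rep(0, nc)),
                    Aeq = cbind(lpd$A, matrix(0, nrow(lpd$A), nc)),
                    beq = rep(0, nrow(lpd$A)),
                    Ain = iq$Ain, bin = iq$bin,
                    lb = c(lpd$lb, rep(0, nc)),
                    ub = c(lpd$ub, rep(.LP_BIG, nc)),
                    maximize = maximize)
    if (res$status != "optimal") next
    res$x <- res$x[seq_len(n)]
    res$objective <- sum(cc * res$x)
    if (best$status != "optimal" ||
        (maximize && res$objective > best$objective) ||
        (!maximize && res$objective < best$objective)) best <- res
  }
  best
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady-state
#' mass balance \eqn{S v = 0} and flux bounds. The objective value is
#' deterministic; the flux vector may be one of several alternate optima.
#'
#' @param model a [MetabolicNetwork-class] or a
#'   [CycleConstrainedModel-class] returned by [applyCycleConstraint()].
#' @param objective reaction id to optimize.
#' @param sense "max" or "min".
#' @param extraBounds named list (reaction id -> c(lb, ub)) overriding model
#'   bounds for this solve.
#' @return a [FluxState-class].
#' @export
setGeneric("fba", function(model, objective, sense = c("max", "min"),
                           extraBounds = NULL) standardGeneric("fba"))

#' @rdname fba
setMethod("fba", "MetabolicNetwork", function(model, objective,
                                              sense = c("max", "min"),
                                              extraBounds = NULL) {
  sense <- match.arg(sense)
  j <- match(objective, model@reactions$id)
  if (is.na(j)) stop("unknown objective reaction '", objective, "'")
  lpd <- .lpData(model, extraBounds)
  cc <- numeric(ncol(lpd$A)); cc[j] <- 1
  res <- .simplexBounded(cc, lpd$A, rep(0, nrow(lpd$A)), lpd$lb, lpd$ub,
                         maximize = (sense == "max"))
  .asFluxState(res, model, objective)
})

#' @rdname fba
setMethod("fba", "CycleConstrainedModel", function(model, objective,
                                                   sense = c("max", "min"),
                                                   extraBounds = NULL) {
  sense <- match.arg(sense)
  net <- model@network
  j <- match(objective, net@reactions$id)
  if (is.na(j)) stop("unknown objective reaction '", objective, "'")
  lpd <- .lpData(net, extraBounds)
  cc <- numeric(ncol(lpd$A)); cc[j] <- 1
  res <- .solveConstrained(net, model@spec, model@signs, cc, lpd,
                           maximize = (sense == "max"))
  .asFluxState(res, net, objective)
})

.asFluxState <- function(res, network, objective) {
  if (res$status != "optimal")
    return(new("FluxState", fluxes = numeric(0), objectiveId = objective,
               objectiveValue = NA_real_, status = res$status))
  v <- res$x
  v[abs(v) < .LP_FLUX_TOL] <- 0
  new("FluxState", fluxes = stats::setNames(v, network@reactions$id),
      objectiveId = objective, objectiveValue = res$objective,
      status = "optimal")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under shared constraints,
#' optionally holding an objective at a fraction of its optimum.
#'
#' @param model a [MetabolicNetwork-class] or [CycleConstrainedModel-class].
#' @param targets reaction ids to scan (default: all).
#' @param fixObjectiveFraction in [0,1]; 0 adds no objective constraint.
#' @param objective reaction id whose optimum is fixed (required if
#'   \code{fixObjectiveFraction > 0}).
#' @param extraBounds named list of bound overrides.
#' @return data.frame(id, min, max); unbounded directions are truncated at
#'   +-1000 and flagged in a \code{truncated} column.
#' @export
setGeneric("fva", function(model, targets = NULL, fixObjectiveFraction = 0,
                           objective = NULL, extraBounds = NULL)
  standardGeneric("fva"))

.fvaCore <- function(network, spec, signs, targets, fixObjectiveFraction,
                     objective, extraBounds) {
  rxn <- network@reactions
  if (is.null(targets)) targets <- rxn$id
  if (!all(targets %in% rxn$id))
    stop("unknown target reaction(s): ",
         paste(setdiff(targets, rxn$id), collapse = ", "))
  lpd <- .lpData(network, extraBounds)
  n <- ncol(lpd$A)
  solveOne <- function(cc, maximize) {
    if (is.null(spec))
      .simplexBounded(cc, lpd$A, rep(0, nrow(lpd$A)), lpd$lb, lpd$ub,
                      maximize = maximize)
    else .solveConstrained(network, spec, signs, cc, lpd, maximize)
  }
  if (fixObjectiveFraction > 0) {
    if (is.null(objective)) stop("objective required when fixing its fraction")
    jo <- match(objective, rxn$id)
    cco <- numeric(n); cco[jo] <- 1
    base <- solveOne(cco, TRUE)
    if (base$status != "optimal") {
      culprit <- .blameBound(network, spec, signs, extraBounds)
      stop("model infeasible under the given constraints",
           if (!is.na(culprit)) paste0("; binding measurement constraint: ", culprit))
    }
    lpd$lb[jo] <- max(lpd$lb[jo], fixObjectiveFraction * base$objective)
  }
  res <- data.frame(id = targets, min = NA_real_, max = NA_real_,
                    truncated = FALSE)
  for (k in seq_along(targets)) {
    j <- match(targets[k], rxn$id)
    cc <- numeric(n); cc[j] <- 1
    lo <- solveOne(cc, FALSE); hi <- solveOne(cc, TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      culprit <- .blameBound(network, spec, signs, extraBounds)
      stop("FVA infeasible",
           if (!is.na(culprit)) paste0("; binding measurement constraint: ", culprit))
    }
    mn <- lo$objective; mx <- hi$objective
    trunc <- FALSE
    if (mn <= -.LP_BIG + 1e-6) { trunc <- TRUE }
    if (mx >= .LP_BIG - 1e-6) { trunc <- TRUE }
    if (abs(mn) < .LP_FLUX_TOL) mn <- 0
    if (abs(mx) < .LP_FLUX_TOL) mx <- 0
    res$min[k] <- mn; res$max[k] <- mx; res$truncated[k] <- trunc
  }
  res
}

.blameBound <- function(network, spec, signs, extraBounds) {
  if (is.null(extraBounds) || !length(extraBounds)) return(NA_character_)
  for (id in names(extraBounds)) {
    eb <- extraBounds[setdiff(names(extraBounds), id)]
    lpd <- .lpData(network, if (length(eb)) eb else NULL)
    cc <- numeric(ncol(lpd$A))
    r <- if (is.null(spec))
      .simplexBounded(cc, lpd$A, rep(0, nrow(lpd$A)), lpd$lb, lpd$ub)
    else .solveConstrained(network, spec, signs, cc, lpd, TRUE)
    if (r$status == "optimal") return(id)
  }
  NA_character_
}

#' @rdname fva
setMethod("fva", "MetabolicNetwork", function(model, targets = NULL,
                                              fixObjectiveFraction = 0,
                                              objective = NULL,
                                              extraBounds = NULL) {
  .fvaCore(model, NULL, NULL, targets, fixObjectiveFraction, objective,
           extraBounds)
})

#' @rdname fva
setMethod("fva", "CycleConstrainedModel", function(model, targets = NULL,
                                                   fixObjectiveFraction = 0,
                                                   objective = NULL,
                                                   extraBounds = NULL) {
  .fvaCore(model@network, model@spec, model@signs, targets,
           fixObjectiveFraction, objective, extraBounds)
})

#' Find thermodynamically infeasible cycles
#'
#' Closes every exchange reaction and runs FVA: any reaction still able to
#' carry flux participates in a TIC (a closed circulation needing no
#' exchange). Participating reactions are grouped into connected components
#' and a consistent circulation direction is extracted from a nullspace
#' basis of the participating submatrix.
#'
#' @param network a MetabolicNetwork.
#' @return list of cycles; each is list(reactions, signs) where signs give a
#'   feasible circulation direction (+1/-1 per reaction). Empty list if the
#'   network is loop-free.
#' @export
findTICs <- function(network) {
  exch <- exchangeIds(network)
  closed <- stats::setNames(rep(list(c(0, 0)), length(exch)), exch)
  rng <- fva(network, extraBounds = closed)
  part <- rng$id[rng$min < -.LP_FLUX_TOL | rng$max > .LP_FLUX_TOL]
  if (!length(part)) return(list())
  Ssub <- as.matrix(network@S[, part, drop = FALSE])
  Ssub <- Ssub[rowSums(Ssub != 0) > 0, , drop = FALSE]
  # connected components over shared metabolites
  comp <- seq_along(part)
  repeat {
    changed <- FALSE
    for (mi in seq_len(nrow(Ssub))) {
      touch <- which(Ssub[mi, ] != 0)
      if (length(touch) > 1) {
        tgt <- min(comp[touch])
        if (any(comp[touch] != tgt)) { comp[touch] <- tgt; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  ns <- .nullspace(Ssub)
  out <- list()
  for (g in unique(comp)) {
    ids <- part[comp == g]
    sel <- match(ids, part)
    sgn <- rep(NA_real_, length(ids))
    if (ncol(ns)) {
      # nullspace vector with largest support on this component
      support <- colSums(abs(ns[sel, , drop = FALSE]))
      v <- ns[sel, which.max(support)]
      if (max(abs(v)) > 1e-9) sgn <- sign(round(v / max(abs(v)), 9))
    }
    out[[length(out) + 1L]] <- list(reactions = ids,
                                    signs = stats::setNames(sgn, ids))
  }
  out
}

.nullspace <- function(A) {
  if (!nrow(A)) return(diag(ncol(A)))
  s <- svd(A, nu = 0, nv = ncol(A))
  r <- sum(s$d > max(dim(A)) * max(s$d, 0) * 1e-12)
  if (r == ncol(A)) matrix(0, ncol(A), 0) else s$v[, (r + 1):ncol(A), drop = FALSE]
}

#' Build a cycle specification
#' @param markers marker metabolite ids (one per cycle, unique to it).
#' @param cycleReactions named list (by marker) of reaction-id vectors J_i.
#' @export
cycleSpec <- function(markers, cycleReactions) {
  new("CycleSpec", markers = markers, cycleReactions = cycleReactions[markers])
}

#' Attach the cycle-elimination constraint to a network
#'
#' For every marker metabolite i and every reaction j* in its cycle set, the
#' absolute flux of j* is forced below the absolute net flux of i through
#' non-cycle reactions. With no exchange open this pins cycle fluxes to
#' zero; with exchanges open all alternate-cofactor reactions may be active
#' simultaneously.
#'
#' @param network a MetabolicNetwork.
#' @param spec a [CycleSpec-class].
#' @param directionHints optional named numeric (+1/-1 by reaction id)
#'   fixing directions of the reactions entering/leaving each loop; when the
#'   hints determine the sign of a cycle's non-cycle sum, that cycle is
#'   solved as a pure LP instead of an enumerated MILP.
#' @return a [CycleConstrainedModel-class] usable with [fba()]/[fva()].
#' @export
applyCycleConstraint <- function(network, spec, directionHints = NULL) {
  rxn <- network@reactions
  for (mk in spec@markers) {
    if (!(mk %in% network@metabolites$id))
      stop("marker metabolite '", mk, "' not in network")
    J <- spec@cycleReactions[[mk]]
    if (!length(J)) stop("empty cycle reaction set for marker '", mk, "'")
    if (!all(J %in% rxn$id))
      stop("cycle reactions not in network: ",
           paste(setdiff(J, rxn$id), collapse = ", "))
    inv <- J[abs(network@S[mk, J]) == 0]
    if (length(inv))
      stop("cycle reaction(s) not involving marker '", mk, "': ",
           paste(inv, collapse = ", "))
  }
  if (!is.null(directionHints)) {
    for (id in names(directionHints)) {
      i <- match(id, rxn$id)
      if (is.na(i)) stop("direction hint for unknown reaction '", id, "'")
      h <- directionHints[[id]]
      if (h > 0 && rxn$ub[i] <= 0)
        stop("direction hint for '", id, "' contradicts its bounds")
      if (h < 0 && rxn$lb[i] >= 0)
        stop("direction hint for '", id, "' contradicts its bounds")
    }
  }
  signs <- rep(NA_real_, length(spec@markers))
  names(signs) <- spec@markers
  if (!is.null(directionHints)) {
    for (ci in seq_along(spec@markers)) {
      mk <- spec@markers[ci]
      J <- spec@cycleReactions[[mk]]
      srow <- network@S[mk, ]
      nonCycle <- setdiff(rxn$id[as.numeric(srow) != 0], J)
      if (length(nonCycle) && all(nonCycle %in% names(directionHints))) {
        termSigns <- sign(as.numeric(srow[nonCycle])) *
          sign(directionHints[nonCycle])
        if (length(unique(termSigns)) == 1) signs[ci] <- termSigns[1]
      }
    }
  }
  new("CycleConstrainedModel", network = network, spec = spec, signs = signs)
}

#' Suggest a marker metabolite for each detected cycle
#'
#' For each cycle, proposes the metabolite shared by all cycle reactions
#' that participates in the fewest reactions outside the cycle.
#' @param network a MetabolicNetwork.
#' @param tics output of [findTICs()] (computed if missing).
#' @return named list marker -> cycle reaction ids.
#' @export
suggestCycleMarkers <- function(network, tics = findTICs(network)) {
  out <- list()
  for (tc in tics) {
    Ssub <- network@S[, tc$reactions, drop = FALSE]
    shared <- rownames(Ssub)[Matrix::rowSums(Ssub != 0) >= 2]
    if (!length(shared))
      shared <- rownames(Ssub)[Matrix::rowSums(Ssub != 0) > 0]
    outside <- vapply(shared, function(mt)
      sum(network@S[mt, setdiff(reactionIds(network), tc$reactions)] != 0),
      numeric(1))
    mk <- shared[which.min(outside)]
    out[[mk]] <- tc$reactions[as.logical(network@S[mk, tc$reactions] != 0)]
  }
  out
}

#' Feasible yield range of a product on a substrate
#'
#' Fixes substrate uptake to one unit (yields are scale-invariant), applies
#' measurement bounds expressed as yields, and reports the feasible range of
#' the product exchange flux, i.e. mol product per mol substrate.
#'
#' @param model a [MetabolicNetwork-class] or [CycleConstrainedModel-class].
#' @param productExchange,substrateExchange exchange reaction ids.
#' @param measurementBounds named list (exchange id -> c(lo, hi) in mol/mol).
#' @return a [YieldRange-class].
#' @export
yieldRange <- function(model, productExchange, substrateExchange,
                       measurementBounds = NULL) {
  network <- if (is(model, "CycleConstrainedModel")) model@network else model
  for (id in c(productExchange, substrateExchange))
    if (!(id %in% network@reactions$id)) stop("unknown exchange '", id, "'")
  eb <- list()
  eb[[substrateExchange]] <- c(-1, -1)       # one unit of uptake
  if (!is.null(measurementBounds))
    for (id in names(measurementBounds))
      eb[[id]] <- sort(measurementBounds[[id]])
  rng <- tryCatch(
    fva(model, targets = productExchange, extraBounds = eb),
    error = function(e)
      stop("infeasible measurement set (mass-imbalanced experimental ",
           "measurements): ", conditionMessage(e)))
  new("YieldRange", productId = productExchange,
      substrateId = substrateExchange,
      minYield = rng$min, maxYield = rng$max)
}

#' @export
setMethod("show", "YieldRange", function(object) {
  cat("YieldRange ", object@productId, "/", object@substrateId, ": [",
      format(object@minYield), ", ", format(object@maxYield), "] mol/mol\n",
      sep = "")
})
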