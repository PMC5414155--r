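# Perturbation case studies: enzyme-level scans (nutrient limitation),
# proteomic stress profiles, and robustness analysis by divergence
# detection.

#' Scan the level of one enzyme
#'
#' Solves the steady state at a sequence of enzyme levels, warm-starting
#' each solve from the previous level's state (continuation) for
#' convergence stability.
#'
#' @param model a [KineticModel-class] (reference levels).
#' @param reaction reaction id whose total enzyme level is scanned.
#' @param levels numeric vector of e_tot values (> 0; use
#'   [applyGenotype()] knockouts for 0).
#' @param method steady-state route, see [steadyState()].
#' @param normalizeBy yield normalization reaction.
#' @return list(levels, states, summary); \code{states} is a list of
#'   [KineticSteadyState-class] per level and \code{summary} a tidy
#'   data.frame(level, quantity, id, value) of yields and pool
#'   fold-changes.
#' @export
scanEnzymeLevel <- function(model, reaction, levels,
                            method = c("dynamic", "newton"),
                            normalizeBy = NULL) {
  method <- match.arg(method)
  if (!(reaction %in% names(model@enzymeLevels)))
    stop("unknown reaction '", reaction, "'")
  if (any(levels <= 0)) stop("levels must be > 0 (knockout via applyGenotype)")
  states <- vector("list", length(levels))
  xPrev <- NULL
  for (k in seq_along(levels)) {
    lv <- stats::setNames(levels[k], reaction)
    states[[k]] <- steadyState(model, enzymeLevels = lv, method = method,
                               normalizeBy = normalizeBy, x0 = xPrev)
    if (states[[k]]@converged) xPrev <- states[[k]]@state
  }
  rows <- list()
  for (k in seq_along(levels)) {
    ss <- states[[k]]
    rows[[length(rows) + 1L]] <-
      data.frame(level = levels[k], quantity = "yield",
                 id = names(ss@yields), value = as.numeric(ss@yields))
    rows[[length(rows) + 1L]] <-
      data.frame(level = levels[k], quantity = "concentration-fold",
                 id = names(ss@concentrations),
                 value = as.numeric(ss@concentrations))
  }
  list(levels = levels, states = states, summary = do.call(rbind, rows))
}

#' Build a stress profile
#' @param enzymeFoldChanges named numeric multipliers on e_tot (> 0), e.g.
#'   0.62 for a 38 percent downregulation.
#' @param poolScalings named numeric multipliers on reference pools; the
#'   listed metabolites are clamped at the scaled value as boundary
#'   conditions. Under the percent-increase reading a pool "increased by
#'   670 percent" is scaled 7.7-fold (\code{percentIncrease = TRUE},
#'   the default interprets the numbers you pass as plain multipliers).
#' @export
stressProfile <- function(enzymeFoldChanges = numeric(0),
                          poolScalings = numeric(0)) {
  if (any(enzymeFoldChanges <= 0) || any(poolScalings <= 0))
    stop("stress-profile multipliers must be > 0")
  list(enzymeFoldChanges = enzymeFoldChanges, poolScalings = poolScalings)
}

#' Apply a stress profile and solve
#'
#' Scales enzyme levels multiplicatively, clamps the listed pools as fixed
#' boundary species at their scaled values, and solves the steady state.
#' Enzyme scaling and pool clamping act on independent model fields, so
#' their application order cannot matter.
#'
#' @param model a [KineticModel-class].
#' @param profile a [stressProfile()].
#' @inheritParams scanEnzymeLevel
#' @return a [KineticSteadyState-class].
#' @export
applyStressProfile <- function(model, profile,
                               method = c("dynamic", "newton"),
                               normalizeBy = NULL) {
  method <- match.arg(method)
  efc <- profile$enzymeFoldChanges
  bad <- setdiff(names(efc), names(model@enzymeLevels))
  if (length(bad)) stop("profile references unknown reaction(s): ",
                        paste(bad, collapse = ", "))
  badp <- setdiff(names(profile$poolScalings),
                  metaboliteIds(model@mechanisms@network))
  if (length(badp)) stop("profile references unknown metabolite(s): ",
                         paste(badp, collapse = ", "))
  model@enzymeLevels[names(efc)] <- model@enzymeLevels[names(efc)] * efc
  ps <- profile$poolScalings
  ps <- ps[ps != 1]                  # scaling by 1 leaves the pool free
  if (length(ps))
    model@clampedPools <- c(model@clampedPools, ps * 1)  # reference pool = 1
  steadyState(model, method = method, normalizeBy = normalizeBy)
}

#' Robustness analysis by enzyme perturbation
#'
#' Perturbs each reaction's enzyme level by each fold and classifies the
#' run as converged or divergent. A divergent run names the runaway
#' species and the adjacent reaction (the saturated consumer of an
#' accumulating species, or the limiting producer of a depleting one): the
#' non-robust node.
#'
#' @param model a [KineticModel-class], convergent at reference.
#' @param folds enzyme-level multipliers (default 0.5 and 2).
#' @param reactions ids to perturb (default: all with nonzero level).
#' @param tmax integration horizon per run.
#' @return data.frame(perturbedReaction, fold, converged, species,
#'   direction, atReaction); converged runs have NA species.
#' @export
robustnessScan <- function(model, folds = c(0.5, 2), reactions = NULL,
                           tmax = 1e4) {
  lev0 <- model@enzymeLevels
  if (anyNA(lev0)) stop("resolve free enzyme levels before scanning")
  if (is.null(reactions)) reactions <- names(lev0)[lev0 > 0]
  ref <- steadyState(model, method = "dynamic")
  if (!ref@converged) stop("model does not converge at reference")
  vref <- model@params@referenceFlux
  net <- model@mechanisms@network
  rows <- list()
  for (rid in reactions) {
    for (fd in folds) {
      lv <- stats::setNames(lev0[[rid]] * fd, rid)
      ss <- steadyState(model, enzymeLevels = lv, method = "dynamic",
                        tmax = tmax)
      if (ss@converged) {
        rows[[length(rows) + 1L]] <-
          data.frame(perturbedReaction = rid, fold = fd, converged = TRUE,
                     species = NA_character_, direction = NA_character_,
                     atReaction = NA_character_)
        next
      }
      div <- ss@divergentSpecies
      if (!length(div)) div <- NA_character_
      for (sp in div) {
        if (is.na(sp)) {
          rows[[length(rows) + 1L]] <-
            data.frame(perturbedReaction = rid, fold = fd, converged = FALSE,
                       species = NA_character_, direction = "stalled",
                       atReaction = NA_character_)
          next
        }
        val <- if (sp %in% names(ss@concentrations) &&
                   !is.na(ss@concentrations[sp])) ss@concentrations[[sp]]
               else ss@state[[sp]]
        direction <- if (val > 1) "accumulating" else "depleting"
        atR <- if (grepl(":", sp, fixed = TRUE)) {
          sub(":.*$", "", sp)
        } else {
          srow <- as.numeric(net@S[sp, ])
          names(srow) <- reactionIds(net)
          # accumulating -> the saturated consumer; depleting -> the producer
          cand <- if (direction == "accumulating")
            names(srow)[srow < 0] else names(srow)[srow > 0]
          if (!length(cand)) cand <- names(srow)[srow != 0]
          if (!length(cand)) NA_character_
          else cand[which.max(abs(vref[cand]))]
        }
        rows[[length(rows) + 1L]] <-
          data.frame(perturbedReaction = rid, fold = fd, converged = FALSE,
                     species = sp, direction = direction, atReaction = atR)
      }
    }
  }
  do.call(rbind, rows)
}
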