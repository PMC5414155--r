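#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t colSums rowSums
NULL

#' Stoichiometric metabolic network
#'
#' Container for a (core or genome-scale) stoichiometric model: metabolite
#' and reaction tables plus a sparse stoichiometric matrix. Reversibility is
#' not stored; it is defined by the bounds (\code{lb < 0 < ub}). Exchange
#' reactions are single-metabolite reactions crossing the system boundary.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula} (elemental formula string, may be NA),
#'   \code{charge} (integer, may be NA).
#' @slot reactions data.frame with columns \code{id}, \code{lb}, \code{ub}
#'   (mmol/gDW/h), \code{gpr} (boolean gene expression string, may be NA),
#'   \code{is_exchange}.
#' @slot S sparse stoichiometric matrix (metabolites x reactions); negative
#'   coefficients consume.
#' @slot biomassId id of the biomass reaction, or NA for networks without one.
#' @slot gam growth-associated maintenance (mmol ATP/gDCW; embedded in the
#'   biomass reaction stoichiometry), NA if not annotated.
#' @slot ngam non-growth-associated maintenance (mmol ATP/gDCW/h; imposed as
#'   a fixed bound on the ATP maintenance reaction), NA if not annotated.
#' @export
setClass("MetabolicNetwork",
  representation(metabolites = "data.frame", reactions = "data.frame",
                 S = "Matrix", biomassId = "character",
                 gam = "numeric", ngam = "numeric"))

setValidity("MetabolicNetwork", function(object) {
  msg <- character(0)
  met <- object@metabolites; rxn <- object@reactions
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (any(!nzchar(met$compartment)))
    msg <- c(msg, "empty metabolite compartment")
  if (any(rxn$lb > rxn$ub))
    msg <- c(msg, "reaction with lb > ub")
  if (!identical(rownames(object@S), met$id) ||
      !identical(colnames(object@S), rxn$id))
    msg <- c(msg, "stoichiometric matrix dimnames out of step with tables")
  if (any(Matrix::colSums(object@S != 0) == 0))
    msg <- c(msg, "reaction with empty stoichiometry")
  if (!is.na(object@biomassId) && !(object@biomassId %in% rxn$id))
    msg <- c(msg, "biomass reaction id not present")
  if (length(msg)) msg else TRUE
})

#' Flux state returned by FBA
#'
#' @slot fluxes named numeric vector of reaction fluxes (mmol/gDW/h); empty
#'   unless status is "optimal".
#' @slot objectiveId reaction id of the objective.
#' @slot objectiveValue optimal objective value (NA if not optimal).
#' @slot status one of "optimal", "infeasible", "unbounded".
#' @export
setClass("FluxState",
  representation(fluxes = "numeric", objectiveId = "character",
                 objectiveValue = "numeric", status = "character"))

#' Cycle specification feeding the cycle-elimination constraint
#'
#' One marker metabolite per thermodynamically infeasible cycle (the set
#' I^c) and, per marker, the alternate-cofactor reactions participating in
#' that cycle (the sets J_i^c).
#'
#' @slot markers character vector of marker metabolite ids.
#' @slot cycleReactions named list (by marker) of reaction-id vectors.
#' @export
setClass("CycleSpec",
  representation(markers = "character", cycleReactions = "list"))

#' A network together with active cycle-elimination constraints
#'
#' Handle returned by [applyCycleConstraint()]; [fba()] and [fva()] methods
#' on it solve the constrained problem (MILP by sign enumeration, or a pure
#' LP when direction hints fix the sign of every non-cycle sum).
#'
#' @slot network the underlying MetabolicNetwork.
#' @slot spec the CycleSpec.
#' @slot signs named numeric (+1/-1 per marker) for cycles whose non-cycle
#'   sum sign is fixed by direction hints; NA when enumerated.
#' @export
setClass("CycleConstrainedModel",
  representation(network = "MetabolicNetwork", spec = "CycleSpec",
                 signs = "numeric"))

#' Yield range from flux variability analysis
#'
#' @slot productId,substrateId exchange reaction ids.
#' @slot minYield,maxYield mol product per mol substrate.
#' @export
setClass("YieldRange",
  representation(productId = "character", substrateId = "character",
                 minYield = "numeric", maxYield = "numeric"))

#' Elementary-step decomposition of a network
#'
#' One mechanism per reaction: enzyme forms and the ordered chain of
#' elementary steps (binding, central conversion, release) plus dead-end
#' regulatory binding steps.
#'
#' @slot network the decomposed MetabolicNetwork.
#' @slot regulations data.frame(effector, target, type).
#' @slot mechanisms named list (by reaction id); each entry has \code{forms}
#'   (character) and \code{steps} (data.frame: index, type, from, to, met,
#'   metStoich).
#' @slot cache internal environment memoizing assembled simulation
#'   structures (index maps, conservation basis, Jacobian pattern) per
#'   active-reaction set.
#' @export
setClass("ReactionMechanisms",
  representation(network = "MetabolicNetwork", regulations = "data.frame",
                 mechanisms = "list", cache = "environment"))

#' One sampled ensemble member
#'
#' Enzyme-form fractions, per-step reversibilities, and the elementary rate
#' constants back-computed so the member reproduces the reference flux state
#' exactly at reference (normalized, = 1) concentrations.
#'
#' @slot fractions named list by reaction: named numeric over enzyme forms,
#'   summing to 1.
#' @slot reversibilities named list by reaction: numeric per step in (0,1).
#' @slot kf,kr named list by reaction: elementary rate constants per step.
#' @slot referenceFlux named numeric: the anchoring flux state.
#' @export
setClass("ElementaryParameterSet",
  representation(fractions = "list", reversibilities = "list",
                 kf = "list", kr = "list", referenceFlux = "numeric"))

#' Solvable kinetic model
#'
#' Mechanisms plus one parameter set plus an enzyme-level profile. The
#' reference state is enzymeLevels == 1 everywhere; 0 encodes knockout.
#'
#' @slot mechanisms ReactionMechanisms.
#' @slot params ElementaryParameterSet.
#' @slot enzymeLevels named numeric, one e_tot >= 0 per reaction (NA marks a
#'   level left free for fitting, see [applyGenotype()]).
#' @slot freeLevels data.frame(reaction, lo, hi) of fitting bands for NA
#'   levels.
#' @slot clampedPools named numeric of metabolite pools held fixed as
#'   boundary conditions (fold of reference), empty if none.
#' @export
setClass("KineticModel",
  representation(mechanisms = "ReactionMechanisms",
                 params = "ElementaryParameterSet",
                 enzymeLevels = "numeric", freeLevels = "data.frame",
                 clampedPools = "numeric"))

#' Steady state of a kinetic model
#'
#' @slot concentrations named numeric, metabolite pools as fold of reference.
#' @slot fluxes named numeric, net reaction fluxes (reference units).
#' @slot yields named numeric, fluxes normalized to substrate uptake
#'   (mol/mol).
#' @slot converged logical.
#' @slot divergentSpecies character: species failing the divergence
#'   criterion (monotone unbounded growth or depletion); empty iff converged.
#' @slot state full raw state vector (metabolites and enzyme forms); used to
#'   warm-start continuation scans.
#' @export
setClass("KineticSteadyState",
  representation(concentrations = "numeric", fluxes = "numeric",
                 yields = "numeric", converged = "logical",
                 divergentSpecies = "character", state = "numeric"))

#' One mutant training dataset
#'
#' @slot name dataset label.
#' @slot genotype data.frame(reaction, directive, level) with directive in
#'   knockout/down/up; level NA leaves the enzyme level free in its band.
#' @slot measurements data.frame(quantity, target, value, cv) with quantity
#'   in yield / concentration-fold / km / kcat.
#' @export
setClass("MutantDataset",
  representation(name = "character", genotype = "data.frame",
                 measurements = "data.frame"))

setValidity("MutantDataset", function(object) {
  msg <- character(0)
  if (nrow(object@measurements) < 1) msg <- c(msg, "no measurements")
  if (any(object@measurements$cv <= 0)) msg <- c(msg, "cv must be > 0")
  if (any(!is.finite(object@measurements$value)))
    msg <- c(msg, "non-finite measurement value")
  if (length(msg)) msg else TRUE
})

#' Scaled-deviation report
#'
#' The fitting objective: per measurement |v - v_exp| / |v_exp| scaled by
#' 1/CV, averaged within each dataset and then across datasets.
#'
#' @slot perDataset named numeric of per-dataset mean scaled deviations.
#' @slot overall mean over datasets.
#' @slot residuals data.frame(dataset, quantity, target, predicted,
#'   measured, scaled) of per-measurement contributions.
#' @export
setClass("DeviationReport",
  representation(perDataset = "numeric", overall = "numeric",
                 residuals = "data.frame"))

#' Synthetic ground truth
#'
#' @slot network the generated MetabolicNetwork.
#' @slot mechanisms its decomposition.
#' @slot trueParams the true ElementaryParameterSet.
#' @slot referenceFlux the anchoring flux state (named numeric).
#' @slot cycleSpec planted-cycle specification (CycleSpec).
#' @slot plantedCycle reaction ids of the planted infeasible cycle.
#' @slot measuredExchanges exchange reaction ids whose yields are "measured".
#' @slot substrateExchange id of the substrate uptake exchange.
#' @export
setClass("GroundTruth",
  representation(network = "MetabolicNetwork",
                 mechanisms = "ReactionMechanisms",
                 trueParams = "ElementaryParameterSet",
                 referenceFlux = "numeric", cycleSpec = "CycleSpec",
                 plantedCycle = "character", measuredExchanges = "character",
                 substrateExchange = "character"))
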