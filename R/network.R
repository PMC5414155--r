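# Construction, accessors and curation helpers for stoichiometric networks.

#' Build a metabolic network
#'
#' @param metabolites data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{compartment} (default "c"), \code{formula},
#'   \code{charge}.
#' @param reactions data.frame with at least \code{id}; optional \code{lb},
#'   \code{ub} (defaults -1000/1000 for reversible, see \code{rev}),
#'   \code{gpr}.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (metabolite id -> coefficient, negative consumes).
#' @param biomassId optional biomass reaction id.
#' @param gam,ngam maintenance parameters (mmol ATP/gDCW(/h)). When
#'   \code{ngam} is given and an ATP-maintenance reaction (id containing
#'   "ATPM") exists, its bounds are fixed at \code{lb = ub = ngam}.
#' @return a validated [MetabolicNetwork-class].
#' @export
metabolicNetwork <- function(metabolites, reactions, stoichiometry,
                             biomassId = NA_character_,
                             gam = NA_real_, ngam = NA_real_) {
  met <- data.frame(id = as.character(metabolites$id),
                    stringsAsFactors = FALSE)
  met$name <- if (!is.null(metabolites$name)) as.character(metabolites$name) else met$id
  met$compartment <- if (!is.null(metabolites$compartment))
    as.character(metabolites$compartment) else .compartmentOf(met$id)
  met$formula <- if (!is.null(metabolites$formula))
    as.character(metabolites$formula) else NA_character_
  met$charge <- if (!is.null(metabolites$charge))
    as.integer(metabolites$charge) else NA_integer_

  rxn <- data.frame(id = as.character(reactions$id), stringsAsFactors = FALSE)
  rxn$lb <- if (!is.null(reactions$lb)) as.numeric(reactions$lb) else -.LP_BIG
  rxn$ub <- if (!is.null(reactions$ub)) as.numeric(reactions$ub) else .LP_BIG
  rxn$gpr <- if (!is.null(reactions$gpr)) as.character(reactions$gpr) else NA_character_
  rxn$lb[!is.finite(rxn$lb)] <- -.LP_BIG
  rxn$ub[!is.finite(rxn$ub)] <- .LP_BIG

  stoichiometry <- stoichiometry[rxn$id]
  bad <- setdiff(unique(unlist(lapply(stoichiometry, names))), met$id)
  if (length(bad))
    stop("stoichiometry references unknown metabolite(s): ",
         paste(bad, collapse = ", "))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(stoichiometry)) {
    sv <- stoichiometry[[j]]
    sv <- sv[sv != 0]
    if (!length(sv)) stop("reaction '", rxn$id[j], "' has empty stoichiometry")
    ii <- c(ii, match(names(sv), met$id)); jj <- c(jj, rep(j, length(sv)))
    xx <- c(xx, as.numeric(sv))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(met), nrow(rxn)),
                            dimnames = list(met$id, rxn$id))
  rxn$is_exchange <- as.vector(Matrix::colSums(S != 0) == 1)

  if (!is.na(ngam)) {
    iatpm <- grep("ATPM", rxn$id)
    if (length(iatpm)) { rxn$lb[iatpm[1]] <- ngam; rxn$ub[iatpm[1]] <- ngam }
  }
  new("MetabolicNetwork", metabolites = met, reactions = rxn, S = S,
      biomassId = biomassId, gam = gam, ngam = ngam)
}

.compartmentOf <- function(ids) {
  comp <- sub("^.*\\(([a-z0-9]+)\\)$", "\\1", ids)
  comp[comp == ids] <- "c"
  comp
}

#' @rdname metabolicNetwork
#' @param object,network a MetabolicNetwork
#' @export
reactionIds <- function(network) network@reactions$id

#' @rdname metabolicNetwork
#' @export
metaboliteIds <- function(network) network@metabolites$id

#' @rdname metabolicNetwork
#' @export
stoichMatrix <- function(network) network@S

#' @rdname metabolicNetwork
#' @export
exchangeIds <- function(network) network@reactions$id[network@reactions$is_exchange]

#' Reversibility of each reaction (lb < 0 < ub)
#' @param network a MetabolicNetwork
#' @export
isReversible <- function(network) {
  r <- network@reactions
  stats::setNames(r$lb < 0 & r$ub > 0, r$id)
}

#' Override bounds on a copy of the network
#' @param network a MetabolicNetwork
#' @param bounds named list (by reaction id) of c(lb, ub).
#' @export
setBounds <- function(network, bounds) {
  for (id in names(bounds)) {
    i <- match(id, network@reactions$id)
    if (is.na(i)) stop("unknown reaction '", id, "'")
    network@reactions$lb[i] <- bounds[[id]][1]
    network@reactions$ub[i] <- bounds[[id]][2]
  }
  validObject(network)
  network
}

#' @export
setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", nrow(object@reactions), "reactions,",
      nrow(object@metabolites), "metabolites\n")
  cat("  exchanges:", sum(object@reactions$is_exchange),
      " reversible:", sum(isReversible(object)), "\n")
  if (!is.na(object@biomassId))
    cat("  biomass:", object@biomassId,
        " GAM:", object@gam, " NGAM:", object@ngam, "\n")
})

#' @export
setMethod("show", "FluxState", function(object) {
  cat("FluxState [", object@status, "] objective ", object@objectiveId,
      " = ", format(object@objectiveValue), "\n", sep = "")
})

# ---- elemental balance ------------------------------------------------------

#' Parse an elemental formula string
#'
#' Accepts Hill-style formulas ("C6H12O6") including pseudo-elements used by
#' synthetic networks (single capital letters such as "R" or "Q").
#' @param formula character formula.
#' @return named integer vector element -> count.
#' @export
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]+$", toks),
                          sub("^[A-Za-z]+", "", toks), "1"))
  tapply(ct, el, sum)[unique(el)]
}

.formulaAdd <- function(acc, f, mult) {
  for (e in names(f)) acc[e] <- (if (e %in% names(acc)) acc[[e]] else 0) + mult * f[[e]]
  acc
}

#' Elemental and charge balance of a reaction
#'
#' Sums coefficient-weighted formulas and charges over the participants.
#' Exchange reactions move matter across the boundary and are reported as
#' skipped. Metabolites lacking a formula make the reaction unverifiable.
#'
#' @param network a MetabolicNetwork.
#' @param reaction a reaction id.
#' @return list with \code{elements} (named surplus, positive = excess on the
#'   product side), \code{charge}, \code{balanced}, \code{skipped},
#'   \code{unverifiable} (metabolite ids with missing formula).
#' @export
checkBalance <- function(network, reaction) {
  j <- match(reaction, network@reactions$id)
  if (is.na(j)) stop("unknown reaction '", reaction, "'")
  if (network@reactions$is_exchange[j])
    return(list(elements = numeric(0), charge = 0, balanced = NA,
                skipped = TRUE, unverifiable = character(0)))
  sv <- network@S[, j]
  sv <- sv[sv != 0]
  met <- network@metabolites[match(names(sv), network@metabolites$id), ]
  missing <- met$id[is.na(met$formula)]
  if (length(missing))
    return(list(elements = numeric(0), charge = NA_real_, balanced = NA,
                skipped = FALSE, unverifiable = missing))
  acc <- numeric(0)
  for (k in seq_along(sv))
    acc <- .formulaAdd(acc, parseFormula(met$formula[k]), sv[[k]])
  acc <- acc[acc != 0]
  chg <- sum(ifelse(is.na(met$charge), 0, met$charge) * sv)
  list(elements = acc, charge = chg,
       balanced = length(acc) == 0 && chg == 0,
       skipped = FALSE, unverifiable = character(0))
}

#' Balance report for every reaction
#' @param network a MetabolicNetwork
#' @return data.frame(id, balanced, skipped, unverifiable, detail)
#' @export
checkBalanceAll <- function(network) {
  rows <- lapply(network@reactions$id, function(id) {
    r <- checkBalance(network, id)
    data.frame(id = id,
               balanced = isTRUE(r$balanced),
               skipped = r$skipped,
               unverifiable = length(r$unverifiable) > 0,
               detail = if (length(r$elements) || (!is.na(r$charge) && r$charge != 0))
                 paste(c(paste0(names(r$elements), ":", r$elements),
                         if (!is.na(r$charge) && r$charge != 0) paste0("charge:", r$charge)),
                       collapse = " ")
               else "")
  })
  do.call(rbind, rows)
}

# ---- core extraction --------------------------------------------------------

#' Extract a core subnetwork
#'
#' Keeps the listed reactions, applies lumping rules (each removes reactions
#' and adds a replacement), adds exchange reactions for metabolites stranded
#' at the cut boundary so the core stays solvable, and drops orphan
#' metabolites.
#'
#' @param network a MetabolicNetwork.
#' @param keepReactions reaction ids to retain.
#' @param lumpingRules list of rules; each is
#'   \code{list(remove = ids, replacement = list(id, stoichiometry, lb, ub))}.
#' @return the core MetabolicNetwork.
#' @export
extractCore <- function(network, keepReactions, lumpingRules = list()) {
  rxn <- network@reactions
  if (!all(keepReactions %in% rxn$id))
    stop("keepReactions not all present: ",
         paste(setdiff(keepReactions, rxn$id), collapse = ", "))
  removedByRule <- unlist(lapply(lumpingRules, `[[`, "remove"))
  keep <- setdiff(keepReactions, removedByRule)
  dropped <- setdiff(rxn$id, keep)

  stoich <- .stoichList(network, keep)
  keepTab <- rxn[match(keep, rxn$id), c("id", "lb", "ub", "gpr")]
  for (rule in lumpingRules) {
    rep <- rule$replacement
    keepTab <- rbind(keepTab, data.frame(id = rep$id,
                                         lb = if (!is.null(rep$lb)) rep$lb else -.LP_BIG,
                                         ub = if (!is.null(rep$ub)) rep$ub else .LP_BIG,
                                         gpr = NA_character_))
    stoich[[rep$id]] <- rep$stoichiometry
  }

  usedMets <- unique(unlist(lapply(stoich, names)))
  # boundary metabolites: used by the core but also touched by dropped
  # non-exchange reactions -> give them an exchange so mass can leave
  exch <- rxn$id[rxn$is_exchange]
  droppedInternal <- setdiff(dropped, exch)
  boundary <- character(0)
  if (length(droppedInternal)) {
    Sdrop <- network@S[, droppedInternal, drop = FALSE]
    touched <- rownames(Sdrop)[Matrix::rowSums(Sdrop != 0) > 0]
    boundary <- intersect(usedMets, touched)
  }
  hasExch <- unlist(lapply(stoich, function(sv) if (length(sv) == 1) names(sv) else NULL))
  for (mt in setdiff(boundary, hasExch)) {
    eid <- paste0("EXCH_", mt)
    while (eid %in% names(stoich)) eid <- paste0(eid, "_core")
    stoich[[eid]] <- stats::setNames(-1, mt)
    keepTab <- rbind(keepTab, data.frame(id = eid, lb = -.LP_BIG, ub = .LP_BIG,
                                         gpr = NA_character_))
  }
  usedMets <- unique(unlist(lapply(stoich, names)))
  metTab <- network@metabolites[match(usedMets, network@metabolites$id), ]

  bio <- if (!is.na(network@biomassId) && network@biomassId %in% keepTab$id)
    network@biomassId else NA_character_
  core <- metabolicNetwork(metTab, keepTab, stoich, biomassId = bio,
                           gam = network@gam, ngam = network@ngam)
  if (!is.na(bio)) {
    sol <- fba(core, objective = bio, sense = "max")
    if (sol@status != "optimal" || sol@objectiveValue < .LP_FLUX_TOL) {
      blocked <- .blockedPrecursors(core, bio)
      stop("core infeasible for biomass; blocked precursor(s): ",
           paste(blocked, collapse = ", "))
    }
  }
  core
}

.stoichList <- function(network, ids = reactionIds(network)) {
  out <- list()
  for (id in ids) {
    sv <- network@S[, id]
    out[[id]] <- sv[sv != 0]
  }
  out
}

.blockedPrecursors <- function(network, biomassId) {
  sv <- network@S[, biomassId]
  precursors <- names(sv)[sv < 0]
  blocked <- character(0)
  for (mt in precursors) {
    producers <- which(network@S[mt, ] > 0)
    consumersRev <- which(network@S[mt, ] < 0 & network@reactions$lb < 0)
    if (length(producers) + length(consumersRev) == 0) blocked <- c(blocked, mt)
  }
  if (!length(blocked)) blocked <- precursors
  blocked
}
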