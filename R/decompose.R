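# Elementary-step decomposition of net reactions.
#
# Every net reaction becomes an ordered sequential mechanism: one binding
# step per substrate molecule (in declared order), one central conversion,
# one release step per product molecule. Substrate-level regulation adds a
# dead-end binding step: to the free enzyme for competitive inhibition (and
# for product inhibition, whose effector is a pathway product), or to the
# fully loaded substrate complex for uncompetitive inhibition.

#' Decompose a network into elementary mass-action mechanisms
#'
#' @param network a [MetabolicNetwork-class]; stoichiometric coefficients
#'   must be integers at core-model scale.
#' @param regulations data.frame(effector, target, type) with type one of
#'   "competitive", "uncompetitive", "product-inhibition"; may be empty.
#' @return a [ReactionMechanisms-class].
#' @export
decomposeNetwork <- function(network, regulations = NULL) {
  if (is.null(regulations))
    regulations <- data.frame(effector = character(0), target = character(0),
                              type = character(0))
  stopifnot(all(c("effector", "target", "type") %in% names(regulations)))
  badT <- setdiff(regulations$type,
                  c("competitive", "uncompetitive", "product-inhibition"))
  if (length(badT)) stop("unknown regulation type(s): ", paste(badT, collapse = ", "))
  badE <- setdiff(regulations$effector, network@metabolites$id)
  if (length(badE)) stop("regulation effector(s) not in network: ",
                         paste(badE, collapse = ", "))
  badR <- setdiff(regulations$target, network@reactions$id)
  if (length(badR)) stop("regulation target(s) not in network: ",
                         paste(badR, collapse = ", "))

  mech <- list()
  for (rid in network@reactions$id) {
    sv <- network@S[, rid]; sv <- sv[sv != 0]
    if (max(abs(sv - round(sv))) > 1e-9)
      stop("reaction '", rid, "' has non-integer stoichiometry; ",
           "lump it before decomposition")
    sv <- round(sv)
    subs <- rep(names(sv)[sv < 0], times = -sv[sv < 0])
    prods <- rep(names(sv)[sv > 0], times = sv[sv > 0])
    if (length(subs) > 4 || length(prods) > 4)
      stop("reaction '", rid, "' has more than 4 substrate or product ",
           "participants; lump parallel chemistry before decomposition")
    p <- length(subs); q <- length(prods)
    forms <- c("E", if (p) paste0("F", seq_len(p)), if (q) paste0("G", seq_len(q)))
    steps <- list()
    idx <- 0L
    fromChain <- "E"
    for (i in seq_len(p)) {
      idx <- idx + 1L
      steps[[idx]] <- data.frame(index = idx, type = "bind",
                                 from = fromChain, to = paste0("F", i),
                                 met = subs[i], metSide = -1)
      fromChain <- paste0("F", i)
    }
    idx <- idx + 1L
    convTo <- if (q) "G1" else "E"
    steps[[idx]] <- data.frame(index = idx, type = "convert",
                               from = fromChain, to = convTo,
                               met = NA_character_, metSide = 0)
    for (i in seq_len(q)) {
      idx <- idx + 1L
      toForm <- if (i < q) paste0("G", i + 1) else "E"
      steps[[idx]] <- data.frame(index = idx, type = "release",
                                 from = paste0("G", i), to = toForm,
                                 met = prods[i], metSide = +1)
    }
    reg <- regulations[regulations$target == rid, , drop = FALSE]
    for (k in seq_len(nrow(reg))) {
      idx <- idx + 1L
      anchorForm <- if (reg$type[k] == "uncompetitive") {
        if (p) paste0("F", p) else "E"
      } else "E"
      iform <- paste0("I", k)
      forms <- c(forms, iform)
      steps[[idx]] <- data.frame(index = idx, type = "regulatory",
                                 from = anchorForm, to = iform,
                                 met = reg$effector[k], metSide = -1)
    }
    mech[[rid]] <- list(forms = forms, steps = do.call(rbind, steps),
                        nChain = p + 1L + q,
                        substrates = subs, products = prods)
  }
  new("ReactionMechanisms", network = network, regulations = regulations,
      mechanisms = mech, cache = new.env(parent = emptyenv()))
}

#' @export
setMethod("show", "ReactionMechanisms", function(object) {
  ns <- vapply(object@mechanisms, function(m) nrow(m$steps), numeric(1))
  cat("ReactionMechanisms:", length(object@mechanisms), "reactions,",
      sum(ns), "elementary steps,", nrow(object@regulations),
      "regulatory interactions\n")
})
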