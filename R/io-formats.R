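# Serialization of analysis objects: cycle specs and stress profiles as
# YAML, flux states and datasets as TSV, parameter sets and deviation
# reports as JSON.

#' Read / write a cycle specification as YAML
#'
#' The YAML maps each marker metabolite to its cycle reaction list, e.g.
#' \code{"h2(c)": [HYDR1, HYDR2]}.
#' @param path file path.
#' @export
readCycleSpec <- function(path) {
  y <- yaml::read_yaml(path)
  cycleSpec(names(y), lapply(y, as.character))
}

#' @rdname readCycleSpec
#' @param spec a [CycleSpec-class].
#' @export
writeCycleSpec <- function(spec, path) {
  yaml::write_yaml(spec@cycleReactions, path)
  invisible(path)
}

#' Read / write a stress profile as YAML
#' @param path file path.
#' @export
readStressProfile <- function(path) {
  y <- yaml::read_yaml(path)
  stressProfile(enzymeFoldChanges = unlist(y$enzymeFoldChanges),
                poolScalings = unlist(y$poolScalings))
}

#' @rdname readStressProfile
#' @param profile a [stressProfile()].
#' @export
writeStressProfile <- function(profile, path) {
  yaml::write_yaml(list(enzymeFoldChanges = as.list(profile$enzymeFoldChanges),
                        poolScalings = as.list(profile$poolScalings)), path)
  invisible(path)
}

#' Write a flux state as TSV (reaction, flux)
#' @param state a [FluxState-class] or [KineticSteadyState-class].
#' @param path file path.
#' @export
writeFluxTSV <- function(state, path) {
  fl <- if (is(state, "FluxState")) state@fluxes else state@fluxes
  utils::write.table(data.frame(reaction = names(fl), flux = fl),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an elementary parameter set as JSON (schema version 1)
#' @param params an [ElementaryParameterSet-class].
#' @param path file path.
#' @export
writeParameterSet <- function(params, path) {
  obj <- list(schema = "elementary-parameter-set/1",
              referenceFlux = as.list(params@referenceFlux),
              reactions = lapply(names(params@kf), function(rid)
                list(fractions = as.list(params@fractions[[rid]]),
                     reversibilities = params@reversibilities[[rid]],
                     kf = params@kf[[rid]], kr = params@kr[[rid]])))
  names(obj$reactions) <- names(params@kf)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParameterSet
#' @export
readParameterSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "elementary-parameter-set/1"))
    stop("unrecognized parameter-set schema: ", obj$schema)
  rids <- names(obj$reactions)
  new("ElementaryParameterSet",
      fractions = lapply(obj$reactions, function(r) unlist(r$fractions)),
      reversibilities = lapply(obj$reactions, `[[`, "reversibilities"),
      kf = lapply(obj$reactions, `[[`, "kf"),
      kr = lapply(obj$reactions, `[[`, "kr"),
      referenceFlux = unlist(obj$referenceFlux))
}

#' Write / read mutant datasets as TSV
#'
#' One row per measurement: dataset, quantity, target, value, cv plus the
#' genotype encoded as "reaction:directive:level" tokens separated by ";".
#' @param datasets list of [MutantDataset-class].
#' @param path file path.
#' @export
writeDatasets <- function(datasets, path) {
  rows <- lapply(datasets, function(ds) {
    gt <- if (nrow(ds@genotype))
      paste(sprintf("%s:%s:%s", ds@genotype$reaction, ds@genotype$directive,
                    ifelse(is.na(ds@genotype$level), "free",
                           .fmtNum(ds@genotype$level))), collapse = ";")
    else ""
    cbind(dataset = ds@name, genotype = gt, ds@measurements)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDatasets
#' @export
readDatasets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (nm in unique(tab$dataset)) {
    sub <- tab[tab$dataset == nm, ]
    gt <- sub$genotype[1]
    genotype <- if (nzchar(gt)) {
      toks <- strsplit(strsplit(gt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      data.frame(reaction = vapply(toks, function(t)
                   paste(t[seq_len(length(t) - 2)], collapse = ":"), ""),
                 directive = vapply(toks, function(t) t[length(t) - 1], ""),
                 level = vapply(toks, function(t)
                   if (t[length(t)] == "free") NA_real_
                   else as.numeric(t[length(t)]), 0))
    } else NULL
    out[[nm]] <- mutantDataset(nm, genotype,
                               sub[, c("quantity", "target", "value", "cv")])
  }
  out
}

#' Write a deviation report as JSON
#' @param report a [DeviationReport-class].
#' @param path file path.
#' @export
writeDeviationReport <- function(report, path) {
  jsonlite::write_json(list(overall = report@overall,
                            perDataset = as.list(report@perDataset),
                            residuals = report@residuals),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
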