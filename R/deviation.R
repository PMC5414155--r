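# The fitting objective: CV-scaled relative deviations.

#' Construct a mutant dataset
#' @param name dataset label.
#' @param genotype data.frame(reaction, directive, level); may be empty for
#'   the wild type.
#' @param measurements data.frame(quantity, target, value, cv).
#' @export
mutantDataset <- function(name, genotype, measurements) {
  if (is.null(genotype))
    genotype <- data.frame(reaction = character(0), directive = character(0),
                           level = numeric(0))
  if (!("level" %in% names(genotype)) && nrow(genotype))
    genotype$level <- NA_real_
  new("MutantDataset", name = name, genotype = genotype,
      measurements = measurements)
}

#' Relative deviation of predictions from measurements
#'
#' For M datasets with N_m measurements each, computes
#' \deqn{\frac{1}{M}\sum_m \frac{1}{N_m}\sum_i \frac{1}{CV_i}
#'       \frac{|v_i - v_i^{exp}|}{|v_i^{exp}|}}
#' The absolute value makes every contribution a magnitude (an "average
#' scaled deviation"); the signed variant, in which residuals of opposite
#' sign can cancel, is available via \code{signed = TRUE}. A zero measured
#' value is scored on the absolute difference scaled by 1/CV and flagged in
#' the residual table.
#'
#' @param predictions named list (by dataset name) of numeric vectors
#'   aligned with each dataset's measurement rows.
#' @param datasets list of [MutantDataset-class].
#' @param signed use the signed residual convention.
#' @return a [DeviationReport-class].
#' @export
relativeDeviation <- function(predictions, datasets, signed = FALSE) {
  perDataset <- numeric(0)
  rows <- list()
  for (ds in datasets) {
    mm <- ds@measurements
    pred <- predictions[[ds@name]]
    if (is.null(pred) || length(pred) != nrow(mm))
      stop("predictions for dataset '", ds@name,
           "' missing or misaligned with its measurements")
    scaled <- numeric(nrow(mm))
    zeroExp <- logical(nrow(mm))
    for (i in seq_len(nrow(mm))) {
      vexp <- mm$value[i]
      if (abs(vexp) < 1e-9) {
        zeroExp[i] <- TRUE
        resid <- (pred[i] - vexp) / mm$cv[i]
      } else {
        resid <- (pred[i] - vexp) / vexp / mm$cv[i]
      }
      scaled[i] <- if (signed) resid else abs(resid)
    }
    perDataset[ds@name] <- mean(scaled)
    rows[[ds@name]] <- data.frame(dataset = ds@name, quantity = mm$quantity,
                                  target = mm$target, predicted = pred,
                                  measured = mm$value, scaled = scaled,
                                  zeroMeasured = zeroExp)
  }
  new("DeviationReport", perDataset = perDataset,
      overall = mean(perDataset), residuals = do.call(rbind, rows))
}

#' @export
setMethod("show", "DeviationReport", function(object) {
  cat("DeviationReport: overall", format(object@overall), "over",
      length(object@perDataset), "dataset(s)\n")
})

# ---- prediction plumbing ----------------------------------------------------

# Measurement targets: yields use an exchange reaction id, concentration
# folds a metabolite id, kcat a reaction id, km "reaction:metabolite".
.predictDataset <- function(mechanisms, params, dataset, levels = NULL,
                            method = "newton", normalizeBy = NULL) {
  model <- kineticModel(mechanisms, params)
  model <- applyGenotype(model, dataset@genotype)
  if (!is.null(levels)) model@enzymeLevels[names(levels)] <- levels
  mm <- dataset@measurements
  needSS <- any(mm$quantity %in% c("yield", "concentration-fold"))
  ss <- NULL
  if (needSS) {
    ss <- tryCatch(steadyState(model, method = method,
                               normalizeBy = normalizeBy),
                   error = function(e) NULL)
    if (is.null(ss) || !ss@converged) return(NULL)
  }
  out <- numeric(nrow(mm))
  kmCache <- list()
  for (i in seq_len(nrow(mm))) {
    q <- mm$quantity[i]; tg <- mm$target[i]
    out[i] <- switch(q,
      "yield" = ss@yields[[tg]],
      "concentration-fold" = ss@concentrations[[tg]],
      "kcat" = {
        if (is.null(kmCache[[tg]]))
          kmCache[[tg]] <- deriveKmKcat(params, tg, mechanisms)
        kmCache[[tg]]$kcat
      },
      "km" = {
        parts <- strsplit(tg, ":", fixed = TRUE)[[1]]
        rid <- parts[1]; met <- paste(parts[-1], collapse = ":")
        if (is.null(kmCache[[rid]]))
          kmCache[[rid]] <- deriveKmKcat(params, rid, mechanisms)
        kmCache[[rid]]$km[[met]]
      },
      stop("unknown measurement quantity '", q, "'"))
    if (!is.finite(out[i])) return(NULL)
  }
  out
}
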