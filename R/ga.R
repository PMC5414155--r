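# Genetic-algorithm selection over sampled ensemble parameters.
#
# An individual picks, for every reaction, one member of the sampled pool
# (the parameters stay anchored, so any mix-and-match individual still
# reproduces the reference state) plus a value for each free enzyme level
# of down/upregulated mutants. Fitness is the overall CV-scaled relative
# deviation across all training datasets; non-convergent steady states earn
# a large penalty instead of being dropped so fitness stays total.

.GA_PENALTY <- 1e3

#' Default GA configuration
#' @param population,generations GA size (defaults 100 x 200).
#' @param crossoverRate probability a selected pair recombines (uniform
#'   crossover).
#' @param mutationRate per-gene mutation probability.
#' @param stagnation stop after this many generations without improvement.
#' @param localSearch polish the final best individual by deterministic
#'   coordinate descent (every alternative pool index per reaction; 1-D
#'   refinement of each free enzyme level).
#' @param nStarts independent GA restarts (deterministically derived seeds,
#'   shared fitness cache); the best run wins. Restarts guard against the
#'   multi-modal landscape of mix-and-match parameter selection.
#' @param seed integer seed (required for determinism).
#' @export
gaConfig <- function(population = 100L, generations = 200L,
                     crossoverRate = 0.8, mutationRate = 0.05,
                     stagnation = 20L, localSearch = TRUE, nStarts = 1L,
                     seed = 1L) {
  list(population = as.integer(population),
       generations = as.integer(generations),
       crossoverRate = crossoverRate, mutationRate = mutationRate,
       stagnation = as.integer(stagnation), localSearch = localSearch,
       nStarts = as.integer(nStarts), seed = as.integer(seed))
}

# Hybrid parameter set: per-reaction slices picked from the pool.
.hybridParams <- function(pool, idx, rids) {
  p1 <- pool[[1]]
  fractions <- list(); revs <- list(); kfL <- list(); krL <- list()
  for (k in seq_along(rids)) {
    src <- pool[[idx[k]]]
    rid <- rids[k]
    fractions[[rid]] <- src@fractions[[rid]]
    revs[[rid]] <- src@reversibilities[[rid]]
    kfL[[rid]] <- src@kf[[rid]]
    krL[[rid]] <- src@kr[[rid]]
  }
  new("ElementaryParameterSet", fractions = fractions,
      reversibilities = revs, kf = kfL, kr = krL,
      referenceFlux = p1@referenceFlux)
}

# free-level slots: one gene per (dataset, reaction) with directive but no
# explicit level
.freeLevelSlots <- function(datasets) {
  rows <- list()
  for (ds in datasets) {
    g <- ds@genotype
    if (!nrow(g)) next
    for (i in seq_len(nrow(g))) {
      if (g$directive[i] %in% c("down", "up") && is.na(g$level[i])) {
        band <- if (g$directive[i] == "down") c(0.1, 1) else c(1, 10)
        rows[[length(rows) + 1L]] <- data.frame(dataset = ds@name,
                                                reaction = g$reaction[i],
                                                lo = band[1], hi = band[2])
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(dataset = character(0), reaction = character(0),
                  lo = numeric(0), hi = numeric(0))
}

.gaFitness <- function(intGenes, realGenes, pool, mechanisms, datasets,
                       slots, rids, signed, normalizeBy, cache) {
  key <- paste(c(intGenes, signif(realGenes, 8)), collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  params <- .hybridParams(pool, intGenes, rids)
  preds <- list()
  for (ds in datasets) {
    lv <- NULL
    if (nrow(slots)) {
      sel <- which(slots$dataset == ds@name)
      if (length(sel)) lv <- stats::setNames(realGenes[sel], slots$reaction[sel])
    }
    preds[ds@name] <- list(.predictDataset(mechanisms, params, ds,
                                           levels = lv,
                                           normalizeBy = normalizeBy))
  }
  bad <- vapply(preds, is.null, logical(1))
  if (any(bad)) {
    for (nm in names(preds)[bad])
      preds[[nm]] <- rep(NA_real_, nrow(datasets[[match(nm, vapply(datasets, function(d) d@name, ""))]]@measurements))
    # non-convergent datasets contribute the penalty directly
    perDs <- numeric(0)
    okPreds <- preds[!bad]
    if (length(okPreds)) {
      rep0 <- relativeDeviation(okPreds, datasets[!bad], signed = signed)
      perDs <- rep0@perDataset
    }
    perDs[names(preds)[bad]] <- .GA_PENALTY
    fit <- mean(perDs)
    out <- list(fitness = fit, report = NULL)
  } else {
    rep0 <- relativeDeviation(preds, datasets, signed = signed)
    out <- list(fitness = rep0@overall, report = rep0)
  }
  cache[[key]] <- out
  out
}

#' Fit the kinetic layer by genetic-algorithm pool selection
#'
#' @param pool list of [ElementaryParameterSet-class] (the sampled ensemble;
#'   candidate parameters per reaction).
#' @param mechanisms the [ReactionMechanisms-class] they belong to.
#' @param datasets list of [MutantDataset-class] training data.
#' @param config a [gaConfig()] list.
#' @param signed use signed residuals in the objective.
#' @param normalizeBy yield normalization reaction (default: substrate
#'   uptake, see [steadyState()]).
#' @return list(params, indices, freeLevels, report, trace, config); trace
#'   is the best objective so far per improvement step (monotone
#'   non-increasing: elitism within a run, best-so-far across restarts and
#'   the final polish).
#' @export
gaFit <- function(pool, mechanisms, datasets, config = gaConfig(),
                  signed = FALSE, normalizeBy = NULL) {
  if (!length(datasets)) stop("at least one dataset required")
  nPool <- length(pool)
  rids <- reactionIds(mechanisms@network)
  nR <- length(rids)
  slots <- .freeLevelSlots(datasets)
  nF <- nrow(slots)
  cache <- new.env(parent = emptyenv())
  evalInd <- function(ind)
    .gaFitness(ind$int, ind$real, pool, mechanisms, datasets, slots, rids,
               signed, normalizeBy, cache)

  runStart <- function(startSeed) {
    set.seed(startSeed)
    popn <- lapply(seq_len(config$population), function(i) {
      list(int = sample.int(nPool, nR, replace = TRUE),
           real = if (nF) stats::runif(nF, slots$lo, slots$hi) else numeric(0))
    })
    # seed one individual with member 1 throughout (plain ensemble member)
    popn[[1]]$int <- rep(1L, nR)
    fits <- vapply(popn, function(ind) evalInd(ind)$fitness, numeric(1))
    if (all(fits >= .GA_PENALTY))
      stop("no individual of generation 0 yields convergent steady states; ",
           "reference anchoring is likely broken")
    best <- which.min(fits)
    bestInd <- popn[[best]]; bestFit <- fits[best]
    trace <- bestFit
    stagnant <- 0L
    for (gen in seq_len(config$generations)) {
      newPop <- list(bestInd)                       # elitism
      while (length(newPop) < config$population) {
        pick <- function() {
          a <- sample.int(config$population, 2)
          popn[[a[if (fits[a[1]] <= fits[a[2]]) 1 else 2]]]
        }
        p1 <- pick(); p2 <- pick()
        c1 <- p1; c2 <- p2
        if (stats::runif(1) < config$crossoverRate) {
          if (nR) {
            mask <- stats::runif(nR) < 0.5
            c1$int[mask] <- p2$int[mask]; c2$int[mask] <- p1$int[mask]
          }
          if (nF) {
            maskr <- stats::runif(nF) < 0.5
            c1$real[maskr] <- p2$real[maskr]; c2$real[maskr] <- p1$real[maskr]
          }
        }
        mutate <- function(ind) {
          mi <- stats::runif(nR) < config$mutationRate
          if (any(mi)) ind$int[mi] <- sample.int(nPool, sum(mi), replace = TRUE)
          if (nF) {
            mr <- stats::runif(nF) < config$mutationRate
            if (any(mr)) ind$real[mr] <- stats::runif(sum(mr), slots$lo[mr],
                                                      slots$hi[mr])
          }
          ind
        }
        newPop[[length(newPop) + 1L]] <- mutate(c1)
        if (length(newPop) < config$population)
          newPop[[length(newPop) + 1L]] <- mutate(c2)
      }
      popn <- newPop
      fits <- vapply(popn, function(ind) evalInd(ind)$fitness, numeric(1))
      gb <- which.min(fits)
      if (fits[gb] < bestFit - 1e-15) {
        bestFit <- fits[gb]; bestInd <- popn[[gb]]; stagnant <- 0L
      } else stagnant <- stagnant + 1L
      trace <- c(trace, bestFit)
      if (bestFit < 1e-12) break
      if (stagnant >= config$stagnation) break
    }
    list(bestInd = bestInd, bestFit = bestFit, trace = trace)
  }

  .withSeed(config$seed, {
    nStarts <- if (is.null(config$nStarts)) 1L else max(1L, config$nStarts)
    bestInd <- NULL; bestFit <- Inf; trace <- numeric(0)
    for (start in seq_len(nStarts)) {
      run <- runStart(config$seed + 7919L * (start - 1L))
      trace <- c(trace, run$trace)
      if (run$bestFit < bestFit) {
        bestFit <- run$bestFit; bestInd <- run$bestInd
      }
      if (bestFit < 1e-12) break
    }
    trace <- cummin(trace)      # best-so-far across restarts stays monotone
    if (isTRUE(config$localSearch) && bestFit > 1e-12) {
      # memetic polish: coordinate descent on the elite individual
      repeat {
        improved <- FALSE
        for (r in seq_len(nR)) {
          for (p in seq_len(nPool)) {
            if (p == bestInd$int[r]) next
            cand <- bestInd; cand$int[r] <- p
            f <- evalInd(cand)$fitness
            if (f < bestFit - 1e-15) {
              bestInd <- cand; bestFit <- f; improved <- TRUE
            }
          }
        }
        for (g in seq_len(nF)) {
          opt <- stats::optimize(function(v) {
            cand <- bestInd; cand$real[g] <- v
            evalInd(cand)$fitness
          }, lower = slots$lo[g], upper = slots$hi[g], tol = 1e-6)
          if (opt$objective < bestFit - 1e-15) {
            bestInd$real[g] <- opt$minimum; bestFit <- opt$objective
            improved <- TRUE
          }
        }
        trace <- c(trace, bestFit)
        if (!improved || bestFit < 1e-12) break
      }
    }
    res <- evalInd(bestInd)
    report <- res$report
    if (is.null(report)) {
      # best individual has non-convergent datasets; rebuild a full report
      report <- new("DeviationReport",
                    perDataset = stats::setNames(rep(.GA_PENALTY,
                                                     length(datasets)),
                                                 vapply(datasets, function(d) d@name, "")),
                    overall = res$fitness, residuals = data.frame())
    }
    freeLv <- if (nF) cbind(slots, level = bestInd$real) else slots
    list(params = .hybridParams(pool, bestInd$int, rids),
         indices = stats::setNames(bestInd$int, rids),
         freeLevels = freeLv, report = report, trace = trace,
         config = config)
  })
}

#' Leave-one-out cross-validation of the GA fit
#'
#' For each fold one dataset is excluded, the model is refit on the rest
#' (same configuration and seed for comparability), and the held-out
#' dataset's deviation under the fold fit is compared with its deviation
#' under the all-data fit. The difference is the accuracy reduction caused
#' by losing that dataset's information.
#'
#' @inheritParams gaFit
#' @return data.frame(dataset, heldOut, fullFit, reduction).
#' @export
crossValidate <- function(pool, mechanisms, datasets, config = gaConfig(),
                          signed = FALSE, normalizeBy = NULL) {
  if (length(datasets) < 2) stop("cross-validation needs >= 2 datasets")
  nms <- vapply(datasets, function(d) d@name, "")
  full <- gaFit(pool, mechanisms, datasets, config, signed, normalizeBy)
  evalOn <- function(fit, ds) {
    lv <- NULL
    if (nrow(fit$freeLevels)) {
      sel <- which(fit$freeLevels$dataset == ds@name)
      if (length(sel)) lv <- stats::setNames(fit$freeLevels$level[sel],
                                             fit$freeLevels$reaction[sel])
    }
    # levels free in the held-out genotype but never fit: band midpoint
    g <- ds@genotype
    if (nrow(g)) for (i in seq_len(nrow(g))) {
      if (g$directive[i] %in% c("down", "up") && is.na(g$level[i]) &&
          !(g$reaction[i] %in% names(lv))) {
        band <- if (g$directive[i] == "down") c(0.1, 1) else c(1, 10)
        lv <- c(lv, stats::setNames(sqrt(band[1] * band[2]), g$reaction[i]))
      }
    }
    pred <- .predictDataset(mechanisms, fit$params, ds, levels = lv,
                            normalizeBy = normalizeBy)
    if (is.null(pred)) return(.GA_PENALTY)
    relativeDeviation(stats::setNames(list(pred), ds@name), list(ds),
                      signed = signed)@overall
  }
  out <- data.frame(dataset = nms, heldOut = NA_real_, fullFit = NA_real_)
  for (k in seq_along(datasets)) {
    rest <- datasets[-k]
    fit_k <- tryCatch(gaFit(pool, mechanisms, rest, config, signed,
                            normalizeBy),
                      error = function(e) {
                        warning("fold '", nms[k], "' skipped: ",
                                conditionMessage(e))
                        NULL
                      })
    if (is.null(fit_k)) next
    out$heldOut[k] <- evalOn(fit_k, datasets[[k]])
    out$fullFit[k] <- evalOn(full, datasets[[k]])
  }
  out$reduction <- out$heldOut - out$fullFit
  out
}
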