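# Ensemble sampling anchored to a reference steady state.
#
# For each reaction the sampled degrees of freedom are (i) the distribution
# of total enzyme across its forms (flat simplex) and (ii) one reversibility
# R in (0,1) per elementary step. Rate constants are then back-computed so
# every step's net rate equals the reaction's reference net flux at
# reference (normalized, = 1) concentrations, which makes the reference
# state an exact steady state of every sampled member.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.sampleMemberReaction <- function(m, vref) {
  nf <- length(m$forms)
  g <- stats::rgamma(nf, shape = 1)
  frac <- stats::setNames(g / sum(g), m$forms)
  ns <- nrow(m$steps)
  R <- stats::runif(ns)
  kf <- kr <- numeric(ns)
  for (s in seq_len(ns)) {
    st <- m$steps[s, ]
    eFrom <- frac[[st$from]]; eTo <- frac[[st$to]]
    if (st$type == "regulatory" || abs(vref) < 1e-12) {
      # dead-end or inactive step: sampled exchange velocity at equilibrium
      lam <- exp(stats::runif(1, log(0.1), log(10))) * max(abs(vref), 1)
      vf <- vr <- lam
    } else if (vref > 0) {
      vf <- vref / (1 - R[s]); vr <- vref * R[s] / (1 - R[s])
    } else {
      vr <- -vref / (1 - R[s]); vf <- -vref * R[s] / (1 - R[s])
    }
    kf[s] <- vf / eFrom            # reference concentrations are all 1
    kr[s] <- vr / eTo
    if (!is.finite(kf[s]) || !is.finite(kr[s]) || kf[s] <= 0 || kr[s] < 0)
      stop("rate-constant back-computation failed (degenerate enzyme fraction)")
  }
  list(frac = frac, R = R, kf = kf, kr = kr)
}

#' Sample an ensemble of anchored parameter sets
#'
#' @param mechanisms a [ReactionMechanisms-class].
#' @param referenceFlux named numeric of reference net fluxes, one per
#'   reaction, satisfying \eqn{S v = 0}.
#' @param nModels ensemble size.
#' @param seed integer seed; the draw is fully deterministic given it and no
#'   global random state is consumed.
#' @param maxRetries resampling attempts per reaction on degenerate draws.
#' @return list of [ElementaryParameterSet-class], length \code{nModels}.
#' @export
sampleEnsemble <- function(mechanisms, referenceFlux, nModels, seed,
                           maxRetries = 25L) {
  net <- mechanisms@network
  rids <- reactionIds(net)
  if (!all(rids %in% names(referenceFlux)))
    stop("referenceFlux missing reactions: ",
         paste(setdiff(rids, names(referenceFlux)), collapse = ", "))
  vref <- referenceFlux[rids]
  resid <- max(abs(as.numeric(net@S %*% vref)))
  if (resid > 1e-6)
    stop("referenceFlux violates S v = 0 (residual ", format(resid), ")")
  .withSeed(seed, {
    lapply(seq_len(nModels), function(k) {
      fractions <- list(); revs <- list(); kfL <- list(); krL <- list()
      for (rid in rids) {
        m <- mechanisms@mechanisms[[rid]]
        smp <- NULL
        for (tr in seq_len(maxRetries)) {
          smp <- tryCatch(.sampleMemberReaction(m, vref[[rid]]),
                          error = function(e) NULL)
          if (!is.null(smp)) break
        }
        if (is.null(smp))
          stop("could not sample consistent parameters for '", rid, "'")
        fractions[[rid]] <- smp$frac
        revs[[rid]] <- smp$R
        kfL[[rid]] <- smp$kf
        krL[[rid]] <- smp$kr
      }
      new("ElementaryParameterSet", fractions = fractions,
          reversibilities = revs, kf = kfL, kr = krL,
          referenceFlux = vref)
    })
  })
}

#' @export
setMethod("show", "ElementaryParameterSet", function(object) {
  cat("ElementaryParameterSet:", length(object@kf), "reactions anchored to",
      "reference flux\n")
})

# ---- lumped Michaelis-Menten constants --------------------------------------

# Quasi-steady-state net rate of one reaction at fixed metabolite
# concentrations: enzyme-form distribution solves the linear balance of the
# elementary steps (total enzyme = 1).
.qssRate <- function(m, kf, kr, conc) {
  forms <- m$forms
  nf <- length(forms)
  A <- matrix(0, nf, nf, dimnames = list(forms, forms))
  for (s in seq_len(nrow(m$steps))) {
    st <- m$steps[s, ]
    # a consumed metabolite multiplies the forward rate, a released one the
    # reverse (rebinding) rate
    f <- kf[s] * (if (!is.na(st$met) && st$metSide < 0) conc[[st$met]] else 1)
    r <- kr[s] * (if (!is.na(st$met) && st$metSide > 0) conc[[st$met]] else 1)
    A[st$from, st$from] <- A[st$from, st$from] - f
    A[st$to, st$from] <- A[st$to, st$from] + f
    A[st$to, st$to] <- A[st$to, st$to] - r
    A[st$from, st$to] <- A[st$from, st$to] + r
  }
  # stationary form distribution: row-equilibrated balance equations stacked
  # with the conservation row (saturating concentrations make raw rows span
  # many orders of magnitude)
  rs <- apply(abs(A), 1, max)
  rs[rs < 1e-300] <- 1
  stacked <- rbind(A / rs, rep(1, nf))
  b <- c(rep(0, nf), 1)
  e <- qr.solve(stacked, b, tol = 1e-12)
  # evaluate the net rate at the central conversion step: it carries no
  # metabolite factor, so saturating concentrations cannot cause
  # catastrophic cancellation
  s1 <- which(m$steps$type == "convert")[1]
  kf[s1] * e[[m$steps$from[s1]]] - kr[s1] * e[[m$steps$to[s1]]]
}

#' Lumped Michaelis-Menten constants implied by elementary parameters
#'
#' Computes the quasi-steady-state saturation curve of one decomposed
#' reaction and reports kcat (limiting rate per total enzyme) and the
#' half-saturating concentration Km of each distinct substrate (co-substrates
#' saturating, products absent), plus the same quantities for the reverse
#' direction. Units are normalized to the reference state (concentrations in
#' fold-of-reference, rates in reference flux units).
#'
#' Dead-end regulatory binding steps are excluded: the lumped constants
#' characterize the catalytic chain itself, the way in-vitro Michaelis-Menten
#' assays report them.
#'
#' @param params an [ElementaryParameterSet-class].
#' @param reaction reaction id.
#' @param mechanisms the [ReactionMechanisms-class] the parameters belong to.
#' @return list(kcat, km, kcatRev, kmRev); km vectors are named by
#'   metabolite.
#' @export
deriveKmKcat <- function(params, reaction, mechanisms) {
  m <- mechanisms@mechanisms[[reaction]]
  if (is.null(m)) stop("unknown reaction '", reaction, "'")
  kf <- params@kf[[reaction]]; kr <- params@kr[[reaction]]
  chain <- m$steps$type != "regulatory"
  if (!all(chain)) {
    m$steps <- m$steps[chain, , drop = FALSE]
    m$forms <- setdiff(m$forms, grep("^I", m$forms, value = TRUE))
    kf <- kf[chain]; kr <- kr[chain]
  }
  subs <- unique(m$substrates); prods <- unique(m$products)
  effectors <- unique(m$steps$met[m$steps$type == "regulatory"])
  SAT <- 1e8; ABSENT <- 0
  baseConc <- function(sVal, pVal) {
    conc <- c(stats::setNames(rep(sVal, length(subs)), subs),
              stats::setNames(rep(pVal, length(prods)), prods))
    for (ef in effectors) if (!(ef %in% names(conc))) conc[ef] <- 0
    conc
  }
  rateAt <- function(conc) .qssRate(m, kf, kr, conc)
  dir1 <- list()
  if (length(subs)) {
    vmax <- rateAt(baseConc(SAT, ABSENT))
    km <- vapply(subs, function(sb) {
      f <- function(lg) {
        conc <- baseConc(SAT, ABSENT); conc[sb] <- 10^lg
        rateAt(conc) - vmax / 2
      }
      10^stats::uniroot(f, c(-9, 8), tol = 1e-12)$root
    }, numeric(1))
    dir1 <- list(kcat = vmax, km = km)
  } else dir1 <- list(kcat = NA_real_, km = stats::setNames(numeric(0), character(0)))
  dir2 <- list()
  if (length(prods)) {
    vmaxR <- -rateAt(baseConc(ABSENT, SAT))
    kmR <- vapply(prods, function(pr) {
      f <- function(lg) {
        conc <- baseConc(ABSENT, SAT); conc[pr] <- 10^lg
        -rateAt(conc) - vmaxR / 2
      }
      10^stats::uniroot(f, c(-9, 8), tol = 1e-12)$root
    }, numeric(1))
    dir2 <- list(kcatRev = vmaxR, kmRev = kmR)
  } else dir2 <- list(kcatRev = NA_real_, kmRev = stats::setNames(numeric(0), character(0)))
  c(dir1, dir2)
}
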