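# Linear programming core.
#
# Dense bounded-variable primal simplex (two phases, Bland's entering rule so
# it cannot cycle). Problem sizes here are small -- core fermentation networks
# have tens of reactions -- so a dense implementation with a fresh basis
# factorization per pivot is both robust and fast enough.

.LP_BIG <- 1000          # flux cap used when a bound is infinite (mmol/gDW/h)
.LP_FEAS_TOL <- 1e-9     # primal feasibility / pivot tolerance
.LP_FLUX_TOL <- 1e-6     # reported-flux rounding tolerance

# Solve  max/min c'x  s.t.  Aeq x = beq,  lb <= x <= ub.
# All bounds must be finite (callers clamp at +-.LP_BIG).
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, objective).
.simplexBounded <- function(cc, Aeq, beq, lb, ub, maximize = TRUE,
                            maxit = 50000L) {
  n <- length(cc)
  m <- nrow(Aeq)
  stopifnot(ncol(Aeq) == n, length(beq) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("internal LP requires finite bounds")
  if (any(lb > ub + .LP_FEAS_TOL))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  obj <- if (maximize) as.numeric(cc) else -as.numeric(cc)

  # Augment with m artificial variables for phase 1.
  ntot <- n + m
  A <- cbind(as.matrix(Aeq), diag(m))
  L <- c(lb, rep(0, m))
  U <- c(ub, rep(Inf, m))

  # Start: structural variables at the bound of smaller magnitude.
  xs <- ifelse(abs(lb) <= abs(ub), lb, ub)
  atLower <- c(abs(lb) <= abs(ub), rep(TRUE, m))
  r <- beq - as.numeric(as.matrix(Aeq) %*% xs)
  for (i in seq_len(m)) A[i, n + i] <- if (r[i] >= 0) 1 else -1
  x <- c(xs, abs(r))
  basis <- n + seq_len(m)
  inBasis <- logical(ntot); inBasis[basis] <- TRUE

  runPhase <- function(cvec, x, basis, inBasis, atLower) {
    it <- 0L
    tol <- .LP_FEAS_TOL
    repeat {
      it <- it + 1L
      if (it > maxit) stop("simplex iteration limit reached")
      B <- A[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cvec[basis]),
                    error = function(e) qr.solve(t(B), cvec[basis]))
      dvec <- cvec - as.numeric(y %*% A)    # reduced costs (maximization form)
      enter <- 0L
      for (j in seq_len(ntot)) {            # Bland: first eligible index
        if (inBasis[j] || L[j] == U[j]) next
        if (atLower[j] && dvec[j] > tol) { enter <- j; break }
        if (!atLower[j] && dvec[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L)
        return(list(x = x, basis = basis, inBasis = inBasis,
                    atLower = atLower, status = "optimal"))
      dirUp <- atLower[enter]
      w <- as.numeric(solve(B, A[, enter]))
      if (!dirUp) w <- -w                   # so x_B moves by -w * t, t >= 0
      tmax <- U[enter] - L[enter]           # distance to the opposite bound
      leave <- 0L; leaveToLower <- TRUE
      for (k in seq_len(m)) {
        bi <- basis[k]
        if (w[k] > tol) {
          t_k <- (x[bi] - L[bi]) / w[k]; toLower <- TRUE
        } else if (w[k] < -tol) {
          t_k <- (U[bi] - x[bi]) / (-w[k]); toLower <- FALSE
        } else next
        if (t_k < tmax - tol) {
          tmax <- t_k; leave <- k; leaveToLower <- toLower
        } else if (t_k <= tmax + tol && leave != 0L && bi < basis[leave]) {
          tmax <- min(tmax, t_k); leave <- k; leaveToLower <- toLower
        }
      }
      if (!is.finite(tmax))
        return(list(x = x, basis = basis, inBasis = inBasis,
                    atLower = atLower, status = "unbounded"))
      tmax <- max(tmax, 0)
      x[basis] <- x[basis] - tmax * w
      x[enter] <- x[enter] + (if (dirUp) tmax else -tmax)
      if (leave == 0L) {                    # entering var flips to other bound
        atLower[enter] <- !atLower[enter]
      } else {
        bi <- basis[leave]
        inBasis[bi] <- FALSE
        atLower[bi] <- leaveToLower
        x[bi] <- if (leaveToLower) L[bi] else U[bi]
        basis[leave] <- enter
        inBasis[enter] <- TRUE
      }
    }
  }

  # Phase 1: drive artificials to zero.
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- runPhase(c1, x, basis, inBasis, atLower)
  art <- p1$x[n + seq_len(m)]
  if (sum(abs(art)) > 1e-7)
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  # Freeze artificials at zero for phase 2.
  U[n + seq_len(m)] <- 0
  x <- p1$x
  x[n + seq_len(m)] <- 0
  c2 <- c(obj, rep(0, m))
  p2 <- runPhase(c2, x, p1$basis, p1$inBasis, p1$atLower)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  sol <- p2$x[seq_len(n)]
  list(status = "optimal", x = sol, objective = sum(cc * sol))
}

# General small LP with optional inequality rows (Ain x <= bin), solved by
# adding slack variables and delegating to the bounded simplex.
.lpSolve <- function(cc, Aeq = NULL, beq = NULL, Ain = NULL, bin = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(cc)
  lb <- pmax(lb, -.LP_BIG); ub <- pmin(ub, .LP_BIG)
  if (is.null(Aeq)) { Aeq <- matrix(0, 0, n); beq <- numeric(0) }
  Aeq <- as.matrix(Aeq)
  if (!is.null(Ain) && nrow(Ain) > 0) {
    Ain <- as.matrix(Ain)
    k <- nrow(Ain)
    slackCap <- abs(bin) + .LP_BIG * (rowSums(abs(Ain)) + 1)
    Aeq <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), k)), cbind(Ain, diag(k)))
    beq <- c(beq, bin)
    res <- .simplexBounded(c(cc, rep(0, k)), Aeq, beq,
                           c(lb, rep(0, k)), c(ub, slackCap),
                           maximize = maximize)
    if (res$status == "optimal") res$x <- res$x[seq_len(n)]
    return(res)
  }
  .simplexBounded(cc, Aeq, beq, lb, ub, maximize = maximize)
}
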