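# Internal linear-programming layer.
#
# Dense two-phase primal simplex with Bland's anti-cycling rule. Written
# in-package because the FBA sub-problems arising here (fixed exchange
# fluxes, hence zero right-hand sides and heavily degenerate bases) are a
# pathological class for the general-purpose simplex routines available in
# the R ecosystem at hand. Every accepted solution is re-validated against
# the original constraints.

# Solve: min/max c'x  s.t.  A x (<=|=) b,  x >= 0.
# sense: character vector per row, "<=" or "=".
# Returns list(status, x, value).
.simplexCore <- function(cc, A, b, sense, maximize = FALSE, tol = 1e-9) {
  if (maximize) cc <- -cc
  n <- nrow(A); m <- ncol(A)
  # normalize to b >= 0 ( "<=" rows with negative b become ">=" )
  geq <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (b[i] < 0) {
      A[i, ] <- -A[i, ]; b[i] <- -b[i]
      if (sense[i] == "<=") geq[i] <- TRUE
    }
  }
  isLe <- sense == "<=" & !geq
  isGe <- sense == "<=" & geq
  isEq <- sense == "="

  nSlack <- sum(isLe) + sum(isGe)
  nArt <- sum(isGe) + sum(isEq)
  total <- m + nSlack + nArt
  T <- matrix(0, n, total + 1)
  T[, seq_len(m)] <- A
  T[, total + 1] <- b
  basis <- integer(n)
  sl <- m; ar <- m + nSlack
  for (i in seq_len(n)) {
    if (isLe[i]) {
      sl <- sl + 1; T[i, sl] <- 1; basis[i] <- sl
    } else if (isGe[i]) {
      sl <- sl + 1; T[i, sl] <- -1
      ar <- ar + 1; T[i, ar] <- 1; basis[i] <- ar
    } else {
      ar <- ar + 1; T[i, ar] <- 1; basis[i] <- ar
    }
  }
  artCols <- seq.int(m + nSlack + 1, length.out = nArt)

  pivot <- function(T, basis, pr, pc) {
    T[pr, ] <- T[pr, ] / T[pr, pc]
    other <- setdiff(seq_len(nrow(T)), pr)
    fac <- T[other, pc]
    T[other, ] <- T[other, , drop = FALSE] -
      outer(fac, T[pr, ])
    basis[pr] <- pc
    list(T = T, basis = basis)
  }

  # entering threshold is tighter than the pivot threshold: leaving a
  # reduced cost of ~1e-9 unexploited shifts small objectives detectably
  enterTol <- 1e-11
  run <- function(T, basis, cost, allowed) {
    # canonical objective row: z_j - c_j = c_B B^-1 a_j - c_j
    maxit <- 500 * (ncol(T) + nrow(T))
    for (it in seq_len(maxit)) {
      cB <- cost[basis]
      red <- as.vector(crossprod(T[, seq_len(ncol(T) - 1), drop = FALSE],
                                 cB)) - cost
      red[!allowed] <- -Inf   # never enter disallowed columns
      ent <- which(red > enterTol)
      if (!length(ent)) return(list(T = T, basis = basis, status = "optimal"))
      pc <- min(ent)                       # Bland: smallest index enters
      col <- T[, pc]
      rows <- which(col > tol)
      if (!length(rows)) return(list(T = T, basis = basis,
                                     status = "unbounded"))
      ratio <- T[rows, ncol(T)] / col[rows]
      rmin <- rows[ratio <= min(ratio) + 1e-12]
      pr <- rmin[which.min(basis[rmin])]   # Bland: smallest basis leaves
      st <- pivot(T, basis, pr, pc)
      T <- st$T; basis <- st$basis
    }
    list(T = T, basis = basis, status = "maxit")
  }

  # phase 1: minimize the sum of artificials (run() minimizes its cost)
  if (nArt > 0) {
    cost1 <- numeric(total); cost1[artCols] <- 1
    allowed <- rep(TRUE, total)
    r1 <- run(T, basis, cost1, allowed)
    T <- r1$T; basis <- r1$basis
    if (r1$status != "optimal")
      return(list(status = "failed", x = NULL, value = NA_real_))
    if (sum(T[basis %in% artCols, ncol(T)]) > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # drive remaining zero-level artificials out of the basis
    dropRows <- integer()
    for (i in which(basis %in% artCols)) {
      cand <- which(abs(T[i, seq_len(m + nSlack)]) > tol)
      if (length(cand)) {
        st <- pivot(T, basis, i, min(cand))
        T <- st$T; basis <- st$basis
      } else dropRows <- c(dropRows, i)   # redundant constraint
    }
    if (length(dropRows)) {
      T <- T[-dropRows, , drop = FALSE]
      basis <- basis[-dropRows]
    }
  }

  # phase 2: minimize the (possibly sign-flipped) cost, artificials barred
  cost2 <- numeric(total); cost2[seq_len(m)] <- cc
  allowed <- rep(TRUE, total)
  if (nArt > 0) allowed[artCols] <- FALSE
  r2 <- run(T, basis, cost2, allowed)
  if (r2$status != "optimal")
    return(list(status = if (r2$status == "unbounded") "unbounded"
                else "failed", x = NULL, value = NA_real_))
  x <- numeric(m)
  inX <- r2$basis <= m
  x[r2$basis[inX]] <- r2$T[inX, ncol(r2$T)]
  val <- sum(cc * x)
  list(status = "optimal", x = x, value = if (maximize) -val else val)
}

# Snap a simplex vertex onto its active set: variables at (near) bounds are
# fixed exactly and the remaining ones re-solved from the equality system,
# removing the roundoff accumulated across tableau pivots. Falls back to the
# unpolished point whenever the refinement is not clearly valid.
.polishVertex <- function(v, obj, Aeq, beq, lb, ub, Aineq = NULL,
                          bineq = NULL, tol = 1e-6) {
  if (is.null(Aeq) || nrow(Aeq) == 0) return(v)
  A <- as.matrix(Aeq)
  scale <- max(1, max(abs(v)))
  atLb <- abs(v - lb) < tol * scale
  atUb <- abs(ub - v) < tol * scale
  act <- which(atLb | atUb)
  free <- setdiff(seq_along(v), act)
  vp <- v
  vp[act] <- ifelse(atLb[act], lb[act], ub[act])
  if (length(free)) {
    Af <- A[, free, drop = FALSE]
    if (qr(Af)$rank < length(free)) return(v)
    sol <- tryCatch(qr.solve(Af, beq - A[, act, drop = FALSE] %*% vp[act]),
                    error = function(e) NULL)
    if (is.null(sol)) return(v)
    vp[free] <- sol
  }
  okEq <- max(abs(as.vector(A %*% vp) - beq)) <= 1e-8 * scale
  okBounds <- all(vp >= lb - 1e-9 * scale) && all(vp <= ub + 1e-9 * scale)
  okObj <- abs(sum(obj * vp) - sum(obj * v)) <= 1e-5 * scale
  okIneq <- is.null(Aineq) || nrow(Aineq) == 0 ||
    all(as.vector(Aineq %*% vp) <= bineq + 1e-8 * scale)
  if (okEq && okBounds && okObj && okIneq) vp else v
}

# Solve  max/min  obj'v  s.t. Aeq v = beq, Aineq v <= bineq, lb <= v <= ub
# (finite bounds). Shifts to the non-negative orthant, runs the simplex and
# validates the result. Returns list(status, x = v, value).
solveLP <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                    lb, ub, maximize = TRUE, tol = 1e-7) {
  m <- length(obj)
  stopifnot(length(lb) == m, length(ub) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solveLP requires finite bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  rows <- list(); rhs <- numeric(); sense <- character()
  addRows <- function(A, b, s) {
    rows[[length(rows) + 1L]] <<- A
    rhs <<- c(rhs, b)
    sense <<- c(sense, rep(s, length(b)))
  }
  addRows(diag(m), ub - lb, "<=")
  if (!is.null(Aineq) && nrow(Aineq))
    addRows(as.matrix(Aineq), bineq - as.vector(Aineq %*% lb), "<=")
  if (!is.null(Aeq) && nrow(Aeq))
    addRows(as.matrix(Aeq), beq - as.vector(as.matrix(Aeq) %*% lb), "=")
  A <- do.call(rbind, rows)

  res <- .simplexCore(obj, A, rhs, sense, maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, value = NA_real_))
  v <- res$x + lb
  v <- .polishVertex(v, obj, Aeq, beq, lb, ub, Aineq, bineq)
  scale <- max(1, max(abs(v)))
  okBounds <- all(v >= lb - tol * scale) && all(v <= ub + tol * scale)
  okEq <- is.null(Aeq) || nrow(Aeq) == 0 ||
    max(abs(as.vector(as.matrix(Aeq) %*% v) - beq)) <= tol * scale
  okIneq <- is.null(Aineq) || nrow(Aineq) == 0 ||
    all(as.vector(as.matrix(Aineq) %*% v) <= bineq + tol * scale)
  if (!(okBounds && okEq && okIneq))
    return(list(status = "failed", x = NULL, value = NA_real_))
  list(status = "optimal", x = v, value = sum(obj * v))
}
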