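# Brute-force vertex-enumeration oracle for small LP instances:
# max obj'v s.t. S v = 0, lb <= v <= ub (finite bounds).
#
# Substitutes out variables with lb == ub, then enumerates every basic
# solution of the reduced polytope (choose dof variables pinned at a bound,
# solve the remaining square system). Independent of the simplex code path.
enumerateLPVertices <- function(S, lb, ub, obj, tol = 1e-7) {
  S <- as.matrix(S)
  m <- length(lb)
  fixed <- which(ub - lb <= 1e-12)
  free <- setdiff(seq_len(m), fixed)
  vfix <- (lb[fixed] + ub[fixed]) / 2
  b <- if (length(fixed)) -as.vector(S[, fixed, drop = FALSE] %*% vfix)
  else rep(0, nrow(S))
  Sf <- S[, free, drop = FALSE]
  keep <- apply(abs(Sf), 1, max) > 1e-12
  stopifnot(all(abs(b[!keep]) < 1e-9))
  Sf <- Sf[keep, , drop = FALSE]; b <- b[keep]
  r <- qr(Sf)$rank
  nf <- length(free)
  dof <- nf - r
  stopifnot(dof >= 0)

  verts <- list()
  addVertex <- function(v) verts[[length(verts) + 1L]] <<- v
  if (dof == 0) {
    sol <- qr.solve(Sf, b)
    v <- numeric(m); v[fixed] <- vfix; v[free] <- sol
    if (all(v >= lb - tol) && all(v <= ub + tol)) addVertex(v)
  } else {
    for (sel in utils::combn(nf, dof, simplify = FALSE)) {
      rest <- setdiff(seq_len(nf), sel)
      A <- Sf[, rest, drop = FALSE]
      if (qr(A)$rank < length(rest)) next
      for (mask in 0:(2^dof - 1)) {
        bits <- as.integer(intToBits(mask))[seq_len(dof)]
        vSel <- ifelse(bits == 1, ub[free][sel], lb[free][sel])
        rhs <- b - Sf[, sel, drop = FALSE] %*% vSel
        sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        v <- numeric(m)
        v[fixed] <- vfix
        v[free[sel]] <- vSel
        v[free[rest]] <- sol
        if (max(abs(S %*% v)) > 1e-6) next
        if (any(v < lb - tol) || any(v > ub + tol)) next
        addVertex(v)
      }
    }
  }
  if (!length(verts)) return(NULL)
  vals <- vapply(verts, function(v) sum(obj * v), numeric(1))
  opt <- max(vals)
  atOpt <- verts[vals >= opt - tol * max(1, abs(opt))]
  sums <- vapply(atOpt, function(v) sum(abs(v)), numeric(1))
  list(opt = opt, minSumAbs = min(sums), nVertices = length(verts),
       nOptimal = length(atOpt))
}
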