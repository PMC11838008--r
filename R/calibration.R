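#' Build a replicate-resolved fermentation dataset
#'
#' Computes per-(time, observable) replicate means and standard deviations.
#' Replicate standard deviations can be zero at individual sampling times,
#' so the weighting sigma is floored at `sigmaFloorFrac` times the
#' observable's maximum mean value.
#'
#' @param data data.frame with columns `time`, `observable`, `replicate`,
#'   `value`.
#' @param mapping Named character vector mapping each observable to a
#'   kinetic state name (e.g. `c(biomass = "X", glucose = "Glx")`).
#' @param sigmaFloorFrac Standard-deviation floor as a fraction of each
#'   observable's maximum (default 0.05).
#' @param sigmaModel `"pointwise"` (default) uses each point's replicate
#'   standard deviation; `"pooled"` scales a per-observable pooled relative
#'   error (median replicate CV) by each point's mean, which is far more
#'   stable when only a handful of replicates is available.
#' @return A [FermentationDataset].
#' @export
fermentationDataset <- function(data, mapping, sigmaFloorFrac = 0.05,
                                sigmaModel = c("pointwise", "pooled")) {
  sigmaModel <- match.arg(sigmaModel)
  need <- c("time", "observable", "replicate", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  nrep <- tapply(data$replicate, data$observable,
                 function(r) length(unique(r)))
  if (any(nrep < 2))
    stop("at least 2 replicates are required to compute sigma from data")
  agg <- stats::aggregate(value ~ time + observable, data = data,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  summ <- data.frame(time = agg$time, observable = agg$observable,
                     mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                     stringsAsFactors = FALSE)
  mx <- tapply(abs(summ$mean), summ$observable, max)
  floorv <- sigmaFloorFrac * pmax(mx[summ$observable], .Machine$double.eps)
  if (sigmaModel == "pointwise") {
    summ$sigma <- pmax(summ$sd, floorv)
  } else {
    cvHat <- vapply(split(summ, summ$observable), function(d) {
      ok <- abs(d$mean) > 1e-3 * max(abs(d$mean))
      stats::median(d$sd[ok] / abs(d$mean[ok]))
    }, numeric(1))
    summ$sigma <- pmax(cvHat[summ$observable] * abs(summ$mean), floorv)
  }
  summ <- summ[order(summ$observable, summ$time), ]
  rownames(summ) <- NULL
  new("FermentationDataset", data = data, mapping = mapping,
      summary = summ, sigmaFloorFrac = sigmaFloorFrac)
}

setMethod("show", "FermentationDataset", function(object) {
  cat("FermentationDataset:", length(unique(object@data$observable)),
      "observables,", length(unique(object@data$time)), "sampling times,",
      length(unique(object@data$replicate)), "replicates\n")
})

# Model predictions for every (time, observable) row of the summary table.
.predictObservables <- function(params, dataset, init, rtol, atol) {
  summ <- dataset@summary
  tGrid <- sort(unique(c(0, summ$time)))
  traj <- simulateKinetics(params, init, tGrid, rtol = rtol, atol = atol)
  states <- stateMatrix(traj)
  ri <- match(summ$time, tGrid)
  ci <- match(dataset@mapping[summ$observable], colnames(states))
  states[cbind(ri, ci)]
}

# Weighted residual vector (yd - ym) / sigma_d over all data points.
.weightedResiduals <- function(params, dataset, init,
                               rtol = 1e-7, atol = 1e-9) {
  summ <- dataset@summary
  ym <- .predictObservables(params, dataset, init, rtol, atol)
  (summ$mean - ym) / summ$sigma
}

#' Weighted log-likelihood calibration cost
#'
#' Weighted sum of squared residuals between replicate means and model
#' predictions, `sum_d ((y_d - y_m) / sigma_d)^2`, equivalent (up to a
#' constant) to minus twice the Gaussian log-likelihood with
#' replicate-derived standard deviations. Integration failures return a
#' large penalized value (flagged via the `"failed"` attribute) so that
#' global searches can continue past pathological parameter draws.
#'
#' @param params A [KineticParameters] object.
#' @param dataset A [FermentationDataset].
#' @param init Named initial state vector.
#' @param rtol,atol Integration tolerances used during calibration.
#' @return Scalar cost; attribute `"failed"` is TRUE when simulation failed.
#' @export
weightedCost <- function(params, dataset, init, rtol = 1e-7, atol = 1e-9) {
  r <- tryCatch(.weightedResiduals(params, dataset, init, rtol, atol),
                error = function(e) NULL)
  if (is.null(r)) {
    out <- 1e10
    attr(out, "failed") <- TRUE
    return(out)
  }
  out <- sum(r^2)
  attr(out, "failed") <- FALSE
  out
}

.applyTheta <- function(params, theta) {
  params@values[names(theta)] <- theta
  params
}

#' Fit kinetic parameters to time-series data
#'
#' Weighted maximum-likelihood estimation by a seeded multistart: Latin
#' hypercube samples within the parameter bounds (plus the supplied
#' template values as the first start), each refined by bounded
#' Levenberg-Marquardt on the weighted residual vector. Only the parameters
#' flagged estimable in `params` (optionally restricted by `subset`) are
#' searched; all others are held fixed. Deterministic given `seed`.
#'
#' @param dataset A [FermentationDataset].
#' @param params Template [KineticParameters]; its values provide the first
#'   start and its `estimable` slot the default free-parameter set.
#' @param init Named initial state for simulation.
#' @param lower,upper Named bounds for the free parameters (defaults: a wide
#'   multiplicative window around the template values).
#' @param subset Optional character vector restricting the free parameters.
#' @param nStarts Number of multistart points (default 5).
#' @param seed Integer seed (mandatory).
#' @param rtol,atol Integration tolerances used during fitting.
#' @return A [FitResult].
#' @export
fitKinetics <- function(dataset, params, init, lower = NULL, upper = NULL,
                        subset = NULL, nStarts = 5, seed,
                        rtol = 1e-7, atol = 1e-9) {
  stopifnot(is(dataset, "FermentationDataset"),
            is(params, "KineticParameters"))
  if (missing(seed)) stop("seed is required")
  free <- estimableParameters(params)
  if (!is.null(subset)) {
    bad <- setdiff(subset, free)
    if (length(bad))
      stop("subset contains non-estimable parameters: ",
           paste(bad, collapse = ", "))
    free <- subset
  }
  v0 <- parameterValues(params)[free]
  if (any(v0 <= 0))
    stop("free parameters must have positive template values ",
         "(the search works on a log scale)")
  if (is.null(lower)) lower <- stats::setNames(v0 / 10, free)
  if (is.null(upper)) upper <- stats::setNames(v0 * 10, free)
  lower <- lower[free]; upper <- upper[free]
  if (anyNA(lower) || anyNA(upper))
    stop("bounds must cover every free parameter")
  if (any(lower <= 0)) stop("lower bounds must be positive (log-scale search)")
  if (length(free) > nrow(dataset@summary))
    warning("more free parameters (", length(free), ") than data points (",
            nrow(dataset@summary), "): the fit is underdetermined")

  # rate and yield parameters span orders of magnitude: search in log10
  # space, which also preserves positivity
  llo <- log10(lower); lup <- log10(upper)
  set.seed(as.integer(seed))
  starts <- matrix(log10(v0), nrow = 1, dimnames = list(NULL, free))
  if (nStarts > 1) {
    u <- lhs::randomLHS(nStarts - 1, length(free))
    smp <- sweep(u, 2, lup - llo, "*")
    smp <- sweep(smp, 2, llo, "+")
    colnames(smp) <- free
    starts <- rbind(starts, smp)
  }

  resFn <- function(ltheta) {
    theta <- 10^ltheta
    names(theta) <- free
    p <- .applyTheta(params, theta)
    r <- tryCatch(.weightedResiduals(p, dataset, init, rtol, atol),
                  error = function(e) NULL)
    if (is.null(r)) rep(1e5, nrow(dataset@summary)) else r
  }

  best <- NULL
  trace <- data.frame(start = integer(), cost = numeric())
  for (i in seq_len(nrow(starts))) {
    fitI <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = llo, upper = lup,
                         fn = resFn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fitI)) next
    costI <- sum(fitI$fvec^2)
    row <- data.frame(start = i, cost = costI)
    row[paste0("theta.", free)] <- as.list(10^fitI$par)
    trace <- rbind(trace, row)
    if (is.null(best) || costI < best$cost)
      best <- list(theta = 10^fitI$par, cost = costI)
  }
  if (is.null(best))
    stop("all multistart points failed (integration errors at every start)")

  theta <- stats::setNames(as.numeric(best$theta), free)
  new("FitResult", params = .applyTheta(params, theta), theta = theta,
      cost = best$cost, trace = trace, seed = as.integer(seed),
      init = init[kineticStateNames()])
}

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", length(object@theta), "estimated parameters, cost =",
      signif(object@cost, 6), "( seed", object@seed, ")\n")
})

#' Fisher-information confidence intervals
#'
#' Approximates the parameter covariance by the inverse of the Fisher
#' information matrix `F = J'J` (Cramer-Rao bound), where `J` is the matrix
#' of weighted-residual sensitivities at the optimum, obtained by central
#' finite differences with relative step `relStep`. Half-widths are
#' `t(1 - alpha/2, gamma) * sqrt(C_ii)` with `gamma = Nd - eta` degrees of
#' freedom. A singular information matrix triggers a warning and a
#' pseudo-inverse.
#'
#' @param fit A [FitResult].
#' @param dataset The [FermentationDataset] used for fitting.
#' @param alpha Significance level (default 0.05).
#' @param relStep Relative finite-difference step (default 1e-5).
#' @param rtol,atol Integration tolerances.
#' @return data.frame with columns `parameter`, `estimate`, `halfWidth`.
#' @export
confidenceIntervals <- function(fit, dataset, alpha = 0.05, relStep = 1e-5,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(fit, "FitResult"))
  theta <- fit@theta
  eta <- length(theta)
  Nd <- nrow(dataset@summary)
  gamma <- Nd - eta
  if (gamma <= 0) stop("degrees of freedom Nd - eta must be positive")

  resAt <- function(th) {
    p <- .applyTheta(fit@params, stats::setNames(th, names(theta)))
    .weightedResiduals(p, dataset, fit@init, rtol, atol)
  }
  J <- matrix(0, Nd, eta)
  for (j in seq_len(eta)) {
    h <- relStep * max(abs(theta[j]), 1e-8)
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (resAt(up) - resAt(dn)) / (2 * h)
  }
  FIM <- crossprod(J)
  sv <- svd(FIM)
  tolSv <- max(dim(FIM)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tolSv)
  if (rank < eta) {
    warning("singular Fisher information matrix (rank ", rank, " of ", eta,
            "); using pseudo-inverse")
    dInv <- ifelse(sv$d > tolSv, 1 / sv$d, 0)
  } else dInv <- 1 / sv$d
  C <- sv$v %*% (dInv * t(sv$u))
  hw <- stats::qt(1 - alpha / 2, gamma) * sqrt(pmax(diag(C), 0))
  data.frame(parameter = names(theta), estimate = unname(theta),
             halfWidth = hw, stringsAsFactors = FALSE)
}

#' Per-observable goodness of fit
#'
#' `R^2 = 1 - SSres / SStot` computed on replicate means. Observables with
#' zero variance are reported as `NA`.
#'
#' @param params A [KineticParameters] or [FitResult].
#' @param dataset A [FermentationDataset].
#' @param init Initial state (taken from the fit when `params` is a
#'   [FitResult]).
#' @param rtol,atol Integration tolerances.
#' @return Named numeric vector of R-squared values per observable.
#' @export
rSquared <- function(params, dataset, init = NULL,
                     rtol = 1e-8, atol = 1e-10) {
  if (is(params, "FitResult")) {
    if (is.null(init)) init <- params@init
    params <- params@params
  }
  if (is.null(init)) stop("init required")
  summ <- dataset@summary
  ym <- .predictObservables(params, dataset, init, rtol, atol)
  obs <- unique(summ$observable)
  out <- vapply(obs, function(o) {
    sel <- summ$observable == o
    if (sum(sel) < 2) return(NA_real_)
    y <- summ$mean[sel]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y - ym[sel])^2) / sst
  }, numeric(1))
  stats::setNames(out, obs)
}

#' Select the production-model variant for a secondary metabolite
#'
#' Fits the product's yield parameter under each candidate variant (delayed
#' until nitrogen depletion, with or without stationary-phase repression)
#' and returns the variant with the smaller information criterion. Ties are
#' broken towards the simpler, un-repressed variant.
#'
#' @param dataset A [FermentationDataset] containing the metabolite.
#' @param metabolite A secondary product state name (see
#'   [secondaryProductNames()]).
#' @param params Template [KineticParameters].
#' @param init Initial state vector.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param seed Integer seed for the per-variant fits.
#' @return The selected variant name, with attribute `"criteria"` holding
#'   the per-variant criterion values.
#' @export
selectProductModel <- function(dataset, metabolite, params, init,
                               criterion = c("AIC", "BIC"), seed = 1) {
  criterion <- match.arg(criterion)
  if (!metabolite %in% secondaryProductNames())
    stop("not a secondary product: ", metabolite)
  cands <- c("nitrogen_delayed", "nitrogen_delayed_repressed")
  Nd <- nrow(dataset@summary)
  crit <- stats::setNames(numeric(length(cands)), cands)
  fits <- list()
  for (ca in cands) {
    p <- params
    p@variants[metabolite] <- ca
    fit <- tryCatch(
      fitKinetics(dataset, p, init, subset = paste0("Y", metabolite),
                  nStarts = 3, seed = seed),
      error = function(e) NULL)
    if (is.null(fit)) {
      crit[ca] <- Inf
      next
    }
    fits[[ca]] <- fit
    k <- length(fit@theta)
    crit[ca] <- fit@cost + if (criterion == "AIC") 2 * k else k * log(Nd)
  }
  if (all(!is.finite(crit)))
    stop("all candidate variant fits failed")
  # <= : ties go to the simpler (un-repressed) variant listed first
  sel <- if (crit[1] <= crit[2]) cands[1] else cands[2]
  attr(sel, "criteria") <- crit
  sel
}
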