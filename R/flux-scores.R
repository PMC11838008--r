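# Trapezoidal integral of a flux x biomass product over [tA, tB], with
# piecewise-linear interpolation at the interval endpoints.
.integrateSeries <- function(times, values, tA, tB) {
  grid <- sort(unique(c(tA, tB, times[times > tA & times < tB])))
  y <- stats::approx(times, values, xout = grid, rule = 2)$y
  pracma::trapz(grid, y)
}

#' Phase flux score
#'
#' `FS_r = 100 * int(v_r * DW) / (int(|v_Glx * DW|) + int(|v_F * DW|))`
#' over `[tA, tB]`: the net amount of compound carried by reaction `r` per
#' mmol of hexose consumed, times 100. Integrals use the trapezoidal rule
#' on the stored grid (fluxes interpolated piecewise-linearly), and the
#' score keeps the sign of the net flux integral.
#'
#' @param fluxtraj A [FluxTrajectory].
#' @param reaction Reaction id.
#' @param tA,tB Interval bounds (h), `tA < tB`, within the trajectory.
#' @return Flux score (mmol per mmol hexose x 100).
#' @export
fluxScore <- function(fluxtraj, reaction, tA, tB) {
  stopifnot(is(fluxtraj, "FluxTrajectory"))
  if (tA >= tB) stop("tA must be < tB")
  times <- fluxtraj@times
  if (tA < times[1] - 1e-9 || tB > times[length(times)] + 1e-9)
    stop("interval outside flux trajectory")
  if (!reaction %in% colnames(fluxtraj@fluxes))
    stop("unknown reaction: ", reaction)
  dwv <- fluxtraj@dw
  num <- .integrateSeries(times, fluxtraj@fluxes[, reaction] * dwv, tA, tB)
  hex <- fluxtraj@hexoseReactions
  den <- .integrateSeries(times, abs(fluxtraj@fluxes[, hex[1]] * dwv),
                          tA, tB) +
    .integrateSeries(times, abs(fluxtraj@fluxes[, hex[2]] * dwv), tA, tB)
  if (den <= 0) stop("zero hexose uptake over the interval: score undefined")
  100 * num / den
}

#' Duration-normalized flux score
#'
#' `NFS = FS / (tB - tA)`, allowing comparison of phases of different
#' lengths.
#'
#' @inheritParams fluxScore
#' @param phase Optional two-element numeric `c(tA, tB)` or a row of
#'   [phaseTable()]; alternatively give `tA`/`tB` directly.
#' @return Normalized flux score (per hour).
#' @export
normalizedFluxScore <- function(fluxtraj, reaction, phase = NULL,
                                tA = NULL, tB = NULL) {
  if (!is.null(phase)) {
    if (is.data.frame(phase)) {
      tA <- phase$start[1]; tB <- phase$end[1]
    } else {
      tA <- phase[1]; tB <- phase[2]
    }
  }
  if (is.null(tA) || is.null(tB)) stop("phase interval required")
  dur <- tB - tA
  if (dur <= 0) stop("phase duration must be > 0")
  fluxScore(fluxtraj, reaction, tA, tB) / dur
}

#' Phase-resolved flux score table
#'
#' Computes FS and NFS for every reaction over each phase of a
#' [PhaseSchedule], clipped to the flux-trajectory span. Zero-length phases
#' are dropped.
#'
#' @param fluxtraj A [FluxTrajectory].
#' @param phases A [PhaseSchedule] (or a data.frame like [phaseTable()]).
#' @param reactions Reactions to include (default all).
#' @return A [FluxScoreTable].
#' @export
fluxScoreTable <- function(fluxtraj, phases, reactions = NULL) {
  tab <- if (is(phases, "PhaseSchedule")) phaseTable(phases) else phases
  tr <- range(fluxtraj@times)
  tab$start <- pmax(tab$start, tr[1])
  tab$end <- pmin(tab$end, tr[2])
  tab <- tab[tab$end - tab$start > 1e-9, , drop = FALSE]
  if (!nrow(tab)) stop("no non-degenerate phases within the trajectory")
  if (is.null(reactions)) reactions <- colnames(fluxtraj@fluxes)
  FS <- matrix(NA_real_, length(reactions), nrow(tab),
               dimnames = list(reactions, tab$phase))
  for (k in seq_len(nrow(tab)))
    FS[, k] <- vapply(reactions, function(r)
      fluxScore(fluxtraj, r, tab$start[k], tab$end[k]), numeric(1))
  NFS <- sweep(FS, 2, tab$end - tab$start, "/")
  new("FluxScoreTable", FS = FS, NFS = NFS,
      phases = tab[, c("phase", "start", "end")])
}

#' @rdname FluxScoreTable-class
#' @export
setMethod("fsMatrix", "FluxScoreTable", function(x) x@FS)

#' @rdname FluxScoreTable-class
#' @export
setMethod("nfsMatrix", "FluxScoreTable", function(x) x@NFS)

setMethod("show", "FluxScoreTable", function(object) {
  cat("FluxScoreTable:", nrow(object@FS), "reactions x",
      ncol(object@FS), "phases (", paste(object@phases$phase,
                                         collapse = ", "), ")\n")
})

#' Differentially used reactions between two flux score tables
#'
#' Returns the reactions whose flux scores differ between two conditions by
#' at least `threshold` on the `|log10(|S1 / S2|)|` scale for the selected
#' phase. Pairs where exactly one score is zero are always included
#' (infinitely different); pairs where both are zero are excluded.
#'
#' @param scoresA,scoresB [FluxScoreTable]s sharing reaction and phase
#'   indices.
#' @param threshold Log10-ratio threshold (default 1e-3).
#' @param phase Phase name (default: the last phase in the table).
#' @return Character vector of reaction ids.
#' @export
differentialReactions <- function(scoresA, scoresB, threshold = 1e-3,
                                  phase = NULL) {
  stopifnot(is(scoresA, "FluxScoreTable"), is(scoresB, "FluxScoreTable"))
  if (!identical(rownames(scoresA@FS), rownames(scoresB@FS)))
    stop("tables must share a reaction index")
  if (!identical(scoresA@phases$phase, scoresB@phases$phase))
    stop("tables must share the same phases")
  if (is.null(phase)) phase <- scoresA@phases$phase[nrow(scoresA@phases)]
  if (!phase %in% scoresA@phases$phase) stop("unknown phase: ", phase)
  s1 <- scoresA@FS[, phase]
  s2 <- scoresB@FS[, phase]
  bothZero <- s1 == 0 & s2 == 0
  oneZero <- xor(s1 == 0, s2 == 0)
  ratioHit <- !bothZero & !oneZero &
    abs(log10(abs(s1 / s2))) >= threshold
  rownames(scoresA@FS)[oneZero | ratioHit]
}
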