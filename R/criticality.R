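## Critical-phenomena analysis: slab phase densities, coexistence-curve
## fits (Wegner expansion, singular diameter, Antoine), the extended IAPWS
## surface-tension fit with emergence temperature, liquid-liquid critical
## point localization on (T,P) grids, and the three-phase melting-point
## protocol driver.

## --------------------------------------------------------------------------
## Multistart trust-region least squares (minpack.lm) from a seeded Latin
## hypercube; all fitters funnel through here.
multistartFit <- function(resid, lower, upper, nStarts = 8, seed = 1,
                          start = NULL) {
  set.seed(seed)
  k <- length(lower)
  starts <- lhs::randomLHS(nStarts, k)
  starts <- sweep(sweep(starts, 2, upper - lower, `*`), 2, lower, `+`)
  if (!is.null(start)) starts <- rbind(pmin(pmax(start, lower), upper), starts)
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     maxiter = 500)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("nonlinear fit failed to converge from every start; the data may ",
         "be degenerate")
  best
}

fitResultFrom <- function(best, parNames, fixed, nObs, info = list()) {
  fit <- best$fit
  par <- stats::setNames(fit$par, parNames)
  k <- length(par)
  dof <- max(1, nObs - k)
  s2 <- best$ssr / dof
  cv <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e)
    matrix(NA_real_, k, k))
  se <- stats::setNames(sqrt(pmax(0, diag(cv))), parNames)
  dimnames(cv) <- list(parNames, parNames)
  new("FitResult", par = par, fixed = fixed, stderr = se, cov = cv,
      residuals = as.numeric(fit$fvec),
      converged = fit$info %in% 1:4,
      info = c(info, list(ssr = best$ssr, message = fit$message)))
}

## --------------------------------------------------------------------------

#' Bulk phase densities from a slab density profile
#'
#' Extracts liquid and vapor densities from the plateau regions of a
#' density profile along the slab normal, excluding an explicit zone
#' around each interface.  Interfaces are located where the profile
#' crosses the midpoint between its extremes.
#'
#' @param profile data.frame with \code{z} (nm) and \code{rho} (kg/m^3)
#' @param exclusion half-width of the interface exclusion zone (nm)
#' @param minContrast minimal (max-min)/max density contrast below which
#'   the profile is declared single-phase
#' @return list with \code{rhoLiquid}, \code{rhoVapor} (kg/m^3) and the
#'   retained point counts
#' @export
slabPhaseDensities <- function(profile, exclusion = 0.4,
                               minContrast = 0.25) {
  stopifnot(all(c("z", "rho") %in% names(profile)))
  rho <- profile$rho
  z <- profile$z
  if ((max(rho) - min(rho)) <= minContrast * max(rho, 1e-12))
    stop("no identifiable liquid/vapor plateaus: the profile is uniform ",
         "(coexistence lost, fully mixed or supercritical)")
  mid <- (max(rho) + min(rho)) / 2
  liquid <- rho > mid
  ## distance of each point to the nearest classification boundary
  flips <- which(diff(liquid) != 0)
  zb <- (z[flips] + z[flips + 1]) / 2
  distToIface <- vapply(z, function(zi) min(abs(zi - zb)), numeric(1))
  keep <- distToIface > exclusion
  if (!any(keep & liquid) || !any(keep & !liquid))
    stop("interface exclusion removed all plateau points; reduce 'exclusion'")
  list(rhoLiquid = mean(rho[keep & liquid]),
       rhoVapor = mean(rho[keep & !liquid]),
       nLiquid = sum(keep & liquid), nVapor = sum(keep & !liquid))
}

#' Wegner-expansion fit of the coexistence density difference
#'
#' Fits rho_l - rho_v = B0 tau^beta (1 + B1 tau^Delta + ...) with
#' tau = 1 - T/T_c and the 3D-Ising exponents fixed (beta = 0.325,
#' Delta = 0.5); the amplitudes and T_c are free.  The number of
#' correction amplitudes is a configuration knob (default 1).
#'
#' @param points data.frame with \code{T}, \code{rhoLiquid},
#'   \code{rhoVapor} (>= 4 subcritical points)
#' @param nCorrections correction amplitudes beyond leading order
#' @param seed multistart seed
#' @return a \code{FitResult} with parameters \code{Tc}, \code{B0},
#'   \code{B1}, ...
#' @export
wegnerFit <- function(points, nCorrections = 1, seed = 1) {
  stopifnot(all(c("T", "rhoLiquid", "rhoVapor") %in% names(points)))
  if (nrow(points) < 4) stop("need at least 4 subcritical points")
  dT <- points$rhoLiquid - points$rhoVapor
  Tmax <- max(points$T)
  resid <- function(p) {
    Tc <- p[1]
    wegnerDelta(points$T, Tc, p[-1]) - dT
  }
  span <- diff(range(points$T))
  lower <- c(Tmax + 1e-6, 1e-3, rep(-20, nCorrections))
  upper <- c(Tmax + 5 * span, 1e4, rep(20, nCorrections))
  start <- c(Tmax + 0.15 * span, max(dT) * 1.5, rep(0, nCorrections))
  best <- multistartFit(resid, lower, upper, seed = seed, start = start)
  fitResultFrom(best, c("Tc", paste0("B", 0:nCorrections)),
                c(beta = 0.325, Delta = 0.5), nrow(points),
                list(model = "Wegner expansion",
                     nCorrections = nCorrections))
}

#' Critical density from the singular-diameter law
#'
#' Fits the coexistence diameter (rho_l + rho_v)/2 =
#' rho_c + a1 tau^(1-alpha') + a2 tau with alpha' = 0.11 fixed and T_c
#' supplied from \code{\link{wegnerFit}}.  Linear in its free parameters,
#' so solved exactly by least squares.
#'
#' @param points as in \code{\link{wegnerFit}}
#' @param Tc critical temperature (K, fixed)
#' @param alphaPrime fixed exponent
#' @return a \code{FitResult} with \code{rhoc}, \code{a1}, \code{a2}
#' @export
criticalDensityFit <- function(points, Tc, alphaPrime = 0.11) {
  dia <- (points$rhoLiquid + points$rhoVapor) / 2
  tau <- 1 - points$T / Tc
  if (any(tau <= 0)) stop("all points must lie below the supplied T_c")
  X <- cbind(1, tau^(1 - alphaPrime), tau)
  fit <- stats::lm.fit(X, dia)
  co <- stats::setNames(fit$coefficients, c("rhoc", "a1", "a2"))
  res <- fit$residuals
  dof <- max(1, length(dia) - 3)
  s2 <- sum(res^2) / dof
  cv <- tryCatch(s2 * solve(crossprod(X)), error = function(e)
    matrix(NA_real_, 3, 3))
  se <- stats::setNames(sqrt(pmax(0, diag(cv))), names(co))
  dimnames(cv) <- list(names(co), names(co))
  new("FitResult", par = co, fixed = c(Tc = Tc, alphaPrime = alphaPrime),
      stderr = se, cov = cv, residuals = res, converged = TRUE,
      info = list(model = "singular diameter"))
}

#' Antoine vapor-pressure fit
#'
#' ln P = A - B/(T + C), fitted by least squares on ln P.
#'
#' @param points data.frame with \code{T} (K) and \code{P} (bar), P > 0,
#'   at least 3 points
#' @param seed multistart seed
#' @return a \code{FitResult} with \code{A}, \code{B}, \code{C}
#' @export
antoineFit <- function(points, seed = 1) {
  stopifnot(all(c("T", "P") %in% names(points)))
  if (any(points$P <= 0)) stop("vapor pressures must be positive")
  if (nrow(points) < 3) stop("need at least 3 (T, P) points")
  lnP <- log(points$P)
  resid <- function(p) p[1] - p[2] / (points$T + p[3]) - lnP
  Tmin <- min(points$T)
  best <- multistartFit(resid,
                        lower = c(-50, 0, -0.9 * Tmin),
                        upper = c(50, 5e4, 300), seed = seed,
                        start = c(10, 3000, -40))
  fitResultFrom(best, c("A", "B", "C"), numeric(0), nrow(points),
                list(model = "Antoine, least squares on ln P"))
}

#' Critical pressure from an Antoine fit
#'
#' Evaluates the fitted Antoine form at the critical temperature.
#'
#' @param fit a \code{FitResult} from \code{\link{antoineFit}}
#' @param Tc critical temperature (K)
#' @return P_c (bar)
#' @export
antoinePc <- function(fit, Tc) {
  p <- fittedPar(fit)
  unname(antoineP(Tc, p["A"], p["B"], p["C"]))
}

#' Extended IAPWS surface-tension fit with emergence temperature
#'
#' Weighted nonlinear least squares of
#' gamma(T) = B tau^mu (1 + b tau) + gamma_s exp(c (T_e - T)) with
#' mu = 11/9 and T_c fixed (taken from liquid-vapor coexistence fits,
#' never fitted here); free parameters B, b, c and T_e under the
#' gamma_s = 1 mN/m emergence convention, so that the fitted curve
#' deviates from the classical IAPWS term by exactly gamma_s at T = T_e.
#' Multistart trust-region optimization with fixed seeds.  The fit is
#' invariant under reordering of the points and under uniform rescaling of
#' the weights.
#'
#' @param points data.frame with \code{T} (K), \code{gamma} (mN/m) and
#'   optionally \code{stderr} (weights 1/stderr)
#' @param Tc fixed critical temperature (K)
#' @param gammaS emergence amplitude (mN/m)
#' @param supercooledBelow identifiability guard: at least one point below
#'   this temperature (K) is required, otherwise T_e is unidentifiable
#' @param seed multistart seed
#' @return a \code{FitResult} with \code{B}, \code{b}, \code{c}, \code{Te};
#'   \code{info$emergenceDetected} is \code{FALSE} when the exponential
#'   component is below numerical noise at every data temperature
#' @export
iapwsEFit <- function(points, Tc, gammaS = 1, supercooledBelow = 260,
                      seed = 1) {
  stopifnot(all(c("T", "gamma") %in% names(points)))
  if (nrow(points) < 5)
    stop("need at least 5 points for 4 free parameters")
  if (min(points$T) >= supercooledBelow)
    stop("no supercooled points (all T >= ", supercooledBelow,
         " K): the emergence temperature T_e is unidentifiable")
  w <- if ("stderr" %in% names(points)) 1 / points$stderr else
    rep(1, nrow(points))
  resid <- function(p)
    w * (iapwsEGamma(points$T, Tc, p[1], p[2], p[3], p[4], gammaS) -
         points$gamma)
  best <- multistartFit(resid,
                        lower = c(10, -3, 1e-3, 100),
                        upper = c(1000, 2, 1.5, 330), seed = seed,
                        start = c(235, -0.6, 0.2, 235))
  fr <- fitResultFrom(best, c("B", "b", "c", "Te"),
                      c(Tc = Tc, mu = 11 / 9, gammaS = gammaS),
                      nrow(points),
                      list(model = "IAPWS-E, weighted least squares",
                           parameterization = "B, b, c, Te free; Tc fixed"))
  p <- fr@par
  emergence <- gammaS * exp(p[["c"]] * (p[["Te"]] - points$T))
  fr@info$emergenceDetected <-
    max(emergence) > 1e-6 * max(abs(points$gamma))
  fr@info$maxEmergenceComponent <- max(emergence)
  fr
}

#' Locate a liquid-liquid critical point on (T, P) grids
#'
#' Classifies each isobar of a kappa_T grid and a density grid as
#' continuous (a kappa_T maximum marks the Widom line) or discontinuous (a
#' density jump between adjacent temperatures exceeding
#' \code{jumpFactor} times the pooled block error).  The critical point is
#' bracketed between the last continuous and first discontinuous isobar;
#' T from the kappa_T maximum at the bracketing continuous pressure, the
#' density from the grid at the estimate.  Uncertainties are never
#' reported below the grid spacing.  Featureless or all-discontinuous
#' grids return a "not bracketed" result rather than a fabricated point.
#'
#' @param kappaGrid data.frame with \code{T} (K), \code{P} (MPa),
#'   \code{kappa} (any consistent units)
#' @param densityGrid data.frame with \code{T}, \code{P}, \code{rho}
#'   (kg/m^3) and optionally \code{stderr}
#' @param jumpFactor first-order classification threshold (in pooled
#'   stderr units)
#' @return list of class \code{"llcpEstimate"}: \code{detected},
#'   \code{Tc}, \code{Pc} (MPa), \code{rhoc}, \code{dT}, \code{dP},
#'   and the per-isobar \code{classification}
#' @export
locateLLCP <- function(kappaGrid, densityGrid, jumpFactor = 5) {
  stopifnot(all(c("T", "P", "kappa") %in% names(kappaGrid)),
            all(c("T", "P", "rho") %in% names(densityGrid)))
  Ps <- sort(unique(densityGrid$P))
  classify <- function(p) {
    d <- densityGrid[densityGrid$P == p, ]
    d <- d[order(d$T), ]
    jumps <- abs(diff(d$rho))
    pooled <- if ("stderr" %in% names(d) && any(d$stderr > 0))
      sqrt(mean(d$stderr^2)) else
      stats::median(abs(diff(d$rho, differences = 2))) / (sqrt(6) * 0.6745)
    if (pooled <= 0) pooled <- 1e-12
    k <- kappaGrid[kappaGrid$P == p, ]
    k <- k[order(k$T), ]
    peakIdx <- which.max(k$kappa)
    hasPeak <- length(k$kappa) >= 3 && peakIdx > 1 &&
      peakIdx < length(k$kappa)
    if (max(jumps) > jumpFactor * sqrt(2) * pooled) "discontinuous"
    else if (hasPeak) "continuous"
    else "featureless"
  }
  cls <- vapply(Ps, classify, character(1))
  names(cls) <- Ps
  disc <- cls == "discontinuous"
  cont <- cls == "continuous"
  out <- list(detected = FALSE, classification = cls)
  class(out) <- "llcpEstimate"
  if (!any(disc) || !any(cont)) {
    out$reason <- if (!any(disc)) "no first-order isobar found"
      else "no continuous isobar found"
    return(out)
  }
  ## boundary between a continuous and an adjacent discontinuous isobar
  adj <- which(cls[-length(cls)] != cls[-1] &
               (cls[-length(cls)] == "discontinuous" | cls[-1] == "discontinuous") &
               (cls[-length(cls)] == "continuous" | cls[-1] == "continuous"))
  if (length(adj) == 0) {
    out$reason <- "no continuous/discontinuous adjacency on the grid"
    return(out)
  }
  i <- adj[1]
  pCont <- if (cls[i] == "continuous") Ps[i] else Ps[i + 1]
  pDisc <- if (cls[i] == "discontinuous") Ps[i] else Ps[i + 1]
  ## Widom-line response maximum on the continuous side ...
  k <- kappaGrid[kappaGrid$P == pCont, ]
  k <- k[order(k$T), ]
  tWidom <- k$T[which.max(k$kappa)]
  ## ... and the first-order jump on the discontinuous side; the critical
  ## temperature lies between the two
  d <- densityGrid[densityGrid$P == pDisc, ]
  d <- d[order(d$T), ]
  j <- which.max(abs(diff(d$rho)))
  tJump <- (d$T[j] + d$T[j + 1]) / 2
  rhoJumpMid <- (d$rho[j] + d$rho[j + 1]) / 2
  dTgrid <- stats::median(diff(sort(unique(k$T))))
  TcLL <- (tWidom + tJump) / 2
  PcLL <- (pCont + pDisc) / 2
  dPgrid <- abs(pDisc - pCont)
  dc <- densityGrid[densityGrid$P == pCont, ]
  rhoCont <- dc$rho[which.min(abs(dc$T - TcLL))]
  out$detected <- TRUE
  out$Tc <- TcLL
  out$Pc <- PcLL
  out$rhoc <- mean(c(rhoCont, rhoJumpMid))
  out$dT <- max(dTgrid, abs(tWidom - tJump) / 2)   # >= grid spacing
  out$dP <- dPgrid / 2
  out$bracket <- sort(c(pCont, pDisc))
  out$widomT <- tWidom
  out$jumpT <- tJump
  out
}

#' @export
print.llcpEstimate <- function(x, ...) {
  if (x$detected)
    cat(sprintf(
      "LLCP estimate: T = %.4g +/- %.2g K, P = %.4g +/- %.2g MPa, rho = %.4g kg/m^3\n",
      x$Tc, x$dT, x$Pc, x$dP, x$rhoc))
  else cat("No LLCP detected:", x$reason, "\n")
  invisible(x)
}

## --------------------------------------------------------------------------
## Three-phase melting point

#' Tetrahedral order parameter
#'
#' The Errington-Debenedetti orientational order of each oxygen with its
#' four nearest oxygen neighbors: q = 1 - 3/8 sum_{j<k} (cos psi_jk +
#' 1/3)^2; q -> 1 in a perfect tetrahedral network (ice) and ~0.5 in the
#' ambient liquid.
#'
#' @param state a \code{SystemState}
#' @return numeric vector, one q per molecule
#' @export
tetrahedralOrder <- function(state) {
  p <- state@positions
  box <- state@box
  n <- nMolecules(state)
  iO <- 3 * (seq_len(n) - 1) + 1
  O <- p[iO, , drop = FALSE]
  q <- numeric(n)
  for (i in seq_len(n)) {
    d <- sweep(O[-i, , drop = FALSE], 2, O[i, ])
    d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
    r <- sqrt(rowSums(d^2))
    nb <- order(r)[1:4]
    u <- d[nb, , drop = FALSE] / r[nb]
    s <- 0
    for (j in 1:3)
      for (k in (j + 1):4)
        s <- s + (sum(u[j, ] * u[k, ]) + 1 / 3)^2
    q[i] <- 1 - 3 / 8 * s
  }
  q
}

#' Classify a configuration as ice-like, liquid-like or ambiguous
#'
#' @param state a \code{SystemState}
#' @param iceAbove,liquidBelow mean-q thresholds
#' @return "ice", "liquid" or "ambiguous"
#' @export
classifyPhase <- function(state, iceAbove = 0.8, liquidBelow = 0.7) {
  qb <- mean(tetrahedralOrder(state))
  if (qb >= iceAbove) "ice" else if (qb <= liquidBelow) "liquid"
  else "ambiguous"
}

#' Three-phase coexistence melting-point driver
#'
#' Protocol driver for the NVE three-phase (ice/liquid/vapor) melting
#' point: runs NVE from the prepared coexistence cell at bracketing
#' initial temperatures, classifies the end state by the tetrahedral order
#' parameter (ice grew vs melted), and bisects between T_H and T_L.  The
#' published protocol uses (T_H, T_L) = (280, 260) K for the flexible
#' model and (275, 255) K for EG273, 0.5 fs steps, and multi-nanosecond
#' runs on 100-1000+ molecule cells; at desk scale supply a custom
#' \code{runner} or reduced \code{steps}.
#'
#' @param cell prepared coexistence \code{SystemState}
#' @param params \code{ForceFieldParameters}
#' @param TH,TL bracketing initial temperatures (K); the T_H end state must
#'   classify as melted and the T_L end state as frozen
#' @param steps,dt NVE length and time step (ps)
#' @param maxBisect bisection depth
#' @param runner function(state, T) -> final \code{SystemState}; defaults
#'   to an NVE run with Maxwell velocities at T
#' @param classifier function(state) -> "ice"/"liquid"/"ambiguous"
#' @param seed seed for initial velocities
#' @param ... passed to \code{\link{runMD}} by the default runner
#' @return list with the final \code{bracket} (K), midpoint \code{TM},
#'   per-run \code{history}, and \code{flags} (ambiguous end states widen
#'   the bracket and are flagged)
#' @export
meltingPointThreePhase <- function(cell, params, TH = 275, TL = 255,
                                   steps = 2000, dt = 5e-4, maxBisect = 4,
                                   runner = NULL, classifier = classifyPhase,
                                   seed = 1, ...) {
  stopifnot(TH > TL)
  if (is.null(runner))
    runner <- function(state, T)
      finalState(runMD(state, params, steps = steps, dt = dt,
                       integrator = "nve", initTemperature = T,
                       seed = seed, ...))
  history <- list()
  flags <- character(0)
  outcome <- function(T) {
    cls <- classifier(runner(cell, T))
    history[[length(history) + 1]] <<- list(T = T, endState = cls)
    cls
  }
  up <- outcome(TH)
  if (up != "liquid")
    flags <- c(flags, sprintf(
      "end state at T_H = %g K classified '%s', expected 'liquid'", TH, up))
  lo <- outcome(TL)
  if (lo != "ice")
    flags <- c(flags, sprintf(
      "end state at T_L = %g K classified '%s', expected 'ice'", TL, lo))
  bracket <- c(TL, TH)
  for (i in seq_len(maxBisect)) {
    Tm <- mean(bracket)
    cls <- outcome(Tm)
    if (cls == "liquid") bracket[2] <- Tm
    else if (cls == "ice") bracket[1] <- Tm
    else {
      flags <- c(flags, sprintf("ambiguous end state at %g K; bracket kept",
                                Tm))
      break
    }
  }
  list(bracket = bracket, TM = mean(bracket), history = history,
       flags = flags)
}
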