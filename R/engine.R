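## R surface of the MD engine: parameter bundles, single-point
## energy/forces, Ewald reference path, constraint projection and the
## NVE/NVT/NPT drivers (the inner loops live in src/core.cpp).

#' Ewald summation settings
#'
#' Plain (non-mesh) Ewald is the reference electrostatics path.  When
#' \code{alpha}/\code{kmax} are left \code{NULL} they are tuned from
#' \code{tol} and the box at run time: \code{alpha} solves
#' erfc(alpha r_cut) = tol, the reciprocal cutoff is
#' k_cut = 2 alpha sqrt(-log tol), and the per-axis mode limits are
#' ceil(k_cut L / 2 pi).
#'
#' @param tol target relative truncation accuracy (dimensionless)
#' @param alpha optional splitting parameter (1/Angstrom)
#' @param kmax optional per-axis integer mode limits (length 1 or 3)
#' @return an object of class \code{"ewaldParams"}
#' @export
ewaldParams <- function(tol = 1e-5, alpha = NULL, kmax = NULL) {
  stopifnot(tol > 0, tol < 1)
  structure(list(tol = tol, alpha = alpha, kmax = kmax),
            class = "ewaldParams")
}

## resolve auto-tuned Ewald settings against a box (Angstrom)
resolveEwald <- function(ew, boxA, rcutA) {
  tol <- ew$tol
  alpha <- ew$alpha
  if (is.null(alpha))
    alpha <- stats::uniroot(function(a) erfc(a * rcutA) - tol,
                            c(1e-4, 100 / rcutA))$root
  kcut <- 2 * alpha * sqrt(-log(tol))
  kmax <- ew$kmax
  if (is.null(kmax)) kmax <- as.integer(ceiling(kcut * boxA / (2 * pi)))
  if (length(kmax) == 1) kmax <- rep(as.integer(kmax), 3)
  if (is.null(ew$kmax) || is.null(ew$alpha)) kcut2 <- kcut^2
  else kcut2 <- (2 * pi * max(kmax / boxA) * 1.0001)^2 * 3
  list(alpha = alpha, kmax = kmax, kcut2 = kcut2)
}

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Cutoff scheme for the van der Waals terms
#'
#' Bulk runs use a 1.0 nm cutoff with uniform-fluid tail corrections to the
#' r^-6 dispersion energy and pressure (the exponential repulsion tail
#' decays faster than any power and is neglected); slab runs use a long
#' 1.75 nm cutoff with corrections off, since the tail formulas assume a
#' homogeneous fluid.
#'
#' @param rCutVdw real-space cutoff (nm)
#' @param lrcEnergy,lrcPressure apply the analytic dispersion tail?
#' @return an object of class \code{"cutoffScheme"}
#' @export
cutoffScheme <- function(rCutVdw = 1.0, lrcEnergy = TRUE, lrcPressure = TRUE) {
  stopifnot(rCutVdw > 0)
  structure(list(rCutVdw = rCutVdw, lrcEnergy = lrcEnergy,
                 lrcPressure = lrcPressure), class = "cutoffScheme")
}

#' @rdname cutoffScheme
#' @export
slabCutoff <- function() cutoffScheme(1.75, FALSE, FALSE)

#' Thermostat / barostat settings
#'
#' Defaults follow the simulation protocols: Nose-Hoover relaxation 2 ps
#' for NPT runs and 5 ps for NVT runs; isotropic cell dynamics with a 5 ps
#' pressure relaxation.
#'
#' @param T target temperature (K)
#' @param tau relaxation time (ps)
#' @return a parameter bundle
#' @export
thermostatParams <- function(T = 298, tau = 2) {
  if (tau <= 0) stop("thermostat relaxation time must be positive")
  structure(list(T = T, tau = tau), class = "thermostatParams")
}

#' @rdname thermostatParams
#' @param P target pressure (bar)
#' @export
barostatParams <- function(P = 1, tau = 5) {
  if (tau <= 0) stop("barostat relaxation time must be positive")
  structure(list(P = P, tau = tau), class = "barostatParams")
}

ffToList <- function(params) {
  list(qM = params@qM, qH = params@qH, a = params@a, AOO = params@AOO,
       alpha = params@alpha, COO = params@COO, A4 = params@A4,
       rc = params@rc, re = params@re,
       thetaE = params@thetaE * pi / 180,
       k2 = params@k2, k3 = params@k3, k4 = params@k4,
       kTheta = params@kTheta, flexible = !isRigid(params))
}

#' Energy, forces and virial of a periodic system
#'
#' Assembles every term of the potential under periodic boundary
#' conditions: real/reciprocal/self Ewald electrostatics with
#' intramolecular exclusions, Born-Mayer repulsion and r^-6 dispersion with
#' optional tail corrections, the hydrogen-bond wall, and (flexible
#' variant) the intramolecular potential.  Forces are the exact negative
#' gradient of the returned energy; the force on the massless M site is
#' redistributed onto O/H1/H2 by the chain rule of the virtual-site
#' definition, which preserves molecular force and torque.
#'
#' @param state a \code{SystemState}
#' @param params a \code{ForceFieldParameters}
#' @param ewald an \code{\link{ewaldParams}} bundle
#' @param cutoff a \code{\link{cutoffScheme}} bundle
#' @return list with \code{energy} (an \code{EnergyBreakdown}; tail
#'   correction folded into the dispersion component), \code{components}
#'   (raw numeric breakdown incl. \code{lrc}), \code{forces}
#'   (n_sites x 3, kcal/mol/Angstrom, physical sites), and
#'   \code{virial}/\code{virialAtomic} (3 x 3, kcal/mol; molecular and
#'   atomic routes)
#' @export
systemEnergyForces <- function(state, params, ewald = ewaldParams(),
                               cutoff = cutoffScheme()) {
  boxA <- state@box * 10
  rcutA <- cutoff$rCutVdw * 10
  ew <- resolveEwald(ewald, boxA, rcutA)
  res <- cppEnergyForces(state@positions * 10, boxA, ffToList(params),
                         ew$alpha, ew$kmax, ew$kcut2, rcutA,
                         cutoff$lrcEnergy, cutoff$lrcPressure)
  eb <- new("EnergyBreakdown", coulomb = res$coulomb,
            repulsion = res$repulsion,
            dispersion = res$dispersion + res$lrc, hb = res$hb,
            intra = res$intra, total = res$total)
  list(energy = eb,
       components = res[c("coulomb", "repulsion", "dispersion", "hb",
                          "intra", "lrc", "total")],
       forces = res$forces, virial = res$virialMolecular,
       virialAtomic = res$virialAtomic)
}

#' Reference Ewald summation for arbitrary point charges
#'
#' Plain Ewald (real-space erfc + reciprocal sum + self term) for a neutral
#' collection of point charges in an orthorhombic periodic box.  Used as
#' the reference electrostatics path and for lattice-energy checks.
#'
#' @param positions n x 3 matrix (nm)
#' @param charges numeric, e; must sum to zero
#' @param box lengths (nm)
#' @param rCut real-space cutoff (nm)
#' @param ewald an \code{\link{ewaldParams}} bundle
#' @return list with \code{energy} (kcal/mol), \code{forces}
#'   (kcal/mol/Angstrom) and the 3 x 3 \code{virial}
#' @export
coulombEwald <- function(positions, charges, box, rCut = min(box) / 2 * 0.999,
                         ewald = ewaldParams(tol = 1e-7)) {
  boxA <- box * 10
  rcutA <- rCut * 10
  ew <- resolveEwald(ewald, boxA, rcutA)
  cppEwald(as.matrix(positions) * 10, charges, boxA, ew$alpha, ew$kmax,
           ew$kcut2, rcutA)
}

#' Project a rigid state onto the constraint manifold
#'
#' Iteratively enforces the two OH bond lengths and the HH distance implied
#' by (r_e, theta_e), and removes velocity components along the
#' constraints.  Linear and angular momentum are preserved by the
#' projection.
#'
#' @param state a \code{SystemState}
#' @param params a rigid-variant \code{ForceFieldParameters}
#' @return the constrained \code{SystemState}
#' @export
constrainRigid <- function(state, params) {
  if (!isRigid(params)) stop("constraints apply to rigid variants only")
  res <- cppConstrain(state@positions * 10, state@velocities * 10,
                      params@re, params@thetaE * pi / 180)
  out <- state
  out@positions <- res$positions / 10
  out@velocities <- res$velocities / 10
  out
}

#' Constraint residuals of a state
#'
#' @param state a \code{SystemState}
#' @param params a rigid-variant \code{ForceFieldParameters}
#' @return list with max |OH - r_e| (Angstrom) and max |HOH - theta_e| (rad)
#' @export
constraintResiduals <- function(state, params) {
  p <- state@positions * 10
  n <- nMolecules(state)
  iO <- 3 * (seq_len(n) - 1) + 1
  dOH1 <- sqrt(rowSums((p[iO + 1, , drop = FALSE] - p[iO, , drop = FALSE])^2))
  dOH2 <- sqrt(rowSums((p[iO + 2, , drop = FALSE] - p[iO, , drop = FALSE])^2))
  u <- p[iO + 1, , drop = FALSE] - p[iO, , drop = FALSE]
  v <- p[iO + 2, , drop = FALSE] - p[iO, , drop = FALSE]
  ct <- rowSums(u * v) / (dOH1 * dOH2)
  list(bond = max(abs(c(dOH1, dOH2) - params@re)),
       angle = max(abs(acos(pmin(1, pmax(-1, ct))) -
                       params@thetaE * pi / 180)))
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Seeds site velocities at a target temperature and removes the net
#' center-of-mass momentum.  For rigid variants the velocity components
#' along the constraints are projected out at run start by the engine.
#'
#' @param state a \code{SystemState}
#' @param T temperature (K)
#' @param seed RNG seed (all stochastic elements of a run are seeded)
#' @return the \code{SystemState} with new velocities
#' @export
maxwellVelocities <- function(state, T, seed = 1) {
  set.seed(seed)
  n <- nrow(state@positions)
  mass <- rep(c(physicalConstants$massO, physicalConstants$massH,
                physicalConstants$massH), length.out = n)
  sigma <- sqrt(physicalConstants$kB * T * physicalConstants$kcalToAmuA2ps2 /
                mass) / 10   # nm/ps
  v <- matrix(stats::rnorm(3 * n), n, 3) * sigma
  p <- colSums(v * mass)
  v <- sweep(v, 2, p / sum(mass))
  ## equipartition the start exactly: rescale center-of-mass and internal
  ## components separately to the target temperature, so that systems with
  ## weak rotation-translation coupling start from the correct partition
  nmol <- n %/% 3L
  iO <- 3 * (seq_len(nmol) - 1) + 1
  mT <- physicalConstants$massO + 2 * physicalConstants$massH
  vcomMol <- (physicalConstants$massO * v[iO, , drop = FALSE] +
              physicalConstants$massH * (v[iO + 1, , drop = FALSE] +
                                         v[iO + 2, , drop = FALSE])) / mT
  vcom <- vcomMol[rep(seq_len(nmol), each = 3L), , drop = FALSE]
  vint <- v - vcom
  kConv <- physicalConstants$kcalToAmuA2ps2 / 100  # (nm/ps)^2 mass -> kcal/mol
  kTrans <- sum(mT * vcomMol^2) / 2 / kConv
  kInt <- sum(mass * vint^2) / 2 / kConv
  kB <- physicalConstants$kB
  sTrans <- sqrt((3 * nmol - 3) * kB * T / (2 * kTrans))
  sInt <- sqrt(6 * nmol * kB * T / (2 * kInt))
  out <- state
  out@velocities <- sTrans * vcom + sInt * vint
  out
}

#' Run molecular dynamics
#'
#' Velocity-Verlet dynamics with optional Nose-Hoover thermostat (single
#' chain) and isotropic cell dynamics for constant pressure.  Rigid
#' variants are integrated with SHAKE/RATTLE on the molecular geometry; the
#' massless M site is reconstructed every step and its force redistributed
#' onto the physical sites.  All stochastic elements (initial velocities)
#' are controlled by \code{seed}; a given seed reproduces the trajectory
#' bit-for-bit on one platform.
#'
#' @param state initial \code{SystemState}
#' @param params \code{ForceFieldParameters}
#' @param steps number of steps
#' @param dt time step (ps); 0.5 fs = 5e-4 ps for flexible/NVE protocols,
#'   2 fs for rigid variants
#' @param integrator "nve", "nvt" or "npt"
#' @param thermostat \code{\link{thermostatParams}} (nvt/npt)
#' @param barostat \code{\link{barostatParams}} (npt)
#' @param ewald,cutoff electrostatics and cutoff bundles
#' @param sampleEvery record the scalar series every this many steps
#' @param snapshotEvery record full snapshots every this many steps (0 = never)
#' @param initTemperature if non-NULL, draw fresh Maxwell velocities at this
#'   temperature using \code{seed}
#' @param seed RNG seed for the initial velocities
#' @param interactions set \code{FALSE} for the ideal-gas surrogate (all
#'   interactions off; used for barostat validation)
#' @return a \code{\link{Trajectory-class}}
#' @export
runMD <- function(state, params, steps, dt,
                  integrator = c("nve", "nvt", "npt"),
                  thermostat = thermostatParams(),
                  barostat = barostatParams(),
                  ewald = ewaldParams(), cutoff = cutoffScheme(),
                  sampleEvery = 10, snapshotEvery = 0,
                  initTemperature = NULL, seed = 1, interactions = TRUE) {
  integrator <- match.arg(integrator)
  if (integrator %in% c("nvt", "npt") && thermostat$tau <= 0)
    stop("thermostat relaxation time must be positive")
  if (integrator == "npt" && barostat$tau <= 0)
    stop("barostat relaxation time must be positive")
  stopifnot(dt > 0, steps >= 1)
  if (!is.null(initTemperature))
    state <- maxwellVelocities(state, initTemperature, seed = seed)
  boxA <- state@box * 10
  rcutA <- cutoff$rCutVdw * 10
  if (interactions && any(boxA < 2 * rcutA))
    stop("box must be at least twice the real-space cutoff")
  ew <- resolveEwald(ewald, boxA, rcutA)
  icode <- match(integrator, c("nve", "nvt", "npt")) - 1L
  res <- cppRunMD(state@positions * 10, state@velocities * 10, boxA,
                  ffToList(params), ew$alpha, ew$kmax, ew$kcut2, rcutA,
                  cutoff$lrcEnergy, cutoff$lrcPressure, interactions,
                  icode, dt, as.integer(steps),
                  thermostat$T, thermostat$tau, barostat$P, barostat$tau,
                  isRigid(params), as.integer(sampleEvery),
                  as.integer(snapshotEvery))
  s <- as.data.frame(res$series)
  s$time <- s$time + state@time
  s$volume <- s$volume / 1e3                      # A^3 -> nm^3
  s[c("boxX", "boxY", "boxZ")] <- s[c("boxX", "boxY", "boxZ")] / 10
  s[c("Mx", "My", "Mz")] <- s[c("Mx", "My", "Mz")] / 10   # e A -> e nm
  toState <- function(pos, vel, box, t)
    new("SystemState", box = box / 10, positions = pos / 10,
        velocities = vel / 10, molecule = state@molecule,
        siteNames = state@siteNames, time = t + state@time,
        wrapped = FALSE, metadata = state@metadata)
  snaps <- lapply(res$snapshots, function(sn)
    toState(sn$positions, sn$velocities, sn$box, sn$time))
  fin <- toState(res$positions, res$velocities, res$box, steps * dt)
  settings <- list(integrator = integrator, dt = dt, steps = steps,
                   sampleEvery = sampleEvery, seed = seed,
                   thermostat = unclass(thermostat),
                   barostat = unclass(barostat),
                   ewald = ew, cutoff = unclass(cutoff),
                   interactions = interactions)
  new("Trajectory", series = s, snapshots = snaps, finalState = fin,
      params = params, settings = settings)
}

#' Instantaneous pressure tensor of a state
#'
#' Kinetic-plus-virial (molecular/group-based) route: the kinetic part uses
#' molecular center-of-mass velocities and the configurational part the
#' molecular virial, so constraint forces never enter.  Includes the
#' dispersion tail correction when enabled in \code{cutoff}.
#'
#' @param state a \code{SystemState} (velocities used for the kinetic part)
#' @param params \code{ForceFieldParameters}
#' @param ewald,cutoff evaluation settings
#' @return list with the symmetric 3 x 3 \code{tensor} (bar) and the scalar
#'   \code{pressure} = trace/3 (bar)
#' @export
pressureTensor <- function(state, params, ewald = ewaldParams(),
                           cutoff = cutoffScheme()) {
  ef <- systemEnergyForces(state, params, ewald, cutoff)
  n <- nMolecules(state)
  mO <- physicalConstants$massO; mH <- physicalConstants$massH
  mTot <- mO + 2 * mH
  vA <- state@velocities * 10    # A/ps
  iO <- 3 * (seq_len(n) - 1) + 1
  vcom <- (mO * vA[iO, , drop = FALSE] + mH * vA[iO + 1, , drop = FALSE] +
           mH * vA[iO + 2, , drop = FALSE]) / mTot
  kin <- mTot * crossprod(vcom) / physicalConstants$kcalToAmuA2ps2
  V <- prod(state@box * 10)      # A^3
  P <- (kin + ef$virial) / V * physicalConstants$pressureUnitBar
  P <- (P + t(P)) / 2
  list(tensor = P, pressure = sum(diag(P)) / 3)
}
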