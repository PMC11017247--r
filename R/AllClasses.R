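## S4 classes for the central data objects.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ForceFieldParameters: one rWAIL model variant
#'
#' Holds every parameter of the intermolecular energy (charges, M-site
#' factor, exponential repulsion, dispersion, hydrogen-bond wall) and, for
#' the flexible variant, the quartic-bond/harmonic-angle intramolecular
#' terms.  Rigid ensemble-geometry (EG) variants carry \code{NA} for the
#' intramolecular force constants; their \code{re}/\code{thetaE} are the
#' constrained geometry.
#'
#' Units: charges e, energies kcal/mol, lengths Angstrom, \code{alpha}
#' 1/Angstrom, \code{thetaE} degrees, \code{kTheta} kcal/(mol rad^2).
#'
#' @slot variant one of "flexible", "EG273", "EG298"
#' @slot qM,qH point charges (e); the molecule is neutral, qM + 2 qH = 0
#' @slot a dimensionless M-site displacement factor
#' @slot AOO,alpha Born-Mayer O-O repulsion A exp(-alpha r)
#' @slot COO O-O dispersion coefficient (kcal Angstrom^6/mol)
#' @slot A4,rc hydrogen-bond wall A4 (r - rc)^4 for r < rc
#' @slot re,thetaE equilibrium / constrained OH length and HOH angle
#' @slot k2,k3,k4,kTheta intramolecular force constants (NA when rigid)
#' @exportClass ForceFieldParameters
setClass("ForceFieldParameters",
  representation(variant = "character",
                 qM = "numeric", qH = "numeric", a = "numeric",
                 AOO = "numeric", alpha = "numeric", COO = "numeric",
                 A4 = "numeric", rc = "numeric",
                 re = "numeric", thetaE = "numeric",
                 k2 = "numeric", k3 = "numeric", k4 = "numeric",
                 kTheta = "numeric"))

setValidity("ForceFieldParameters", function(object) {
  msg <- character()
  if (!object@variant %in% c("flexible", "EG273", "EG298"))
    msg <- c(msg, "variant must be one of 'flexible', 'EG273', 'EG298'")
  if (abs(object@qM + 2 * object@qH) > 1e-12)
    msg <- c(msg, "molecule must be neutral: q_M + 2 q_H = 0")
  for (nm in c("AOO", "alpha", "COO", "A4", "rc"))
    if (!(slot(object, nm) > 0))
      msg <- c(msg, sprintf("%s must be > 0", nm))
  rigid <- object@variant != "flexible"
  ks <- c(object@k2, object@k3, object@k4, object@kTheta)
  if (rigid && !all(is.na(ks)))
    msg <- c(msg, "rigid variants carry no intramolecular force constants")
  if (!rigid && any(is.na(ks)))
    msg <- c(msg, "flexible variant requires k2, k3, k4, k_theta")
  if (length(msg)) msg else TRUE
})

#' @describeIn ForceFieldParameters is the variant rigid (constrained geometry)?
#' @param params a \code{ForceFieldParameters} object
#' @export
isRigid <- function(params) params@variant != "flexible"

#' @describeIn ForceFieldParameters the variant name
#' @export
ffVariant <- function(params) params@variant

setMethod("show", "ForceFieldParameters", function(object) {
  cat(sprintf("rWAIL force field, %s variant (%s)\n", object@variant,
              if (isRigid(object)) "rigid" else "flexible"))
  cat(sprintf("  charges: q_M = %.4f e, q_H = %.4f e, a = %.3g\n",
              object@qM, object@qH, object@a))
  cat(sprintf("  O-O: A = %.4g kcal/mol, alpha = %.4g 1/A, C6 = %.6g kcal A^6/mol\n",
              object@AOO, object@alpha, object@COO))
  cat(sprintf("  HB wall: A4 = %.5g kcal/(mol A^4), r_c = %.4g A\n",
              object@A4, object@rc))
  cat(sprintf("  geometry: r_e = %.4f A, theta_e = %.2f deg\n",
              object@re, object@thetaE))
  if (!isRigid(object))
    cat(sprintf("  bonds: k2 = %.5g, k3 = %.5g, k4 = %.5g; angle k = %.4g\n",
                object@k2, object@k3, object@k4, object@kTheta))
})

#' WaterSiteSet: the four interaction sites of one molecule
#'
#' Positions in Angstrom.  \code{rM} is always the deterministic function of
#' the three physical sites (the virtual-site rule); charges are bound from
#' the parameter set at construction.
#'
#' @slot rO,rH1,rH2,rM site positions, numeric length-3 (Angstrom)
#' @slot qH,qM bound charges (e)
#' @exportClass WaterSiteSet
setClass("WaterSiteSet",
  representation(rO = "numeric", rH1 = "numeric", rH2 = "numeric",
                 rM = "numeric", qH = "numeric", qM = "numeric"))

setValidity("WaterSiteSet", function(object) {
  if (length(object@rO) != 3 || length(object@rH1) != 3 ||
      length(object@rH2) != 3 || length(object@rM) != 3)
    return("site positions must be numeric vectors of length 3")
  TRUE
})

#' EnergyBreakdown: components of an interaction energy
#'
#' All entries kcal/mol.  \code{total} is the sum of the components; the
#' validity method enforces this.
#'
#' @slot coulomb,repulsion,dispersion,hb,intra,total energies (kcal/mol)
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
  representation(coulomb = "numeric", repulsion = "numeric",
                 dispersion = "numeric", hb = "numeric",
                 intra = "numeric", total = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  s <- object@coulomb + object@repulsion + object@dispersion +
    object@hb + object@intra
  if (!all(is.finite(s))) return("energy components must be finite")
  if (abs(s - object@total) > 1e-9 * max(1, abs(s)))
    return("total must equal the sum of components")
  TRUE
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("Energy breakdown (kcal/mol)\n")
  for (nm in c("coulomb", "repulsion", "dispersion", "hb", "intra", "total"))
    cat(sprintf("  %-10s % .8g\n", nm, slot(object, nm)))
})

#' SystemState: a periodic simulation state
#'
#' Physical sites only (O, H, H per molecule; the massless M site is never
#' stored, it is reconstructed from the virtual-site rule wherever needed).
#' User-facing units are Gromacs-like: box and positions nm, velocities
#' nm/ps, time ps.
#'
#' @slot box orthorhombic box lengths, numeric length-3 (nm)
#' @slot positions n_sites x 3 matrix (nm)
#' @slot velocities n_sites x 3 matrix (nm/ps)
#' @slot molecule integer molecule index per site
#' @slot siteNames site labels, "OW"/"HW1"/"HW2" repeating
#' @slot time simulation time (ps)
#' @slot wrapped logical: are positions wrapped into the primary box?
#' @slot metadata free-form list (provenance, generator seeds, ...)
#' @exportClass SystemState
setClass("SystemState",
  representation(box = "numeric", positions = "matrix",
                 velocities = "matrix", molecule = "integer",
                 siteNames = "character", time = "numeric",
                 wrapped = "logical", metadata = "list"))

setValidity("SystemState", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (length(object@box) != 3 || any(object@box <= 0))
    msg <- c(msg, "box must be three positive lengths (nm)")
  if (n %% 3 != 0)
    msg <- c(msg, "positions must hold 3 physical sites per molecule")
  if (!all(dim(object@velocities) == dim(object@positions)))
    msg <- c(msg, "velocities must match positions in shape")
  if (length(object@molecule) != n)
    msg <- c(msg, "molecule index must have one entry per site")
  if (length(msg)) msg else TRUE
})

#' @describeIn SystemState number of water molecules
#' @param state a \code{SystemState}
#' @export
nMolecules <- function(state) nrow(state@positions) %/% 3L

#' @describeIn SystemState box lengths in nm
#' @export
boxLengths <- function(state) state@box

#' @describeIn SystemState positions matrix (nm)
#' @export
sitePositions <- function(state) state@positions

#' @describeIn SystemState velocities matrix (nm/ps)
#' @export
siteVelocities <- function(state) state@velocities

setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState: %d water molecules, box %.4g x %.4g x %.4g nm, t = %.4g ps\n",
              nMolecules(object), object@box[1], object@box[2], object@box[3],
              object@time))
  cat(sprintf("  positions %s (metadata: %s)\n",
              if (object@wrapped) "wrapped" else "unwrapped",
              if (length(object@metadata))
                paste(names(object@metadata), collapse = ", ") else "none"))
})

#' TimeSeries: a tagged observable stream
#'
#' @slot observable name of the observable
#' @slot values numeric vector (or column-wise components for tensors, see
#'   \code{surfaceTension} which takes a data.frame instead)
#' @slot units unit string
#' @slot dt sampling interval (ps)
#' @slot blockSize default number of blocks for error analysis
#' @exportClass TimeSeries
setClass("TimeSeries",
  representation(observable = "character", values = "numeric",
                 units = "character", dt = "numeric", blockSize = "numeric"))

setValidity("TimeSeries", function(object) {
  if (length(object@values) < 1) return("empty series")
  if (object@dt <= 0) return("sampling interval must be positive")
  TRUE
})

#' Construct a TimeSeries
#' @param values numeric observations
#' @param observable name
#' @param units unit string
#' @param dt sampling interval in ps
#' @param blockSize number of blocks used by default for error bars
#' @return a \code{TimeSeries}
#' @export
newTimeSeries <- function(values, observable = "observable", units = "",
                          dt = 1, blockSize = 10) {
  new("TimeSeries", observable = observable, values = as.numeric(values),
      units = units, dt = dt, blockSize = blockSize)
}

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries '%s' [%s]: %d samples, dt = %g ps, mean = %.6g\n",
              object@observable, object@units, length(object@values),
              object@dt, mean(object@values)))
})

#' @describeIn TimeSeries the raw numeric values
#' @param x a \code{TimeSeries}
#' @export
seriesValues <- function(x) x@values

#' PropertyEstimate: a value with uncertainty and provenance
#'
#' @slot value point estimate
#' @slot units unit string (SI-facing at this boundary)
#' @slot stderr standard error (block averaging unless stated otherwise)
#' @slot settings estimator settings (discard fraction, blocks, windows, ...)
#' @slot provenance free-form description of the input series
#' @exportClass PropertyEstimate
setClass("PropertyEstimate",
  representation(value = "numeric", units = "character", stderr = "numeric",
                 settings = "list", provenance = "character"))

setMethod("show", "PropertyEstimate", function(object) {
  cat(sprintf("%.6g +/- %.3g %s\n", object@value, object@stderr, object@units))
  if (length(object@settings))
    cat("  settings:", paste(names(object@settings), unlist(lapply(
      object@settings, function(x) paste(format(x), collapse = "/"))),
      sep = "=", collapse = ", "), "\n")
})

#' @describeIn PropertyEstimate the point estimate
#' @param x a \code{PropertyEstimate}
#' @export
estimateValue <- function(x) x@value

#' @describeIn PropertyEstimate the standard error
#' @export
estimateStderr <- function(x) x@stderr

#' FitResult: fitted and fixed parameters with diagnostics
#'
#' @slot par named numeric vector of fitted parameters
#' @slot fixed named numeric vector of parameters held fixed
#' @slot stderr standard errors of \code{par} (NA when not available)
#' @slot cov covariance matrix of \code{par}
#' @slot residuals fit residuals
#' @slot converged logical
#' @slot info free-form list (model form, multistart diagnostics, ...)
#' @exportClass FitResult
setClass("FitResult",
  representation(par = "numeric", fixed = "numeric", stderr = "numeric",
                 cov = "matrix", residuals = "numeric", converged = "logical",
                 info = "list"))

setMethod("show", "FitResult", function(object) {
  cat("Fit result", if (isTRUE(object@converged)) "(converged)" else
    "(NOT converged)", "\n")
  for (nm in names(object@par))
    cat(sprintf("  %-8s %.8g +/- %.3g\n", nm, object@par[[nm]],
                object@stderr[[nm]]))
  if (length(object@fixed))
    cat("  fixed:", paste(names(object@fixed), signif(object@fixed, 8),
                          sep = "=", collapse = ", "), "\n")
})

#' @describeIn FitResult fitted parameters
#' @param x a \code{FitResult}
#' @export
fittedPar <- function(x) x@par

#' Trajectory: sampled output of an MD run
#'
#' @slot series data.frame of sampled scalars: time (ps), epot, ekin, etot,
#'   enthalpy (kcal/mol), temperature (K), volume (nm^3), pressure and the
#'   diagonal/off-diagonal pressure-tensor components (bar), box lengths
#'   (nm), and the total-dipole components (e nm)
#' @slot snapshots list of \code{SystemState} (possibly empty)
#' @slot finalState the final \code{SystemState}
#' @slot params the \code{ForceFieldParameters} used
#' @slot settings run settings (integrator, dt, seeds, cutoffs, ...)
#' @exportClass Trajectory
setClass("Trajectory",
  representation(series = "data.frame", snapshots = "list",
                 finalState = "SystemState", params = "ForceFieldParameters",
                 settings = "list"))

setMethod("show", "Trajectory", function(object) {
  n <- nrow(object@series)
  cat(sprintf("Trajectory: %d samples over %.4g ps (%s, %d molecules), %d snapshots\n",
              n, if (n) max(object@series$time) - min(object@series$time) else 0,
              object@settings$integrator %||% "?", nMolecules(object@finalState),
              length(object@snapshots)))
})

#' @describeIn Trajectory the sampled scalar series as a data.frame
#' @param traj a \code{Trajectory}
#' @export
trajectorySeries <- function(traj) traj@series

#' @describeIn Trajectory the final state
#' @export
finalState <- function(traj) traj@finalState

#' @describeIn Trajectory extract one sampled observable as a TimeSeries
#' @param name column of the series data.frame
#' @export
trajectoryObservable <- function(traj, name) {
  s <- traj@series
  if (!name %in% names(s))
    stop("no observable '", name, "' in trajectory; available: ",
         paste(setdiff(names(s), "time"), collapse = ", "))
  dt <- if (nrow(s) > 1) s$time[2] - s$time[1] else 1
  units <- c(epot = "kcal/mol", ekin = "kcal/mol", etot = "kcal/mol",
             enthalpy = "kcal/mol", temperature = "K", volume = "nm^3",
             pressure = "bar", Pxx = "bar", Pyy = "bar", Pzz = "bar")
  newTimeSeries(s[[name]], observable = name,
                units = units[[name]] %||% "", dt = dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
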