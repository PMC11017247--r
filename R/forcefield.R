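## The rWAIL energy expressions: parameter loading, the M-site rule, the
## hydrogen-bond wall, dimer energies and the intramolecular potential.
## Periodic system-level energies/forces are delegated to the C++ core
## (see systemEnergyForces in engine.R).

ffVariants <- c("flexible", "EG273", "EG298")

#' Load a published rWAIL parameter set
#'
#' Reads the packaged parameter table for one model variant.  The three
#' variants share every intermolecular parameter and differ only in
#' \code{r_e}, \code{theta_e} and the presence of intramolecular terms.
#'
#' @param variant one of \code{"flexible"}, \code{"EG273"}, \code{"EG298"}
#' @param file optional path to a parameter file written by
#'   \code{\link{writeParameters}} (overrides \code{variant})
#' @return a \code{\link{ForceFieldParameters-class}} object
#' @examples
#' p <- loadParameters("flexible")
#' p@qM   # -1.3464 e
#' @export
loadParameters <- function(variant = "flexible", file = NULL) {
  if (is.null(file)) {
    if (length(variant) != 1 || !variant %in% ffVariants)
      stop("unknown variant '", paste(variant, collapse = ","),
           "'; valid variants: ", paste(ffVariants, collapse = ", "))
    file <- system.file("extdata", "params",
                        paste0("rwail_", variant, ".yaml"),
                        package = "rwail", mustWork = TRUE)
  }
  y <- yaml::read_yaml(file)
  num <- function(nm, default = NA_real_) {
    v <- y[[nm]]
    if (is.null(v)) default else as.numeric(v)
  }
  new("ForceFieldParameters",
      variant = as.character(y$variant),
      qM = num("q_M"), qH = num("q_H"), a = num("a"),
      AOO = num("A_OO"), alpha = num("alpha"), COO = num("C_OO"),
      A4 = num("A_4"), rc = num("r_c"),
      re = num("r_e"), thetaE = num("theta_e"),
      k2 = num("k2"), k3 = num("k3"), k4 = num("k4"),
      kTheta = num("k_theta"))
}

#' Serialize a parameter set
#'
#' Writes the structured-text parameter format read by
#' \code{\link{loadParameters}}.  Values are written with 17 significant
#' digits so the round trip is bit-exact.
#'
#' @param params a \code{ForceFieldParameters} object
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeParameters <- function(params, path) {
  fields <- c(q_M = "qM", q_H = "qH", a = "a", A_OO = "AOO", alpha = "alpha",
              C_OO = "COO", A_4 = "A4", r_c = "rc", r_e = "re",
              k2 = "k2", k3 = "k3", k4 = "k4", theta_e = "thetaE",
              k_theta = "kTheta")
  lines <- c(paste0("variant: ", params@variant))
  for (nm in names(fields)) {
    v <- slot(params, fields[[nm]])
    if (!is.na(v)) lines <- c(lines, sprintf("%s: %.17g", nm, v))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Virtual M-site position
#'
#' The negative-charge site is placed from the two full O-H bond vectors:
#' r_M = r_O + a * ((r_H1 - r_O) + (r_H2 - r_O)).  The rule is linear in the
#' physical positions, so the force on the massless M site redistributes
#' onto O/H1/H2 with constant weights (1 - 2a, a, a).
#'
#' @param rO,rH1,rH2 positions (Angstrom), numeric length-3
#' @param a dimensionless displacement factor
#' @return the M position, numeric length-3 (Angstrom)
#' @export
msitePosition <- function(rO, rH1, rH2, a) {
  stopifnot(length(rO) == 3, length(rH1) == 3, length(rH2) == 3,
            all(is.finite(c(rO, rH1, rH2, a))))
  if (sqrt(sum((rH1 - rO)^2)) < 1e-8 || sqrt(sum((rH2 - rO)^2)) < 1e-8 ||
      sqrt(sum((rH1 - rH2)^2)) < 1e-8)
    stop("coincident O/H positions: M site undefined")
  rO + a * ((rH1 - rO) + (rH2 - rO))
}

#' Assemble the four interaction sites of one molecule
#'
#' @param rO,rH1,rH2 physical site positions (Angstrom)
#' @param params a \code{ForceFieldParameters} object (binds charges and the
#'   M-site factor)
#' @return a \code{\link{WaterSiteSet-class}}
#' @export
waterSites <- function(rO, rH1, rH2, params) {
  new("WaterSiteSet", rO = as.numeric(rO), rH1 = as.numeric(rH1),
      rH2 = as.numeric(rH2),
      rM = msitePosition(rO, rH1, rH2, params@a),
      qH = params@qH, qM = params@qM)
}

#' Hydrogen-bond wall term
#'
#' U_HB(r_MH) = A_4 (r_MH - r_c)^4 for r_MH < r_c and exactly zero beyond
#' the cutoff; the quartic contact makes the term C3-continuous at r_c.
#' It acts between the M site of one molecule and the H sites of another,
#' countering the strong short-range M-H Coulomb attraction.
#'
#' @param rMH intermolecular M-H distance(s), Angstrom (vectorized)
#' @param params a \code{ForceFieldParameters} object
#' @return energy (kcal/mol), same length as \code{rMH}
#' @export
hbTerm <- function(rMH, params) {
  if (any(rMH <= 0)) stop("r_MH must be positive")
  ifelse(rMH < params@rc, params@A4 * (rMH - params@rc)^4, 0)
}

#' Intermolecular pair energy of two water molecules
#'
#' Open-boundary (non-periodic) evaluation of the intermolecular energy:
#' Coulomb over all charge-site pairs (M and two H per molecule),
#' Born-Mayer repulsion and r^-6 dispersion on the O-O distance, and the
#' hydrogen-bond wall over all intermolecular M-H pairs.  Symmetric under
#' exchange of the two molecules.
#'
#' @param A,B \code{WaterSiteSet} objects
#' @param params a \code{ForceFieldParameters} object
#' @param overlapFloor O-O distance (Angstrom) below which the evaluation
#'   errors rather than return the unphysical diverging attraction
#' @return an \code{\link{EnergyBreakdown-class}} (intra component zero)
#' @export
pairEnergy <- function(A, B, params, overlapFloor = 0.5) {
  rOO <- sqrt(sum((A@rO - B@rO)^2))
  if (rOO < overlapFloor)
    stop(sprintf("unphysical O-O overlap: r_OO = %.3g A < %.3g A floor",
                 rOO, overlapFloor))
  ke <- physicalConstants$coulomb
  chargedA <- rbind(A@rH1, A@rH2, A@rM)
  chargedB <- rbind(B@rH1, B@rH2, B@rM)
  qA <- c(A@qH, A@qH, A@qM)
  qB <- c(B@qH, B@qH, B@qM)
  d <- sqrt(outer(rowSums(chargedA^2), rep(1, 3)) +
            outer(rep(1, 3), rowSums(chargedB^2)) -
            2 * chargedA %*% t(chargedB))
  if (any(d < 1e-8)) stop("coincident charge sites across molecules")
  coulomb <- ke * sum(outer(qA, qB) / d)
  repulsion <- params@AOO * exp(-params@alpha * rOO)
  dispersion <- -params@COO / rOO^6
  dMH <- c(sqrt(sum((A@rM - B@rH1)^2)), sqrt(sum((A@rM - B@rH2)^2)),
           sqrt(sum((B@rM - A@rH1)^2)), sqrt(sum((B@rM - A@rH2)^2)))
  hb <- sum(hbTerm(dMH, params))
  new("EnergyBreakdown", coulomb = coulomb, repulsion = repulsion,
      dispersion = dispersion, hb = hb, intra = 0,
      total = coulomb + repulsion + dispersion + hb)
}

#' Intramolecular energy of a flexible molecule
#'
#' Quartic bonds and a harmonic angle about the equilibrium geometry, under
#' the prefactor convention recorded in
#' \code{\link{intraPrefactorConvention}}:
#' U = sum_i [ (k2/2) d_i^2 + (k3/3) d_i^3 + (k4/4) d_i^4 ]
#'     + (k_theta/2) (theta - theta_e)^2,  d_i = r_i - r_e.
#' Zero with zero gradient at (r_e, r_e, theta_e); symmetric in r1, r2.
#'
#' @param r1,r2 the two OH bond lengths (Angstrom)
#' @param theta the HOH angle (radians)
#' @param params a flexible-variant \code{ForceFieldParameters}
#' @return energy (kcal/mol)
#' @export
intramolecularEnergy <- function(r1, r2, theta, params) {
  if (isRigid(params))
    stop("intramolecular energy is defined for the flexible variant only; ",
         "'", params@variant, "' is rigid")
  stopifnot(r1 > 0, r2 > 0, theta > 0, theta < pi)
  pf <- intraPrefactorConvention
  bond <- function(r) {
    d <- r - params@re
    pf[["bond2"]] * params@k2 * d^2 + pf[["bond3"]] * params@k3 * d^3 +
      pf[["bond4"]] * params@k4 * d^4
  }
  dth <- theta - params@thetaE * pi / 180
  bond(r1) + bond(r2) + pf[["angle"]] * params@kTheta * dth^2
}
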