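## Physical constants and unit conversions.
##
## Internal working units everywhere below the reporting boundary:
## energy kcal/mol, length Angstrom, time ps, charge e, mass amu,
## temperature K.  SI conversions happen only in estimators/exporters.

#' Physical constants used by the package
#'
#' A named list of the physical constants and unit-conversion factors used
#' internally (CODATA 2018 where applicable).  Exposed so that unit
#' conversions can be audited and cross-checked in tests.
#'
#' @format Named list with elements:
#' \describe{
#'   \item{coulomb}{Coulomb prefactor e^2/(4 pi eps0) in kcal Angstrom/(mol e^2).}
#'   \item{kB}{Boltzmann constant in kcal/(mol K).}
#'   \item{kcalToAmuA2ps2}{1 kcal/mol expressed in amu Angstrom^2/ps^2 (exactly 418.4).}
#'   \item{pressureUnitBar}{1 kcal/(mol Angstrom^3) in bar.}
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{kBSI}{Boltzmann constant, J/K.}
#'   \item{eCharge}{Elementary charge, C.}
#'   \item{eps0}{Vacuum permittivity, F/m.}
#'   \item{debye}{1 Debye in C m.}
#'   \item{massO, massH}{Atomic masses, amu.}
#'   \item{waterMolarMass}{g/mol.}
#'   \item{RGas}{Molar gas constant, J/(mol K).}
#' }
#' @export
physicalConstants <- list(
  coulomb          = 332.06371,          # kcal A / (mol e^2)
  kB               = 1.987204259e-3,     # kcal / (mol K)
  kcalToAmuA2ps2   = 418.4,              # exact: 4184 J/mol = 418.4 amu A^2/ps^2
  pressureUnitBar  = 4184 / 6.02214076e23 / 1e-30 / 1e5,  # kcal/mol/A^3 -> bar
  avogadro         = 6.02214076e23,
  kBSI             = 1.380649e-23,
  eCharge          = 1.602176634e-19,
  eps0             = 8.8541878128e-12,
  debye            = 3.33564e-30,
  massO            = 15.999,
  massH            = 1.008,
  waterMolarMass   = 18.015,
  RGas             = 8.314462618
)

#' Intramolecular polynomial prefactor convention
#'
#' The quartic-bond/harmonic-angle intramolecular potential is evaluated as
#' U = (k2/2) dr^2 + (k3/3) dr^3 + (k4/4) dr^4 per bond plus
#' (k_theta/2) dtheta^2 for the angle, i.e. the 1/n prefactor convention in
#' which the force on a bond is -(k2 dr + k3 dr^2 + k4 dr^3).  Under this
#' convention k2 equals the curvature of the bond potential at r_e, which
#' matches the physical OH-stretch force constant; see the methods vignette.
#' This named constant is the single switch the convention lives behind and
#' is locked by a regression test.
#'
#' @export
intraPrefactorConvention <- c(bond2 = 1 / 2, bond3 = 1 / 3, bond4 = 1 / 4,
                              angle = 1 / 2)
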