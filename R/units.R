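# Physical constants (CODATA 2018) used throughout. Coordinates are stored in
# angstrom at the API surface and converted to bohr exactly once, at the
# boundary of each numerical routine, to avoid unit drift.

.EV_PER_HARTREE   <- 27.211386245988
.HC_EV_NM         <- 1239.84198        # photon energy (eV) x wavelength (nm)
.ANGSTROM_PER_BOHR <- 0.529177210903
.ME_PER_AMU       <- 1822.888486209    # electron masses per unified amu
.CM_PER_HARTREE   <- 219474.6313632
.KB_HARTREE_PER_K <- 3.166811563e-6

.CM_PER_EV <- .CM_PER_HARTREE / .EV_PER_HARTREE

#' Unit conversion constants
#'
#' Returns the conversion factors the package uses internally: Hartree to eV
#' and to wavenumbers, the photon energy-wavelength product, bohr to angstrom,
#' and electron masses per atomic mass unit. Every conversion round-trips to
#' identity to better than 1e-12 relative.
#'
#' @return Named list of conversion factors.
#' @export
#' @examples
#' unit_constants()$cm_per_hartree
unit_constants <- function() {
  list(
    ev_per_hartree   = .EV_PER_HARTREE,
    hc_ev_nm         = .HC_EV_NM,
    angstrom_per_bohr = .ANGSTROM_PER_BOHR,
    me_per_amu       = .ME_PER_AMU,
    cm_per_hartree   = .CM_PER_HARTREE,
    cm_per_ev        = .CM_PER_EV,
    kb_hartree_per_k = .KB_HARTREE_PER_K
  )
}

#' Convert photon energy to wavelength
#'
#' `lambda = hc / E` with `hc = 1239.84198` eV nm, so e.g. an incident energy
#' of 2.49 eV corresponds to a 497 nm excitation line.
#'
#' @param energy_ev Photon energy in eV (> 0).
#' @return Wavelength in nm.
#' @export
#' @examples
#' round(ev_to_nm(2.49))
ev_to_nm <- function(energy_ev) {
  if (any(!is.finite(energy_ev)) || any(energy_ev <= 0)) {
    stop("ev_to_nm(): energy must be positive and finite")
  }
  .HC_EV_NM / energy_ev
}

#' @rdname ev_to_nm
#' @param wavelength_nm Wavelength in nm (> 0).
#' @export
nm_to_ev <- function(wavelength_nm) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop("nm_to_ev(): wavelength must be positive and finite")
  }
  .HC_EV_NM / wavelength_nm
}

#' Energy unit conversions
#'
#' Conversions between Hartree, eV and spectroscopic wavenumbers (cm-1).
#'
#' @param x Numeric vector of values in the source unit.
#' @return Numeric vector in the target unit.
#' @export
hartree_to_cm <- function(x) x * .CM_PER_HARTREE

#' @rdname hartree_to_cm
#' @export
cm_to_hartree <- function(x) x / .CM_PER_HARTREE

#' @rdname hartree_to_cm
#' @export
ev_to_cm <- function(x) x * .CM_PER_EV

#' @rdname hartree_to_cm
#' @export
cm_to_ev <- function(x) x / .CM_PER_EV

#' @rdname hartree_to_cm
#' @export
hartree_to_ev <- function(x) x * .EV_PER_HARTREE

#' @rdname hartree_to_cm
#' @export
ev_to_hartree <- function(x) x / .EV_PER_HARTREE

#' Length unit conversions between bohr and angstrom
#' @param x Numeric vector of lengths.
#' @return Numeric vector in the target unit.
#' @export
bohr_to_angstrom <- function(x) x * .ANGSTROM_PER_BOHR

#' @rdname bohr_to_angstrom
#' @export
angstrom_to_bohr <- function(x) x / .ANGSTROM_PER_BOHR

# Standard atomic weights (CIAAW abridged values), amu.
.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904, Xe = 131.293
)

#' Standard atomic mass lookup
#'
#' @param symbols Character vector of element symbols (case sensitive, e.g.
#'   `"C"`, `"Cl"`).
#' @return Numeric vector of standard atomic weights in amu.
#' @export
#' @examples
#' atomic_masses(c("O", "H", "H"))
atomic_masses <- function(symbols) {
  m <- .ATOMIC_MASSES[symbols]
  if (anyNA(m)) {
    bad <- unique(symbols[is.na(m)])
    stop("atomic_masses(): unknown element symbol(s): ",
         paste(bad, collapse = ", "))
  }
  unname(m)
}
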