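# Resonance Raman engine: finite displacements along normal modes, central
# differences of the complex frequency-dependent polarizability, rotational
# invariants of the (complex) derivative tensors, short-time-approximation
# stick intensities, Lorentzian broadening and persistence-weighted averaging.
#
# A polarizability calculator is any function
#   calculator(structure, incident_ev, damping_cm) -> 3x3 complex matrix (au)
# returning the symmetric polarizability at that geometry; the electronic
# lifetime (damping) enters inside the calculator through the complex
# frequency argument.

#' Displace a structure along a normal mode
#'
#' Coordinates are displaced by `+/- step * M^(-1/2) L_k`, where `L_k` is the
#' mass-weighted-orthonormal mode vector and `step` is in mass-weighted atomic
#' units (bohr sqrt(m_e)); the default step is 0.001 au on each side, and the
#' result is converted back to angstrom.
#'
#' @param structure A `molecular_structure`.
#' @param modes A `normal_mode_set`.
#' @param k Mode index (must have a real, i.e. positive, wavenumber).
#' @param step Displacement in bohr sqrt(m_e) (> 0; default 0.001).
#' @return List of two `molecular_structure`s: `plus` and `minus`.
#' @export
displace_along_mode <- function(structure, modes, k, step = 0.001) {
  if (step < 0) stop("displace_along_mode(): step must be nonnegative")
  if (modes$wavenumbers[k] < 0) {
    stop(sprintf(paste0("displace_along_mode(): mode %d is imaginary; ",
                        "imaginary modes are excluded from RR evaluation"), k))
  }
  # vectors are amu-mass-weighted-orthonormal; in m_e units the Cartesian
  # displacement per unit mass-weighted coordinate is l / sqrt(me_per_amu)
  dx_bohr <- matrix(modes$vectors[, k], ncol = 3L, byrow = TRUE) /
    sqrt(.ME_PER_AMU)
  dx <- bohr_to_angstrom(step * dx_bohr)
  plus <- structure; minus <- structure
  plus$coords <- structure$coords + dx
  minus$coords <- structure$coords - dx
  list(plus = plus, minus = minus)
}

.check_polarizability <- function(alpha, where = "calculator") {
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(3L, 3L))) {
    stop(where, " must return a 3x3 tensor")
  }
  scale <- max(abs(alpha), 1e-300)
  if (max(abs(alpha - t(alpha))) / scale > 1e-8) {
    stop(where, ": polarizability tensor antisymmetric beyond tolerance; ",
         "the invariant formulas require a symmetric tensor")
  }
  (alpha + t(alpha)) / 2
}

#' Complex polarizability derivatives along normal modes
#'
#' Central finite difference `(alpha_plus - alpha_minus) / (2 step)` of the
#' complex frequency-dependent polarizability along every real mode; modes
#' flagged imaginary are skipped (and recorded in the result). Derivatives are
#' in au per mass-weighted normal coordinate (bohr sqrt(m_e)).
#'
#' @param calculator Function `(structure, incident_ev, damping_cm) -> 3x3
#'   complex matrix`; see the module description.
#' @param structure Geometry at which to differentiate.
#' @param modes A `normal_mode_set`.
#' @param incident_ev Incident photon energy in eV.
#' @param damping_cm Electronic lifetime broadening Gamma in cm-1
#'   (default 500).
#' @param step Displacement step in bohr sqrt(m_e) (default 0.001).
#' @return Object of class `polarizability_derivative_set`: list `tensors`
#'   (3x3 complex per real mode, `NULL` for skipped ones), `wavenumbers`,
#'   `skipped` (imaginary mode indices), `incident_ev`, `damping_cm`, `step`.
#' @export
polarizability_derivatives <- function(calculator, structure, modes,
                                       incident_ev, damping_cm = 500,
                                       step = 0.001) {
  n_modes <- length(modes$wavenumbers)
  tensors <- vector("list", n_modes)
  skipped <- integer(0)
  for (k in seq_len(n_modes)) {
    if (modes$wavenumbers[k] < 0) {
      skipped <- c(skipped, k)
      next
    }
    disp <- displace_along_mode(structure, modes, k, step = step)
    ap <- tryCatch(
      .check_polarizability(calculator(disp$plus, incident_ev, damping_cm)),
      error = function(e) stop(sprintf(
        "polarizability_derivatives(): calculator failed on mode %d (+): %s",
        k, conditionMessage(e)), call. = FALSE))
    am <- tryCatch(
      .check_polarizability(calculator(disp$minus, incident_ev, damping_cm)),
      error = function(e) stop(sprintf(
        "polarizability_derivatives(): calculator failed on mode %d (-): %s",
        k, conditionMessage(e)), call. = FALSE))
    tensors[[k]] <- (ap - am) / (2 * step)
  }
  if (length(skipped)) {
    message(sprintf("polarizability_derivatives(): skipped %d imaginary mode(s): %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  out <- list(tensors = tensors, wavenumbers = modes$wavenumbers,
              skipped = skipped, incident_ev = incident_ev,
              damping_cm = damping_cm, step = step)
  class(out) <- "polarizability_derivative_set"
  out
}

#' Rotational invariants of a complex polarizability derivative tensor
#'
#' For a symmetric complex tensor `d`, the isotropic invariant is
#' `a2 = |(d_xx + d_yy + d_zz) / 3|^2` and the anisotropy is
#' `g2 = ((|d_xx - d_yy|^2 + |d_yy - d_zz|^2 + |d_zz - d_xx|^2) / 2) +
#' 3 (|d_xy|^2 + |d_yz|^2 + |d_zx|^2)`. Both are real, nonnegative and
#' invariant under proper rotation of the molecule.
#'
#' @param dalpha 3x3 complex symmetric tensor.
#' @return Named list `a2`, `g2`.
#' @export
raman_invariants <- function(dalpha) {
  d <- .check_polarizability(dalpha, where = "raman_invariants()")
  a2 <- Mod(sum(diag(d)) / 3)^2
  g2 <- 0.5 * (Mod(d[1, 1] - d[2, 2])^2 + Mod(d[2, 2] - d[3, 3])^2 +
                 Mod(d[3, 3] - d[1, 1])^2) +
    3 * (Mod(d[1, 2])^2 + Mod(d[2, 3])^2 + Mod(d[3, 1])^2)
  list(a2 = a2, g2 = g2)
}

#' Short-time-approximation resonance Raman stick spectrum
#'
#' Stokes stick intensities
#' `I_k = (nu0 - nu_k)^3 nu0 (45 a2_k + 7 g2_k) / nu_k`, the standard
#' differential Raman cross-section frequency factors combined with the
#' scattering activity of the complex derivative tensors; all constant
#' prefactors are omitted since spectra are later max-normalized. An optional
#' thermal factor `1 / (1 - exp(-h c nu_k / kB T))` can be enabled.
#' Modes at or above the incident wavenumber are skipped with a warning, as
#' are numerical-zero modes below `min_wavenumber_cm`.
#'
#' @param derivatives A `polarizability_derivative_set`.
#' @param incident_ev Incident photon energy in eV (defaults to the one the
#'   derivatives were computed at).
#' @param temperature_k Temperature for the thermal occupation factor; `NULL`
#'   (default) disables it.
#' @param min_wavenumber_cm Modes below this wavenumber are treated as
#'   numerical zeros and skipped (default 1 cm-1).
#' @return Data frame with columns `mode`, `wavenumber`, `intensity`
#'   (arbitrary units).
#' @export
stick_spectrum <- function(derivatives, incident_ev = derivatives$incident_ev,
                           temperature_k = NULL, min_wavenumber_cm = 1) {
  nu0 <- ev_to_cm(incident_ev)
  rows <- list()
  for (k in seq_along(derivatives$tensors)) {
    dk <- derivatives$tensors[[k]]
    if (is.null(dk)) next
    nu <- derivatives$wavenumbers[k]
    if (nu < min_wavenumber_cm) next
    if (nu >= nu0) {
      warning(sprintf(paste0("stick_spectrum(): mode %d at %.1f cm-1 is at or ",
                             "above the incident wavenumber %.1f cm-1; skipped"),
                      k, nu, nu0))
      next
    }
    inv <- raman_invariants(dk)
    I <- (nu0 - nu)^3 * nu0 * (45 * inv$a2 + 7 * inv$g2) / nu
    if (!is.null(temperature_k)) {
      if (temperature_k < 0) stop("stick_spectrum(): negative temperature")
      if (temperature_k > 0) {
        x <- cm_to_hartree(nu) / (.KB_HARTREE_PER_K * temperature_k)
        I <- I / (1 - exp(-x))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(mode = k, wavenumber = nu,
                                            intensity = I)
  }
  if (!length(rows)) {
    return(data.frame(mode = integer(0), wavenumber = numeric(0),
                      intensity = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Raman spectrum container
#'
#' @param grid Strictly increasing wavenumber grid (cm-1).
#' @param intensity Nonnegative intensities on the grid.
#' @param sticks Optional stick table (as from [stick_spectrum()]).
#' @param metadata Named list of provenance metadata (incident energy,
#'   damping, broadening, weights, normalization).
#' @return Object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(grid, intensity, sticks = NULL, metadata = list()) {
  if (length(grid) != length(intensity)) {
    stop("raman_spectrum(): grid and intensity lengths differ")
  }
  if (any(diff(grid) <= 0)) stop("raman_spectrum(): grid must be strictly increasing")
  if (any(intensity < 0)) stop("raman_spectrum(): negative intensity")
  structure(list(grid = as.numeric(grid), intensity = as.numeric(intensity),
                 sticks = sticks, metadata = metadata),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f..%.0f cm-1, max %.3g\n",
              length(x$grid), min(x$grid), max(x$grid), max(x$intensity)))
  invisible(x)
}

#' Convolve stick intensities with a Lorentzian band shape
#'
#' `S(nu) = sum_k I_k (1/pi) gamma / ((nu - nu_k)^2 + gamma^2)` with
#' `gamma = hwhm`, so an isolated peak has full width at half maximum
#' `2 * hwhm` (the default HWHM of 10 cm-1 gives 20 cm-1 FWHM) and unit area
#' per unit stick intensity.
#'
#' @param sticks Stick table with columns `wavenumber`, `intensity`.
#' @param grid Strictly increasing wavenumber grid (cm-1); default
#'   1000-2000 cm-1 at 0.5 cm-1.
#' @param hwhm_cm Lorentzian half-width at half maximum in cm-1 (> 0,
#'   default 10).
#' @param metadata Extra metadata merged into the spectrum's metadata.
#' @return A `raman_spectrum`.
#' @export
convolve_lorentzian <- function(sticks, grid = seq(1000, 2000, by = 0.5),
                                hwhm_cm = 10, metadata = list()) {
  if (hwhm_cm <= 0) stop("convolve_lorentzian(): hwhm must be positive")
  S <- numeric(length(grid))
  for (k in seq_len(nrow(sticks))) {
    S <- S + sticks$intensity[k] * (hwhm_cm / pi) /
      ((grid - sticks$wavenumber[k])^2 + hwhm_cm^2)
  }
  md <- utils::modifyList(list(hwhm_cm = hwhm_cm, normalized = FALSE), metadata)
  raman_spectrum(grid, S, sticks = sticks, metadata = md)
}

#' Persistence-weighted average of spectra
#'
#' Pointwise weighted mean over a common grid, optionally max-normalized so
#' the strongest peak is exactly 1 (the convention used for plotting and
#' comparing strategies). Weights are the cluster persistence fractions; they
#' are renormalized with a warning if they do not sum to 1.
#'
#' @param spectra List of `raman_spectrum` objects on one common grid.
#' @param weights Nonnegative weights, one per spectrum (default equal).
#' @param normalize Divide by the maximum so the peak is 1 (default `TRUE`).
#' @return A `raman_spectrum`.
#' @export
average_spectra <- function(spectra, weights = NULL, normalize = TRUE) {
  if (!length(spectra)) stop("average_spectra(): no spectra given")
  grid <- spectra[[1L]]$grid
  for (s in spectra) {
    if (length(s$grid) != length(grid) || any(abs(s$grid - grid) > 1e-9)) {
      stop("average_spectra(): spectra are not on a common grid")
    }
  }
  if (is.null(weights)) weights <- rep(1 / length(spectra), length(spectra))
  if (length(weights) != length(spectra) || any(weights < 0)) {
    stop("average_spectra(): weights must be nonnegative, one per spectrum")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    warning("average_spectra(): weights do not sum to 1; renormalizing")
  }
  weights <- weights / sum(weights)
  S <- numeric(length(grid))
  for (i in seq_along(spectra)) S <- S + weights[i] * spectra[[i]]$intensity
  if (normalize && max(S) > 0) S <- S / max(S)
  md <- utils::modifyList(spectra[[1L]]$metadata,
                          list(weights = weights, normalized = normalize))
  raman_spectrum(grid, S, metadata = md)
}
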