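# Analytic toy models: spectrally synthesized harmonic molecules with exactly
# known modes, Morse pair-potential clusters with closed-form Hessians, a
# resonance-pole polarizability calculator with closed-form derivatives, and
# seeded synthetic trajectories. Every pipeline stage is testable against
# these with no electronic-structure engine and no external data.

#' Harmonic toy molecule with prescribed vibrational frequencies
#'
#' Draws a seeded random non-degenerate geometry and synthesizes a Cartesian
#' Hessian spectrally, `H = M^(1/2) L diag(lambda) L^T M^(1/2)`, from a random
#' mass-weighted-orthonormal mode basis orthogonal to the translation/rotation
#' space, so that harmonic analysis of the Hessian recovers exactly the
#' requested wavenumbers (negative entries produce imaginary modes).
#'
#' @param n_atoms Number of atoms (>= 3; geometry is non-collinear).
#' @param frequencies_cm Numeric vector of `3 n_atoms - 6` wavenumbers in
#'   cm-1; negative values encode imaginary curvature.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param elements Element symbols, recycled over atoms (default `"C"`).
#' @param box_a Edge of the sampling cube for coordinates, angstrom.
#' @return List with `structure` (`molecular_structure`), `hessian`
#'   (`hessian_matrix`) and `modes` (the exact `normal_mode_set` used in the
#'   synthesis, sorted by wavenumber).
#' @export
make_harmonic_molecule <- function(n_atoms, frequencies_cm, seed = 1L,
                                   elements = "C", box_a = 3) {
  if (n_atoms < 3L) stop("make_harmonic_molecule(): need at least 3 atoms")
  n_modes <- 3L * n_atoms - 6L
  if (length(frequencies_cm) != n_modes) {
    stop(sprintf("make_harmonic_molecule(): expected %d frequencies, got %d",
                 n_modes, length(frequencies_cm)))
  }
  labels <- rep_len(elements, n_atoms)
  set.seed(seed)
  repeat {
    coords <- matrix(stats::runif(3L * n_atoms, -box_a / 2, box_a / 2),
                     n_atoms, 3L)
    # reject (nearly) collinear geometries: need full-rank rotation space
    if (n_atoms >= 3L) {
      s <- svd(sweep(coords, 2L, colMeans(coords)))$d
      if (s[2L] > 0.2 * s[1L]) break
    }
  }
  mol <- molecular_structure(labels, coords)
  D <- transrot_basis(mol)                     # 3N x 6
  G <- matrix(stats::rnorm(3L * n_atoms * n_modes), 3L * n_atoms, n_modes)
  G <- G - D %*% crossprod(D, G)
  L <- qr.Q(qr(G))                             # orthonormal, perp to D
  ord <- order(frequencies_cm)
  freqs <- frequencies_cm[ord]
  lambda <- sign(freqs) * (freqs / .CM_PER_HARTREE)^2
  Hmw <- L %*% (lambda * t(L))
  sqrt_m <- sqrt(.mass_vec3(mol$masses) * .ME_PER_AMU)
  H <- hessian_matrix(Hmw * tcrossprod(sqrt_m), atom_count = n_atoms)
  cart <- (L / sqrt_m) * sqrt(.ME_PER_AMU)
  modes <- normal_mode_set(freqs, cart, mol$masses)
  list(structure = mol, hessian = H, modes = modes)
}

#' Analytic Hessian of a pairwise Morse cluster
#'
#' Potential `V = sum_{i<j} De (1 - exp(-a (r_ij - r0)))^2` over all atom
#' pairs, with closed-form gradient and Hessian. Because the Morse curvature
#' turns negative beyond its inflection point, geometries displaced off the
#' minimum develop imaginary modes -- a minimal analytic stand-in for the
#' off-minimum snapshot Hessians of a trajectory.
#'
#' @param structure A `molecular_structure` (coordinates in angstrom).
#' @param de Well depth in Hartree (default 0.1).
#' @param a Morse range parameter in 1/bohr (default 1).
#' @param r0 Equilibrium pair distance in angstrom (default 1.5).
#' @return List with `energy` (Hartree), `gradient` (3N, Hartree/bohr) and
#'   `hessian` (`hessian_matrix`, Hartree/bohr^2).
#' @export
morse_cluster_hessian <- function(structure, de = 0.1, a = 1, r0 = 1.5) {
  x <- angstrom_to_bohr(structure$coords)
  r0b <- angstrom_to_bohr(r0)
  n <- nrow(x)
  H <- matrix(0, 3L * n, 3L * n)
  g <- numeric(3L * n)
  energy <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dvec <- x[j, ] - x[i, ]
      r <- sqrt(sum(dvec^2))
      u <- dvec / r
      e <- exp(-a * (r - r0b))
      energy <- energy + de * (1 - e)^2
      v1 <- 2 * de * a * e * (1 - e)          # dV/dr
      v2 <- 2 * de * a^2 * e * (2 * e - 1)    # d2V/dr2
      blk <- (v2 - v1 / r) * tcrossprod(u) + (v1 / r) * diag(3)
      ii <- (3L * (i - 1L) + 1L):(3L * i)
      jj <- (3L * (j - 1L) + 1L):(3L * j)
      H[ii, ii] <- H[ii, ii] + blk
      H[jj, jj] <- H[jj, jj] + blk
      H[ii, jj] <- H[ii, jj] - blk
      H[jj, ii] <- H[jj, ii] - blk
      g[ii] <- g[ii] - v1 * u
      g[jj] <- g[jj] + v1 * u
    }
  }
  list(energy = energy, gradient = g,
       hessian = hessian_matrix(H, atom_count = n))
}

#' Resonance-pole polarizability calculator
#'
#' Builds a calculator satisfying the polarizability contract from a sum of
#' electronic poles:
#' `alpha(omega) = sum_j mu_j (x) mu_j [1 / (E_j - hw - i Gamma) +
#' 1 / (E_j + hw + i Gamma)]`,
#' with excitation energies `E_j(structure)` in eV from
#' `excitation_energy_fn`, transition dipoles (au) from
#' `transition_dipole_fn`, and the damping argument converted from cm-1 to
#' eV. The tensor is symmetric by construction. Geometry dependence of the
#' excitation energy is what couples modes to the electronic transition and
#' produces resonance enhancement.
#'
#' @param excitation_energy_fn Function `structure -> numeric vector` of
#'   excitation energies E_j in eV (all > 0).
#' @param transition_dipole_fn Function `structure -> matrix` (n_states x 3)
#'   of transition dipoles in au (or a length-3 vector for a single state).
#' @return A calculator function `(structure, incident_ev, damping_cm) ->
#'   3x3 complex matrix`.
#' @export
pole_polarizability_calculator <- function(excitation_energy_fn,
                                           transition_dipole_fn) {
  force(excitation_energy_fn); force(transition_dipole_fn)
  function(structure, incident_ev, damping_cm) {
    E <- excitation_energy_fn(structure)
    if (any(E <= 0)) stop("pole_polarizability_calculator(): E_j must be positive")
    mu <- transition_dipole_fn(structure)
    if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
    if (nrow(mu) != length(E)) {
      stop("pole_polarizability_calculator(): one dipole row per state required")
    }
    gamma_ev <- cm_to_ev(damping_cm)
    alpha <- matrix(0 + 0i, 3L, 3L)
    for (j in seq_along(E)) {
      outer_mu <- tcrossprod(mu[j, ])
      alpha <- alpha + outer_mu *
        (1 / complex(real = E[j] - incident_ev, imaginary = -gamma_ev) +
           1 / complex(real = E[j] + incident_ev, imaginary = gamma_ev))
    }
    alpha
  }
}

#' Seeded synthetic trajectory from classical harmonic sampling
#'
#' Draws frames with independent Gaussian normal-coordinate displacements at
#' the classical thermal variance `kB T / omega_k^2` per mass-weighted mode
#' coordinate (equipartition), maps them to Cartesian displacements, and
#' optionally applies a uniform random rigid rotation per frame (to exercise
#' the superposition strategy). At `T = 0` every frame equals the input
#' geometry up to that rotation. Classical (not Wigner) sampling is used,
#' matching the classical-MD provenance of trajectory snapshots.
#'
#' @param structure Equilibrium `molecular_structure`.
#' @param modes A `normal_mode_set`; all wavenumbers must be real (positive).
#' @param temperature_k Temperature in K (>= 0).
#' @param n_frames Number of frames.
#' @param stride_ps Timestamp spacing in ps (default 1).
#' @param seed Integer seed; fixed seed gives identical frames.
#' @param rotate Apply a uniform random rigid rotation per frame
#'   (default `FALSE`).
#' @return A `frame_set` with timestamps.
#' @export
make_synthetic_trajectory <- function(structure, modes, temperature_k,
                                      n_frames, stride_ps = 1, seed = 1L,
                                      rotate = FALSE) {
  if (temperature_k < 0) stop("make_synthetic_trajectory(): negative temperature")
  if (any(modes$wavenumbers <= 0)) {
    stop("make_synthetic_trajectory(): all mode wavenumbers must be positive")
  }
  set.seed(seed)
  omega <- cm_to_hartree(modes$wavenumbers)          # a.u. angular frequency
  sigma_q <- if (temperature_k > 0) {
    sqrt(.KB_HARTREE_PER_K * temperature_k) / omega  # bohr sqrt(m_e)
  } else {
    rep(0, length(omega))
  }
  n <- n_atoms(structure)
  # Cartesian displacement per unit mass-weighted coordinate, angstrom
  disp_basis <- bohr_to_angstrom(modes$vectors / sqrt(.ME_PER_AMU))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    q <- stats::rnorm(length(omega), sd = sigma_q)
    dx <- matrix(as.numeric(disp_basis %*% q), n, 3L, byrow = TRUE)
    coords <- structure$coords + dx
    if (rotate) {
      R <- random_rotation_matrix()
      ctr <- colMeans(coords)
      coords <- sweep(coords, 2L, ctr) %*% t(R) +
        matrix(ctr, n, 3L, byrow = TRUE)
    }
    frames[[f]] <- molecular_structure(structure$labels, coords,
                                       structure$masses,
                                       resid = structure$resid)
  }
  frame_set(frames, timestamps = (seq_len(n_frames) - 1) * stride_ps)
}

#' Uniform random rotation matrix
#'
#' Drawn from the Haar measure on SO(3) via a normalized random quaternion;
#' uses the current RNG state.
#'
#' @return 3 x 3 proper orthogonal matrix.
#' @export
random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Toy molecule with one decoupled torsional mode
#'
#' Builds a four-atom chain whose mass-weighted Hessian is assembled from (a)
#' the normalized torsion direction of the declared dihedral, carrying its own
#' prescribed curvature, and (b) a random stiff basis orthogonal to it and to
#' translations/rotations. Projecting that torsion out with [reduced_modes()]
#' therefore removes exactly one mode and leaves every other wavenumber
#' untouched; giving the torsion a negative wavenumber yields a Hessian whose
#' only imaginary direction is the soft coordinate.
#'
#' @param stiff_frequencies_cm Wavenumbers (cm-1) of the 3N - 7 stiff modes.
#' @param torsion_frequency_cm Wavenumber of the torsional mode (may be
#'   negative for imaginary curvature).
#' @param seed Integer seed for the stiff basis.
#' @return List with `structure`, `hessian`, `spec` (the `soft_coordinate`)
#'   and `torsion_frequency_cm`.
#' @export
make_torsion_molecule <- function(stiff_frequencies_cm,
                                  torsion_frequency_cm = 80,
                                  seed = 1L) {
  coords <- rbind(c(0.0, 1.0, 0.3), c(0.0, 0.0, 0.0),
                  c(1.4, 0.0, 0.0), c(1.9, 0.9, 0.6))
  mol <- molecular_structure(c("C", "C", "C", "O"), coords)
  n3 <- 12L
  if (length(stiff_frequencies_cm) != n3 - 7L) {
    stop(sprintf("make_torsion_molecule(): expected %d stiff frequencies",
                 n3 - 7L))
  }
  spec <- soft_coordinate(1:4, label = "chain torsion")
  D <- transrot_basis(mol)
  inv_sqrt_m <- 1 / sqrt(.mass_vec3(mol$masses) * .ME_PER_AMU)
  u <- wilson_b_row(mol, spec) * inv_sqrt_m
  u <- u - D %*% crossprod(D, u)
  u <- u / sqrt(sum(u^2))
  set.seed(seed)
  fixed <- cbind(D, u)
  G <- matrix(stats::rnorm(n3 * (n3 - 7L)), n3, n3 - 7L)
  G <- G - fixed %*% crossprod(fixed, G)
  L <- qr.Q(qr(G))
  freqs <- sort(stiff_frequencies_cm)
  lam_stiff <- sign(freqs) * (freqs / .CM_PER_HARTREE)^2
  lam_tors <- sign(torsion_frequency_cm) *
    (torsion_frequency_cm / .CM_PER_HARTREE)^2
  Hmw <- L %*% (lam_stiff * t(L)) + lam_tors * tcrossprod(u)
  sqrt_m <- sqrt(.mass_vec3(mol$masses) * .ME_PER_AMU)
  H <- hessian_matrix(Hmw * tcrossprod(sqrt_m), atom_count = 4L)
  list(structure = mol, hessian = H, spec = spec,
       torsion_frequency_cm = torsion_frequency_cm)
}
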