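# Harmonic analysis: mass weighting, Eckart (translation/rotation) projection,
# full diagonalization (strategy A0) and partial Hessian vibrational analysis
# (strategy PHVA).
#
# Internally the mass-weighted Hessian uses atomic units throughout: masses in
# electron masses, curvature in Hartree/bohr^2, so an eigenvalue lambda maps to
# a wavenumber sign(lambda) * sqrt(|lambda|) * cm_per_hartree.

#' Mass-weight a Cartesian Hessian
#'
#' Element (i, j) is scaled by `1 / sqrt(m_i m_j)` with masses converted to
#' atomic units (electron masses), so eigenvalues of the result are in
#' Hartree / (m_e bohr^2), ready for conversion to cm-1.
#'
#' @param hessian A `hessian_matrix` or plain 3N x 3N matrix (Hartree/bohr^2).
#' @param masses Atom masses in amu (length N, all > 0).
#' @return 3N x 3N mass-weighted matrix.
#' @export
mass_weight <- function(hessian, masses) {
  H <- if (inherits(hessian, "hessian_matrix")) hessian$matrix else as.matrix(hessian)
  if (any(masses <= 0)) stop("mass_weight(): non-positive mass")
  if (nrow(H) != 3L * length(masses)) {
    stop("mass_weight(): Hessian dimension inconsistent with mass vector")
  }
  inv_sqrt_m <- 1 / sqrt(.mass_vec3(masses) * .ME_PER_AMU)
  H * tcrossprod(inv_sqrt_m)
}

# Orthonormal basis (3N x r) of the mass-weighted translation and
# infinitesimal-rotation space at the structure's center of mass. r = 6 for a
# nonlinear molecule, 5 for a linear one, 3 for a single atom: the rank is
# detected from the singular values (collinear geometries lose one rotation).
transrot_basis <- function(structure) {
  m <- structure$masses
  x <- structure$coords
  com <- colSums(x * m) / sum(m)
  xc <- sweep(x, 2L, com)
  n <- nrow(x)
  sm <- sqrt(rep(m, each = 3L))
  D <- matrix(0, 3L * n, 6L)
  for (a in 1:3) D[seq(a, 3L * n, by = 3L), a] <- 1
  # rotation about axis a: displacement e_a x (r - com) per atom
  ax <- diag(3)
  for (a in 1:3) {
    disp <- t(apply(xc, 1L, function(r) c(ax[a, 2] * r[3] - ax[a, 3] * r[2],
                                          ax[a, 3] * r[1] - ax[a, 1] * r[3],
                                          ax[a, 1] * r[2] - ax[a, 2] * r[1])))
    D[, 3L + a] <- as.vector(t(disp))
  }
  D <- D * sm
  s <- svd(D)
  rank <- sum(s$d > 1e-8 * s$d[1L])
  s$u[, seq_len(rank), drop = FALSE]
}

#' Eckart projection of a mass-weighted Hessian
#'
#' Projects the three translational and three (two for a linear geometry)
#' infinitesimal-rotation directions about the center of mass out of a
#' mass-weighted Hessian. Linearity is auto-detected from the rank of the
#' rotation space, so collinear geometries need no flag.
#'
#' @param mw_hessian 3N x 3N mass-weighted Hessian.
#' @param structure The `molecular_structure` the Hessian belongs to.
#' @return List with `matrix` (the projected Hessian `P H P`), `projector`
#'   (symmetric idempotent `P`) and `basis` (the 3N x r orthonormal
#'   translation/rotation basis).
#' @export
eckart_project <- function(mw_hessian, structure) {
  D <- transrot_basis(structure)
  P <- diag(nrow(mw_hessian)) - tcrossprod(D)
  P <- (P + t(P)) / 2
  list(matrix = P %*% mw_hessian %*% P, projector = P, basis = D)
}

# Shared eigensolution -> normal_mode_set conversion. vectors of eigen() are
# orthonormal in the m_e mass-weighted metric; rescale so that amu
# mass-weighting is orthonormal (multiply by sqrt(me_per_amu)).
.modes_from_eigen <- function(values, vectors, masses, active_atoms,
                              drop_basis = NULL, drop_tol_cm = 1) {
  wn <- sign(values) * sqrt(abs(values)) * .CM_PER_HARTREE
  keep <- rep(TRUE, length(values))
  if (!is.null(drop_basis) && ncol(drop_basis) > 0L) {
    ov <- colSums((crossprod(drop_basis, vectors))^2)
    null_idx <- order(ov, decreasing = TRUE)[seq_len(ncol(drop_basis))]
    if (any(abs(wn[null_idx]) > drop_tol_cm)) {
      stop(sprintf(paste0("projected null-space mode at %.3f cm-1 exceeds the ",
                          "%.1f cm-1 residue threshold; check the projection set"),
                   max(abs(wn[null_idx])), drop_tol_cm))
    }
    keep[null_idx] <- FALSE
  }
  ord <- order(wn[keep])
  wn <- wn[keep][ord]
  V <- vectors[, keep, drop = FALSE][, ord, drop = FALSE]
  cart <- V / sqrt(.mass_vec3(masses) * .ME_PER_AMU) # bohr-space direction
  # renormalize so sqrt(m_amu)-weighted columns are orthonormal
  cart <- cart * sqrt(.ME_PER_AMU)
  normal_mode_set(wn, cart, masses, active_atoms = active_atoms)
}

#' Normal modes by full diagonalization of the snapshot Hessian (strategy A0)
#'
#' Diagonalizes the mass-weighted Hessian of a snapshot as-is, without any
#' geometry optimization. Eigenvalues are converted to wavenumbers as
#' `sign(lambda) sqrt(|lambda|)`, so negative wavenumbers mark imaginary
#' modes; off-minimum snapshot geometries routinely produce them and they are
#' data, not errors. With `project_transrot = TRUE` the translation/rotation
#' space is Eckart-projected out first and the corresponding null modes are
#' dropped.
#'
#' @param hessian A `hessian_matrix` (Hartree/bohr^2).
#' @param structure The snapshot `molecular_structure`.
#' @param project_transrot Project out translations/rotations first
#'   (default `TRUE`).
#' @param drop_tol_cm Magnitude (cm-1) below which projected null modes must
#'   fall; larger residues raise an error.
#' @return A `normal_mode_set` with 3N modes (projection off) or 3N - r modes.
#' @export
normal_modes_a0 <- function(hessian, structure, project_transrot = TRUE,
                            drop_tol_cm = 1) {
  Hmw <- mass_weight(hessian, structure$masses)
  drop_basis <- NULL
  if (project_transrot) {
    pr <- eckart_project(Hmw, structure)
    Hmw <- pr$matrix
    drop_basis <- pr$basis
  }
  e <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  .modes_from_eigen(e$values, e$vectors, structure$masses,
                    seq_len(n_atoms(structure)),
                    drop_basis = drop_basis, drop_tol_cm = drop_tol_cm)
}

#' Partial Hessian vibrational analysis (strategy PHVA)
#'
#' Separates the vibrational degrees of freedom of an active subsystem from
#' those of its environment: the 3Na x 3Na sub-block of the mass-weighted
#' Hessian over the active atoms is diagonalized while every other atom is
#' treated as infinitely heavy (frozen). No translation/rotation projection is
#' applied by default because the frozen environment breaks the invariance;
#' `project_active_translations` optionally removes the three rigid
#' translations of the active set only.
#'
#' With all atoms active and projection off this reduces exactly to
#' [normal_modes_a0()] with `project_transrot = FALSE`.
#'
#' @param hessian A `hessian_matrix` spanning the full system.
#' @param structure Full-system `molecular_structure`.
#' @param active_atoms Integer indices of the active atoms (nonempty).
#' @param project_active_translations Remove the active-set rigid translations
#'   (default `FALSE`).
#' @return A `normal_mode_set` whose vectors vanish on frozen atoms;
#'   `active_atoms` records the subsystem.
#' @export
phva_modes <- function(hessian, structure, active_atoms,
                       project_active_translations = FALSE) {
  n <- n_atoms(structure)
  active_atoms <- sort(unique(as.integer(active_atoms)))
  if (!length(active_atoms) || any(active_atoms < 1L | active_atoms > n)) {
    stop("phva_modes(): active_atoms must be a nonempty subset of atom indices")
  }
  Hmw <- mass_weight(hessian, structure$masses)
  idx <- as.vector(vapply(active_atoms, function(a) (3L * (a - 1L)) + 1:3,
                          integer(3)))
  sub <- Hmw[idx, idx, drop = FALSE]
  drop_basis <- NULL
  if (project_active_translations) {
    na <- length(active_atoms)
    D <- matrix(0, 3L * na, 3L)
    for (a in 1:3) D[seq(a, 3L * na, by = 3L), a] <- 1
    D <- D * sqrt(rep(structure$masses[active_atoms], each = 3L))
    D <- qr.Q(qr(D))
    P <- diag(3L * na) - tcrossprod(D)
    sub <- P %*% sub %*% P
    drop_basis <- D
  }
  e <- eigen((sub + t(sub)) / 2, symmetric = TRUE)
  # embed active-block eigenvectors into the full 3N space (zeros on frozen)
  full <- matrix(0, 3L * n, ncol(e$vectors))
  full[idx, ] <- e$vectors
  drop_full <- NULL
  if (!is.null(drop_basis)) {
    drop_full <- matrix(0, 3L * n, ncol(drop_basis))
    drop_full[idx, ] <- drop_basis
  }
  .modes_from_eigen(e$values, full, structure$masses, active_atoms,
                    drop_basis = drop_full)
}

#' Count imaginary modes
#'
#' Imaginary frequencies are encoded as negative wavenumbers; the default
#' threshold of -1 cm-1 ignores numerical-zero translation/rotation residue.
#'
#' @param modes A `normal_mode_set`.
#' @param threshold_cm Wavenumbers below this count as imaginary.
#' @return List with `n_imaginary` and `indices` (mode positions).
#' @export
count_imaginary <- function(modes, threshold_cm = -1) {
  idx <- which(modes$wavenumbers < threshold_cm)
  list(n_imaginary = length(idx), indices = idx)
}
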