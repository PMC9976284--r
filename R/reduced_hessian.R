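# Strategy A2: project user-declared soft internal coordinates (proper
# dihedrals) out of the mass-weighted Hessian via Wilson B rows and
# rediagonalize, yielding a reduced-dimensionality set of stiff modes.

#' Declare a soft internal coordinate
#'
#' Only proper dihedrals are supported: the soft degrees of freedom this
#' protocol targets (methyl and ammonium torsions, hydroxyl dihedrals) are all
#' torsions.
#'
#' @param atoms Ordered quadruple of 1-based atom indices i-j-k-l.
#' @param label Free-text label used in diagnostics.
#' @param kind Coordinate kind; only `"dihedral"`.
#' @return Object of class `soft_coordinate`.
#' @export
soft_coordinate <- function(atoms, label = paste(atoms, collapse = "-"),
                            kind = "dihedral") {
  kind <- match.arg(kind, "dihedral")
  atoms <- as.integer(atoms)
  if (length(atoms) != 4L || anyDuplicated(atoms) || any(atoms < 1L)) {
    stop("soft_coordinate(): atoms must be four distinct positive indices")
  }
  structure(list(kind = kind, atoms = atoms, label = label),
            class = "soft_coordinate")
}

#' Signed dihedral angle
#'
#' IUPAC sign convention: the angle between the plane (i, j, k) and the plane
#' (j, k, l), signed by `sign((b1 x b2) . b3)` and computed with `atan2`, in
#' (-pi, pi]. A cis (eclipsed) arrangement gives 0, trans gives pi.
#'
#' @param structure A `molecular_structure`.
#' @param spec A `soft_coordinate` (dihedral).
#' @return Angle in radians.
#' @export
dihedral_value <- function(structure, spec) {
  r <- structure$coords[spec$atoms, , drop = FALSE]
  b1 <- r[2, ] - r[1, ]
  b2 <- r[3, ] - r[2, ]
  b3 <- r[4, ] - r[3, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop(sprintf("dihedral_value(): collinear or coincident atoms in quadruple %s",
                 spec$label))
  }
  atan2(nb2 * sum(b1 * n2), sum(n1 * n2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wilson B row of a dihedral
#'
#' Analytic gradient of the signed dihedral with respect to all 3N Cartesian
#' coordinates (rad/angstrom). Nonzero only on the four defining atoms; the
#' row is orthogonal to uniform translations (components sum to zero) and to
#' infinitesimal rigid rotations (zero net torque), since neither motion
#' changes an internal coordinate.
#'
#' @inheritParams dihedral_value
#' @return Numeric vector of length 3N.
#' @export
wilson_b_row <- function(structure, spec) {
  r <- structure$coords[spec$atoms, , drop = FALSE]
  b1 <- r[2, ] - r[1, ]
  b2 <- r[3, ] - r[2, ]
  b3 <- r[4, ] - r[3, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  n1sq <- sum(n1^2)
  n2sq <- sum(n2^2)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || n1sq < 1e-20 || n2sq < 1e-20) {
    stop(sprintf("wilson_b_row(): collinear or coincident atoms in quadruple %s",
                 spec$label))
  }
  gi <- -nb2 / n1sq * n1
  gl <- nb2 / n2sq * n2
  s <- sum(b1 * b2) / (nb2^2)
  t <- sum(b3 * b2) / (nb2^2)
  gj <- -(1 + s) * gi + t * gl
  gk <- s * gi - (1 + t) * gl
  B <- numeric(3L * n_atoms(structure))
  put <- function(a, g) B[(3L * (a - 1L) + 1L):(3L * a)] <<- g
  put(spec$atoms[1L], gi)
  put(spec$atoms[2L], gj)
  put(spec$atoms[3L], gk)
  put(spec$atoms[4L], gl)
  B
}

# Modified Gram-Schmidt with one re-orthogonalization pass. `fixed` columns
# are assumed orthonormal already; each candidate is orthogonalized against
# fixed + previously accepted columns. Candidates whose residual norm falls
# below rank_tol * original norm are rank-deficient.
.mgs_extend <- function(fixed, candidates, rank_tol = 1e-8) {
  basis <- fixed
  kept <- logical(ncol(candidates))
  for (k in seq_len(ncol(candidates))) {
    v <- candidates[, k]
    norm0 <- sqrt(sum(v^2))
    for (pass in 1:2) {
      if (!is.null(basis) && ncol(basis) > 0L) {
        v <- v - basis %*% crossprod(basis, v)
      }
    }
    nr <- sqrt(sum(v^2))
    if (nr > rank_tol * norm0) {
      basis <- cbind(basis, as.numeric(v) / nr)
      kept[k] <- TRUE
    }
  }
  list(basis = basis, kept = kept)
}

#' Reduced-dimensionality normal modes (strategy A2)
#'
#' Builds the mass-weighted soft-coordinate directions
#' `u_i = M^(-1/2) B_i^T` from the Wilson B rows of the declared dihedrals,
#' orthonormalizes them together with the translation/rotation basis
#' (modified Gram-Schmidt with re-orthogonalization, rank tolerance 1e-8),
#' forms the projector `P = I - sum_i u_i u_i^T`, diagonalizes `P H_mw P` and
#' drops the 6 + m null-space modes. The result is the set of 3N - 6 - m
#' stiff modes with the soft torsions removed from the harmonic treatment;
#' imaginary curvature confined to a declared torsion disappears from the
#' reduced spectrum.
#'
#' @param hessian A `hessian_matrix` (Hartree/bohr^2).
#' @param structure The `molecular_structure` the Hessian belongs to.
#' @param soft_specs List of `soft_coordinate` objects (may be empty, in which
#'   case the result equals [normal_modes_a0()] with projection).
#' @param project_transrot Include the translation/rotation space in the
#'   projector (default `TRUE`).
#' @param drop_tol_cm Null modes must fall below this magnitude in cm-1.
#' @return A `normal_mode_set` of the reduced-dimensionality modes.
#' @export
reduced_modes <- function(hessian, structure, soft_specs,
                          project_transrot = TRUE, drop_tol_cm = 1) {
  if (inherits(soft_specs, "soft_coordinate")) soft_specs <- list(soft_specs)
  Hmw <- mass_weight(hessian, structure$masses)
  n3 <- nrow(Hmw)
  fixed <- if (project_transrot) transrot_basis(structure) else
    matrix(numeric(0), n3, 0L)
  inv_sqrt_m <- 1 / sqrt(.mass_vec3(structure$masses) * .ME_PER_AMU)
  if (length(soft_specs)) {
    U <- vapply(soft_specs, function(sp) {
      wilson_b_row(structure, sp) * inv_sqrt_m
    }, numeric(n3))
    ext <- .mgs_extend(fixed, U)
    if (!all(ext$kept)) {
      bad <- vapply(soft_specs[!ext$kept], `[[`, character(1), "label")
      stop("reduced_modes(): soft coordinates linearly dependent ",
           "(after mass-weighting and trans/rot removal): ",
           paste(bad, collapse = ", "))
    }
    basis <- ext$basis
  } else {
    basis <- fixed
  }
  if (is.null(basis)) basis <- matrix(numeric(0), n3, 0L)
  P <- diag(n3) - tcrossprod(basis)
  P <- (P + t(P)) / 2
  Hp <- P %*% Hmw %*% P
  e <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
  .modes_from_eigen(e$values, e$vectors, structure$masses,
                    seq_len(n_atoms(structure)),
                    drop_basis = basis, drop_tol_cm = drop_tol_cm)
}
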