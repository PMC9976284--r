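# Strategy A1: best-fit rigid superposition (Kabsch) of a reference structure
# onto each trajectory frame, and rotation of the reference normal modes into
# the frame's orientation.

#' Best-fit rigid superposition of a reference onto a frame
#'
#' Finds the proper rotation `R` and translation `t` minimizing the weighted
#' RMSD between `R %*% ref + t` and the frame (Kabsch, via SVD of the weighted
#' covariance). The reflection branch is disabled by default: `det(R)` is
#' forced to +1. For a degenerate (collinear) atom cloud the rotation about
#' the molecular axis is undetermined; the smallest-angle rotation mapping the
#' reference axis onto the frame axis is returned with a warning.
#'
#' `rmsd_before` is the RMSD after translation-only (centroid) alignment, so
#' `rmsd_after <= rmsd_before` always holds and the result is invariant to
#' pre-translation of either input.
#'
#' @param reference,frame `molecular_structure` objects with identical atom
#'   ordering.
#' @param weights Per-atom nonnegative fitting weights, not all zero
#'   (default: unit weights; pass masses for a mass-weighted fit).
#' @param allow_reflection Permit an improper transform when it fits better
#'   (default `FALSE`).
#' @return Object of class `superposition_result`: `rotation` (3 x 3, maps
#'   reference onto frame), `translation` (angstrom), `rmsd_before`,
#'   `rmsd_after` (angstrom).
#' @export
superpose <- function(reference, frame, weights = NULL,
                      allow_reflection = FALSE) {
  if (n_atoms(reference) != n_atoms(frame)) {
    stop("superpose(): atom-count mismatch between reference and frame")
  }
  n <- n_atoms(reference)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("superpose(): weights must be nonnegative, not all zero")
  }
  w <- weights / sum(weights)
  A <- reference$coords
  B <- frame$coords
  ca <- colSums(A * w)
  cb <- colSums(B * w)
  Ac <- sweep(A, 2L, ca)
  Bc <- sweep(B, 2L, cb)
  wrmsd <- function(X, Y) sqrt(sum(w * rowSums((X - Y)^2)))
  rmsd_before <- wrmsd(Ac, Bc)

  C <- crossprod(Ac * w, Bc)          # 3x3 covariance, maps ref -> frame
  s <- svd(C)
  rank <- sum(s$d > max(s$d[1L], 1e-300) * 1e-9)
  if (rank <= 1L) {
    warning("superpose(): collinear atom cloud; rotation about the axis is ",
            "undetermined, returning the smallest-angle axis alignment")
    R <- .axis_align_rotation(Ac, Bc, w)
  } else {
    d <- sign(det(s$v %*% t(s$u)))
    if (allow_reflection) d <- 1
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  }
  rmsd_after <- wrmsd(Ac %*% t(R), Bc)
  structure(list(rotation = R, translation = as.numeric(cb - R %*% ca),
                 rmsd_before = rmsd_before, rmsd_after = rmsd_after),
            class = "superposition_result")
}

# Smallest-angle rotation taking the dominant axis of Ac onto that of Bc
# (degenerate-cloud tie-break).
.axis_align_rotation <- function(Ac, Bc, w) {
  u <- svd(Ac * sqrt(w))$v[, 1L]
  v <- svd(Bc * sqrt(w))$v[, 1L]
  if (sum(u * v) < 0) v <- -v
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  cth <- max(-1, min(1, sum(u * v)))
  if (s < 1e-14) return(diag(3))
  rotation_about_axis(axis / s, atan2(s, cth))
}

#' Rotation matrix about an axis
#'
#' Rodrigues form; used for tie-breaks and by the test oracles.
#'
#' @param axis Unit 3-vector.
#' @param angle Angle in radians.
#' @return 3 x 3 proper orthogonal matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @export
print.superposition_result <- function(x, ...) {
  ang <- acos(max(-1, min(1, (sum(diag(x$rotation)) - 1) / 2)))
  cat(sprintf("<superposition_result> rotation %.2f deg, rmsd %.4f -> %.4f A\n",
              ang * 180 / pi, x$rmsd_before, x$rmsd_after))
  invisible(x)
}

#' Apply a superposition to a structure
#'
#' @param structure A `molecular_structure`.
#' @param transform A `superposition_result`.
#' @return The transformed `molecular_structure`.
#' @export
apply_superposition <- function(structure, transform) {
  out <- structure
  out$coords <- structure$coords %*% t(transform$rotation) +
    matrix(transform$translation, n_atoms(structure), 3, byrow = TRUE)
  out
}

#' Mass-weighted normal-coordinate value of a displaced structure
#'
#' Projects the displacement of `structure` from `reference` onto mode `k`
#' after best-fit rigid alignment, returning the mass-weighted normal
#' coordinate in atomic units (bohr sqrt(m_e)) -- the same unit as the
#' displacement step of the finite-difference engine, so a structure produced
#' by [displace_along_mode()] with step `s` has coordinate exactly `+/- s`.
#'
#' @param structure Displaced `molecular_structure`.
#' @param reference Reference `molecular_structure` the modes belong to.
#' @param modes A `normal_mode_set` of the reference.
#' @param k Mode index.
#' @param align Superpose `structure` onto `reference` first (default `TRUE`);
#'   turn off when both are known to share one orientation.
#' @return Normal-coordinate value in bohr sqrt(m_e).
#' @export
mode_coordinate <- function(structure, reference, modes, k, align = TRUE) {
  s <- structure
  if (align) s <- apply_superposition(s, superpose(s, reference))
  dx <- angstrom_to_bohr(as.vector(t(s$coords - reference$coords)))
  lk <- modes$vectors[, k]
  sqrt(.ME_PER_AMU) * sum(.mass_vec3(modes$masses) * lk * dx)
}

#' Rotate reference normal modes onto a frame (strategy A1)
#'
#' Left-multiplies every atom's 3-vector displacement in every mode by the
#' superposition rotation, projecting the reference modes onto the frame's
#' orientation. Wavenumbers and reduced masses are untouched; mass-weighted
#' orthonormality is preserved exactly because the transform is orthogonal.
#' The rotated vectors are not re-orthogonalized against the frame's
#' translation/rotation space: the operation is a pure rotation.
#'
#' @param reference_modes A `normal_mode_set` for the reference structure.
#' @param transform A `superposition_result` (or plain 3 x 3 rotation matrix)
#'   from [superpose()].
#' @return A `normal_mode_set` in the frame's orientation.
#' @export
rotate_modes <- function(reference_modes, transform) {
  R <- if (inherits(transform, "superposition_result")) transform$rotation
       else as.matrix(transform)
  V <- reference_modes$vectors
  n <- length(reference_modes$masses)
  out <- V
  for (k in seq_len(ncol(V))) {
    disp <- matrix(V[, k], n, 3, byrow = TRUE)
    out[, k] <- as.vector(t(disp %*% t(R)))
  }
  normal_mode_set(reference_modes$wavenumbers, out, reference_modes$masses,
                  active_atoms = reference_modes$active_atoms)
}
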