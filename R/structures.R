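# Domain containers. Lightweight S3 lists with validating constructors, in the
# style of bio3d objects: plain data, predictable fields, print methods.

#' Molecular structure container
#'
#' Element labels, Cartesian coordinates in angstrom and atomic masses in amu.
#' Masses default to standard atomic weights looked up from the labels.
#'
#' @param labels Character vector of element symbols.
#' @param coords N x 3 numeric matrix of Cartesian coordinates (angstrom).
#' @param masses Optional numeric vector of masses in amu (all > 0).
#' @param resid Optional integer vector of residue ids per atom (used by the
#'   solvent-shell cut); defaults to one residue per atom.
#' @return Object of class `molecular_structure`.
#' @export
#' @examples
#' water <- molecular_structure(
#'   c("O", "H", "H"),
#'   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
molecular_structure <- function(labels, coords, masses = NULL, resid = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (length(labels) != n) stop("length(labels) must equal nrow(coords)")
  if (is.null(masses)) masses <- atomic_masses(labels)
  if (length(masses) != n) stop("length(masses) must equal nrow(coords)")
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all masses must be positive and finite")
  }
  if (is.null(resid)) resid <- seq_len(n)
  if (length(resid) != n) stop("length(resid) must equal nrow(coords)")
  structure(
    list(labels = as.character(labels), coords = unname(coords),
         masses = as.numeric(masses), resid = as.integer(resid)),
    class = "molecular_structure")
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat(sprintf("<molecular_structure> %d atoms (%s)\n", length(x$labels),
              paste(utils::head(x$labels, 8L), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A `molecular_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$coords)

#' Ordered set of trajectory frames
#'
#' Frames share one atom ordering unless `ragged = TRUE` (frames produced by a
#' per-frame solvent-shell cut may keep different residues).
#'
#' @param frames List of `molecular_structure` objects.
#' @param timestamps Optional numeric vector of times in ps, one per frame.
#' @param ragged If `TRUE`, skip the same-atom-ordering consistency check.
#' @return Object of class `frame_set`.
#' @export
frame_set <- function(frames, timestamps = NULL, ragged = FALSE) {
  if (!length(frames)) stop("frame_set(): at least one frame required")
  ok <- vapply(frames, inherits, logical(1), what = "molecular_structure")
  if (!all(ok)) stop("all frames must be molecular_structure objects")
  if (!ragged) {
    ref <- frames[[1L]]$labels
    same <- vapply(frames, function(f) identical(f$labels, ref), logical(1))
    if (!all(same)) {
      stop("frame_set(): frames differ in atom count or label sequence ",
           "(use ragged = TRUE for shell-cut frames)")
    }
  }
  if (!is.null(timestamps) && length(timestamps) != length(frames)) {
    stop("timestamps must have one entry per frame")
  }
  structure(list(frames = frames, timestamps = timestamps, ragged = ragged),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames, %s atoms%s\n", length(x$frames),
              if (x$ragged) "ragged" else nrow(x$frames[[1L]]$coords),
              if (is.null(x$timestamps)) "" else ", timestamped"))
  invisible(x)
}

#' @export
length.frame_set <- function(x) length(x$frames)

#' Cartesian Hessian matrix container
#'
#' A 3N x 3N real symmetric matrix of second derivatives in Hartree/bohr^2.
#' The input is symmetrized as `(H + t(H)) / 2`; relative asymmetry beyond
#' 1e-6 warns and beyond 1e-3 is an error.
#'
#' @param matrix 3N x 3N numeric matrix, Hartree/bohr^2.
#' @param atom_count N; defaults to `nrow(matrix) / 3`.
#' @return Object of class `hessian_matrix` with fields `matrix`, `atom_count`.
#' @export
hessian_matrix <- function(matrix, atom_count = nrow(matrix) %/% 3L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("Hessian must be square")
  if (nrow(matrix) != 3L * atom_count) {
    stop(sprintf("Hessian dimension mismatch: expected %d rows for %d atoms, found %d",
                 3L * atom_count, atom_count, nrow(matrix)))
  }
  scale <- max(abs(matrix), 1e-300)
  asym <- max(abs(matrix - t(matrix))) / scale
  if (asym > 1e-3) {
    stop(sprintf("Hessian asymmetry %.3g exceeds 1e-3 relative; refusing to symmetrize", asym))
  }
  if (asym > 1e-6) {
    warning(sprintf("Hessian asymmetry %.3g above 1e-6 relative; symmetrizing", asym))
  }
  structure(list(matrix = unname((matrix + t(matrix)) / 2),
                 atom_count = as.integer(atom_count)),
            class = "hessian_matrix")
}

#' @export
print.hessian_matrix <- function(x, ...) {
  cat(sprintf("<hessian_matrix> %d atoms (%d x %d), Hartree/bohr^2\n",
              x$atom_count, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Harmonic normal mode set
#'
#' Wavenumbers in cm-1 (negative values encode imaginary frequencies),
#' Cartesian displacement vectors, and reduced masses. Columns of `vectors`
#' are normalized so that the mass-weighted vectors `sqrt(m) * l` (masses in
#' amu) are mutually orthonormal; the reduced mass of mode k is then
#' `1 / sum(l_k^2)` in amu.
#'
#' @param wavenumbers Numeric vector, cm-1; negative = imaginary mode.
#' @param vectors 3N x n_modes matrix of Cartesian displacements (columns),
#'   mass-weighted-orthonormal as described above.
#' @param masses Atom masses in amu (length N).
#' @param active_atoms Integer indices of the atoms the modes span (whole
#'   molecule unless the set came from a partial Hessian analysis).
#' @return Object of class `normal_mode_set` with fields `wavenumbers`,
#'   `vectors`, `masses`, `reduced_masses`, `active_atoms`.
#' @export
normal_mode_set <- function(wavenumbers, vectors, masses,
                            active_atoms = seq_along(masses)) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L * length(masses)) {
    stop("vectors must have 3 * length(masses) rows")
  }
  if (length(wavenumbers) != ncol(vectors)) {
    stop("one wavenumber per mode column required")
  }
  if (ncol(vectors) > 3L * length(active_atoms)) {
    stop("more modes than active degrees of freedom")
  }
  reduced <- 1 / colSums(vectors^2)
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 vectors = unname(vectors),
                 masses = as.numeric(masses),
                 reduced_masses = as.numeric(reduced),
                 active_atoms = as.integer(active_atoms)),
            class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  n_im <- sum(x$wavenumbers < 0)
  cat(sprintf("<normal_mode_set> %d modes (%d imaginary), %.1f..%.1f cm-1\n",
              length(x$wavenumbers), n_im,
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

# mass-weighting matrix diag(sqrt(m)) expanded over x,y,z, masses in amu
.mass_vec3 <- function(masses) rep(masses, each = 3L)

#' Gram matrix of the mass-weighted mode vectors
#'
#' Identity (within tolerance) for any valid mode set; useful to check
#' orthonormality after transformations.
#'
#' @param modes A `normal_mode_set`.
#' @return n_modes x n_modes numeric matrix.
#' @export
mode_gram <- function(modes) {
  mw <- modes$vectors * sqrt(.mass_vec3(modes$masses))
  crossprod(mw)
}
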