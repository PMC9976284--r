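# Independent oracles and small fixtures shared across the suite. These stay
# deliberately naive (random search, finite differences, explicit formulas)
# so they never share code paths with the implementation they check.

cc <- unit_constants()

# displace one Cartesian component of a structure
nudge <- function(st, atom, axis, h) {
  st$coords[atom, axis] <- st$coords[atom, axis] + h
  st
}

# central-difference gradient of a scalar function of a structure
fd_gradient <- function(st, f, h = 1e-5) {
  n <- n_atoms(st)
  g <- numeric(3L * n)
  for (a in seq_len(n)) {
    for (x in 1:3) {
      g[3L * (a - 1L) + x] <-
        (f(nudge(st, a, x, h)) - f(nudge(st, a, x, -h))) / (2 * h)
    }
  }
  g
}

# dihedral via explicit plane normals and acos + sign (independent of the
# atan2 formulation in the package)
dihedral_by_normals <- function(coords) {
  b1 <- coords[2, ] - coords[1, ]
  b2 <- coords[3, ] - coords[2, ]
  b3 <- coords[4, ] - coords[3, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(max(-1, min(1, cosphi)))
  s <- sum(cr(n1, n2) * b2)
  if (s < 0) phi <- -phi
  phi
}

# minimized RMSD by seeded random search over rotations with shrinking-step
# refinement; independent of the SVD solution
brute_rmsd_min <- function(A, B, seed = 99, n_coarse = 3000) {
  set.seed(seed)
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  val <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  best_R <- diag(3); best <- val(best_R)
  for (i in seq_len(n_coarse)) {
    R <- random_rotation_matrix()
    v <- val(R)
    if (v < best) { best <- v; best_R <- R }
  }
  ang <- 0.6
  for (it in 1:10) {
    for (i in 1:400) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rotation_about_axis(ax, stats::rnorm(1, sd = ang)) %*% best_R
      v <- val(R)
      if (v < best) { best <- v; best_R <- R }
    }
    ang <- ang / 3
  }
  best
}

# diatomic Cartesian Hessian with force constant k (Hartree/bohr^2) along the
# bond axis
diatomic_hessian <- function(k, axis = c(1, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  blk <- k * tcrossprod(u)
  hessian_matrix(rbind(cbind(blk, -blk), cbind(-blk, blk)), atom_count = 2L)
}

# rotate a structure and conjugate its Hessian by the block rotation
rotate_system <- function(structure, hessian, R) {
  n <- n_atoms(structure)
  structure$coords <- structure$coords %*% t(R)
  Rbig <- matrix(0, 3L * n, 3L * n)
  for (a in seq_len(n)) {
    idx <- (3L * (a - 1L) + 1L):(3L * a)
    Rbig[idx, idx] <- R
  }
  H <- Rbig %*% hessian$matrix %*% t(Rbig)
  list(structure = structure, hessian = hessian_matrix(H, atom_count = n))
}

# two structural families: `n_a` frames around a base geometry and `n_b`
# around a strongly deformed copy, with small seeded Cartesian noise
two_blob_frames <- function(n_a = 30, n_b = 10, seed = 5) {
  set.seed(seed)
  toy <- make_harmonic_molecule(4, seq(600, 1800, length.out = 6), seed = seed)
  base_a <- toy$structure
  base_b <- toy$structure
  base_b$coords <- base_b$coords +
    matrix(c(1.6, -1.1, 0.9), n_atoms(base_b), 3, byrow = TRUE) *
      (seq_len(n_atoms(base_b)) %% 2 * 2 - 1)
  jitter_frame <- function(base) {
    f <- base
    f$coords <- f$coords + matrix(stats::rnorm(12, sd = 0.02), 4, 3)
    f
  }
  frames <- c(lapply(seq_len(n_a), function(i) jitter_frame(base_a)),
              lapply(seq_len(n_b), function(i) jitter_frame(base_b)))
  frame_set(frames)
}

# toy resonance system: harmonic molecule whose excitation energy is linear
# in one normal coordinate, so exactly that mode is resonance-enhanced
resonance_toy <- function(seed = 17, target_mode = 6,
                          slope_ev_per_q = 30, e0_ev = 2.49) {
  toy <- make_harmonic_molecule(5, seq(700, 1660, length.out = 9), seed = seed)
  ref <- toy$structure
  modes <- toy$modes
  calc <- pole_polarizability_calculator(
    function(s) e0_ev + slope_ev_per_q *
      mode_coordinate(s, ref, modes, target_mode),
    function(s) c(1, 0.3, 0.1))
  list(toy = toy, calculator = calc, target_mode = target_mode,
       target_wavenumber = modes$wavenumbers[target_mode])
}
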