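test_that("mass weighting follows the 1/sqrt(m_i m_j) rule", {
  me_amu <- 1 / cc$me_per_amu          # exactly 1 electron mass, in amu
  H <- diag(6) * 0.3
  st_masses <- rep(me_amu, 2)
  expect_equal(mass_weight(H, st_masses), H, tolerance = 1e-12)
  m <- c(2, 8)
  mw <- mass_weight(H, m)
  expect_equal(diag(mw), 0.3 / (rep(m, each = 3) * cc$me_per_amu),
               tolerance = 1e-12)
  expect_error(mass_weight(H, c(1, -1)), "mass")
})

test_that("diatomic frequencies match the closed form over 3 decades", {
  for (k in c(0.01, 0.1, 1, 10)) {
    for (m_amu in c(0.5, 5, 50)) {
      st <- molecular_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
                                masses = c(2 * m_amu, 2 * m_amu))  # mu = m_amu
      h <- diatomic_hessian(k, axis = c(1, 0, 0))
      modes <- normal_modes_a0(h, st, project_transrot = TRUE)
      got <- max(modes$wavenumbers)
      closed <- sqrt(k / (m_amu * cc$me_per_amu)) * cc$cm_per_hartree
      expect_equal(got, closed, tolerance = 1e-9)
    }
  }
})

test_that("Eckart projector is symmetric, idempotent, and spans >= 6 null modes", {
  set.seed(4)
  st <- molecular_structure(rep("C", 4), matrix(runif(12, -1.5, 1.5), 4, 3))
  mc <- morse_cluster_hessian(st)
  Hmw <- mass_weight(mc$hessian, st$masses)
  pr <- eckart_project(Hmw, st)
  P <- pr$projector
  expect_lt(max(abs(P %*% P - P)), 1e-10)
  expect_lt(max(abs(P - t(P))), 1e-12)
  ev <- eigen(pr$matrix, symmetric = TRUE)$values
  wn <- sign(ev) * sqrt(abs(ev)) * cc$cm_per_hartree
  expect_gte(sum(abs(wn) < 1), 6L)
})

test_that("projection leaves genuine vibrations of a clean Hessian unchanged", {
  toy <- make_harmonic_molecule(5, seq(400, 2300, length.out = 9), seed = 8)
  un <- normal_modes_a0(toy$hessian, toy$structure, project_transrot = FALSE)
  pr <- normal_modes_a0(toy$hessian, toy$structure, project_transrot = TRUE)
  vib <- sort(un$wavenumbers)[-(1:6)]  # drop the six exact zeros
  expect_equal(sort(pr$wavenumbers), vib, tolerance = 1e-4)
})

test_that("spectral-synthesis oracle: frequencies and vectors are recovered", {
  freqs <- seq(450, 2250, length.out = 9)
  toy <- make_harmonic_molecule(5, freqs, seed = 13)
  rec <- normal_modes_a0(toy$hessian, toy$structure)
  expect_equal(rec$wavenumbers, freqs, tolerance = 1e-6)
  expect_lt(max(abs(mode_gram(rec) - diag(9))), 1e-6)
  # vectors match within phase: |overlap| of mass-weighted vectors = 1
  mwamp <- function(m) m$vectors * sqrt(rep(m$masses, each = 3))
  ov <- abs(colSums(mwamp(rec) * mwamp(toy$modes)))
  expect_equal(ov, rep(1, 9), tolerance = 1e-8)
})

test_that("all-negative curvature gives all-negative wavenumbers", {
  st <- molecular_structure(rep("C", 2), rbind(c(0, 0, 0), c(1, 0, 0)))
  h <- hessian_matrix(-diag(6), atom_count = 2L)
  modes <- normal_modes_a0(h, st, project_transrot = FALSE)
  expect_true(all(modes$wavenumbers < 0))
})

test_that("frequencies are invariant under global rotation of the system", {
  toy <- make_harmonic_molecule(5, seq(400, 2300, length.out = 9), seed = 21)
  R <- rotation_about_axis(c(1, 2, -1), 1.1)
  rot <- rotate_system(toy$structure, toy$hessian, R)
  a <- normal_modes_a0(toy$hessian, toy$structure)
  b <- normal_modes_a0(rot$hessian, rot$structure)
  expect_equal(a$wavenumbers, b$wavenumbers, tolerance = 1e-6)
})

test_that("PHVA with the full active set equals full diagonalization", {
  toy <- make_harmonic_molecule(4, seq(500, 1800, length.out = 6), seed = 6)
  a0 <- normal_modes_a0(toy$hessian, toy$structure, project_transrot = FALSE)
  ph <- phva_modes(toy$hessian, toy$structure, 1:4)
  expect_equal(ph$wavenumbers, a0$wavenumbers, tolerance = 1e-8)
})

test_that("PHVA on one of two uncoupled diatomics gives the isolated frequency", {
  k1 <- 0.7; k2 <- 0.2
  H <- matrix(0, 12, 12)
  blk <- function(k, u) k * tcrossprod(u / sqrt(sum(u^2)))
  b1 <- blk(k1, c(1, 0, 0)); b2 <- blk(k2, c(0, 1, 0))
  H[1:3, 1:3] <- b1; H[4:6, 4:6] <- b1; H[1:3, 4:6] <- -b1; H[4:6, 1:3] <- -b1
  H[7:9, 7:9] <- b2; H[10:12, 10:12] <- b2
  H[7:9, 10:12] <- -b2; H[10:12, 7:9] <- -b2
  st <- molecular_structure(rep("N", 4),
                            rbind(c(0, 0, 0), c(1.1, 0, 0),
                                  c(8, 0, 0), c(8, 1.1, 0)),
                            masses = c(4, 4, 10, 10))
  ph <- phva_modes(hessian_matrix(H, 4L), st, active_atoms = 1:2)
  mu <- 2  # reduced mass of the 4,4 pair
  closed <- sqrt(k1 / (mu * cc$me_per_amu)) * cc$cm_per_hartree
  expect_equal(max(ph$wavenumbers), closed, tolerance = 1e-8)
  expect_equal(length(ph$wavenumbers), 6L)  # 3 * N_active
})

test_that("PHVA on a coupled bilinear pair gives the sub-block frequency, not a full eigenvalue", {
  k11 <- 0.5; k22 <- 0.3; k12 <- 0.15
  H <- matrix(0, 6, 6)
  H[1, 1] <- k11; H[4, 4] <- k22; H[1, 4] <- H[4, 1] <- k12
  st <- molecular_structure(c("C", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                            masses = c(3, 7))
  ph <- phva_modes(hessian_matrix(H, 2L), st, active_atoms = 1L)
  got <- max(ph$wavenumbers)
  sub_closed <- sqrt(k11 / (3 * cc$me_per_amu)) * cc$cm_per_hartree
  expect_equal(got, sub_closed, tolerance = 1e-8)
  full <- normal_modes_a0(hessian_matrix(H, 2L), st, project_transrot = FALSE)
  expect_gt(min(abs(max(full$wavenumbers) - got),
                abs(sort(full$wavenumbers, decreasing = TRUE)[2] - got)), 1)
})

test_that("imaginary-mode counting respects the residue threshold", {
  toy <- make_harmonic_molecule(4, c(-150, seq(500, 1700, length.out = 5)),
                                seed = 9)
  modes <- normal_modes_a0(toy$hessian, toy$structure)
  ci <- count_imaginary(modes)
  expect_equal(ci$n_imaginary, 1L)
  expect_equal(modes$wavenumbers[ci$indices], -150, tolerance = 1e-6)
  pos <- make_harmonic_molecule(4, seq(500, 1800, length.out = 6), seed = 9)
  expect_equal(count_imaginary(normal_modes_a0(pos$hessian, pos$structure))$n_imaginary, 0L)
})

test_that("off-minimum Morse snapshots develop more imaginary modes than the minimum", {
  r0 <- 1.5
  eq <- molecular_structure(rep("C", 3),
                            rbind(c(0, 0, 0), c(r0, 0, 0),
                                  c(r0 / 2, r0 * sqrt(3) / 2, 0)))
  n_imag <- function(st) {
    h <- morse_cluster_hessian(st, de = 0.1, a = 1, r0 = r0)$hessian
    count_imaginary(normal_modes_a0(h, st))$n_imaginary
  }
  expect_equal(n_imag(eq), 0L)
  set.seed(31)
  displaced <- vapply(1:20, function(i) {
    st <- eq
    st$coords <- st$coords + matrix(rnorm(9, sd = 0.35), 3, 3)
    n_imag(st)
  }, integer(1))
  expect_gt(sum(displaced), 0L)
})
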