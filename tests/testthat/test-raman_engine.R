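test_that("mode displacement is symmetric and scales as step * M^(-1/2) L", {
  toy <- make_harmonic_molecule(4, seq(500, 1800, length.out = 6), seed = 2)
  d0 <- displace_along_mode(toy$structure, toy$modes, 2, step = 0)
  expect_equal(d0$plus$coords, toy$structure$coords)
  expect_equal(d0$minus$coords, toy$structure$coords)
  d <- displace_along_mode(toy$structure, toy$modes, 2, step = 0.003)
  expect_equal((d$plus$coords + d$minus$coords) / 2, toy$structure$coords,
               tolerance = 1e-12)

  # diatomic: pure stretch changes only the bond length, by the hand-computed
  # mass-weighted scaling
  st <- molecular_structure(c("O", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  modes <- normal_modes_a0(diatomic_hessian(0.4), st)
  k <- which.max(modes$wavenumbers)
  step <- 0.01
  dd <- displace_along_mode(st, modes, k, step = step)
  bond <- function(s) sqrt(sum((s$coords[2, ] - s$coords[1, ])^2))
  mu_me <- (st$masses[1] / 2) * cc$me_per_amu
  # relative stretch coordinate: |d(bond)/dQ| = 1/sqrt(mu) in a.u.
  expected <- step / sqrt(mu_me) * cc$angstrom_per_bohr
  expect_equal(abs(bond(dd$plus) - bond(st)), expected, tolerance = 1e-8)
  expect_equal(bond(dd$plus) - bond(st), -(bond(dd$minus) - bond(st)),
               tolerance = 1e-12)

  neg <- make_harmonic_molecule(4, c(-200, seq(600, 1700, length.out = 5)),
                                seed = 3)
  m <- normal_modes_a0(neg$hessian, neg$structure)
  expect_error(displace_along_mode(neg$structure, m, 1), "imaginary")
})

test_that("central differences are exact for a calculator linear in the mode", {
  toy <- make_harmonic_molecule(4, seq(500, 1800, length.out = 6), seed = 6)
  ref <- toy$structure
  slope <- matrix(c(2, 0.5, 0.1, 0.5, 1, 0, 0.1, 0, 3), 3, 3)
  calc <- function(s, ev, damp) {
    q <- mode_coordinate(s, ref, toy$modes, 4, align = FALSE)
    (1 + q * 5) * slope + 0i
  }
  der <- polarizability_derivatives(calc, ref, toy$modes, 2.49, 500, 0.001)
  expect_equal(Re(der$tensors[[4]]), 5 * slope, tolerance = 1e-7)
  expect_lt(max(Mod(der$tensors[[2]])), 1e-7)
})

test_that("finite differences converge at second order against the pole model", {
  rt <- resonance_toy(seed = 17)
  toy <- rt$toy
  # closed-form derivative of the single-pole tensor in the target mode
  e0 <- 2.49; slope <- 30; gam <- cm_to_ev(500); win <- 2.3
  mu <- c(1, 0.3, 0.1)
  dalpha_exact <- -tcrossprod(mu) * slope *
    (1 / (complex(real = e0 - win, imaginary = -gam))^2 +
       1 / (complex(real = e0 + win, imaginary = gam))^2)
  err_for <- function(h) {
    der <- polarizability_derivatives(rt$calculator, toy$structure, toy$modes,
                                      incident_ev = win, damping_cm = 500,
                                      step = h)
    max(Mod(der$tensors[[rt$target_mode]] - dalpha_exact))
  }
  e1 <- err_for(0.001)
  e2 <- err_for(0.0005)
  ratio <- e1 / e2
  expect_gt(ratio, 3.8)
  expect_lt(ratio, 4.2)
})

test_that("derivative magnitude decreases monotonically with damping", {
  rt <- resonance_toy(seed = 11)
  toy <- rt$toy
  norms <- vapply(c(250, 500, 1000, 2000), function(g) {
    der <- polarizability_derivatives(rt$calculator, toy$structure, toy$modes,
                                      incident_ev = 2.49, damping_cm = g,
                                      step = 0.001)
    sqrt(sum(Mod(der$tensors[[rt$target_mode]])^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("Raman invariants: isotropic, traceless and rotation-invariant cases", {
  iso <- raman_invariants((2 + 1i) * diag(3))
  expect_equal(iso$a2, Mod(2 + 1i)^2, tolerance = 1e-12)
  expect_equal(iso$g2, 0, tolerance = 1e-12)
  tl <- raman_invariants(diag(c(1, -1, 0)))
  expect_equal(tl$a2, 0, tolerance = 1e-12)
  expect_equal(tl$g2, 3, tolerance = 1e-12)
  set.seed(30)
  for (i in 1:5) {
    d <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
    d <- (d + t(d)) / 2
    R <- random_rotation_matrix()
    dr <- R %*% d %*% t(R)
    a <- raman_invariants(d); b <- raman_invariants(dr)
    expect_equal(a$a2, b$a2, tolerance = 1e-10)
    expect_equal(a$g2, b$g2, tolerance = 1e-10)
  }
  asym <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3)
  expect_error(raman_invariants(asym), "antisymmetric")
})

test_that("stick intensities follow the (nu0-nu)^3 nu0 A / nu law", {
  mk_der <- function(wn, tensors, ev = nm_to_ev(500)) {
    out <- list(tensors = tensors, wavenumbers = wn, skipped = integer(0),
                incident_ev = ev, damping_cm = 500, step = 0.001)
    class(out) <- "polarizability_derivative_set"
    out
  }
  t1 <- diag(3) + 0i
  nu0 <- ev_to_cm(cm_to_ev(20000))
  der <- mk_der(c(1000, 2000), list(t1, t1), ev = cm_to_ev(20000))
  st <- stick_spectrum(der)
  expect_equal(st$intensity[1] / st$intensity[2],
               ((nu0 - 1000)^3 / 1000) / ((nu0 - 2000)^3 / 2000),
               tolerance = 1e-10)
  # zero tensor -> zero intensity
  der0 <- mk_der(c(1000, 2000), list(t1 * 0, t1), ev = cm_to_ev(20000))
  expect_equal(stick_spectrum(der0)$intensity[1], 0)
  # mode above the excitation line is skipped with a warning
  der_hot <- mk_der(c(1000, 25000), list(t1, t1), ev = cm_to_ev(20000))
  expect_warning(st2 <- stick_spectrum(der_hot), "above the incident")
  expect_equal(nrow(st2), 1L)
  # thermal factor raises low-frequency intensity
  stT <- stick_spectrum(der, temperature_k = 298.15)
  expect_gt(stT$intensity[1] / st$intensity[1],
            stT$intensity[2] / st$intensity[2])
})

test_that("stick intensity peaks at resonance over an incident-energy scan", {
  rt <- resonance_toy(seed = 17)
  toy <- rt$toy
  scan <- seq(2.0, 3.0, by = 0.125)
  peak <- vapply(scan, function(ev) {
    der <- polarizability_derivatives(rt$calculator, toy$structure, toy$modes,
                                      incident_ev = ev, damping_cm = 500,
                                      step = 0.001)
    stick_spectrum(der)$intensity[rt$target_mode]
  }, numeric(1))
  expect_equal(scan[which.max(peak)], 2.5, tolerance = 0.13)
})

test_that("Lorentzian convolution has the contracted height, width and area", {
  sticks <- data.frame(mode = 1L, wavenumber = 1500, intensity = 1)
  grid <- seq(1000, 2000, by = 0.1)
  sp <- convolve_lorentzian(sticks, grid = grid, hwhm_cm = 10)
  expect_equal(max(sp$intensity), 1 / (pi * 10), tolerance = 1e-4)
  expect_equal(sp$grid[which.max(sp$intensity)], 1500, tolerance = 0.1)
  # trapezoid area ~ total stick intensity (tails cut by the finite window)
  area <- sum(diff(grid) * (head(sp$intensity, -1) + tail(sp$intensity, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.02)
  expect_error(convolve_lorentzian(sticks, grid, hwhm_cm = 0), "positive")
})

test_that("spectral averaging is a weighted pointwise mean with exact normalization", {
  grid <- seq(1000, 1200, by = 0.5)
  mk <- function(center) convolve_lorentzian(
    data.frame(mode = 1L, wavenumber = center, intensity = 1), grid = grid)
  s <- list(mk(1050), mk(1100), mk(1150))
  eq <- average_spectra(s, normalize = FALSE)
  expect_equal(eq$intensity,
               (s[[1]]$intensity + s[[2]]$intensity + s[[3]]$intensity) / 3,
               tolerance = 1e-12)
  first <- average_spectra(s, weights = c(1, 0, 0), normalize = FALSE)
  expect_equal(first$intensity, s[[1]]$intensity, tolerance = 1e-12)
  w <- c(0.5, 0.3, 0.2)
  direct <- 0.5 * s[[1]]$intensity + 0.3 * s[[2]]$intensity +
    0.2 * s[[3]]$intensity
  got <- average_spectra(s, weights = w, normalize = FALSE)
  expect_equal(got$intensity, direct, tolerance = 1e-12)
  norm <- average_spectra(s, weights = w, normalize = TRUE)
  expect_identical(max(norm$intensity), 1)
  expect_warning(average_spectra(s, weights = c(2, 1, 1)), "renormalizing")
})

test_that("stick spectra are invariant under rotation of the whole system", {
  rt <- resonance_toy(seed = 23)
  toy <- rt$toy
  der <- polarizability_derivatives(rt$calculator, toy$structure, toy$modes,
                                    incident_ev = 2.49, damping_cm = 500)
  s0 <- stick_spectrum(der)
  R <- rotation_about_axis(c(1, -2, 2), 1.15)
  rot <- rotate_system(toy$structure, toy$hessian, R)
  rot_modes <- rotate_modes(toy$modes, R)
  # the toy excitation energy aligns the frame internally, so the same
  # calculator is valid in the rotated orientation
  der_r <- polarizability_derivatives(rt$calculator, rot$structure, rot_modes,
                                      incident_ev = 2.49, damping_cm = 500)
  s1 <- stick_spectrum(der_r)
  expect_equal(s1$intensity / max(s1$intensity),
               s0$intensity / max(s0$intensity), tolerance = 1e-6)
})

test_that("off-resonance activity ratios converge to the static limit", {
  # two electronic states coupled to two different modes: the ratio of their
  # activities depends on the detuning near resonance but saturates at the
  # static (omega -> 0) value far below both poles
  toy <- make_harmonic_molecule(5, seq(700, 1660, length.out = 9), seed = 17)
  ref <- toy$structure
  calc <- pole_polarizability_calculator(
    function(s) c(2.49 + 30 * mode_coordinate(s, ref, toy$modes, 6),
                  6.00 + 30 * mode_coordinate(s, ref, toy$modes, 3)),
    function(s) rbind(c(1, 0.3, 0.1), c(0.2, 1, 0.4)))
  ratio_at <- function(ev) {
    der <- polarizability_derivatives(calc, ref, toy$modes,
                                      incident_ev = ev, damping_cm = 500)
    a6 <- raman_invariants(der$tensors[[6]])
    a3 <- raman_invariants(der$tensors[[3]])
    (45 * a6$a2 + 7 * a6$g2) / (45 * a3$a2 + 7 * a3$g2)
  }
  near <- ratio_at(2.49)
  seqs <- vapply(c(0.4, 0.2, 0.1, 0.05), ratio_at, numeric(1))
  # monotone approach to a static plateau, far from the resonant ratio
  expect_equal(seqs[3], seqs[4], tolerance = 0.02)
  expect_gt(near / seqs[4], 10)
})
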