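# End-to-end protocol: snapshot selection -> RMSD clustering -> per-
# representative normal modes (strategy a0 | phva | a1 | a2) -> complex
# polarizability derivatives -> stick spectrum -> Lorentzian broadening ->
# persistence-weighted average. Configured from a YAML file or an equivalent
# named list; every physical default mirrors the protocol's reference values
# (step 0.001 au, damping 500 cm-1, HWHM 10 cm-1, grid 1000-2000 cm-1).

.default_config <- function() {
  list(
    strategy = "a0",
    incident_ev = 2.49,
    damping_cm = 500,
    step = 0.001,
    hwhm_cm = 10,
    grid = c(1000, 2000, 0.5),
    project_transrot = TRUE,
    cluster = list(cutoff = 1.0),
    snapshot = list(stride = 1, shell_cutoff = Inf),
    normalize = TRUE,
    seed = 1L
  )
}

#' Build a polarizability calculator from a config entry
#'
#' Supported type: `"pole"`, a single-state resonance-pole model whose
#' excitation energy is linear in one bond length:
#' `E(structure) = e0_ev + slope_ev_per_a * (r_bond - r_ref_a)`, with a fixed
#' transition dipole. This is the built-in analytic stand-in for an external
#' electronic-structure calculator.
#'
#' @param spec Named list with `type = "pole"`, `e0_ev`, `slope_ev_per_a`,
#'   `bond` (two atom indices), `r_ref_a`, `dipole` (length-3, au).
#' @return A calculator function suitable for
#'   [polarizability_derivatives()].
#' @export
calculator_from_config <- function(spec) {
  if (is.null(spec$type) || spec$type != "pole") {
    stop("calculator_from_config(): only type 'pole' is built in")
  }
  bond <- as.integer(spec$bond)
  e0 <- spec$e0_ev
  slope <- spec$slope_ev_per_a
  r_ref <- spec$r_ref_a
  dip <- as.numeric(spec$dipole)
  pole_polarizability_calculator(
    excitation_energy_fn = function(s) {
      r <- sqrt(sum((s$coords[bond[1L], ] - s$coords[bond[2L], ])^2))
      e0 + slope * (r - r_ref)
    },
    transition_dipole_fn = function(s) dip
  )
}

.modes_for_frame <- function(strategy, hessian, frame, config, reference,
                             reference_modes) {
  switch(strategy,
    a0 = normal_modes_a0(hessian, frame,
                         project_transrot = isTRUE(config$project_transrot)),
    phva = phva_modes(hessian, frame, active_atoms = config$active),
    a1 = rotate_modes(reference_modes, superpose(reference, frame)),
    a2 = {
      specs <- lapply(config$soft, function(s) {
        soft_coordinate(s$atoms, label = if (is.null(s$label))
          paste(s$atoms, collapse = "-") else s$label)
      })
      reduced_modes(hessian, frame, specs,
                    project_transrot = isTRUE(config$project_transrot))
    },
    stop("unknown strategy: ", strategy))
}

#' Run the full resonance Raman protocol
#'
#' Executes snapshot decimation and solvent-shell cutting, RMSD clustering
#' into structural families, per-representative normal-mode analysis with the
#' chosen strategy, complex polarizability derivatives by central finite
#' difference, short-time-approximation stick intensities, Lorentzian
#' broadening, and persistence-weighted averaging; writes all outputs and a
#' machine-readable manifest to `out_dir`.
#'
#' Config entries (YAML file or named list): `frames` (multi-frame XYZ path
#' or a `frame_set`), `hessian` (path or `hessian_matrix`), `strategy`
#' (`"a0"`, `"phva"`, `"a1"`, `"a2"`), `reference` (XYZ path or structure,
#' a1 only), `active` (atom indices, phva), `soft` (list of
#' `{atoms, label}`, a2), `calculator` (config for
#' [calculator_from_config()], unless a calculator function is passed
#' directly), `incident_ev`, `damping_cm`, `step`, `hwhm_cm`, `grid`
#' (min, max, spacing), `cluster$cutoff`, `cluster$selection` (atom indices),
#' `snapshot$stride`, `snapshot$shell_cutoff`, `snapshot$target_atoms`,
#' `normalize`, `seed`.
#'
#' Frames that fail mode analysis or the calculator are logged and skipped; if
#' more than half of the representatives fail the run errors out.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param calculator Optional calculator function overriding
#'   `config$calculator`.
#' @param out_dir Output directory (default `config$out_dir`, else a temp
#'   directory).
#' @return (Invisibly) list with `spectrum` (`raman_spectrum`), `assignment`
#'   (`cluster_assignment`), `per_cluster` (sticks, spectra and imaginary-mode
#'   info per representative) and `out_dir`.
#' @export
run_protocol <- function(config, calculator = NULL, out_dir = NULL) {
  cfg_dir <- "."
  if (is.character(config)) {
    cfg_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.default_config(), config)
  # input paths in a config file are relative to the file's directory
  for (f in c("frames", "hessian", "reference")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]])) {
      cfg[[f]] <- file.path(cfg_dir, cfg[[f]])
    }
  }
  cfg$snapshot$shell_cutoff <- as.numeric(cfg$snapshot$shell_cutoff)
  cfg$grid <- as.numeric(unlist(cfg$grid))
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("resoraman_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))

  # --- inputs -------------------------------------------------------------
  if (is.null(cfg$frames)) stop("run_protocol(): config must name frames")
  frames <- if (is.character(cfg$frames)) read_xyz(cfg$frames) else cfg$frames
  hessian <- NULL
  if (!is.null(cfg$hessian)) {
    hessian <- if (is.character(cfg$hessian)) read_hessian(cfg$hessian)
               else cfg$hessian
  }
  reference <- NULL
  reference_modes <- NULL
  if (identical(cfg$strategy, "a1")) {
    if (is.null(cfg$reference)) stop("run_protocol(): strategy a1 needs a reference")
    reference <- if (is.character(cfg$reference)) {
      read_xyz(cfg$reference)$frames[[1L]]
    } else cfg$reference
    reference_modes <- normal_modes_a0(hessian, reference,
                                       project_transrot = TRUE)
  }
  if (is.null(hessian) && !identical(cfg$strategy, "a1")) {
    stop("run_protocol(): config must name a hessian for strategy ", cfg$strategy)
  }
  if (is.null(calculator)) {
    if (is.null(cfg$calculator)) stop("run_protocol(): no calculator configured")
    calculator <- calculator_from_config(cfg$calculator)
  }

  # --- snapshot selection and clustering ----------------------------------
  snap <- cfg$snapshot
  frames <- select_snapshots(frames, stride = snap$stride,
                             shell_cutoff = snap$shell_cutoff,
                             target_atoms = snap$target_atoms)
  selection <- cfg$cluster$selection
  if (is.null(selection)) selection <- heavy_atom_selection(frames$frames[[1L]])
  rmsd <- rmsd_matrix(frames, selection = selection)
  assignment <- cluster_frames(rmsd, cutoff = cfg$cluster$cutoff)

  # --- per-representative spectra -----------------------------------------
  grid <- seq(cfg$grid[1L], cfg$grid[2L], by = cfg$grid[3L])
  per_cluster <- list()
  spectra <- list()
  ok <- logical(length(assignment$representatives))
  log_lines <- character(0)
  for (ci in seq_along(assignment$representatives)) {
    rep_idx <- assignment$representatives[ci]
    frame <- frames$frames[[rep_idx]]
    res <- tryCatch({
      modes <- .modes_for_frame(cfg$strategy, hessian, frame, cfg,
                                reference, reference_modes)
      imag <- count_imaginary(modes)
      derivs <- suppressMessages(
        polarizability_derivatives(calculator, frame, modes,
                                   incident_ev = cfg$incident_ev,
                                   damping_cm = cfg$damping_cm,
                                   step = cfg$step))
      sticks <- stick_spectrum(derivs)
      spec <- convolve_lorentzian(sticks, grid = grid, hwhm_cm = cfg$hwhm_cm,
                                  metadata = list(
                                    incident_ev = cfg$incident_ev,
                                    damping_cm = cfg$damping_cm,
                                    strategy = cfg$strategy,
                                    cluster = ci, frame = rep_idx))
      list(modes = modes, imaginary = imag, sticks = sticks, spectrum = spec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines, sprintf("SKIP cluster %d (frame %d): %s",
                                        ci, rep_idx, conditionMessage(res)))
      next
    }
    ok[ci] <- TRUE
    per_cluster[[ci]] <- res
    spectra[[ci]] <- res$spectrum
  }
  if (sum(ok) < length(ok) / 2) {
    stop("run_protocol(): more than half of the representatives failed:\n",
         paste(log_lines, collapse = "\n"))
  }
  weights <- assignment$persistence[ok]
  avg <- average_spectra(spectra[ok], weights = weights / sum(weights),
                         normalize = isTRUE(cfg$normalize))
  avg$metadata <- utils::modifyList(avg$metadata, list(
    incident_ev = cfg$incident_ev, damping_cm = cfg$damping_cm,
    hwhm_cm = cfg$hwhm_cm, strategy = cfg$strategy, step = cfg$step))

  # --- outputs ------------------------------------------------------------
  write_spectrum(avg, file.path(out_dir, "spectrum.tsv"))
  cl_tab <- data.frame(frame = seq_along(assignment$labels),
                       cluster = assignment$labels,
                       is_representative = seq_along(assignment$labels) %in%
                         assignment$representatives)
  utils::write.table(cl_tab, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  imag_tab <- do.call(rbind, lapply(which(ok), function(ci) {
    data.frame(cluster = ci,
               representative = assignment$representatives[ci],
               n_imaginary = per_cluster[[ci]]$imaginary$n_imaginary,
               indices = paste(per_cluster[[ci]]$imaginary$indices,
                               collapse = ","))
  }))
  utils::write.table(imag_tab, file.path(out_dir, "imaginary_modes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ci in which(ok)) {
    utils::write.table(per_cluster[[ci]]$sticks,
                       file.path(out_dir, sprintf("sticks_cluster%02d.tsv", ci)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("resoraman")),
    strategy = cfg$strategy, incident_ev = cfg$incident_ev,
    damping_cm = cfg$damping_cm, step = cfg$step, hwhm_cm = cfg$hwhm_cm,
    grid = cfg$grid, cluster_cutoff = cfg$cluster$cutoff,
    snapshot = cfg$snapshot[c("stride", "shell_cutoff")],
    seed = cfg$seed, n_frames = length(frames$frames),
    n_clusters = length(assignment$representatives),
    persistence = assignment$persistence,
    skipped = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(log_lines)) {
    writeLines(log_lines, file.path(out_dir, "skipped.log"))
  }
  invisible(list(spectrum = avg, assignment = assignment,
                 per_cluster = per_cluster, out_dir = out_dir))
}

#' Write a self-contained toy fixture for the pipeline
#'
#' Generates a seeded harmonic toy molecule, a synthetic trajectory, the
#' plain-text Hessian, a reference XYZ and a ready-to-run YAML config using
#' the built-in pole calculator whose excitation energy is linear in the
#' first bond length. `recipe = "small"` is a 4-atom molecule with 20 frames;
#' `"medium"` is 6 atoms with 60 frames.
#'
#' @param dir Output directory.
#' @param recipe `"small"` or `"medium"`.
#' @param seed Integer seed.
#' @return Path to the written config file, invisibly.
#' @export
write_toy_fixture <- function(dir, recipe = c("small", "medium"), seed = 42L) {
  recipe <- match.arg(recipe)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- if (recipe == "small") 4L else 6L
  nf <- if (recipe == "small") 20L else 60L
  freqs <- seq(600, 1800, length.out = 3L * n - 6L)
  toy <- make_harmonic_molecule(n, freqs, seed = seed)
  traj <- make_synthetic_trajectory(toy$structure, toy$modes,
                                    temperature_k = 150, n_frames = nf,
                                    seed = seed + 1L)
  write_xyz(traj, file.path(dir, "frames.xyz"))
  write_xyz(toy$structure, file.path(dir, "reference.xyz"))
  write_hessian(toy$hessian, file.path(dir, "hessian.txt"))
  r12 <- sqrt(sum((toy$structure$coords[1L, ] - toy$structure$coords[2L, ])^2))
  cfg <- list(
    frames = "frames.xyz", hessian = "hessian.txt",
    reference = "reference.xyz", strategy = "a0",
    incident_ev = 2.49, damping_cm = 500, step = 0.001, hwhm_cm = 10,
    grid = c(500, 2000, 0.5), seed = seed,
    cluster = list(cutoff = 1.0),
    snapshot = list(stride = 1L, shell_cutoff = "Inf"),
    calculator = list(type = "pole", e0_ev = 2.49, slope_ev_per_a = 2.0,
                      bond = c(1L, 2L), r_ref_a = r12,
                      dipole = c(1.0, 0.2, 0.1)))
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
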