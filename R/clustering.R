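# Trajectory clustering: pairwise-RMSD matrix, greedy neighbor-count
# (GROMOS/Daura) clustering into structural families, representative frames
# and persistence weights, plus snapshot decimation with a solvent-shell cut.

#' Pairwise minimized-RMSD matrix of a trajectory
#'
#' Entry (i, j) is the RMSD between frames i and j restricted to `selection`,
#' minimized over rigid superposition when `superpose_first` is on. Hydrogens
#' are commonly excluded via the selection (see [heavy_atom_selection()]).
#'
#' @param frames A `frame_set` (not ragged).
#' @param selection Integer atom indices entering the RMSD (nonempty).
#' @param superpose_first Minimize over rigid superposition first
#'   (default `TRUE`).
#' @return Symmetric numeric matrix (angstrom) with zero diagonal.
#' @export
rmsd_matrix <- function(frames, selection = heavy_atom_selection(frames$frames[[1L]]),
                        superpose_first = TRUE) {
  if (frames$ragged) stop("rmsd_matrix(): frames must share one atom ordering")
  selection <- as.integer(selection)
  if (!length(selection)) stop("rmsd_matrix(): empty atom selection")
  sub <- lapply(frames$frames, function(f) {
    molecular_structure(f$labels[selection],
                        f$coords[selection, , drop = FALSE],
                        f$masses[selection])
  })
  nf <- length(sub)
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      r <- if (superpose_first) superpose(sub[[j]], sub[[i]])$rmsd_after
           else sqrt(mean(rowSums((sub[[i]]$coords - sub[[j]]$coords)^2)))
      M[i, j] <- M[j, i] <- r
    }
  }
  M
}

#' Heavy-atom (non-hydrogen) selection of a structure
#'
#' @param structure A `molecular_structure`.
#' @return Integer indices of atoms that are not H or D.
#' @export
heavy_atom_selection <- function(structure) {
  which(!structure$labels %in% c("H", "D"))
}

#' Greedy neighbor-count clustering of frames (GROMOS/Daura)
#'
#' Iteratively takes the frame with the most neighbors within `cutoff` as the
#' representative of a new structural family, removes it and its neighbors,
#' and repeats until every frame is assigned. Ties are broken by the lowest
#' frame index, making the assignment deterministic. The persistence of a
#' cluster -- the fraction of trajectory frames it absorbs -- is the weight
#' later used when averaging per-representative spectra.
#'
#' @param rmsd Square symmetric nonnegative RMSD matrix (angstrom).
#' @param cutoff Neighbor cutoff in angstrom (> 0; default 1.0).
#' @return Object of class `cluster_assignment`: `labels` (cluster id per
#'   frame, 1-based in discovery order), `representatives` (frame index per
#'   cluster) and `persistence` (fractions summing to 1).
#' @export
cluster_frames <- function(rmsd, cutoff = 1.0) {
  if (!is.matrix(rmsd) || nrow(rmsd) != ncol(rmsd)) {
    stop("cluster_frames(): rmsd must be a square matrix")
  }
  if (cutoff <= 0) stop("cluster_frames(): cutoff must be positive")
  if (max(abs(rmsd - t(rmsd))) > 1e-9 * max(1, max(abs(rmsd)))) {
    stop("cluster_frames(): rmsd matrix must be symmetric")
  }
  nf <- nrow(rmsd)
  labels <- integer(nf)
  reps <- integer(0)
  remaining <- seq_len(nf)
  cl <- 0L
  while (length(remaining)) {
    sub <- rmsd[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)     # includes self
    best <- remaining[which.max(counts)] # which.max takes the first maximum
    members <- remaining[sub[match(best, remaining), ] <= cutoff]
    cl <- cl + 1L
    labels[members] <- cl
    reps <- c(reps, best)
    remaining <- setdiff(remaining, members)
  }
  persistence <- as.numeric(tabulate(labels, nbins = cl)) / nf
  structure(list(labels = labels, representatives = reps,
                 persistence = persistence),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters over %d frames; persistence %s\n",
              length(x$representatives), length(x$labels),
              paste(sprintf("%.2f", x$persistence), collapse = " ")))
  invisible(x)
}

#' Decimate a trajectory and cut the environment to a solvent shell
#'
#' Keeps every `stride`-th frame (in ps when timestamps are present and
#' `stride_unit = "ps"`, else in frame counts), then removes, per kept frame,
#' every environment residue whose atoms all lie farther than `shell_cutoff`
#' from every target atom. The cut is residue-level: a residue is kept when
#' ANY of its atoms is within the cutoff of ANY target atom, so molecules are
#' never broken. Frames may end up with different residue sets, so the result
#' is a ragged `frame_set` unless the cutoff is infinite.
#'
#' @param frames A `frame_set`.
#' @param stride Positive decimation stride.
#' @param shell_cutoff Shell cutoff in angstrom (default `Inf`: keep all).
#' @param target_atoms Atom indices of the solute/target (default: all atoms,
#'   which makes the shell cut a no-op).
#' @param stride_unit `"frames"` or `"ps"`.
#' @return A `frame_set` (ragged if the shell cut removed atoms).
#' @export
select_snapshots <- function(frames, stride = 1, shell_cutoff = Inf,
                             target_atoms = NULL,
                             stride_unit = c("frames", "ps")) {
  stride_unit <- match.arg(stride_unit)
  if (stride <= 0) stop("select_snapshots(): stride must be positive")
  if (stride_unit == "ps") {
    if (is.null(frames$timestamps)) {
      stop("select_snapshots(): stride in ps requires timestamps")
    }
    t0 <- frames$timestamps[1L]
    # pick the frame nearest each stride multiple of the elapsed time
    targets <- seq(t0, max(frames$timestamps), by = stride)
    keep_idx <- unique(vapply(targets, function(tt) {
      which.min(abs(frames$timestamps - tt))
    }, integer(1)))
  } else {
    keep_idx <- seq(1L, length(frames$frames), by = as.integer(stride))
  }
  kept <- frames$frames[keep_idx]
  ts <- if (!is.null(frames$timestamps)) frames$timestamps[keep_idx]
  if (!is.finite(shell_cutoff)) {
    return(frame_set(kept, timestamps = ts, ragged = frames$ragged))
  }
  cut <- lapply(kept, function(f) {
    tgt <- if (is.null(target_atoms)) seq_len(n_atoms(f)) else target_atoms
    tc <- f$coords[tgt, , drop = FALSE]
    # per-atom min distance to any target atom
    d2 <- vapply(seq_len(n_atoms(f)), function(a) {
      min(colSums((t(tc) - f$coords[a, ])^2))
    }, numeric(1))
    keep_res <- unique(f$resid[sqrt(d2) <= shell_cutoff | seq_len(n_atoms(f)) %in% tgt])
    keep_atom <- f$resid %in% keep_res
    molecular_structure(f$labels[keep_atom],
                        f$coords[keep_atom, , drop = FALSE],
                        f$masses[keep_atom],
                        resid = f$resid[keep_atom])
  })
  counts <- vapply(cut, n_atoms, integer(1))
  same <- length(unique(counts)) == 1L &&
    all(vapply(cut, function(f) identical(f$labels, cut[[1L]]$labels),
               logical(1)))
  frame_set(cut, timestamps = ts, ragged = !same)
}
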