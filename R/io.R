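# Readers and writers: multi-frame XYZ, a plain-text Hessian format, and
# two-column TSV spectra with "#" metadata headers.

#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `symbol x y z` line per atom; frames are concatenated. Masses are filled
#' from the bundled standard-atomic-weight table.
#'
#' @param path Path to the XYZ file.
#' @return A `frame_set` with all frames in file order.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  # drop trailing blank lines only; blanks inside the file are format errors
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L) {
      stop(sprintf("read_xyz(): malformed atom count on line %d: '%s'",
                   i, lines[i]))
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("read_xyz(): truncated frame starting at line %d", i))
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(tok) < 4L)
    if (length(bad)) {
      stop(sprintf("read_xyz(): malformed atom line %d", i + 1L + bad[1L]))
    }
    labels <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      stop(sprintf("read_xyz(): non-numeric coordinates in frame at line %d", i))
    }
    frames[[length(frames) + 1L]] <- molecular_structure(labels, xyz)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("read_xyz(): no frames found in ", path)
  frame_set(frames)
}

#' Write structures to a (multi-frame) XYZ file
#'
#' @param x A `molecular_structure` or `frame_set`.
#' @param path Output path.
#' @param comment Comment line(s), recycled over frames.
#' @param digits Coordinate decimals (default 8).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "", digits = 8L) {
  if (inherits(x, "molecular_structure")) x <- frame_set(list(x))
  comment <- rep_len(comment, length(x$frames))
  fmt <- sprintf("%%-3s %% .%df %% .%df %% .%df", digits, digits, digits)
  out <- unlist(lapply(seq_along(x$frames), function(k) {
    f <- x$frames[[k]]
    c(as.character(nrow(f$coords)), comment[k],
      sprintf(fmt, f$labels, f$coords[, 1], f$coords[, 2], f$coords[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a plain-text Hessian file
#'
#' Format: one header line `hessian <N> <unit-tag>`, then 3N rows of 3N
#' whitespace-separated numbers (Hartree/bohr^2). The matrix is symmetrized on
#' construction; see [hessian_matrix()] for the asymmetry policy.
#'
#' @param path Path to the Hessian file.
#' @param atom_count Expected atom count N; checked against the header.
#' @return A `hessian_matrix`.
#' @export
read_hessian <- function(path, atom_count = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_hessian(): empty file ", path)
  head_tok <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(head_tok) < 2L || head_tok[1L] != "hessian") {
    stop("read_hessian(): first line must be 'hessian <N> <unit-tag>'")
  }
  n <- suppressWarnings(as.integer(head_tok[2L]))
  if (is.na(n) || n <= 0L) stop("read_hessian(): bad atom count in header")
  if (!is.null(atom_count) && n != atom_count) {
    stop(sprintf("read_hessian(): expected %d atoms, file declares %d",
                 atom_count, n))
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != 3L * n) {
    stop(sprintf("read_hessian(): expected %d matrix rows, found %d",
                 3L * n, length(body)))
  }
  vals <- lapply(strsplit(trimws(body), "[[:space:]]+"), as.numeric)
  if (any(lengths(vals) != 3L * n) || anyNA(unlist(vals))) {
    stop(sprintf("read_hessian(): expected %d numeric entries per row", 3L * n))
  }
  hessian_matrix(do.call(rbind, vals), atom_count = n)
}

#' Write a Hessian to the plain-text format
#'
#' @param hessian A `hessian_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hessian <- function(hessian, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("hessian %d hartree_bohr2", hessian$atom_count), con)
  utils::write.table(format(hessian$matrix, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a spectrum as two-column TSV
#'
#' Wavenumber (cm-1) and intensity columns preceded by `#`-prefixed metadata
#' header lines recording the provenance of the spectrum.
#'
#' @param spectrum A `raman_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  md <- spectrum$metadata
  hdr <- c("# resoraman spectrum",
           sprintf("# %s\t%s", names(md),
                   vapply(md, function(v) paste(format(v, digits = 12),
                                                collapse = ","),
                          character(1))),
           "# wavenumber_cm\tintensity")
  body <- sprintf("%.6f\t%.12g", spectrum$grid, spectrum$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a spectrum TSV written by [write_spectrum()]
#'
#' @param path Path to the spectrum file.
#' @return A `raman_spectrum` (metadata restored as character).
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  grid <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  intensity <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
  md <- list()
  for (ml in meta_lines) {
    tok <- strsplit(sub("^#\\s*", "", ml), "\t", fixed = TRUE)[[1L]]
    if (length(tok) == 2L) md[[tok[1L]]] <- tok[2L]
  }
  raman_spectrum(grid, intensity, metadata = md)
}
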