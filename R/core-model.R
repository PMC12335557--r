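# Structure/trajectory data model shared by all analysis stages.
#
# An atom_frame is one configuration: an n x 3 coordinate matrix (angstrom)
# plus per-atom metadata (name, resname, resid, segid, element, vdw radius)
# and an optional orthorhombic box. A frame_series stacks frames of constant
# topology with strictly increasing times (ns). Periodic images are never
# unwrapped: counting regions are assumed to lie well inside the box.

# ---- van der Waals radius tables ------------------------------------------

# Bondi-type element radii (angstrom). Elements missing from the table get
# `default_radius` and a warning.
.vdw_tables <- list(
  bondi = c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
    CL = 1.75, BR = 1.85, I = 1.98, K = 2.75, "NA" = 2.27, MG = 1.73,
    CA = 2.31, ZN = 1.39
  )
)

#' Look up van der Waals radii for elements
#'
#' @param elements character vector of element symbols.
#' @param table name of a bundled radius table (currently `"bondi"`).
#' @param default_radius radius (angstrom) assigned to elements missing from
#'   the table; a warning reports which elements fell back.
#' @return numeric vector of radii in angstrom.
#' @export
vdw_radii <- function(elements, table = "bondi", default_radius = 1.7) {
  tab <- .vdw_tables[[table]]
  if (is.null(tab)) stop("unknown vdW radius table: ", table)
  r <- unname(tab[toupper(elements)])
  missing <- is.na(r)
  if (any(missing)) {
    warning(
      "no vdW radius for element(s) ",
      paste(unique(elements[missing]), collapse = ", "),
      "; using default ", default_radius, " A"
    )
    r[missing] <- default_radius
  }
  r
}

infer_elements <- function(names, elesy = NULL) {
  el <- rep(NA_character_, length(names))
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- !is.na(e) & nzchar(e)
    el[ok] <- e[ok]
  }
  todo <- is.na(el) | !nzchar(el)
  if (any(todo)) {
    stripped <- toupper(gsub("[^A-Za-z]", "", names[todo]))
    two <- substr(stripped, 1, 2)
    one <- substr(stripped, 1, 1)
    # two-letter symbols only when they are real table entries (CL, BR, ...)
    known2 <- two %in% names(.vdw_tables$bondi) & !(two %in% c("CA", "NA"))
    el[todo] <- ifelse(known2, two, one)
  }
  el
}

# ---- atom_frame ------------------------------------------------------------

#' Construct an atom frame
#'
#' @param xyz n x 3 numeric matrix of coordinates (angstrom).
#' @param atoms data frame with columns `name`, `resname`, `resid`, `segid`,
#'   `element`, `vdw` (one row per atom). Missing columns are filled with
#'   defaults; `vdw` is looked up from `radius_table` when absent.
#' @param box optional length-3 orthorhombic box (angstrom).
#' @param radius_table vdW table used to fill a missing `vdw` column.
#' @return object of class `atom_frame`.
#' @export
atom_frame <- function(xyz, atoms, box = NULL, radius_table = "bondi") {
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom_frame")
  n <- nrow(xyz)
  if (n == 0L) stop("empty structure: no atoms")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) != n) stop("atom metadata rows (", nrow(atoms),
                             ") do not match coordinate rows (", n, ")")
  if (is.null(atoms$name)) atoms$name <- rep("X", n)
  if (is.null(atoms$resname)) atoms$resname <- rep("UNK", n)
  if (is.null(atoms$resid)) atoms$resid <- seq_len(n)
  if (is.null(atoms$segid)) atoms$segid <- rep("", n)
  if (is.null(atoms$element)) atoms$element <- infer_elements(atoms$name)
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radii(atoms$element, radius_table)
  if (any(!is.finite(atoms$vdw)) || any(atoms$vdw <= 0)) {
    stop("vdW radii must be positive and finite")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be 3 positive lengths (angstrom)")
    }
  }
  structure(list(xyz = xyz, atoms = atoms, box = box), class = "atom_frame")
}

#' @export
print.atom_frame <- function(x, ...) {
  cat("atom_frame:", nrow(x$xyz), "atoms,",
      length(unique(paste(x$atoms$segid, x$atoms$resid))), "residues",
      if (!is.null(x$box)) sprintf("; box %.1f x %.1f x %.1f A",
                                   x$box[1], x$box[2], x$box[3]) else "",
      "\n")
  invisible(x)
}

#' Number of atoms in a frame or series
#' @param x an `atom_frame` or `frame_series`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "atom_frame")) nrow(x$xyz)
  else if (inherits(x, "frame_series")) dim(x$xyz)[1]
  else stop("n_atoms: unsupported object")
}

# ---- frame_series ----------------------------------------------------------

#' Construct a frame series (trajectory of constant topology)
#'
#' @param topology an `atom_frame` providing the shared metadata.
#' @param xyz array of dim (n_atoms, 3, n_frames), or a list of n x 3 matrices.
#' @param times frame times in ns, strictly increasing.
#' @return object of class `frame_series`.
#' @export
frame_series <- function(topology, xyz, times) {
  stopifnot(inherits(topology, "atom_frame"))
  if (is.list(xyz)) {
    xyz <- array(unlist(xyz), dim = c(nrow(xyz[[1]]), 3, length(xyz)))
  }
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L) {
    stop("xyz must be an (n_atoms, 3, n_frames) array")
  }
  if (dim(xyz)[1] != n_atoms(topology)) {
    stop("trajectory atom count (", dim(xyz)[1],
         ") does not match topology (", n_atoms(topology), ")")
  }
  nf <- dim(xyz)[3]
  times <- as.numeric(times)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(atoms = topology$atoms, xyz = xyz, times = times,
                 box = topology$box), class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat("frame_series:", dim(x$xyz)[3], "frames x", dim(x$xyz)[1], "atoms,",
      sprintf("t = %.3f..%.3f ns\n", min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a series
#' @param series a `frame_series`.
#' @return integer frame count.
#' @export
n_frames <- function(series) dim(series$xyz)[3]

#' Extract one frame of a series as an `atom_frame`
#' @param series a `frame_series`.
#' @param i frame index (1-based).
#' @return an `atom_frame`.
#' @export
get_frame <- function(series, i) {
  if (i < 1 || i > n_frames(series)) stop("frame index out of range")
  structure(list(xyz = series$xyz[, , i, drop = TRUE], atoms = series$atoms,
                 box = series$box), class = "atom_frame")
}

# ---- readers ---------------------------------------------------------------

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file (", path, "): too short")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1L) stop("malformed GRO file (", path, "): bad atom count at line 2")
  if (length(lines) < 2L + n) stop("malformed GRO file (", path, "): truncated at line ",
                                   length(lines))
  al <- lines[3:(2 + n)]
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(al, 21, 28)); y <- num(substr(al, 29, 36)); z <- num(substr(al, 37, 44))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad)) stop("malformed GRO file (", path, "): bad coordinates at line ",
                        bad[1] + 2L)
  atoms <- data.frame(
    name = trimws(substr(al, 11, 15)),
    resname = trimws(substr(al, 6, 10)),
    resid = as.integer(trimws(substr(al, 1, 5))),
    segid = "",
    stringsAsFactors = FALSE
  )
  boxv <- num(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  box <- if (length(boxv) >= 3 && all(is.finite(boxv[1:3])) && all(boxv[1:3] > 0)) {
    boxv[1:3] * 10
  } else NULL
  list(xyz = cbind(x, y, z) * 10, atoms = atoms, box = box) # nm -> angstrom
}

#' Read a structure file (PDB or GRO) into an `atom_frame`
#'
#' PDB files are parsed with \pkg{bio3d}; GRO files with a bundled fixed-width
#' reader (coordinates converted from nm to angstrom). vdW radii are assigned
#' per element from `radius_table`; unknown elements fall back to
#' `default_radius` with a warning.
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @param radius_table name of the element radius table (see [vdw_radii()]).
#' @param default_radius fallback radius in angstrom for unknown elements.
#' @return an `atom_frame`.
#' @export
load_structure <- function(path, radius_table = "bondi", default_radius = 1.7) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    g <- read_gro(path)
    g$atoms$element <- infer_elements(g$atoms$name)
    g$atoms$vdw <- vdw_radii(g$atoms$element, radius_table, default_radius)
    return(atom_frame(g$xyz, g$atoms, box = g$box))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(pdb$atom) == 0L) stop("empty structure: ", path)
  a <- pdb$atom
  atoms <- data.frame(
    name = a$elety, resname = a$resid, resid = a$resno,
    segid = ifelse(is.na(a$segid) | !nzchar(a$segid),
                   ifelse(is.na(a$chain), "", a$chain), a$segid),
    stringsAsFactors = FALSE
  )
  atoms$element <- infer_elements(atoms$name, a$elesy)
  atoms$vdw <- vdw_radii(atoms$element, radius_table, default_radius)
  atom_frame(cbind(a$x, a$y, a$z), atoms)
}

#' Read a trajectory (multi-model PDB or DCD) into a `frame_series`
#'
#' Times are synthesized as `(model_index - 1) * dt` (ns) unless `times` is
#' given; the default `dt` of 0.02 ns corresponds to frames saved every 20 ps.
#'
#' @param structure the `atom_frame` topology the trajectory belongs to.
#' @param path path to a multi-model `.pdb` or a `.dcd` file.
#' @param stride keep every `stride`-th frame (default 1).
#' @param dt frame spacing in ns used to synthesize times.
#' @param times optional explicit times (ns) for all frames before striding.
#' @return a `frame_series`.
#' @export
load_trajectory <- function(structure, path, stride = 1L, dt = 0.02,
                            times = NULL) {
  stopifnot(inherits(structure, "atom_frame"))
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be a positive integer")
  ext <- tolower(tools::file_ext(path))
  xyz <- if (ext == "dcd") {
    bio3d::read.dcd(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)$xyz
  }
  xyz <- as.matrix(xyz)
  n <- n_atoms(structure)
  if (ncol(xyz) != 3L * n) {
    stop("trajectory atom count (", ncol(xyz) / 3,
         ") does not match structure (", n, ")")
  }
  nf <- nrow(xyz)
  if (nf == 0L) stop("trajectory contains no frames")
  keep <- seq(1L, nf, by = stride)
  if (length(keep) == 0L) stop("zero frames after applying stride ", stride)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf) stop("times length must equal raw frame count")
  arr <- array(NA_real_, dim = c(n, 3, length(keep)))
  for (j in seq_along(keep)) {
    arr[, , j] <- matrix(xyz[keep[j], ], ncol = 3, byrow = TRUE)
  }
  frame_series(structure, arr, times[keep])
}

# ---- writers ---------------------------------------------------------------

pdb_atom_lines <- function(atoms, xyz) {
  nm <- atoms$name
  # standard PDB convention: names shorter than 4 characters start in col 14
  nm <- ifelse(nchar(nm) < 4L, paste0(" ", nm), nm)
  sprintf(
    "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
    seq_len(nrow(xyz)) %% 100000L, nm, atoms$resname,
    atoms$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
    atoms$segid, atoms$element
  )
}

#' Write an `atom_frame` or `frame_series` as (multi-model) PDB
#'
#' Fixed-width ATOM records (names, residue names/numbers, segids, element
#' symbols) with one MODEL/ENDMDL block per frame for a series.
#'
#' @param x an `atom_frame` or `frame_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "atom_frame")) {
    writeLines(pdb_atom_lines(x$atoms, x$xyz), con)
  } else if (inherits(x, "frame_series")) {
    for (f in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(pdb_atom_lines(x$atoms, x$xyz[, , f, drop = TRUE]), con)
      writeLines("ENDMDL", con)
    }
  } else stop("write_pdb_frames: unsupported object")
  writeLines("END", con)
  invisible(path)
}

# ---- geometry helpers ------------------------------------------------------

#' Coordinates of a selection within a frame
#' @param frame an `atom_frame`.
#' @param selection an `atom_selection`, integer indices, or `NULL` (all atoms).
#' @return m x 3 coordinate matrix.
#' @export
coords <- function(frame, selection = NULL) {
  idx <- as_indices(selection, frame)
  frame$xyz[idx, , drop = FALSE]
}

#' Unweighted center of mass (centroid) of a selection
#' @inheritParams coords
#' @return length-3 numeric vector.
#' @export
com <- function(frame, selection = NULL) colMeans(coords(frame, selection))

#' Apply a rigid transform to a frame
#' @param frame an `atom_frame`.
#' @param R 3x3 rotation matrix (default identity).
#' @param shift length-3 translation (angstrom).
#' @return transformed `atom_frame` (box dropped: an orthorhombic box does not
#'   survive a general rotation).
#' @export
transform_frame <- function(frame, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- frame$xyz %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  structure(list(xyz = xyz, atoms = frame$atoms, box = NULL),
            class = "atom_frame")
}
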