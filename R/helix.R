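# Helix-axis estimation and pore-lining (S6) helix tilt distributions.
#
# The helix axis is the dominant principal direction of the centered C-alpha
# point set (SVD), oriented from the first toward the last residue; for a
# regular alpha-helix this agrees with local-axis averaging schemes to within
# about a degree. The pore-lining helix of interest carries a documented kink,
# so the axis can be computed over a residue sub-window.

#' Principal axis of an ordered C-alpha trace
#'
#' @param ca_coords n x 3 matrix of C-alpha coordinates in sequence order
#'   (n >= 6).
#' @return unit vector (length 3) pointing from the first toward the last
#'   residue.
#' @export
helix_axis <- function(ca_coords) {
  X <- as.matrix(ca_coords)
  if (nrow(X) < 6L) stop("helix_axis needs at least 6 C-alpha positions")
  Xc <- sweep(X, 2, colMeans(X), "-")
  if (max(abs(Xc)) < 1e-12) stop("degenerate helix: zero spatial extent")
  v <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  s <- sum(v * (X[nrow(X), ] - X[1, ]))
  if (s < 0) v <- -v
  unitize(v)
}

#' Tilt angle between a helix axis and the membrane normal
#'
#' `theta = acos(|axis . vertical|)` in degrees, in `[0, 90]`; the absolute
#' dot product makes the angle invariant under axis sign flips.
#'
#' @param axis helix axis vector.
#' @param vertical membrane-normal ("vertical") vector, default `c(0, 0, 1)`.
#' @return tilt angle in degrees.
#' @export
tilt_angle <- function(axis, vertical = c(0, 0, 1)) {
  if (abs(vnorm(axis) - 1) > 1e-6) {
    warning("axis is not a unit vector; normalizing")
    axis <- unitize(axis)
  }
  if (abs(vnorm(vertical) - 1) > 1e-6) {
    warning("vertical is not a unit vector; normalizing")
    vertical <- unitize(vertical)
  }
  acos(min(1, abs(sum(axis * vertical)))) * 180 / pi
}

#' Pooled per-frame, per-subunit helix tilt distribution
#'
#' @param series a `frame_series`.
#' @param s6_selections list of per-subunit C-alpha selections (each >= 6
#'   atoms, in residue order).
#' @param vertical membrane-normal vector.
#' @param residue_window optional integer range `c(first, last)` of positions
#'   within each selection over which to fit the axis (e.g. the segment below
#'   a kink); default uses the full selection.
#' @param bw kernel bandwidth rule for the pooled KDE (default Scott's rule).
#' @return object of class `tilt_distribution`: list with `angles` (data
#'   frame: `frame`, `subunit`, `theta_deg`) and `kde` (a [stats::density()]
#'   object, or NULL if the pooled angles are constant). Bimodal distributions
#'   are representable; no unimodality is assumed.
#' @export
tilt_distribution <- function(series, s6_selections, vertical = c(0, 0, 1),
                              residue_window = NULL, bw = "nrd") {
  stopifnot(inherits(series, "frame_series"))
  if (length(s6_selections) < 1L) stop("need at least one subunit selection")
  top <- get_frame(series, 1L)
  idxs <- lapply(s6_selections, as_indices, frame = top)
  for (ix in idxs) {
    n <- length(ix)
    if (!is.null(residue_window)) {
      n <- length(seq(max(1L, residue_window[1]), min(n, residue_window[2])))
    }
    if (n < 6L) stop("each subunit selection needs >= 6 residues (after windowing)")
  }
  vertical <- unitize(vertical)
  rows <- list()
  for (f in seq_len(n_frames(series))) {
    fr <- get_frame(series, f)
    for (s in seq_along(idxs)) {
      ix <- idxs[[s]]
      if (!is.null(residue_window)) {
        ix <- ix[seq(max(1L, residue_window[1]),
                     min(length(ix), residue_window[2]))]
      }
      th <- tilt_angle(helix_axis(fr$xyz[ix, , drop = FALSE]), vertical)
      rows[[length(rows) + 1L]] <- data.frame(frame = f, subunit = s,
                                              theta_deg = th)
    }
  }
  angles <- do.call(rbind, rows)
  kde <- if (stats::sd(angles$theta_deg) > 1e-8) {
    stats::density(angles$theta_deg, bw = bw)
  } else NULL
  structure(list(angles = angles, kde = kde), class = "tilt_distribution")
}

#' @export
print.tilt_distribution <- function(x, ...) {
  cat("tilt_distribution:", nrow(x$angles), "angles,",
      sprintf("mean %.1f deg, range [%.1f, %.1f]\n",
              mean(x$angles$theta_deg), min(x$angles$theta_deg),
              max(x$angles$theta_deg)))
  invisible(x)
}

#' Local maxima of a tilt (or any) kernel density estimate
#' @param kde a [stats::density()] object.
#' @return data frame with `x` (mode locations) and `y` (density values).
#' @export
density_modes <- function(kde) {
  y <- kde$y
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  data.frame(x = kde$x[i], y = y[i])
}
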