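# Pore axis construction and inscribed-sphere radius profiling.
#
# The axial coordinate z is 0 at the selectivity-filter (SF) center of mass
# and negative toward the cytosolic side. The pore radius at a slice is the
# largest clearance max_c min_i (|c - x_i| - vdw_i) over in-plane centers c,
# found by a deterministic coarse-to-fine grid search plus Nelder-Mead
# refinement (replacing stochastic simulated annealing for reproducibility).

#' Construct a pore axis from origin and direction
#' @param origin length-3 point (angstrom), conventionally the SF COM.
#' @param direction direction vector (normalized internally).
#' @return object of class `pore_axis`.
#' @export
pore_axis_from <- function(origin, direction) {
  structure(list(origin = as.numeric(origin), direction = unitize(direction)),
            class = "pore_axis")
}

#' Estimate the pore axis from a selectivity-filter selection
#'
#' The origin is the unweighted COM of `sf_selection`; the direction is the
#' dominant principal axis of the centered SF ring stack. The sign is fixed so
#' that positive z points away from the cytosolic side: when `reference` is
#' given (conventionally a pore-helix selection on the cytosolic side), the
#' direction points from the reference COM toward the SF COM; otherwise the
#' direction is chosen with a non-negative laboratory-z component.
#'
#' @param frame an `atom_frame`.
#' @param sf_selection selection defining the SF (>= 3 atoms).
#' @param reference optional selection fixing the axis sign.
#' @return a `pore_axis`.
#' @export
pore_axis <- function(frame, sf_selection, reference = NULL) {
  X <- coords(frame, sf_selection)
  if (nrow(X) < 3L) stop("pore_axis needs at least 3 SF atoms")
  origin <- colMeans(X)
  Xc <- sweep(X, 2, origin, "-")
  if (max(abs(Xc)) < 1e-9) stop("degenerate SF geometry: zero extent")
  v <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  if (!is.null(reference)) {
    ref_com <- com(frame, reference)
    s <- sum(v * (origin - ref_com))
    if (abs(s) < 1e-12) stop("reference selection does not break the axis sign")
    v <- v * sign(s)
  } else if (v[3] < 0) v <- -v
  pore_axis_from(origin, v)
}

# Orthonormal basis with e3 = axis direction. The in-plane pair (e1, e2) is a
# deterministic function of the direction only.
axis_basis <- function(axis) {
  e3 <- axis$direction
  a <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(a - sum(a * e3) * e3)
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cbind(e1, e2, e3)
}

# Coordinates in the axis-local frame: column 3 is the signed axial coordinate.
to_axis_frame <- function(xyz, axis) {
  sweep(rbind(xyz), 2, axis$origin, "-") %*% axis_basis(axis)
}

#' Deep-pore-volume cylinder below the selectivity filter
#'
#' Default geometry: radius 7 angstrom (0.7 nm), height 5 angstrom (0.5 nm),
#' top face 12 angstrom (1.2 nm) below the SF center of mass.
#'
#' @param axis a `pore_axis`.
#' @param radius cylinder radius (angstrom).
#' @param z_top axial coordinate of the top face (angstrom; negative =
#'   cytosolic side of the SF COM).
#' @param height cylinder height (angstrom); the bottom face sits at
#'   `z_top - height`.
#' @return a `cylinder_region`.
#' @export
dpv_region <- function(axis, radius = 7, z_top = -12, height = 5) {
  cylinder_region(axis, radius = radius, z_top = z_top,
                  z_bottom = z_top - height)
}

# Clearance field for one slice: for candidate in-plane centers (cx, cy) at
# axial coordinate z, the distance to the nearest atom *sphere* using the full
# 3D point-to-sphere distance. `lx`: atoms in axis-local coordinates.
slice_clearance <- function(cx, cy, z, lx, vdw, cap) {
  m <- length(cx)
  best <- rep(cap, m)
  # chunk candidate points to bound the m x n distance matrix
  chunk <- max(1L, floor(5e6 / max(1L, nrow(lx))))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(m, s + chunk - 1L)
    dx <- outer(cx[s:e], lx[, 1], "-")
    dy <- outer(cy[s:e], lx[, 2], "-")
    dz2 <- (z - lx[, 3])^2
    d <- sqrt(sweep(dx^2 + dy^2, 2, dz2, "+"))
    d <- sweep(d, 2, vdw, "-")
    best[s:e] <- pmin(cap, apply(d, 1, min))
  }
  best
}

disc_grid <- function(spacing, radius, center = c(0, 0)) {
  g <- seq(-radius, radius, by = spacing)
  gx <- rep(g, times = length(g)) + center[1]
  gy <- rep(g, each = length(g)) + center[2]
  keep <- (gx^2 + gy^2) <= radius^2 + 1e-9
  cbind(gx[keep], gy[keep])
}

#' Inscribed-sphere pore radius profile
#'
#' For each z slice, the radius is the maximal clearance
#' `max_c min_i (|c - x_i| - vdw_i)` over in-plane centers `c` within
#' `search_radius` of the axis. Atoms with `|z_atom - z_slice| <= vdw + dz`
#' contribute via the full 3D point-to-sphere distance. The maximization is a
#' coarse (1 angstrom) then fine (`grid_spacing`) grid search seeded with the
#' previous slice's maximizer, followed by Nelder-Mead refinement. The search
#' disc is deliberately pore-sized: a wider disc would let the maximizer slip
#' through or around the channel wall into bulk. Radii are clamped to
#' `[0, cap]`; slices with no contributing atoms report the cap with
#' `flag = TRUE` ("no pore constriction here").
#'
#' @param frame an `atom_frame`.
#' @param axis a `pore_axis`.
#' @param z_range length-2 axial range (angstrom, relative to the axis origin).
#' @param dz slice spacing in angstrom (default 0.5).
#' @param include selection of atoms lining the pore (e.g. protein only, or
#'   protein + lipids); must be non-empty.
#' @param grid_spacing fine-grid spacing for the in-plane search (angstrom).
#' @param search_radius radius of the in-plane search disc around the pore
#'   axis (angstrom).
#' @param cap largest reported radius (angstrom).
#' @param refine logical: polish the grid maximizer with Nelder-Mead.
#' @param label free-text label describing the include set.
#' @return object of class `radius_profile`: data frame with columns `z`, `r`,
#'   `se` (NA for a single frame) and `flag`.
#' @export
radius_profile <- function(frame, axis, z_range, dz = 0.5, include = NULL,
                           grid_spacing = 0.2, search_radius = 5,
                           cap = 12, refine = TRUE, label = "") {
  if (dz <= 0) stop("dz must be positive")
  idx <- as_indices(include, frame)
  if (length(idx) == 0L) stop("include selection is empty")
  lx <- to_axis_frame(frame$xyz[idx, , drop = FALSE], axis)
  vdw <- frame$atoms$vdw[idx]
  zs <- seq(z_range[1], z_range[2], by = dz)
  r <- numeric(length(zs))
  flag <- logical(length(zs))
  seed <- c(0, 0)
  coarse <- disc_grid(max(1, grid_spacing), search_radius)
  for (j in seq_along(zs)) {
    z <- zs[j]
    in_slab <- abs(lx[, 3] - z) <= vdw + dz
    if (!any(in_slab)) {
      r[j] <- cap
      flag[j] <- TRUE
      next
    }
    ax <- lx[in_slab, , drop = FALSE]
    av <- vdw[in_slab]
    cand <- rbind(coarse, seed)
    cl <- slice_clearance(cand[, 1], cand[, 2], z, ax, av, cap)
    b <- cand[which.max(cl), ]
    fine <- disc_grid(grid_spacing, 1.5, center = b)
    keepf <- rowSums(fine^2) <= search_radius^2
    fine <- fine[keepf, , drop = FALSE]
    if (nrow(fine)) {
      clf <- slice_clearance(fine[, 1], fine[, 2], z, ax, av, cap)
      if (max(clf) > max(cl)) b <- fine[which.max(clf), ]
    }
    best <- max(max(cl), if (nrow(fine)) max(clf) else -Inf)
    if (refine) {
      obj <- function(p) {
        if (sum(p^2) > search_radius^2) return(1e6)
        -min(cap, min(sqrt((p[1] - ax[, 1])^2 + (p[2] - ax[, 2])^2 +
                             (z - ax[, 3])^2) - av))
      }
      opt <- stats::optim(b, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 800))
      if (-opt$value > best) {
        best <- -opt$value
        b <- opt$par
      }
    }
    r[j] <- min(cap, max(0, best))
    seed <- b
  }
  structure(
    data.frame(z = zs, r = r, se = NA_real_, flag = flag),
    class = c("radius_profile", "data.frame"),
    label = label, search_radius = search_radius, cap = cap
  )
}

#' Average radius profiles over frames with block-analysis errors
#'
#' @param profiles list of `radius_profile` objects sharing one z grid
#'   (one per frame, in time order).
#' @param block_length block size in frames for the block-average standard
#'   error (see [block_se()]); a trailing partial block is discarded.
#' @return a `radius_profile` with per-z mean radius and block standard error
#'   (NA with a warning when only one complete block is available).
#' @export
average_radius_profile <- function(profiles, block_length = 1L) {
  if (length(profiles) == 0L) stop("no profiles to average")
  z <- profiles[[1]]$z
  for (p in profiles) {
    if (length(p$z) != length(z) || max(abs(p$z - z)) > 1e-9) {
      stop("profiles do not share a z grid")
    }
  }
  R <- do.call(rbind, lapply(profiles, function(p) p$r))
  nf <- nrow(R)
  block_length <- as.integer(block_length)
  if (nf < block_length) stop("fewer frames (", nf, ") than one block (",
                              block_length, ")")
  nb <- nf %/% block_length
  se <- if (nb < 2L) {
    warning("only one complete block: standard errors are NA")
    rep(NA_real_, length(z))
  } else {
    vapply(seq_along(z), function(j) block_se(R[, j], block_length),
           numeric(1))
  }
  structure(
    data.frame(z = z, r = colMeans(R), se = se,
               flag = apply(do.call(rbind, lapply(profiles, function(p) p$flag)),
                            2, any)),
    class = c("radius_profile", "data.frame"),
    label = attr(profiles[[1]], "label"),
    search_radius = attr(profiles[[1]], "search_radius"),
    cap = attr(profiles[[1]], "cap"),
    n_frames = nf, block_length = block_length
  )
}

#' Write a radius profile as TSV
#'
#' Columns `z_A`, `radius_A`, `se_A`, `flag`; header comments record the
#' include-set label.
#'
#' @param profile a `radius_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_radius_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# radius profile; include = %s",
                     attr(profile, "label") %||% ""), con)
  writeLines("z_A\tradius_A\tse_A\tflag", con)
  utils::write.table(
    data.frame(z_A = profile$z, radius_A = profile$r, se_A = profile$se,
               flag = as.integer(profile$flag)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
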