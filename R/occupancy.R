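# Water/lipid occupancy of counting volumes, wet/dry statistics,
# selectivity-filter contact waters, the lipid-density collective variable,
# and annular-lipid contact analysis.
#
# Conventions: water is counted by its oxygen position (one site per
# molecule); "lipid carbon atoms" means acyl-tail carbons only, selected by an
# atom-name template per lipid type; regions are closed (boundaries inside).

#' Sharp count of selected atoms inside a region
#'
#' @param frame an `atom_frame`.
#' @param region a `cylinder_region`, `box_region` or `sphere_region`.
#' @param selection atoms to count; an empty selection yields 0.
#' @return integer count (boundary atoms count as inside).
#' @export
count_in_region <- function(frame, region, selection) {
  idx <- as_indices(selection, frame)
  if (length(idx) == 0L) return(0L)
  sum(region_contains(region, frame$xyz[idx, , drop = FALSE]))
}

#' Fermi-smoothed count in a box region
#'
#' The continuous counting variable restrained in restrained-MD sampling:
#' each atom contributes the product over box axes of Fermi factors
#' `1 / (1 + exp((|u_a| - L_a) / lambda))` with `u` the atom position in box
#' coordinates and `L_a` the half-lengths. With `fermi_lambda = 0` this equals
#' [count_in_region()] exactly.
#'
#' @param frame an `atom_frame`.
#' @param region a `box_region` carrying the smoothing parameter.
#' @param selection atoms to count.
#' @return real number in `[0, n_selected]`.
#' @export
smooth_count <- function(frame, region, selection) {
  stopifnot(inherits(region, "box_region"))
  idx <- as_indices(selection, frame)
  if (length(idx) == 0L) return(0)
  u <- abs(sweep(frame$xyz[idx, , drop = FALSE], 2, region$center, "-") %*%
             region$orientation)
  lam <- region$fermi_lambda
  w <- fermi_switch(u[, 1] - region$half_lengths[1], lam) *
    fermi_switch(u[, 2] - region$half_lengths[2], lam) *
    fermi_switch(u[, 3] - region$half_lengths[3], lam)
  sum(w)
}

#' Per-frame water and lipid-carbon counts in the deep pore volume
#'
#' The DPV cylinder is recomputed for every frame from that frame's
#' selectivity-filter selection, so the counting region tracks the protein.
#'
#' @param series a `frame_series`.
#' @param water selection (or expression) of water oxygens.
#' @param lipid selection (or expression) of lipid tail carbons; must be
#'   disjoint from `water`.
#' @param sf selectivity-filter selection defining the per-frame pore axis.
#' @param reference optional axis-sign reference selection (see [pore_axis()]).
#' @param region_args list of overrides passed to [dpv_region()]
#'   (`radius`, `z_top`, `height`).
#' @return object of class `occupancy_series`: data frame with columns
#'   `time` (ns), `n_water`, `n_lipid`.
#' @export
occupancy_series <- function(series, water, lipid, sf, reference = NULL,
                             region_args = list()) {
  stopifnot(inherits(series, "frame_series"))
  top <- get_frame(series, 1L)
  wi <- as_indices(water, top)
  li <- as_indices(lipid, top)
  if (length(intersect(wi, li))) {
    stop("water and lipid selections overlap")
  }
  sfi <- as_indices(sf, top)
  refi <- if (is.null(reference)) NULL else as_indices(reference, top)
  nf <- n_frames(series)
  nw <- integer(nf)
  nl <- integer(nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(series, i)
    ax <- pore_axis(fr, sfi, reference = refi)
    reg <- do.call(dpv_region, c(list(axis = ax), region_args))
    nw[i] <- count_in_region(fr, reg, wi)
    nl[i] <- count_in_region(fr, reg, li)
  }
  structure(data.frame(time = series$times, n_water = nw, n_lipid = nl),
            class = c("occupancy_series", "data.frame"))
}

#' Construct an occupancy series from raw vectors
#' @param times frame times (ns).
#' @param n_water,n_lipid per-frame counts (>= 0).
#' @return an `occupancy_series`.
#' @export
occupancy_series_from <- function(times, n_water, n_lipid) {
  stopifnot(length(times) == length(n_water),
            length(times) == length(n_lipid))
  if (any(n_water < 0) || any(n_lipid < 0)) stop("counts must be >= 0")
  structure(data.frame(time = times, n_water = n_water, n_lipid = n_lipid),
            class = c("occupancy_series", "data.frame"))
}

#' Equilibrium occupancy statistics
#'
#' Means, standard deviations and 1D kernel density estimates of the water and
#' lipid counts over frames with `time >= t_min` (discarding the approach to
#' equilibrium; 200 ns in microsecond-scale production runs, rescaled to the
#' length of the input via the pipeline configuration).
#'
#' @param series an `occupancy_series`.
#' @param t_min equilibration cutoff (same unit as `series$time`).
#' @param bw kernel bandwidth rule or value for [stats::density()]; the
#'   default `"nrd"` is Scott's rule.
#' @return list with `n_used`, `mean_water`, `sd_water`, `mean_lipid`,
#'   `sd_lipid`, `correlation`, and densities `kde_water`, `kde_lipid`.
#' @export
occupancy_stats <- function(series, t_min = 0, bw = "nrd") {
  s <- series[series$time >= t_min, ]
  if (nrow(s) < 2L) stop("fewer than 2 frames with time >= ", t_min)
  kde <- function(x) {
    if (stats::sd(x) < 1e-8) NULL else stats::density(x, bw = bw)
  }
  list(
    n_used = nrow(s),
    mean_water = mean(s$n_water), sd_water = stats::sd(s$n_water),
    mean_lipid = mean(s$n_lipid), sd_lipid = stats::sd(s$n_lipid),
    correlation = if (stats::sd(s$n_water) > 0 && stats::sd(s$n_lipid) > 0) {
      stats::cor(s$n_water, s$n_lipid)
    } else NA_real_,
    kde_water = kde(s$n_water), kde_lipid = kde(s$n_lipid)
  )
}

#' Joint negative-log density map of water vs lipid counts
#'
#' 2D kernel density estimate over `(n_water, n_lipid)` reported on a negative
#' logarithmic scale with the global minimum shifted to zero, the conventional
#' way of displaying the wet/dry basin structure.
#'
#' @param series an `occupancy_series` (>= 2 distinct points).
#' @param n grid points per axis.
#' @param lims optional `c(xmin, xmax, ymin, ymax)` limits.
#' @param h optional bandwidth(s) passed to [MASS::kde2d()].
#' @return list with `x`, `y` grids and matrix `z` = `-log(density)` shifted
#'   so `min(z) == 0` (empty cells are `Inf`).
#' @export
joint_histogram <- function(series, n = 64, lims = NULL, h = NULL) {
  if (nrow(series) < 2L) stop("joint_histogram needs at least 2 points")
  if (stats::sd(series$n_water) == 0 && stats::sd(series$n_lipid) == 0) {
    stop("degenerate occupancy series: all mass at a single point")
  }
  jitter_bw <- function(x) {
    b <- tryCatch(MASS::bandwidth.nrd(x), error = function(e) 0)
    if (!is.finite(b) || b <= 0) 4 * max(1e-3, stats::sd(x), 0.25) else b
  }
  if (is.null(h)) h <- c(jitter_bw(series$n_water), jitter_bw(series$n_lipid))
  args <- list(x = series$n_water, y = series$n_lipid, n = n, h = h)
  if (!is.null(lims)) args$lims <- lims
  k <- do.call(MASS::kde2d, args)
  z <- -log(k$z)
  z <- z - min(z[is.finite(z)])
  list(x = k$x, y = k$y, z = z)
}

#' Classify frames as wet or dry by water count
#'
#' @param series an `occupancy_series`.
#' @param water_threshold frames with `n_water >= water_threshold` are wet.
#'   The default 5 sits between the dewetted (~1 water) and hydrated
#'   (~14-16 waters) occupancy regimes of the deep pore volume.
#' @return factor of levels `c("dry", "wet")` per frame, with attribute
#'   `switches`: frame indices i where state(i) != state(i-1).
#' @export
wet_dry_classify <- function(series, water_threshold = 5) {
  if (water_threshold <= 0) stop("water_threshold must be positive")
  st <- factor(ifelse(series$n_water >= water_threshold, "wet", "dry"),
               levels = c("dry", "wet"))
  sw <- if (length(st) > 1L) which(st[-1] != st[-length(st)]) + 1L else integer()
  attr(st, "switches") <- sw
  st
}

#' Waters in contact with the innermost selectivity-filter ion
#'
#' @param frame an `atom_frame`.
#' @param innermost_k selection holding exactly one atom (the innermost
#'   potassium ion).
#' @param water selection of water oxygens.
#' @param cutoff contact distance in angstrom, inclusive (default 3.6).
#' @return integer count of waters within `cutoff` of the ion.
#' @export
sf_contact_waters <- function(frame, innermost_k, water, cutoff = 3.6) {
  ki <- as_indices(innermost_k, frame)
  if (length(ki) != 1L) {
    stop("innermost_k must select exactly one atom (got ", length(ki), ")")
  }
  wi <- as_indices(water, frame)
  if (length(wi) == 0L) return(0L)
  d <- sqrt(rowSums(sweep(frame$xyz[wi, , drop = FALSE], 2,
                          frame$xyz[ki, ], "-")^2))
  sum(d <= cutoff)
}

#' Lipid tail-carbon density in a sphere (metadynamics collective variable)
#'
#' Smoothed count of tail carbons inside the sphere using a radial Fermi
#' switch `1 / (1 + exp((|x - c| - R) / smooth))`; `smooth = 0` gives the
#' sharp count. With `normalize = TRUE` the count is divided by the sphere
#' volume and reported per nm^3.
#'
#' @param frame an `atom_frame`.
#' @param sphere a `sphere_region`.
#' @param tail_carbons selection of lipid acyl-tail carbons.
#' @param smooth radial Fermi parameter (angstrom, >= 0).
#' @param normalize report a number density (nm^-3) instead of a count.
#' @return real number.
#' @export
lipid_density_cv <- function(frame, sphere, tail_carbons, smooth = 0,
                             normalize = FALSE) {
  stopifnot(inherits(sphere, "sphere_region"))
  if (smooth < 0) stop("smooth must be >= 0")
  idx <- as_indices(tail_carbons, frame)
  if (length(idx) == 0L) {
    v <- 0
  } else {
    d <- sqrt(rowSums(sweep(frame$xyz[idx, , drop = FALSE], 2,
                            sphere$center, "-")^2))
    v <- sum(fermi_switch(d - sphere$radius, smooth))
  }
  if (normalize) v / (4 / 3 * pi * (sphere$radius / 10)^3) else v
}

min_dist <- function(A, B) {
  # smallest pairwise distance between two coordinate sets
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- rowSums(sweep(B, 2, A[i, ], "-")^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Annular lipids in simultaneous contact with the pore gate
#'
#' Scans lipid residues for the simultaneous-contact criterion: minimum
#' heavy-atom distance to each of the pore-lining helix selection, the R329
#' side-chain selection, and the K392 side-chain selection all below `cutoff`.
#' Each qualifying lipid yields one record with head-group distances, a
#' deep-pore penetration flag, a tail saturation label, and the xy projections
#' of its tail atoms in the pore-axis frame.
#'
#' @param frame an `atom_frame`.
#' @param lipids selection covering the lipid residues to scan.
#' @param r329,k392,s6 selections of the arginine side chains, lysine side
#'   chains and pore-lining (S6) helices.
#' @param dpv the deep-pore `cylinder_region` (penetration flag).
#' @param cutoff simultaneous-contact distance in angstrom (default 6).
#' @param tail_templates named character vector of atom-name glob patterns
#'   labelling tails; the default maps the sn-1 `C3*` chain to `saturated`
#'   (palmitoyl) and the sn-2 `C2*` chain to `unsaturated` (oleoyl).
#' @param phosphate_names,head_names atom-name globs for the phosphate and
#'   head-group atoms.
#' @return data frame (class `contact_records`) with one row per qualifying
#'   lipid: `segid`, `resid`, `tail`, `d_phosphate_r329`, `d_head_k392`,
#'   `penetration`; attribute `tail_xy` holds the per-record tail-atom xy
#'   projection matrices.
#' @export
annular_lipid_contacts <- function(frame, lipids, r329, k392, s6, dpv,
                                   cutoff = 6,
                                   tail_templates = c(saturated = "C3*",
                                                      unsaturated = "C2*"),
                                   phosphate_names = "P*",
                                   head_names = c("P*", "N*", "C1*")) {
  li <- as_indices(lipids, frame)
  ri <- as_indices(r329, frame)
  ki <- as_indices(k392, frame)
  si <- as_indices(s6, frame)
  if (!length(li) || !length(ri) || !length(ki) || !length(si)) {
    stop("annular_lipid_contacts: empty selection among lipids/r329/k392/s6")
  }
  stopifnot(inherits(dpv, "cylinder_region"))
  at <- frame$atoms
  glob_match <- function(names, globs) {
    Reduce(`|`, lapply(globs, function(g) grepl(utils::glob2rx(g), names)))
  }
  key <- paste(at$segid[li], at$resid[li])
  groups <- split(li, key)
  recs <- list()
  tail_xy <- list()
  B <- axis_basis(dpv$axis)
  for (g in groups) {
    X <- frame$xyz[g, , drop = FALSE]
    heavy <- at$element[g] != "H"
    Xh <- X[heavy, , drop = FALSE]
    if (!nrow(Xh)) next
    ok <- min_dist(Xh, frame$xyz[si, , drop = FALSE]) < cutoff &&
      min_dist(Xh, frame$xyz[ri, , drop = FALSE]) < cutoff &&
      min_dist(Xh, frame$xyz[ki, , drop = FALSE]) < cutoff
    if (!ok) next
    nm <- at$name[g]
    phos <- glob_match(nm, phosphate_names)
    headm <- glob_match(nm, head_names)
    tails <- lapply(tail_templates, function(p) which(glob_match(nm, p)))
    tail_atoms <- unlist(tails, use.names = FALSE)
    pen_by_tail <- vapply(tails, function(ix) {
      if (!length(ix)) return(FALSE)
      any(region_contains(dpv, X[ix, , drop = FALSE]))
    }, logical(1))
    penetration <- any(pen_by_tail)
    # label: the penetrating tail if any, else the tail closest to the axis
    lab <- if (penetration) {
      names(tail_templates)[which(pen_by_tail)[1]]
    } else {
      dmin <- vapply(tails, function(ix) {
        if (!length(ix)) return(Inf)
        lxy <- to_axis_frame(X[ix, , drop = FALSE], dpv$axis)
        min(sqrt(lxy[, 1]^2 + lxy[, 2]^2))
      }, numeric(1))
      names(tail_templates)[which.min(dmin)]
    }
    recs[[length(recs) + 1L]] <- data.frame(
      segid = at$segid[g][1], resid = at$resid[g][1], tail = lab,
      d_phosphate_r329 = if (any(phos)) {
        min_dist(X[phos, , drop = FALSE], frame$xyz[ri, , drop = FALSE])
      } else NA_real_,
      d_head_k392 = if (any(headm)) {
        min_dist(X[headm, , drop = FALSE], frame$xyz[ki, , drop = FALSE])
      } else NA_real_,
      penetration = penetration,
      stringsAsFactors = FALSE
    )
    lxy <- to_axis_frame(X[tail_atoms, , drop = FALSE], dpv$axis)
    tail_xy[[length(tail_xy) + 1L]] <- lxy[, 1:2, drop = FALSE]
  }
  out <- if (length(recs)) do.call(rbind, recs) else {
    data.frame(segid = character(), resid = integer(), tail = character(),
               d_phosphate_r329 = numeric(), d_head_k392 = numeric(),
               penetration = logical(), stringsAsFactors = FALSE)
  }
  attr(out, "tail_xy") <- tail_xy
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Write an occupancy series (with wet/dry states) as TSV
#' @param series an `occupancy_series`.
#' @param path output path.
#' @param water_threshold wet/dry threshold (see [wet_dry_classify()]).
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(series, path, water_threshold = 5) {
  st <- wet_dry_classify(series, water_threshold)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# occupancy series; wet threshold = %g", water_threshold),
             con)
  writeLines("time_ns\tn_water\tn_lipid\tstate", con)
  utils::write.table(
    data.frame(series$time, series$n_water, series$n_lipid, as.character(st)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
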