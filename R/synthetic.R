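# Synthetic-data generators. Every input the analysis stack consumes can be
# produced here with known ground truth: channel-like coordinate fixtures with
# scripted water/lipid occupancy, restrained-sampling series drawn from a
# declared free-energy landscape, metadynamics traces with a recorded hill
# list, and ideal alpha-helices at prescribed tilts. The generators make no
# claim of physical realism: their contract is that the accompanying manifest
# describes the emitted configurations exactly, so that analysis operations
# can be validated against it.

#' Ideal alpha-helix C-alpha trace at a prescribed tilt
#'
#' Defaults follow canonical alpha-helix geometry: rise 1.5 angstrom per
#' residue, C-alpha ring radius 2.3 angstrom, 100 degrees twist per residue.
#' The helix is built along the z axis, centered at the origin, then rotated
#' by `tilt_deg` about the y axis (and optionally swung about z by `azimuth`).
#'
#' @param tilt_deg tilt from the z axis in degrees.
#' @param n_residues number of residues (>= 6).
#' @param rise,radius,twist helix geometry (angstrom, angstrom, deg/residue).
#' @param azimuth rotation about z applied after tilting (degrees).
#' @return n x 3 matrix of C-alpha coordinates in sequence order.
#' @export
build_helix <- function(tilt_deg = 0, n_residues = 30, rise = 1.5,
                        radius = 2.3, twist = 100, azimuth = 0) {
  if (n_residues < 6L) stop("build_helix needs n_residues >= 6")
  t <- seq_len(n_residues) - 1
  ang <- t * twist * pi / 180
  X <- cbind(radius * cos(ang), radius * sin(ang), t * rise)
  X <- sweep(X, 2, colMeans(X), "-")
  X %*% t(rot_z(azimuth) %*% rot_y(tilt_deg))
}

ring_points <- function(radius, z, n, phase = 0) {
  a <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(a), radius * sin(a), z)
}

#' Stack of atom rings forming a cylindrical pore shell
#'
#' A minimal "protein" for radius-profile tests: rings of `n_per_ring` carbon
#' atoms of the given vdW radius at `shell_radius` from the z axis. A slice
#' through a ring plane has inscribed-sphere radius `shell_radius - vdw`.
#'
#' @param shell_radius ring radius in angstrom.
#' @param z_min,z_max,dz axial extent and ring spacing (angstrom).
#' @param n_per_ring atoms per ring.
#' @param vdw van der Waals radius assigned to every shell atom.
#' @param resname,name,segid metadata given to the shell atoms.
#' @return an `atom_frame`.
#' @export
build_ring_stack <- function(shell_radius = 5, z_min = -5, z_max = 5,
                             dz = 0.5, n_per_ring = 24, vdw = 1.7,
                             resname = "SHL", name = "C", segid = "PROT") {
  zs <- seq(z_min, z_max, by = dz)
  xyz <- do.call(rbind, lapply(zs, function(z)
    ring_points(shell_radius, z, n_per_ring)))
  n <- nrow(xyz)
  atoms <- data.frame(name = name, resname = resname,
                      resid = rep(seq_along(zs), each = n_per_ring),
                      segid = segid, element = "C", vdw = vdw,
                      stringsAsFactors = FALSE)
  atom_frame(xyz, atoms)
}

# deterministic low-discrepancy-ish placement inside a cylinder
cylinder_points <- function(n, radius, z_min, z_max) {
  if (n == 0L) return(matrix(numeric(), 0, 3))
  r <- radius * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a), runif(n, z_min, z_max))
}

#' Channel-like coordinate fixture with scripted occupancy and ground truth
#'
#' Builds a toy channel along the z axis: a selectivity-filter (SF) marker
#' stack whose COM defines z = 0 and whose principal axis defines the pore
#' axis, a cytosolic reference marker fixing the axis sign, a cylindrical pore
#' shell, an innermost-potassium marker, water oxygens inside the deep pore
#' volume (DPV), SF-contact waters at prescribed distances from the ion,
#' coarse two-tailed lipids (saturated `C3*` / unsaturated `C2*` tails,
#' phosphate `P`, head `N`/`C1`), contact-site markers (R329/K392 side chains,
#' pore-lining S6 helices at prescribed tilts), and scripted events: at
#' `water_exit$frame` a number of DPV waters relocate to the bulk, at
#' `lipid_entry$frame` tail carbons of one lipid relocate into the DPV.
#'
#' All placements are deterministic given `seed`; the returned
#' `manifest` describes the emitted frames exactly (per-frame DPV counts,
#' event frames, SF-contact distances, selection expressions, helix tilts).
#'
#' @param n_frames number of trajectory frames.
#' @param dt frame spacing in ns.
#' @param pore_radius shell ring radius (angstrom).
#' @param n_water_dpv waters placed inside the DPV in the initial frame.
#' @param sf_water_distances distances (angstrom) of SF-contact waters from
#'   the innermost potassium.
#' @param n_lipids number of lipid residues.
#' @param contact_lipids indices of lipids placed in simultaneous contact
#'   with S6/R329/K392 (others are placed far from the protein).
#' @param lipid_entry `NULL`, or `list(frame=, lipid=, tail=, n_carbons=)`
#'   scripting tail-carbon entry into the DPV.
#' @param water_exit `NULL`, or `list(frame=, n=)` scripting water departure.
#' @param s6_tilts per-subunit S6 tilt angles in degrees.
#' @param seed RNG seed.
#' @param write_dir if non-NULL, write `structure.pdb`, `traj.pdb` and
#'   `manifest.json` into this directory.
#' @return list with `series` (a `frame_series`), `structure` (frame 1),
#'   `manifest` (ground-truth list) and, when written, `paths`.
#' @export
build_channel_fixture <- function(n_frames = 25, dt = 0.02, pore_radius = 5,
                                  n_water_dpv = 14,
                                  sf_water_distances = c(3, 3, 3, 4, 4),
                                  n_lipids = 4, contact_lipids = 1L,
                                  lipid_entry = NULL, water_exit = NULL,
                                  s6_tilts = c(25, 25, 25, 25), seed = 1,
                                  write_dir = NULL) {
  set.seed(seed)
  dpv_rad <- 7; dpv_top <- -12; dpv_bot <- -17
  blocks <- list()
  add <- function(xyz, name, resname, resid, segid, element, vdw = NULL) {
    xyz <- rbind(xyz)
    n <- nrow(xyz)
    el <- rep_len(element, n)
    blocks[[length(blocks) + 1L]] <<- list(
      xyz = xyz,
      atoms = data.frame(name = rep_len(name, n), resname = rep_len(resname, n),
                         resid = rep_len(resid, n), segid = rep_len(segid, n),
                         element = el,
                         vdw = if (is.null(vdw)) vdw_radii(el) else rep_len(vdw, n),
                         stringsAsFactors = FALSE)
    )
  }
  # SF marker stack: COM at origin, tall and narrow so the dominant principal
  # axis is the pore axis
  for (i in seq_along(c(-2.25, -0.75, 0.75, 2.25))) {
    z <- c(-2.25, -0.75, 0.75, 2.25)[i]
    add(ring_points(1.4, z, 4), "C", "SFM", i, "FILT", "C")
  }
  # cytosolic reference marker (fixes the axis sign)
  add(ring_points(3, -30, 4), "C", "REF", 1L, "REFS", "C")
  # pore shell
  shell_z <- seq(-24, 4, by = 2)
  for (i in seq_along(shell_z)) {
    add(ring_points(pore_radius, shell_z[i], 16), "C", "SHL", i, "PROT", "C",
        vdw = 1.7)
  }
  # innermost potassium
  k_pos <- c(0, 0, -3)
  add(k_pos, "K", "POT", 1L, "IONS", "K")
  # SF-contact waters at prescribed distances from the ion (kept far above
  # the DPV so they never perturb DPV counts)
  wat_res <- 0L
  for (d in sf_water_distances) {
    u <- unitize(c(runif(2, -1, 1), runif(1, 0.5, 1)))
    wat_res <- wat_res + 1L
    add(k_pos + d * u, "OH2", "TIP3", wat_res, "WAT", "O")
  }
  n_sf_waters <- wat_res
  # DPV waters: strictly inside the cylinder and inside the shell
  dpv_wat <- cylinder_points(n_water_dpv, min(dpv_rad, pore_radius) - 1.2,
                             dpv_bot + 0.5, dpv_top - 0.5)
  dpv_wat_res <- integer(0)
  for (i in seq_len(n_water_dpv)) {
    wat_res <- wat_res + 1L
    dpv_wat_res <- c(dpv_wat_res, wat_res)
    add(dpv_wat[i, ], "OH2", "TIP3", wat_res, "WAT", "O")
  }
  # contact-site markers: 4 subunits at 90 degrees
  sub_ang <- (seq_len(4) - 1) * pi / 2
  marker_rad <- pore_radius + 2
  for (s in 1:4) {
    a <- sub_ang[s]
    add(c(marker_rad * cos(a), marker_rad * sin(a), -18), "CZ", "ARG", 329L,
        paste0("PRO", LETTERS[s]), "C")
    add(c(marker_rad * cos(a), marker_rad * sin(a), -22), "NZ", "LYS", 392L,
        paste0("PRO", LETTERS[s]), "N")
  }
  # S6 helices at prescribed tilts, outside the DPV radius
  s6_rad <- 11
  for (s in seq_along(s6_tilts)) {
    a <- sub_ang[(s - 1) %% 4 + 1] + pi / 9 # 20 deg from the marker spoke
    hx <- build_helix(s6_tilts[s], n_residues = 20)
    hx <- sweep(hx, 2, c(s6_rad * cos(a), s6_rad * sin(a), -12), "+")
    add(hx, "CA", "LEU", 301L + seq_len(nrow(hx)) - 1L,
        paste0("S6", LETTERS[s]), "C")
  }
  # lipids: two 6-carbon tails, phosphate + head markers
  lipid_tmpl <- function(center_a, center_r, z_head) {
    p <- c(center_r * cos(center_a), center_r * sin(center_a), z_head)
    tails_z <- z_head - 0.5 - seq_len(6)
    list(
      P = p, N = p + c(0, 0, 1), C1 = p + c(0.5, 0, 0.5),
      C2 = cbind(p[1] + 0.4, p[2], tails_z),      # unsaturated (oleoyl) tail
      C3 = cbind(p[1] - 0.4, p[2], tails_z)       # saturated (palmitoyl) tail
    )
  }
  lipid_atoms_idx <- list()
  for (l in seq_len(n_lipids)) {
    in_contact <- l %in% contact_lipids
    a <- if (in_contact) sub_ang[(l - 1) %% 4 + 1] else
      sub_ang[(l - 1) %% 4 + 1] + pi
    r <- if (in_contact) pore_radius + 5 else pore_radius + 13
    tp <- lipid_tmpl(a, r, -18)
    add(tp$P, "P", "POPC", l, "MEMB", "P")
    add(tp$N, "N", "POPC", l, "MEMB", "N")
    add(tp$C1, "C1", "POPC", l, "MEMB", "C")
    add(tp$C2, paste0("C2", seq_len(6)), "POPC", l, "MEMB", "C")
    add(tp$C3, paste0("C3", seq_len(6)), "POPC", l, "MEMB", "C")
  }
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  atoms <- do.call(rbind, lapply(blocks, `[[`, "atoms"))
  base <- atom_frame(xyz, atoms)

  # scripted events ----------------------------------------------------------
  n_entry <- 0L
  entry_frame <- NA_integer_
  exit_frame <- NA_integer_
  n_exit <- 0L
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) frames[[f]] <- xyz
  if (!is.null(water_exit)) {
    exit_frame <- as.integer(water_exit$frame)
    n_exit <- min(as.integer(water_exit$n), n_water_dpv)
    move_res <- utils::tail(dpv_wat_res, n_exit)
    rows <- which(atoms$resname == "TIP3" & atoms$resid %in% move_res)
    for (f in seq(exit_frame, n_frames)) {
      frames[[f]][rows, ] <- cbind(14 + seq_along(rows), 14, -28)
    }
  }
  if (!is.null(lipid_entry)) {
    entry_frame <- as.integer(lipid_entry$frame)
    n_entry <- as.integer(lipid_entry$n_carbons %||% 3L)
    tail_pfx <- if ((lipid_entry$tail %||% "unsaturated") == "saturated") "C3"
    else "C2"
    lip <- as.integer(lipid_entry$lipid %||% contact_lipids[1])
    rows <- which(atoms$resname == "POPC" & atoms$resid == lip &
                    startsWith(atoms$name, tail_pfx))[seq_len(n_entry)]
    inside <- cbind(1.0, 0.3 * seq_len(n_entry),
                    seq(-13, -16, length.out = n_entry))
    for (f in seq(entry_frame, n_frames)) frames[[f]][rows, ] <- inside
  }
  series <- frame_series(base, frames, times = (seq_len(n_frames) - 1) * dt)

  per_frame_water <- vapply(seq_len(n_frames), function(f) {
    if (!is.na(exit_frame) && f >= exit_frame) n_water_dpv - n_exit
    else n_water_dpv
  }, numeric(1))
  per_frame_lipid <- vapply(seq_len(n_frames), function(f) {
    if (!is.na(entry_frame) && f >= entry_frame) n_entry else 0L
  }, numeric(1))

  manifest <- list(
    seed = seed, n_atoms = nrow(xyz), n_frames = n_frames, dt_ns = dt,
    shell = list(radius = pore_radius, vdw = 1.7,
                 ring_clearance = pore_radius - 1.7, ring_z = shell_z),
    dpv = list(radius = dpv_rad, z_top = dpv_top, z_bottom = dpv_bot),
    n_water_dpv = per_frame_water, n_lipid_dpv = per_frame_lipid,
    water_exit_frame = exit_frame, lipid_entry_frame = entry_frame,
    sf_contact = list(distances = sf_water_distances,
                      n_within_3p6 = sum(sf_water_distances <= 3.6),
                      n_sf_waters = n_sf_waters),
    s6_tilts_deg = s6_tilts,
    contact_lipids = contact_lipids,
    selections = list(
      water = "resname TIP3 and name OH2",
      lipid_tails = "resname POPC and name C2* C3*",
      lipids = "resname POPC",
      sf = "resname SFM", reference = "resname REF",
      innermost_k = "resname POT and name K",
      shell = "resname SHL",
      r329 = "resname ARG and name CZ", k392 = "resname LYS and name NZ",
      s6 = paste0("segid S6", LETTERS[seq_along(s6_tilts)], " and name CA"),
      s6_all = "name CA and resname LEU"
    )
  )
  out <- list(series = series, structure = base, manifest = manifest)
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(structure = file.path(write_dir, "structure.pdb"),
                  trajectory = file.path(write_dir, "traj.pdb"),
                  manifest = file.path(write_dir, "manifest.json"))
    write_pdb_frames(base, paths$structure)
    write_pdb_frames(series, paths$trajectory)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}

#' Restrained sampling of a counting coordinate on a known landscape
#'
#' For each target N*, draws Metropolis samples from the Boltzmann density
#' proportional to `exp(-beta [F(N) + k/2 (N - N*)^2])` on the continuous N
#' line (the restraint acts on a smoothed, continuous count). Reproducible
#' given `seed`; the acceptance rate of each chain is recorded as an
#' attribute of its window.
#'
#' @param landscape vectorized function F(N) in kcal/mol.
#' @param k harmonic constant (kcal/mol per count^2).
#' @param targets vector of window targets N*.
#' @param n_samples Metropolis samples per window (including burn-in period).
#' @param dt nominal sample spacing in ps (1 sample = 1 ps by default).
#' @param temperature temperature in kelvin.
#' @param seed RNG seed.
#' @param step proposal half-width; default `2 * sqrt(kT / k)`.
#' @param burn_in,block_length passed to [restraint_window()] (ps).
#' @return list of `restraint_window`s, one per target, each with attribute
#'   `acceptance`.
#' @export
sample_restrained_series <- function(landscape, k = 1, targets,
                                     n_samples = 22000, dt = 1,
                                     temperature = 300, seed = 1,
                                     step = NULL, burn_in = 2000,
                                     block_length = 100) {
  beta <- 1 / (.kB * temperature)
  if (is.null(step)) step <- 2 * sqrt(1 / (beta * k))
  set.seed(seed)
  lapply(targets, function(tgt) {
    U <- function(x) landscape(x) + k / 2 * (x - tgt)^2
    if (!is.finite(U(tgt))) stop("landscape not finite at target ", tgt)
    x <- tgt
    ux <- U(x)
    prop <- runif(n_samples, -step, step)
    lu <- log(runif(n_samples))
    out <- numeric(n_samples)
    acc <- 0L
    for (i in seq_len(n_samples)) {
      xp <- x + prop[i]
      up <- U(xp)
      if (lu[i] < -beta * (up - ux)) {
        x <- xp
        ux <- up
        acc <- acc + 1L
      }
      out[i] <- x
    }
    w <- restraint_window(tgt, k = k, series = out, dt = dt,
                          burn_in = burn_in, block_length = block_length)
    attr(w, "acceptance") <- acc / n_samples
    w
  })
}

#' Metadynamics trace on a known landscape (overdamped Langevin walker)
#'
#' Euler-Maruyama integration of an overdamped Langevin walker on
#' `F(s) + V_bias(s, t)`, with repulsive Gaussians of the given height and
#' width deposited at the walker position every `pace` steps. Zero hill
#' height degenerates to unbiased sampling. Optional reflecting `bounds` keep
#' the walker on the region of interest.
#'
#' @param landscape vectorized function F(s) in kcal/mol.
#' @param hill_height,hill_width Gaussian bias parameters (kcal/mol,
#'   CV units).
#' @param pace deposit a hill every `pace` steps.
#' @param n_steps total integration steps.
#' @param temperature temperature in kelvin.
#' @param seed RNG seed.
#' @param x0 initial position (default: midpoint of `bounds`, else 0).
#' @param dt integrator time step (CV-diffusion units).
#' @param diffusion diffusion coefficient D.
#' @param bounds optional reflecting boundaries `c(lo, hi)`.
#' @param stride record the CV every `stride` steps.
#' @return a `metad_trace`.
#' @export
sample_metad_trace <- function(landscape, hill_height = 1.0, hill_width = 1.0,
                               pace = 250, n_steps = 50000, temperature = 300,
                               seed = 1, x0 = NULL, dt = 0.05, diffusion = 1,
                               bounds = NULL, stride = 10) {
  if (hill_width <= 0) stop("hill_width must be positive")
  if (pace < 1L) stop("pace must be >= 1")
  beta <- 1 / (.kB * temperature)
  set.seed(seed)
  if (is.null(x0)) x0 <- if (!is.null(bounds)) mean(bounds) else 0
  eps <- 1e-5
  hc <- numeric(0); hw <- numeric(0); hh <- numeric(0); ht <- numeric(0)
  bias_grad <- function(x) {
    if (!length(hc)) return(0)
    e <- hh * exp(-(x - hc)^2 / (2 * hw^2))
    sum(e * (-(x - hc) / hw^2))
  }
  noise <- rnorm(n_steps, 0, sqrt(2 * diffusion * dt))
  x <- x0
  rec_i <- seq(stride, n_steps, by = stride)
  s_out <- numeric(length(rec_i))
  t_out <- rec_i * dt
  ri <- 1L
  for (i in seq_len(n_steps)) {
    g <- (landscape(x + eps) - landscape(x - eps)) / (2 * eps) + bias_grad(x)
    x <- x - diffusion * beta * g * dt + noise[i]
    if (!is.null(bounds)) {
      if (x < bounds[1]) x <- 2 * bounds[1] - x
      if (x > bounds[2]) x <- 2 * bounds[2] - x
      x <- min(max(x, bounds[1]), bounds[2])
    }
    if (hill_height > 0 && i %% pace == 0L) {
      hc <- c(hc, x); hw <- c(hw, hill_width)
      hh <- c(hh, hill_height); ht <- c(ht, i * dt)
    }
    if (ri <= length(rec_i) && i == rec_i[ri]) {
      s_out[ri] <- x
      ri <- ri + 1L
    }
  }
  metad_trace(t_out, s_out,
              hills = data.frame(time = ht, center = hc, height = hh,
                                 width = hw),
              temperature = temperature)
}

#' Write restrained windows as TSV series plus a JSON manifest
#'
#' One two-column (time_ps, count) TSV per window plus `windows.json`
#' referencing them; the layout read back by [read_windows()].
#'
#' @param windows list of `restraint_window`s.
#' @param dir output directory (created if needed).
#' @return path to the manifest, invisibly.
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    f <- sprintf("window_%03d.tsv", i)
    utils::write.table(
      data.frame(time_ps = seq_along(w$series) * w$dt, count = w$series),
      file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE
    )
    list(target = w$target, k = w$k, dt = w$dt, burn_in = w$burn_in,
         block_length = w$block_length, series_file = f)
  })
  path <- file.path(dir, "windows.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a metadynamics trace as CV TSV + hills TSV
#' @param trace a `metad_trace`.
#' @param dir output directory.
#' @return list of written paths, invisibly.
#' @export
write_metad_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cv <- file.path(dir, "cv.tsv")
  hills <- file.path(dir, "hills.tsv")
  utils::write.table(data.frame(time = trace$times, s = trace$s), cv,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(trace$hills, hills, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(cv = cv, hills = hills))
}
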