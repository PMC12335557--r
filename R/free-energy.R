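# Restrained-sampling mean forces, thermodynamic integration (TI) into
# free-energy profiles, block-average errors, metadynamics reweighting, and
# profile feature extraction.
#
# Restrained sampling adds k/2 (N - Ntilde(r))^2 to the Hamiltonian, where
# Ntilde is the Fermi-smoothed particle count and N the target filling level.
# The free-energy gradient at each window is estimated as -k<Ntilde - N>
# (averaged after a burn-in), its standard error by block averaging, and the
# profile is reconstructed by integrating the mean forces across windows.

#' Restrained-sampling window
#'
#' @param target restrained target count N*.
#' @param k harmonic constant in kcal/mol per count^2 (default 1).
#' @param series time series of the instantaneous smoothed count.
#' @param dt sample spacing in ps (default 1: counts recorded every ps).
#' @param burn_in initial transient discarded before averaging, in ps
#'   (default 2000, i.e. the first 2 ns of a 4 ns window).
#' @param block_length block length for the block-average standard error, in
#'   ps (default 100).
#' @return object of class `restraint_window`.
#' @export
restraint_window <- function(target, k = 1, series, dt = 1,
                             burn_in = 2000, block_length = 100) {
  if (k <= 0) stop("harmonic constant k must be positive")
  if (dt <= 0) stop("dt must be positive")
  series <- as.numeric(series)
  if (length(series) * dt <= burn_in + block_length) {
    stop("window too short: length * dt must exceed burn_in + block_length")
  }
  structure(list(target = target, k = k, series = series, dt = dt,
                 burn_in = burn_in, block_length = block_length),
            class = "restraint_window")
}

#' Block-average standard error
#'
#' Standard deviation of non-overlapping block means divided by the square
#' root of the number of blocks; a trailing partial block is discarded. Robust
#' to serial correlation when blocks exceed the correlation time.
#'
#' @param series numeric samples.
#' @param block_length block size in samples (>= 1); at least 2 complete
#'   blocks are required.
#' @return standard error of the series mean.
#' @export
block_se <- function(series, block_length) {
  block_length <- as.integer(block_length)
  if (block_length < 1L) stop("block_length must be >= 1 sample")
  nb <- length(series) %/% block_length
  if (nb < 2L) stop("block_se needs at least 2 complete blocks (got ", nb, ")")
  bm <- colMeans(matrix(series[seq_len(nb * block_length)],
                        nrow = block_length))
  stats::sd(bm) / sqrt(nb)
}

#' Mean force of a restrained window
#'
#' `mean_force = -k * mean(Ntilde - N*)` over samples past the burn-in;
#' `se = k * block_se(...)`. The post-burn-in sample mean of the count
#' (`mean_position`) is also reported: for a locally quadratic landscape the
#' mean force equals the landscape derivative evaluated exactly at that
#' position, which is the abscissa used when integrating for landscape
#' recovery (see [integrate_profile()]).
#'
#' @param window a `restraint_window`.
#' @return object of class `mean_force_point`: list with `target`,
#'   `mean_force` (kcal/mol per count), `se`, `mean_position`, `n_samples`.
#' @export
mean_force <- function(window) {
  stopifnot(inherits(window, "restraint_window"))
  t <- seq_along(window$series) * window$dt
  post <- window$series[t > window$burn_in]
  L <- max(1L, as.integer(round(window$block_length / window$dt)))
  if (length(post) < 2L * L) {
    stop("insufficient post-burn-in samples for block analysis")
  }
  structure(list(
    target = window$target,
    mean_force = -window$k * mean(post - window$target),
    se = window$k * block_se(post, L),
    mean_position = mean(post),
    n_samples = length(post)
  ), class = "mean_force_point")
}

#' Thermodynamic integration of mean forces into a free-energy profile
#'
#' Integrates the per-window mean forces over the restrained coordinate.
#' `method = "euler"` is the left-Riemann sum; `"trapezoid"` is exact for a
#' linear force (quadratic landscape) and is preferred for landscape recovery.
#' Standard errors propagate in quadrature: `se(F_j) = sqrt(sum (se_i dN_i)^2)`
#' from the integration origin, so they are non-decreasing with distance from
#' the first grid point.
#'
#' Abscissae: `"target"` integrates over the window targets N* (recovering the
#' spring-smoothed profile, which tends to the underlying landscape as the
#' spring stiffens); `"mean_position"` integrates the same forces over the
#' window mean counts, which for locally quadratic landscapes recovers the
#' underlying landscape at any spring constant.
#'
#' @param points list of `mean_force_point`s (or a data frame with columns
#'   `target`, `mean_force`, `se`, and optionally `mean_position`).
#' @param method `"euler"` (default) or `"trapezoid"`.
#' @param reference index of the grid point where F is set to zero
#'   (default 1).
#' @param abscissa `"target"` (default) or `"mean_position"`.
#' @return object of class `free_energy_profile`: data frame with columns
#'   `grid`, `F` (kcal/mol), `se`.
#' @export
integrate_profile <- function(points, method = c("euler", "trapezoid"),
                              reference = 1L,
                              abscissa = c("target", "mean_position")) {
  method <- match.arg(method)
  abscissa <- match.arg(abscissa)
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, function(p) {
      data.frame(target = p$target, mean_force = p$mean_force, se = p$se,
                 mean_position = p$mean_position %||% NA_real_)
    }))
  }
  if (anyDuplicated(points$target)) stop("duplicate window targets")
  if (is.unsorted(points$target)) {
    warning("windows not sorted by target; sorting")
    points <- points[order(points$target), ]
  }
  x <- if (abscissa == "target") points$target else points$mean_position
  if (abscissa == "mean_position") {
    if (any(is.na(x))) stop("mean_position abscissa requested but missing")
    o <- order(x)
    points <- points[o, ]
    x <- x[o]
  }
  f <- points$mean_force
  s <- points$se
  m <- length(x)
  if (m < 2L) stop("need at least 2 windows to integrate")
  dx <- diff(x)
  Fv <- numeric(m)
  Vv <- numeric(m)
  for (j in 2:m) {
    if (method == "euler") {
      Fv[j] <- Fv[j - 1] + f[j - 1] * dx[j - 1]
      Vv[j] <- Vv[j - 1] + (s[j - 1] * dx[j - 1])^2
    } else {
      Fv[j] <- Fv[j - 1] + (f[j - 1] + f[j]) / 2 * dx[j - 1]
      Vv[j] <- Vv[j - 1] + ((s[j - 1] + s[j]) / 2 * dx[j - 1])^2
    }
  }
  reference <- as.integer(reference)
  if (reference < 1L || reference > m) stop("reference index out of range")
  free_energy_profile(x, Fv - Fv[reference], sqrt(Vv),
                      reference = reference, method = method)
}

#' Construct a free-energy profile object
#' @param grid coordinate values (count or density), strictly increasing.
#' @param F free energies (kcal/mol).
#' @param se standard errors (kcal/mol, >= 0; NA allowed).
#' @param reference index of the zero point.
#' @param method provenance tag (e.g. `"euler"`, `"reweight"`).
#' @return object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(grid, F, se = NA_real_, reference = 1L,
                                method = "") {
  stopifnot(length(grid) == length(F))
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  structure(data.frame(grid = grid, F = F, se = se),
            class = c("free_energy_profile", "data.frame"),
            reference = reference, method = method)
}

# ---- metadynamics ----------------------------------------------------------

#' Metadynamics trace (collective-variable samples plus bias record)
#'
#' @param times sample times (arbitrary unit, increasing).
#' @param s collective-variable samples.
#' @param hills data frame of deposited Gaussians with columns `time`,
#'   `center`, `height` (kcal/mol, >= 0), `width` (standard deviation of the
#'   Gaussian); may be empty.
#' @param temperature simulation temperature in kelvin (default 300).
#' @param bias_fn optional precomputed final-bias evaluator `V(s)` in
#'   kcal/mol; overrides `hills` when supplied.
#' @return object of class `metad_trace`.
#' @export
metad_trace <- function(times, s, hills = NULL, temperature = 300,
                        bias_fn = NULL) {
  stopifnot(length(times) == length(s))
  if (temperature <= 0) stop("temperature must be positive")
  if (is.null(hills)) {
    hills <- data.frame(time = numeric(), center = numeric(),
                        height = numeric(), width = numeric())
  }
  if (nrow(hills) && any(hills$height < 0)) stop("hill heights must be >= 0")
  if (nrow(hills) && any(hills$width <= 0)) stop("hill widths must be positive")
  structure(list(times = times, s = s, hills = hills,
                 temperature = temperature, bias_fn = bias_fn),
            class = "metad_trace")
}

#' Evaluate the accumulated metadynamics bias
#' @param trace a `metad_trace`.
#' @param s points at which to evaluate the bias.
#' @param time evaluate the bias deposited up to this time (default: all
#'   hills, i.e. the final bias).
#' @return bias values in kcal/mol.
#' @export
metad_bias <- function(trace, s, time = Inf) {
  if (!is.null(trace$bias_fn)) return(trace$bias_fn(s))
  h <- trace$hills[trace$hills$time <= time, , drop = FALSE]
  v <- numeric(length(s))
  for (i in seq_len(nrow(h))) {
    v <- v + h$height[i] * exp(-(s - h$center[i])^2 / (2 * h$width[i]^2))
  }
  v
}

#' Free-energy profile by reweighting a metadynamics trace
#'
#' Each sample is weighted by `exp(+V_final(s_i) / kT)` where `V_final` is the
#' total bias at the end of the run (last-bias approximation), the weighted
#' histogram gives a density estimate, and `F = -kT log p` shifted so the
#' global minimum is zero. With zero bias the result equals the plain
#' histogram estimator exactly. Standard errors come from block analysis over
#' `n_blocks` contiguous time blocks.
#'
#' @param trace a `metad_trace`.
#' @param grid bin-center grid for the histogram; default: `bins` equal bins
#'   spanning the sampled range.
#' @param bins number of bins when `grid` is not given.
#' @param n_blocks blocks for the block-analysis error (0 disables).
#' @return a `free_energy_profile` over the bin centers (empty bins carry
#'   `F = Inf`).
#' @export
metad_reweight <- function(trace, grid = NULL, bins = 61L, n_blocks = 5L) {
  stopifnot(inherits(trace, "metad_trace"))
  if (length(trace$s) == 0L) stop("empty trace")
  kT <- .kB * trace$temperature
  if (is.null(grid)) {
    grid <- seq(min(trace$s), max(trace$s), length.out = bins)
  }
  if (length(grid) < 2L) stop("grid needs at least 2 points")
  dgrid <- diff(grid)
  edges <- c(grid[1] - dgrid[1] / 2, grid[-length(grid)] + dgrid / 2,
             grid[length(grid)] + dgrid[length(dgrid)] / 2)
  w <- exp(metad_bias(trace, trace$s) / kT)
  hist_F <- function(s, w) {
    bin <- findInterval(s, edges, rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= length(grid)
    p <- vapply(seq_along(grid), function(b) sum(w[ok & bin == b]), numeric(1))
    p <- p / (sum(w) * diff(edges))
    Fv <- -kT * log(p)
    Fv - min(Fv[is.finite(Fv)])
  }
  Fv <- hist_F(trace$s, w)
  se <- rep(NA_real_, length(grid))
  if (n_blocks >= 2L && length(trace$s) >= 2L * n_blocks) {
    nb <- as.integer(n_blocks)
    blk <- cut(seq_along(trace$s), nb, labels = FALSE)
    Fb <- sapply(seq_len(nb), function(b) hist_F(trace$s[blk == b], w[blk == b]))
    Fb[!is.finite(Fb)] <- NA
    se <- apply(Fb, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    })
  }
  free_energy_profile(grid, Fv, se, reference = which.min(Fv),
                      method = "reweight")
}

# ---- profile features ------------------------------------------------------

#' Minima and barriers of a free-energy profile
#'
#' Local minima are grid points not exceeded by their neighbours (boundary
#' points qualify against their single neighbour); for each pair of adjacent
#' minima the barrier is the highest intervening point (the saddle) minus the
#' shallower (higher) of the two minima. Minima separated by a barrier lower
#' than `min_barrier` are merged into the deeper of the pair, which filters
#' statistical roughness out of noisy (e.g. reweighted-histogram) profiles.
#'
#' @param profile a `free_energy_profile` (>= 3 grid points).
#' @param min_barrier smallest barrier (kcal/mol) that separates two distinct
#'   minima (default 0: no filtering).
#' @return list with `minima` (data frame: `grid`, `F`), `barriers` (data
#'   frame: `from`, `to`, `saddle_grid`, `height`), and `global_min` (list:
#'   `grid`, `F`).
#' @export
profile_features <- function(profile, min_barrier = 0) {
  Fv <- profile$F
  g <- profile$grid
  n <- length(Fv)
  if (n < 3L) stop("profile_features needs at least 3 grid points")
  finite <- is.finite(Fv)
  is_min <- logical(n)
  for (i in which(finite)) {
    left <- if (i > 1L) Fv[i] <= Fv[i - 1L] else TRUE
    right <- if (i < n) Fv[i] <= Fv[i + 1L] else TRUE
    strict <- (i > 1L && Fv[i] < Fv[i - 1L]) || (i < n && Fv[i] < Fv[i + 1L])
    is_min[i] <- left && right && (strict || (i > 1L && i < n &&
                                                Fv[i - 1L] == Fv[i] &&
                                                Fv[i + 1L] == Fv[i]))
  }
  # collapse runs of equal-F plateau minima to their midpoint
  mi <- which(is_min)
  if (length(mi) > 1L) {
    runs <- split(mi, cumsum(c(1, diff(mi) != 1L)))
    mi <- vapply(runs, function(r) r[ceiling(length(r) / 2)], integer(1))
  }
  barrier_between <- function(a, b) {
    seg <- a:b
    k <- seg[which.max(Fv[seg])]
    c(saddle = k, height = Fv[k] - max(Fv[a], Fv[b]))
  }
  # merge minima separated by sub-threshold barriers into the deeper one
  while (length(mi) > 1L) {
    hb <- vapply(seq_len(length(mi) - 1L), function(j) {
      barrier_between(mi[j], mi[j + 1L])["height"]
    }, numeric(1))
    j <- which.min(hb)
    if (hb[j] > min_barrier && hb[j] > 0) break
    drop <- if (Fv[mi[j]] >= Fv[mi[j + 1L]]) j else j + 1L
    mi <- mi[-drop]
  }
  minima <- data.frame(grid = g[mi], F = Fv[mi])
  barriers <- NULL
  if (length(mi) > 1L) {
    rows <- lapply(seq_len(length(mi) - 1L), function(j) {
      a <- mi[j]; b <- mi[j + 1L]
      bb <- barrier_between(a, b)
      data.frame(from = g[a], to = g[b], saddle_grid = g[bb["saddle"]],
                 height = bb["height"])
    })
    barriers <- do.call(rbind, rows)
    barriers <- barriers[barriers$height > 0, , drop = FALSE]
    rownames(barriers) <- NULL
  }
  if (is.null(barriers)) {
    barriers <- data.frame(from = numeric(), to = numeric(),
                           saddle_grid = numeric(), height = numeric())
  }
  gi <- which.min(ifelse(finite, Fv, Inf))
  list(minima = minima, barriers = barriers,
       global_min = list(grid = g[gi], F = Fv[gi]))
}

# ---- file interfaces -------------------------------------------------------

#' Read restrained-sampling windows from a manifest plus series files
#'
#' The manifest (JSON or YAML) is a list of records with fields `target`,
#' `series_file` and optional `k`, `dt`, `burn_in`, `block_length`; each
#' series file is a one- or two-column table whose last column is the count
#' series.
#'
#' @param manifest_path path to the JSON/YAML manifest.
#' @param dir directory against which relative `series_file`s are resolved
#'   (default: the manifest's directory).
#' @return list of `restraint_window`s.
#' @export
read_windows <- function(manifest_path, dir = dirname(manifest_path)) {
  man <- if (grepl("\\.ya?ml$", manifest_path)) {
    yaml::read_yaml(manifest_path)
  } else {
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  }
  lapply(man, function(w) {
    f <- w$series_file
    if (!file.exists(f)) f <- file.path(dir, w$series_file)
    tab <- utils::read.table(f, header = FALSE, comment.char = "#")
    restraint_window(
      target = w$target, k = w$k %||% 1,
      series = tab[[ncol(tab)]], dt = w$dt %||% 1,
      burn_in = w$burn_in %||% 2000, block_length = w$block_length %||% 100
    )
  })
}

#' Read a metadynamics hill list (four-column TSV: time, center, height, width)
#' @param path path to the hills file.
#' @return data frame with columns `time`, `center`, `height`, `width`.
#' @export
read_hills <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 4L) stop("hills file needs 4 columns: time center height width")
  stats::setNames(tab[, 1:4], c("time", "center", "height", "width"))
}

#' Write a free-energy profile as TSV (columns grid, F_kcal_mol, se)
#' @param profile a `free_energy_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# free-energy profile; method = %s",
                     attr(profile, "method") %||% ""), con)
  writeLines("grid\tF_kcal_mol\tse", con)
  utils::write.table(data.frame(profile$grid, profile$F, profile$se),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
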