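# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: brute-force enumeration for the pore radius, quadrature
# for restrained Boltzmann averages.

# Dense-grid brute-force pore radius at one slice: exhaustive 2D grid over the
# in-plane search disc, same slab rule and 3D point-to-sphere clearance as the
# spec'd definition, no coarse stage, no refinement.
dense_radius_oracle <- function(frame, axis, z, dz = 0.5, include = NULL,
                                spacing = 0.02, search_radius = 5,
                                cap = 12) {
  idx <- if (is.null(include)) seq_len(nrow(frame$atoms)) else {
    if (inherits(include, "atom_selection")) include$indices else include
  }
  B <- local({
    e3 <- axis$direction
    a <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * e3) * e3
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
            e3[3] * e1[1] - e3[1] * e1[3],
            e3[1] * e1[2] - e3[2] * e1[1])
    cbind(e1, e2, e3)
  })
  lx <- sweep(frame$xyz[idx, , drop = FALSE], 2, axis$origin, "-") %*% B
  vdw <- frame$atoms$vdw[idx]
  slab <- abs(lx[, 3] - z) <= vdw + dz
  if (!any(slab)) return(cap)
  ax <- lx[slab, , drop = FALSE]
  av <- vdw[slab]
  g <- seq(-search_radius, search_radius, by = spacing)
  best <- -Inf
  for (gy in g) {
    keep <- g^2 + gy^2 <= search_radius^2
    if (!any(keep)) next
    gx <- g[keep]
    d <- sqrt(outer(gx, ax[, 1], "-")^2 +
                outer(rep(gy, length(gx)), ax[, 2], "-")^2 +
                matrix((z - ax[, 3])^2, length(gx), nrow(ax), byrow = TRUE))
    cl <- apply(sweep(d, 2, av, "-"), 1, min)
    best <- max(best, max(cl))
  }
  min(cap, max(0, best))
}

# Restrained Boltzmann average <x> under exp(-beta [F(x) + k/2 (x - t)^2])
# by direct quadrature on a dense grid.
restrained_mean_oracle <- function(landscape, k, target, temperature = 300,
                                   lims = c(-50, 70)) {
  beta <- 1 / (0.0019872041 * temperature)
  x <- seq(lims[1], lims[2], length.out = 200001)
  u <- landscape(x) + k / 2 * (x - target)^2
  w <- exp(-beta * (u - min(u)))
  sum(x * w) / sum(w)
}

# Double-well landscape used across free-energy tests: minima at 2 and 14,
# central barrier 3 kcal/mol.
double_well <- function(x) 3 * (((x - 8) / 6)^2 - 1)^2

make_test_frame <- function(xyz, names = NULL, resnames = NULL,
                            resids = NULL, segids = NULL, vdw = 1.7,
                            element = "C") {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  atom_frame(xyz, data.frame(
    name = rep_len(names %||% "C", n),
    resname = rep_len(resnames %||% "UNK", n),
    resid = rep_len(resids %||% seq_len(n), n),
    segid = rep_len(segids %||% "A", n),
    element = rep_len(element, n),
    vdw = rep_len(vdw, n)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ring_points_test <- function(radius, z, n) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(a), radius * sin(a), z)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
    2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
    2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3)
}
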