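# Counting volumes: cylinder, box (with Fermi-smoothed borders), sphere.
# All regions are closed sets: points exactly on the boundary count as inside
# (a measure-zero convention that matters only for hand-built fixtures).

#' Cylindrical counting region along a pore axis
#'
#' The cylinder is coaxial with `axis`; `z_top`/`z_bottom` are signed axial
#' coordinates (angstrom) relative to the axis origin, positive along the axis
#' direction.
#'
#' @param axis a `pore_axis`.
#' @param radius cylinder radius in angstrom.
#' @param z_top axial coordinate of the top face (angstrom).
#' @param z_bottom axial coordinate of the bottom face (angstrom).
#' @return object of class `cylinder_region`.
#' @export
cylinder_region <- function(axis, radius, z_top, z_bottom) {
  stopifnot(inherits(axis, "pore_axis"))
  if (radius <= 0) stop("cylinder radius must be positive")
  if (z_bottom >= z_top) stop("z_bottom must be below z_top")
  structure(list(axis = axis, radius = radius, z_top = z_top,
                 z_bottom = z_bottom), class = c("cylinder_region", "region"))
}

#' Rectangular counting box with Fermi-smoothed borders
#'
#' Houses the counting volume of the restrained water-count collective
#' variable. The smoothed per-atom weight is a separable product over the box
#' axes of Fermi factors `f(d) = 1 / (1 + exp(d / lambda))` evaluated at the
#' signed distance `d = |u_a| - L_a` outside each face; `fermi_lambda = 0`
#' reduces to the sharp indicator.
#'
#' @param center box center (length-3, angstrom).
#' @param half_lengths positive half-lengths per box axis (angstrom).
#' @param orientation 3x3 orthonormal matrix whose columns are the box axes
#'   (default: identity, laboratory axes).
#' @param fermi_lambda Fermi smoothing parameter in angstrom (>= 0);
#'   3 angstrom is the conventional value for the water-count variable.
#' @return object of class `box_region`.
#' @export
box_region <- function(center, half_lengths, orientation = diag(3),
                       fermi_lambda = 0) {
  center <- as.numeric(center)
  half_lengths <- as.numeric(half_lengths)
  stopifnot(length(center) == 3L, length(half_lengths) == 3L)
  if (any(half_lengths <= 0)) stop("half_lengths must be positive")
  if (fermi_lambda < 0) stop("fermi_lambda must be >= 0")
  orientation <- as.matrix(orientation)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6) {
    stop("orientation must be orthonormal")
  }
  structure(list(center = center, half_lengths = half_lengths,
                 orientation = orientation, fermi_lambda = fermi_lambda),
            class = c("box_region", "region"))
}

#' Spherical counting region
#'
#' Houses the lipid tail-carbon density collective variable (conventionally a
#' 7 angstrom sphere centered at the ring of pore-facing phenylalanines).
#'
#' @param center sphere center (length-3, angstrom).
#' @param radius sphere radius in angstrom.
#' @return object of class `sphere_region`.
#' @export
sphere_region <- function(center, radius) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (radius <= 0) stop("sphere radius must be positive")
  structure(list(center = center, radius = radius),
            class = c("sphere_region", "region"))
}

#' Test points for region membership
#'
#' @param region a `cylinder_region`, `box_region` or `sphere_region`.
#' @param xyz m x 3 coordinate matrix (angstrom).
#' @return logical vector of length m; boundary points are inside.
#' @export
region_contains <- function(region, xyz) UseMethod("region_contains")

#' @export
region_contains.cylinder_region <- function(region, xyz) {
  xyz <- rbind(xyz)
  u <- sweep(xyz, 2, region$axis$origin, "-")
  z <- as.vector(u %*% region$axis$direction)
  rad2 <- rowSums(u^2) - z^2
  z >= region$z_bottom & z <= region$z_top &
    rad2 <= region$radius^2 + 1e-12
}

#' @export
region_contains.box_region <- function(region, xyz) {
  xyz <- rbind(xyz)
  u <- abs(sweep(xyz, 2, region$center, "-") %*% region$orientation)
  u[, 1] <= region$half_lengths[1] & u[, 2] <= region$half_lengths[2] &
    u[, 3] <= region$half_lengths[3]
}

#' @export
region_contains.sphere_region <- function(region, xyz) {
  xyz <- rbind(xyz)
  d2 <- rowSums(sweep(xyz, 2, region$center, "-")^2)
  d2 <= region$radius^2 + 1e-12
}

# Fermi switching function: 1 deep inside (d << 0), 1/2 at the border (d = 0),
# 0 far outside. lambda = 0 gives the sharp closed-region indicator.
fermi_switch <- function(d, lambda) {
  if (lambda == 0) return(as.numeric(d <= 0))
  1 / (1 + exp(d / lambda))
}

#' Rigidly transform a region
#'
#' Applies the same rotation + translation used by [transform_frame()], so
#' that point-in-region tests transform covariantly.
#'
#' @param region a region object.
#' @param R 3x3 rotation matrix.
#' @param shift length-3 translation.
#' @return transformed region of the same class.
#' @export
transform_region <- function(region, R = diag(3), shift = c(0, 0, 0)) {
  if (inherits(region, "cylinder_region")) {
    ax <- region$axis
    ax2 <- pore_axis_from(as.vector(R %*% ax$origin) + shift,
                          as.vector(R %*% ax$direction))
    region$axis <- ax2
  } else if (inherits(region, "box_region")) {
    region$center <- as.vector(R %*% region$center) + shift
    region$orientation <- R %*% region$orientation
  } else if (inherits(region, "sphere_region")) {
    region$center <- as.vector(R %*% region$center) + shift
  } else stop("unsupported region")
  region
}
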