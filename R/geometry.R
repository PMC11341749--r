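# Axisymmetric stenosis geometry and structured body-fitted meshing.

#' Axisymmetric stenosis geometry
#'
#' Dimensionless geometry of an idealised stenosed artery: unstenosed pipe
#' radius 1, occlusion height `h`, flat throat half-length `l1` and ramp
#' length `l2` (steepness scales with `h/l2`). The constriction is symmetric
#' about `z = 0`; the inlet sits at `z_i` and the outlet at `z_o`, far
#' enough downstream to contain any recirculation zone.
#'
#' @param h Stenosis height, `0 <= h < 1` (fraction of the radius occluded).
#' @param l1 Half-length of the flat throat, `> 0`.
#' @param l2 Ramp length, `> 0`.
#' @param z_i Inlet position (`< -(l1 + l2)`), default -10.
#' @param z_o Outlet position (`> l1 + l2`), default `30 + l1 + l2`.
#' @return An object of class `stenosis_geometry`.
#' @export
stenosis_geometry <- function(h = 0.5, l1 = 1.5, l2 = 2, z_i = -10,
                              z_o = 30 + l1 + l2) {
  if (h < 0 || h >= 1) stop("h must lie in [0, 1)")
  if (l1 <= 0 || l2 <= 0) stop("l1 and l2 must be positive")
  if (z_i >= -(l1 + l2)) stop("z_i must lie upstream of the ramp, z_i < -(l1+l2)")
  if (z_o <= l1 + l2) stop("z_o must lie downstream of the ramp, z_o > l1+l2")
  structure(list(h = h, l1 = l1, l2 = l2, z_i = z_i, z_o = z_o),
            class = "stenosis_geometry")
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat(sprintf("stenosis: h = %g, l1 = %g, l2 = %g (steepness h/l2 = %.3g), z in [%g, %g]\n",
              x$h, x$l1, x$l2, x$h / x$l2, x$z_i, x$z_o))
  invisible(x)
}

#' Wall radius of the stenosed pipe
#'
#' The wall is the C1 flat-topped cosine bump
#' \eqn{r_w(z) = 1 - h B(|z|)} with `B = 1` over the throat
#' (`|z| <= l1`), a half-cosine ramp over `l1 < |z| <= l1 + l2`, and `B = 0`
#' beyond. The steepest wall slope is `pi*h/(2*l2)`. `wall_slope()` and
#' `wall_curvature()` give the analytic first and second derivatives used by
#' the body-fitted coordinate transform.
#'
#' @param z Axial position(s), inside `[z_i, z_o]`.
#' @param geom A [stenosis_geometry()].
#' @return Wall radius (in `[1 - h, 1]`), slope, or second derivative.
#' @export
wall_profile <- function(z, geom) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (any(z < geom$z_i - 1e-12) || any(z > geom$z_o + 1e-12))
    stop("z outside the domain [z_i, z_o]")
  az <- abs(z)
  B <- ifelse(az <= geom$l1, 1,
              ifelse(az <= geom$l1 + geom$l2,
                     0.5 * (1 + cos(pi * (az - geom$l1) / geom$l2)), 0))
  1 - geom$h * B
}

#' @rdname wall_profile
#' @export
wall_slope <- function(z, geom) {
  az <- abs(z)
  ramp <- az > geom$l1 & az <= geom$l1 + geom$l2
  out <- numeric(length(z))
  out[ramp] <- geom$h * pi / (2 * geom$l2) *
    sin(pi * (az[ramp] - geom$l1) / geom$l2) * sign(z[ramp])
  out
}

#' @rdname wall_profile
#' @export
wall_curvature <- function(z, geom) {
  az <- abs(z)
  ramp <- az > geom$l1 & az <= geom$l1 + geom$l2
  out <- numeric(length(z))
  out[ramp] <- geom$h * pi^2 / (2 * geom$l2^2) *
    cos(pi * (az[ramp] - geom$l1) / geom$l2)
  out
}

#' Mesh resolution specification
#'
#' Controls the structured body-fitted grid: axial spacing `dz` in the
#' refined window around the stenosis, growing geometrically to at most
#' `dz_max` towards inlet and outlet; `nr` radial lines with a tanh
#' clustering of strength `wall_cluster` towards the wall (boundary-layer
#' grading).
#'
#' @param dz Fine axial cell size over the stenosis (`> 0`).
#' @param dz_max Far-field axial cell size (`>= dz`).
#' @param nr Number of radial nodes (`>= 8`).
#' @param wall_cluster Radial clustering strength (`> 0`); larger values
#'   concentrate more lines near the wall.
#' @param growth Geometric growth ratio of axial spacing outside the
#'   refined window.
#' @param refine_upstream,refine_downstream Extent (in radii) of the
#'   refined window beyond the ramp ends.
#' @return An object of class `mesh_spec`.
#' @export
mesh_spec <- function(dz = 0.06, dz_max = 0.6, nr = 44, wall_cluster = 1.5,
                      growth = 1.12, refine_upstream = 2,
                      refine_downstream = 8) {
  if (dz <= 0 || dz_max < dz) stop("need 0 < dz <= dz_max")
  if (nr < 8) stop("nr must be at least 8")
  if (wall_cluster <= 0 || growth <= 1) stop("wall_cluster > 0 and growth > 1 required")
  structure(list(dz = dz, dz_max = dz_max, nr = as.integer(nr),
                 wall_cluster = wall_cluster, growth = growth,
                 refine_upstream = refine_upstream,
                 refine_downstream = refine_downstream),
            class = "mesh_spec")
}

# Graded 1-D node sequence from a fine uniform window out to the ends.
graded_axis <- function(z_lo, z_hi, fine_lo, fine_hi, dz, dz_max, growth) {
  fine_lo <- max(fine_lo, z_lo); fine_hi <- min(fine_hi, z_hi)
  mid <- seq(fine_lo, fine_hi, by = dz)
  if (mid[length(mid)] < fine_hi - 1e-9) mid <- c(mid, fine_hi)
  left <- numeric(0); zc <- fine_lo; step <- dz
  while (zc > z_lo + 1e-9) {
    step <- min(step * growth, dz_max, zc - z_lo)
    step <- max(step, min(dz, zc - z_lo))
    zc <- zc - step
    left <- c(zc, left)
  }
  right <- numeric(0); zc <- fine_hi; step <- dz
  while (zc < z_hi - 1e-9) {
    step <- min(step * growth, dz_max, z_hi - zc)
    zc <- zc + step
    right <- c(right, zc)
  }
  z <- c(left, mid, right)
  z[c(TRUE, diff(z) > 1e-10)]
}

#' Build the structured body-fitted mesh
#'
#' Constructs the computational grid for the stenosed pipe: axial nodes
#' `z[i]` (graded per the [mesh_spec()]) and radial lines `eta[j]` in
#' `[0, 1]` that follow the wall, with physical radius
#' `r = eta * r_w(z)`. The four boundaries carry the tags `inlet`
#' (`z = z_i`), `outlet` (`z = z_o`), `wall` (`eta = 1`) and `axis`
#' (`eta = 0`). Nodes are numbered radial-line first (`k = (i-1)*nr + j`).
#'
#' @param geom A [stenosis_geometry()].
#' @param spec A [mesh_spec()].
#' @return An object of class `stenosis_mesh`: node coordinates, analytic
#'   wall radius/slope/curvature per axial station, boundary index sets,
#'   and grid-quality statistics.
#' @export
build_mesh <- function(geom, spec = mesh_spec()) {
  stopifnot(inherits(geom, "stenosis_geometry"), inherits(spec, "mesh_spec"))
  ramp <- geom$l1 + geom$l2
  z <- graded_axis(geom$z_i, geom$z_o,
                   -ramp - spec$refine_upstream, ramp + spec$refine_downstream,
                   spec$dz, spec$dz_max, spec$growth)
  nz <- length(z)
  nr <- spec$nr
  q <- seq(0, 1, length.out = nr)
  eta <- tanh(spec$wall_cluster * q) / tanh(spec$wall_cluster)
  eta[1] <- 0; eta[nr] <- 1
  R <- wall_profile(z, geom)
  Rp <- wall_slope(z, geom)
  Rpp <- wall_curvature(z, geom)
  n <- nz * nr
  idx <- function(i, j) (i - 1L) * nr + j
  bnd <- list(axis = idx(seq_len(nz), 1L),
              wall = idx(seq_len(nz), nr),
              inlet = idx(1L, 2:(nr - 1L)),
              outlet = idx(nz, 2:(nr - 1L)))
  r_nodes <- as.vector(t(outer(R, eta)))          # k = (i-1)*nr + j
  z_nodes <- rep(z, each = nr)
  dz_all <- diff(z)
  quality <- list(n_nodes = n, nz = nz, nr = nr,
                  dz_range = range(dz_all),
                  dr_wall = (eta[nr] - eta[nr - 1]) * min(R),
                  max_aspect = max(dz_all) / ((eta[2] - eta[1]) * min(R)))
  structure(list(geom = geom, spec = spec, z = z, eta = eta,
                 R = R, Rp = Rp, Rpp = Rpp, nz = nz, nr = nr, n = n,
                 r_nodes = r_nodes, z_nodes = z_nodes,
                 boundary = bnd, quality = quality),
            class = "stenosis_mesh")
}

#' @export
print.stenosis_mesh <- function(x, ...) {
  cat(sprintf("stenosis_mesh: %d x %d = %d nodes, dz in [%.3g, %.3g], wall dr = %.3g\n",
              x$nz, x$nr, x$n, x$quality$dz_range[1], x$quality$dz_range[2],
              x$quality$dr_wall))
  print(x$geom)
  invisible(x)
}
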