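# Steady axisymmetric Navier-Stokes in streamfunction-vorticity form.
#
# With w = (1/r) dpsi/dr, u = -(1/r) dpsi/dz and azimuthal vorticity
# omega = du/dz - dw/dr, the steady dimensionless equations become
#   E^2 psi + r omega = 0,          E^2 = d_rr - (1/r) d_r + d_zz
#   u om_r + w om_z - u om / r - (1/Re)(Lap om - om/r^2) = 0.
# Continuity is identically satisfied, and the volumetric flux through
# every cross-section equals the inlet flux by construction
# (2 pi (psi_wall - psi_axis) is constant).
#
# Boundary conditions: parabolic inlet (psi = r^2/2 - r^4/4, omega = 2r),
# axis psi = omega = 0, wall psi = 1/4 with no-slip enforced through a
# one-sided second-order wall-vorticity closure (psi_eta = 0), and fully
# developed outflow (d/dz = 0 for both unknowns).

inlet_psi <- function(r) r^2 / 2 - r^4 / 4

flow_boundary_system <- function(mesh, ops) {
  n <- mesh$n; nr <- mesh$nr
  bnd <- mesh$boundary
  bc_rows <- integer(0); bc_cols <- integer(0); bc_vals <- numeric(0)
  rhs <- numeric(2 * n)
  add <- function(rows, cols, vals) {
    bc_rows <<- c(bc_rows, rows); bc_cols <<- c(bc_cols, cols)
    bc_vals <<- c(bc_vals, vals)
  }
  # axis: psi = 0, omega = 0
  add(bnd$axis, bnd$axis, rep(1, length(bnd$axis)))
  add(n + bnd$axis, n + bnd$axis, rep(1, length(bnd$axis)))
  # inlet: psi = psi_in(r), omega = 2 r
  add(bnd$inlet, bnd$inlet, rep(1, length(bnd$inlet)))
  rhs[bnd$inlet] <- inlet_psi(mesh$r_nodes[bnd$inlet])
  add(n + bnd$inlet, n + bnd$inlet, rep(1, length(bnd$inlet)))
  rhs[n + bnd$inlet] <- 2 * mesh$r_nodes[bnd$inlet]
  # outlet: fully developed, d(psi)/dxi = d(omega)/dxi = 0 (one-sided rows)
  Dxi <- ops$Dxi
  for (k in bnd$outlet) {
    row <- Dxi[k, , drop = FALSE]
    nzc <- Matrix::which(row != 0)
    add(rep(k, length(nzc)), nzc, as.numeric(row[1, nzc]))
    add(rep(n + k, length(nzc)), n + nzc, as.numeric(row[1, nzc]))
  }
  # wall: psi = flux constant; vorticity closure from psi_etaeta with
  # psi_eta = 0 (one-sided, second order in the last two spacings)
  wall <- bnd$wall
  add(wall, wall, rep(1, length(wall)))
  rhs[wall] <- inlet_psi(1)
  # quartic fit through the three near-wall points with psi_eta(wall) = 0
  # gives psi_etaeta at the wall exactly for quartic profiles (Poiseuille)
  dd <- mesh$eta[nr] - mesh$eta[(nr - 1):(nr - 3)]
  Mfit <- cbind(dd^2 / 2, -dd^3 / 6, dd^4 / 24)
  wfit <- solve(Mfit)[1, ]   # psi'' = sum_k wfit[k] (psi_{nr-k} - psi_w)
  coef <- (1 + mesh$Rp^2) / mesh$R^2
  rw <- mesh$r_nodes[wall]
  for (k in 1:3) add(n + wall, wall - k, coef * wfit[k])
  add(n + wall, wall, -coef * sum(wfit))
  add(n + wall, n + wall, rw)
  J_bc <- Matrix::sparseMatrix(i = bc_rows, j = bc_cols, x = bc_vals,
                               dims = c(2 * n, 2 * n))
  bmask <- rep(1, 2 * n)
  bmask[c(bnd$axis, bnd$inlet, bnd$outlet, wall)] <- 0
  bmask[n + c(bnd$axis, bnd$inlet, bnd$outlet, wall)] <- 0
  list(J_bc = J_bc, rhs = rhs, interior = bmask)
}

velocity_from_psi <- function(mesh, ops, psi) {
  u <- -as.numeric(ops$Dz %*% psi) / ops$rsafe
  w <- as.numeric(ops$Dr %*% psi) / ops$rsafe
  axis <- mesh$boundary$axis
  u[axis] <- 0
  w[axis] <- as.numeric(ops$Drr %*% psi)[axis]
  wall <- mesh$boundary$wall     # no-slip is exact; do not leave the
  u[wall] <- 0                   # one-sided derivative's truncation there
  w[wall] <- 0
  list(u = u, w = w)
}

#' Steady axisymmetric flow through the stenosed pipe
#'
#' Solves the steady dimensionless Navier-Stokes equations in
#' streamfunction-vorticity form on the body-fitted mesh, by Newton
#' iteration with continuation in Reynolds number from a Stokes start.
#' Advection is discretised with first-order upwinding inside the Newton
#' loop and sharpened to second-order upwinding by defect-correction
#' iterations, so the converged solution carries second-order convective
#' accuracy. The volumetric flux is conserved identically by the
#' streamfunction formulation.
#'
#' @param mesh A [build_mesh()] result.
#' @param Re Reynolds number, in `(0, 500]` (the steady laminar regime).
#' @param re_step Maximum continuation step in Re.
#' @param tol Relative residual reduction required (also bounded by an
#'   absolute floor scaled with Re).
#' @param max_iter Newton iterations allowed per continuation step.
#' @param defect Logical; apply second-order defect correction (default
#'   TRUE).
#' @param quiet Suppress progress messages.
#' @return An object of class `flow_field`: node vectors `psi`, `omega`,
#'   `u` (radial velocity), `w` (axial velocity), the mesh, `Re`, and
#'   residual diagnostics.
#' @export
solve_flow <- function(mesh, Re, re_step = 100, tol = 1e-10, max_iter = 50,
                       defect = TRUE, quiet = TRUE) {
  stopifnot(inherits(mesh, "stenosis_mesh"))
  if (Re <= 0 || Re > 500)
    stop("Re must lie in (0, 500], the steady laminar regime")
  ops <- get_ops(mesh)
  n <- mesh$n
  bc <- flow_boundary_system(mesh, ops)
  Pint <- sdiag(bc$interior)
  rvec <- ops$rsafe
  visc_op <- ops$Lap - sdiag(1 / rvec^2)

  residual <- function(x, order) {
    psi <- x[1:n]; om <- x[(n + 1):(2 * n)]
    vel <- velocity_from_psi(mesh, ops, psi)
    c_xi <- vel$w
    c_eta <- vel$u / ops$Rn + vel$w * ops$e
    Adv <- advection_operator(ops, c_xi, c_eta, order)
    Rpsi <- as.numeric(ops$Eop %*% psi) + ops$r * om
    Rom <- as.numeric(Adv %*% om) - vel$u * om / rvec -
      (1 / Re) * as.numeric(visc_op %*% om)
    bc$interior * c(Rpsi, Rom) +
      as.numeric(bc$J_bc %*% x) - bc$rhs
  }

  jacobian <- function(x) {
    psi <- x[1:n]; om <- x[(n + 1):(2 * n)]
    vel <- velocity_from_psi(mesh, ops, psi)
    c_xi <- vel$w
    c_eta <- vel$u / ops$Rn + vel$w * ops$e
    pz <- as.numeric(c_xi >= 0); pe <- as.numeric(c_eta >= 0)
    Dz_up <- sdiag(pz) %*% ops$up$z_bw1 + sdiag(1 - pz) %*% ops$up$z_fw1
    De_up <- sdiag(pe) %*% ops$up$e_bw1 + sdiag(1 - pe) %*% ops$up$e_fw1
    Adv <- sdiag(c_xi) %*% Dz_up + sdiag(c_eta) %*% De_up
    dU <- sdiag(-1 / rvec) %*% ops$Dz
    dW <- sdiag(1 / rvec) %*% ops$Dr
    Joo <- Adv - sdiag(vel$u / rvec) - (1 / Re) * visc_op
    Jop <- sdiag(as.numeric(Dz_up %*% om)) %*% dW +
      sdiag(as.numeric(De_up %*% om)) %*%
      (sdiag(1 / ops$Rn) %*% dU + sdiag(ops$e) %*% dW) -
      sdiag(om / rvec) %*% dU
    J <- rbind(cbind(ops$Eop, sdiag(ops$r)), cbind(Jop, Joo))
    Pint %*% J + bc$J_bc
  }

  # Stokes start (linear)
  Zn <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, n))
  Alin <- rbind(cbind(ops$Eop, sdiag(ops$r)),
                cbind(Zn, -(1 / Re) * visc_op))
  Astokes <- Pint %*% Alin + bc$J_bc
  x <- as.numeric(Matrix::solve(Astokes, bc$rhs))

  re_seq <- unique(c(seq(min(re_step, Re), Re, by = re_step), Re))
  hist <- list()
  for (re_now in re_seq) {
    Re_save <- Re; Re <- re_now
    r0 <- max(abs(residual(x, 1)))
    target <- max(tol * max(r0, 1), 1e-11 * (1 + re_now))
    it <- 0
    repeat {
      R <- residual(x, 1)
      rn <- max(abs(R))
      if (rn <= target) break
      it <- it + 1
      if (it > max_iter)
        stop(sprintf("Newton divergence at Re = %g (residual %.3g); try smaller re_step", re_now, rn))
      J <- jacobian(x)
      dx <- as.numeric(Matrix::solve(J, -R))
      step <- 1
      repeat {
        xn <- x + step * dx
        rn_new <- max(abs(residual(xn, 1)))
        if (is.finite(rn_new) && rn_new < rn) break
        step <- step / 2
        if (step < 1e-4)
          stop(sprintf("line search failed at Re = %g (residual %.3g); try smaller re_step", re_now, rn))
      }
      x <- xn
      if (!quiet) message(sprintf("  Re %g it %d residual %.3e (step %.3g)", re_now, it, rn_new, step))
    }
    hist[[length(hist) + 1]] <- c(Re = re_now, res = max(abs(residual(x, 1))))
    Re <- Re_save
  }

  res2 <- NA_real_
  if (defect) {
    J <- jacobian(x)
    fac <- Matrix::lu(J)
    r0 <- max(abs(residual(x, 2)))
    target2 <- max(tol * max(r0, 1), 1e-10 * (1 + Re))
    best <- r0
    for (it in 1:80) {
      R2 <- residual(x, 2)
      res2 <- max(abs(R2))
      if (res2 <= target2) break
      dx <- as.numeric(Matrix::solve(fac, -R2))
      step <- 1
      repeat {
        xn <- x + step * dx
        rn_new <- max(abs(residual(xn, 2)))
        if (is.finite(rn_new) && rn_new < res2 * (1 + 1e-9)) break
        step <- step / 2
        if (step < 1e-3) break
      }
      if (step < 1e-3) {            # refresh the frozen Jacobian
        J <- jacobian(x); fac <- Matrix::lu(J)
        dx <- as.numeric(Matrix::solve(fac, -R2))
        xn <- x + dx
        if (max(abs(residual(xn, 2))) > res2) break
      }
      x <- xn
      if (res2 < best) best <- res2
    }
  }

  psi <- x[1:n]; om <- x[(n + 1):(2 * n)]
  vel <- velocity_from_psi(mesh, ops, psi)
  out <- structure(list(mesh = mesh, Re = Re, psi = psi, omega = om,
                        u = vel$u, w = vel$w,
                        residual_first_order = hist[[length(hist)]][["res"]],
                        residual_second_order = res2),
                   class = "flow_field")
  attr(out, "ops") <- ops
  out
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: Re = %g on %d x %d mesh; max |w| = %.4g; residual %.2e (2nd-order %.2e)\n",
              x$Re, x$mesh$nz, x$mesh$nr, max(abs(x$w)),
              x$residual_first_order, x$residual_second_order))
  invisible(x)
}

#' Scalar shear- and rotation-rate fields of a flow
#'
#' Computes the axisymmetric velocity-gradient tensor (including the hoop
#' strain rate `u/r`) and returns \eqn{\dot\gamma = \sqrt{2 D:D}} and
#' \eqn{\dot\omega = \sqrt{2 W:W}} at every node, along with the gradient
#' components. For Poiseuille flow \eqn{\dot\gamma = 2r} exactly and the
#' two rates coincide (simple shear).
#'
#' @param flow A [solve_flow()] result.
#' @return A list of node vectors: `gamma_dot`, `omega_dot`, `l_rr`,
#'   `l_rz`, `l_zr`, `l_zz`, `hoop` and the divergence `div` (a
#'   discretisation check).
#' @export
rate_fields <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  mesh <- flow$mesh; ops <- get_ops_flow(flow)
  l_rr <- as.numeric(ops$Dr %*% flow$u)
  l_rz <- as.numeric(ops$Dz %*% flow$u)
  l_zr <- as.numeric(ops$Dr %*% flow$w)
  l_zz <- as.numeric(ops$Dz %*% flow$w)
  hoop <- flow$u / ops$rsafe
  hoop[mesh$boundary$axis] <- l_rr[mesh$boundary$axis]
  d_rz <- (l_rz + l_zr) / 2
  w_rz <- (l_rz - l_zr) / 2
  list(gamma_dot = sqrt(2 * (l_rr^2 + l_zz^2 + hoop^2) + 4 * d_rz^2),
       omega_dot = 2 * abs(w_rz),
       l_rr = l_rr, l_rz = l_rz, l_zr = l_zr, l_zz = l_zz, hoop = hoop,
       div = l_rr + l_zz + hoop)
}

get_ops_flow <- function(flow) {
  ops <- attr(flow, "ops")
  if (is.null(ops)) ops <- get_ops(flow$mesh)
  ops
}

#' Detect a downstream recirculation zone
#'
#' A recirculation zone reveals itself through reversed wall shear: the
#' wall vorticity changes sign downstream of the constriction. Returns
#' whether reversed flow exists and the axial interval over which the wall
#' shear is negative.
#'
#' @param flow A [solve_flow()] result.
#' @param rel_tol Sign threshold relative to the maximum wall vorticity.
#' @return A list with `exists` (logical) and `extent` (z-interval, or
#'   `NULL`).
#' @export
detect_recirculation <- function(flow, rel_tol = 1e-4) {
  mesh <- flow$mesh
  wall <- mesh$boundary$wall
  om_w <- flow$omega[wall]
  z <- mesh$z
  rev <- om_w < -rel_tol * max(abs(om_w))
  rev[z < 0] <- FALSE            # only downstream separation is of interest
  if (!any(rev)) return(list(exists = FALSE, extent = NULL))
  list(exists = TRUE, extent = range(z[rev]))
}
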