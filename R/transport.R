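# Steady transport of the VWF configuration tensor on a computed flow.
#
# Dimensionless form (one-way coupled, planar tensor in the (r,z) plane):
#   xi Re ( u . grad A - L A - A L^T - (1/Pe) Lap A )
#       = -(1/tau_hat(gamma_dot)) (f(A) A - a I),
# with L_ij = du_i/dx_j, tau_hat the dimensionless saturating relaxation
# time, and a small artificial diffusivity 1/Pe (relative to the advective
# scale) regularising the otherwise hyperbolic equation.
#
# Boundary conditions: Dirichlet inlet profile (local steady-shear
# solution), symmetry dA/dr = 0 on the axis, and no normal diffusive flux
# at the wall and outlet.

#' Inlet configuration-tensor profile
#'
#' The inlet condition for the transport solve: at each radius the
#' homogeneous steady-shear solution at the local dimensionless shear rate
#' of the parabolic inlet flow (`gamma_dot_hat = 2r` from `w = 1 - r^2`),
#' with the effective Weissenberg product
#' `xi * Re * gamma_dot_hat * tau_hat`, rotated into `(r, z)` components.
#' The off-diagonal sign follows the sign of `dw/dr` (negative for
#' `r > 0`).
#'
#' @param r Radii in `[0, 1]`.
#' @param groups A `dimensionless_groups` object (see
#'   [groups_from_table()]).
#' @return A data frame with columns `r`, `a_rr`, `a_rz`, `a_zz`.
#' @export
inlet_profile <- function(r, groups) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]")
  g_hat <- 2 * r
  s <- groups$xi * groups$Re * g_hat * relaxation_time_hat(g_hat, groups)
  comp <- shear_components(s, groups$L_max)
  data.frame(r = r, a_rr = comp$a_22, a_rz = -comp$a_12, a_zz = comp$a_11)
}

#' Steady configuration-tensor field on a flow
#'
#' Solves the steady dimensionless FENE-P transport equation for the three
#' planar tensor components on a converged [solve_flow()] field, with
#' upwinded advection, artificial diffusion at Peclet number `Pe`, and
#' Newton iteration (analytic Jacobian, pseudo-transient continuation for
#' robustness). The flow is frozen: the model is one-way coupled.
#'
#' @param flow A [solve_flow()] result.
#' @param groups A `dimensionless_groups` object carrying `xi`, `Re`,
#'   `beta_hat`, `gamma_star_hat`, `delta` and `L_max`; its `Re` is
#'   overridden by the flow's.
#' @param Pe Artificial-diffusion Peclet number (default 1e3).
#' @param tol Residual tolerance (max-norm, relative to the initial
#'   residual with an absolute floor).
#' @param max_iter Newton iterations allowed.
#' @param quiet Suppress progress messages.
#' @return An object of class `tensor_field`: node vectors `a_rr`, `a_rz`,
#'   `a_zz`, derived `length` and `extension`, the relaxation-time and
#'   shear-rate fields used, `Pe`, and references to mesh and flow.
#' @export
solve_vwf_field <- function(flow, groups, Pe = 1e3, tol = 1e-8,
                            max_iter = 60, quiet = TRUE) {
  stopifnot(inherits(flow, "flow_field"),
            inherits(groups, "dimensionless_groups"))
  if (Pe <= 0) stop("Pe must be positive")
  groups$Re <- flow$Re
  mesh <- flow$mesh
  ops <- get_ops_flow(flow)
  n <- mesh$n
  L2 <- groups$L_max^2
  a_nat <- natural_constant(groups$L_max)
  xiRe <- groups$xi * groups$Re

  rates <- rate_fields(flow)
  tau_hat <- relaxation_time_hat(rates$gamma_dot, groups)
  itau <- 1 / tau_hat

  c_xi <- flow$w
  c_eta <- flow$u / ops$Rn + flow$w * ops$e
  Adv <- advection_operator(ops, c_xi, c_eta, 1)
  Tlin <- xiRe * (Adv - (1 / Pe) * ops$Lap)   # advection + diffusion, per component

  l_rr <- rates$l_rr; l_rz <- rates$l_rz; l_zr <- rates$l_zr; l_zz <- rates$l_zz

  # boundary bookkeeping (per component)
  bnd <- mesh$boundary
  bdry_all <- c(bnd$axis, bnd$wall, bnd$inlet, bnd$outlet)
  interior <- rep(1, n); interior[bdry_all] <- 0

  # the axis and wall corners at the inlet keep their axis/wall rows;
  # Dirichlet rows cover the inlet strip proper
  inlet_idx <- bnd$inlet
  prof_in <- inlet_profile(mesh$r_nodes[inlet_idx], groups)

  # BC operator rows, identical for each tensor component
  bc_i <- integer(0); bc_j <- integer(0); bc_x <- numeric(0)
  addbc <- function(i, j, x) {
    bc_i <<- c(bc_i, i); bc_j <<- c(bc_j, j); bc_x <<- c(bc_x, x)
  }
  addbc(inlet_idx, inlet_idx, rep(1, length(inlet_idx)))
  # axis: dA/deta = 0 (symmetry); one-sided first-derivative rows
  Deta <- ops$Deta
  for (k in bnd$axis) {
    row <- Deta[k, , drop = FALSE]
    nzc <- Matrix::which(row != 0)
    addbc(rep(k, length(nzc)), nzc, as.numeric(row[1, nzc]))
  }
  # outlet: dA/dxi = 0
  Dxi <- ops$Dxi
  for (k in setdiff(bnd$outlet, bnd$axis)) {
    row <- Dxi[k, , drop = FALSE]
    nzc <- Matrix::which(row != 0)
    addbc(rep(k, length(nzc)), nzc, as.numeric(row[1, nzc]))
  }
  # wall: no normal diffusive flux, (1+R'^2)/R dA/deta - R' dA/dxi = 0
  wall <- setdiff(bnd$wall, c(bnd$inlet, bnd$outlet))
  Rw <- rep(mesh$R, each = mesh$nr); Rpw <- rep(mesh$Rp, each = mesh$nr)
  for (k in wall) {
    rowe <- Deta[k, , drop = FALSE]; rowx <- Dxi[k, , drop = FALSE]
    ne <- Matrix::which(rowe != 0); nx <- Matrix::which(rowx != 0)
    addbc(rep(k, length(ne)), ne,
          (1 + Rpw[k]^2) / Rw[k] * as.numeric(rowe[1, ne]))
    addbc(rep(k, length(nx)), nx, -Rpw[k] * as.numeric(rowx[1, nx]))
  }
  Bc <- Matrix::sparseMatrix(i = bc_i, j = bc_j, x = bc_x, dims = c(n, n))
  # The off-diagonal component is odd in r: regularity demands A_rz = 0 on
  # the axis (the printed symmetry condition applies to the even
  # components). Replace its axis rows with Dirichlet rows.
  Ax <- sdiag(replace(rep(1, n), bnd$axis, 0))
  Bc_off <- Ax %*% Bc +
    Matrix::sparseMatrix(i = bnd$axis, j = bnd$axis,
                         x = rep(1, length(bnd$axis)), dims = c(n, n))
  rhs_bc <- list(a_rr = numeric(n), a_rz = numeric(n), a_zz = numeric(n))
  rhs_bc$a_rr[inlet_idx] <- prof_in$a_rr
  rhs_bc$a_rz[inlet_idx] <- prof_in$a_rz
  rhs_bc$a_zz[inlet_idx] <- prof_in$a_zz

  Pint <- sdiag(interior)
  Tmask <- Pint %*% Tlin + Bc        # linear transport part with BC rows
  Tmask_off <- Pint %*% Tlin + Bc_off

  residual <- function(X) {
    Arr <- X[1:n]; Arz <- X[(n + 1):(2 * n)]; Azz <- X[(2 * n + 1):(3 * n)]
    f <- L2 / (L2 - (Arr + Azz))
    S_rr <- 2 * (l_rr * Arr + l_rz * Arz)
    S_rz <- (l_rr + l_zz) * Arz + l_rz * Azz + l_zr * Arr
    S_zz <- 2 * (l_zr * Arz + l_zz * Azz)
    R_rr <- interior * (-xiRe * S_rr + itau * (f * Arr - a_nat)) +
      as.numeric(Tmask %*% Arr) - rhs_bc$a_rr
    R_rz <- interior * (-xiRe * S_rz + itau * (f * Arz)) +
      as.numeric(Tmask_off %*% Arz) - rhs_bc$a_rz
    R_zz <- interior * (-xiRe * S_zz + itau * (f * Azz - a_nat)) +
      as.numeric(Tmask %*% Azz) - rhs_bc$a_zz
    c(R_rr, R_rz, R_zz)
  }

  jacobian <- function(X, pseudo_dt = Inf) {
    Arr <- X[1:n]; Arz <- X[(n + 1):(2 * n)]; Azz <- X[(2 * n + 1):(3 * n)]
    T_tr <- Arr + Azz
    f <- L2 / (L2 - T_tr)
    dfdT <- f^2 / L2
    Di <- function(v) Pint %*% sdiag(v)
    J11 <- Tmask + Di(-2 * xiRe * l_rr + itau * (f + Arr * dfdT))
    J12 <- Di(-2 * xiRe * l_rz)
    J13 <- Di(itau * Arr * dfdT)
    J21 <- Di(-xiRe * l_zr + itau * Arz * dfdT)
    J22 <- Tmask_off + Di(-xiRe * (l_rr + l_zz) + itau * f)
    J23 <- Di(-xiRe * l_rz + itau * Arz * dfdT)
    J31 <- Di(itau * Azz * dfdT)
    J32 <- Di(-2 * xiRe * l_zr)
    J33 <- Tmask + Di(-2 * xiRe * l_zz + itau * (f + Azz * dfdT))
    J <- rbind(cbind(J11, J12, J13), cbind(J21, J22, J23),
               cbind(J31, J32, J33))
    if (is.finite(pseudo_dt))
      J <- J + (1 / pseudo_dt) * Matrix::Diagonal(3 * n)
    J
  }

  feasible <- function(X) {
    T_tr <- X[1:n] + X[(2 * n + 1):(3 * n)]
    all(is.finite(X)) && all(T_tr < (1 - 1e-9) * L2)
  }

  # initial guess: local steady-shear equilibrium at the local shear rate
  g0 <- rates$gamma_dot
  s0 <- xiRe * g0 * tau_hat
  shear_sign <- sign(l_zr + l_rz)
  shear_sign[shear_sign == 0] <- 1
  comp0 <- shear_components(s0, groups$L_max)
  X <- c(comp0$a_22, shear_sign * comp0$a_12, comp0$a_11)
  if (!feasible(X)) stop("infeasible initial tensor guess")

  r0 <- max(abs(residual(X)))
  target <- max(tol * max(r0, 1), 1e-10 * (1 + xiRe))
  dt <- 0.1
  rn <- r0
  for (it in seq_len(max_iter)) {
    R <- residual(X)
    rn <- max(abs(R))
    if (!quiet) message(sprintf("  transport it %d residual %.3e (dt %.3g)", it, rn, dt))
    if (rn <= target) break
    J <- jacobian(X, pseudo_dt = dt)
    dX <- as.numeric(Matrix::solve(J, -R))
    step <- 1
    repeat {
      Xn <- X + step * dX
      if (feasible(Xn) && max(abs(residual(Xn))) < rn * (1 + 1e-9)) break
      step <- step / 2
      if (step < 1e-4) break
    }
    if (step < 1e-4) { dt <- dt / 4; next }
    X <- Xn
    dt <- min(dt * 2.5, 1e12)
    if (it == max_iter)
      stop(sprintf("transport Newton did not converge (residual %.3g); consider a finer mesh or smaller Pe", rn))
  }
  if (rn > target)
    stop(sprintf("transport Newton did not converge (residual %.3g); consider a finer mesh or smaller Pe", rn))

  Arr <- X[1:n]; Arz <- X[(n + 1):(2 * n)]; Azz <- X[(2 * n + 1):(3 * n)]
  len <- sqrt((Arr + Azz) / 2)
  spd_ok <- all(Arr > 0) && all(Azz > 0) && all(Arr * Azz - Arz^2 > 0)
  out <- structure(list(mesh = mesh, flow = flow, Pe = Pe,
                        a_rr = Arr, a_rz = Arz, a_zz = Azz,
                        length = len, extension = len - 1,
                        gamma_dot = rates$gamma_dot, tau_hat = tau_hat,
                        groups = groups, residual = rn, spd = spd_ok),
                   class = "tensor_field")
  out
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: Pe = %g, max extension %.4g (of %.4g achievable), SPD %s, residual %.2e\n",
              x$Pe, max(x$extension), x$groups$L_max / sqrt(2) - 1,
              if (x$spd) "yes" else "NO", x$residual))
  invisible(x)
}
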