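# Sparse finite-difference operators on the body-fitted grid.
#
# Computational coordinates are (xi, eta) with xi = z and eta = r / R(z);
# for a scalar phi the physical derivatives follow from the chain rule with
# e = eta_z = -eta R'/R:
#   phi_r  = phi_eta / R
#   phi_z  = phi_xi + e phi_eta
#   phi_rr = phi_etaeta / R^2
#   phi_zz = phi_xixi + 2 e phi_xieta + e^2 phi_etaeta + e_z phi_eta,
# with e_z = eta (2 R'^2/R^2 - R''/R).

# Fornberg finite-difference weights for the m-th derivative at x0 from
# stencil nodes x (exact for polynomials of degree length(x)-1).
fd_weights <- function(x, x0, m) {
  n <- length(x)
  c_mat <- matrix(0, n, m + 1)
  c1 <- 1; c4 <- x[1] - x0
  c_mat[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i - 1, m)
    c2 <- 1; c5 <- c4; c4 <- x[i] - x0
    for (j in 1:(i - 1)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1) {
        for (k in mn:1)
          c_mat[i, k + 1] <- c1 * (k * c_mat[i - 1, k] - c5 * c_mat[i - 1, k + 1]) / c2
        c_mat[i, 1] <- -c1 * c5 * c_mat[i - 1, 1] / c2
      }
      for (k in mn:1)
        c_mat[j, k + 1] <- (c4 * c_mat[j, k + 1] - k * c_mat[j, k]) / c3
      c_mat[j, 1] <- c4 * c_mat[j, 1] / c3
    }
    c1 <- c2
  }
  c_mat[, m + 1]
}

# n x n sparse 1-D derivative matrix of order m on nodes x, centred
# np-point stencils inside, shifted near the ends (np = 5 in the radial
# direction makes the quartic Poiseuille streamfunction exact).
d_matrix_1d <- function(x, m, np = 3) {
  n <- length(x)
  np <- min(np, n)
  half <- (np - 1) %/% 2
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (i in seq_len(n)) {
    lo <- min(max(1, i - half), n - np + 1)
    s <- lo:(lo + np - 1)
    w <- fd_weights(x[s], x[i], m)
    ii <- c(ii, rep(i, length(s))); jj <- c(jj, s); vv <- c(vv, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

# One-sided 1-D first-derivative matrices for upwinding: direction "bw"
# uses nodes behind (flow from low to high index), "fw" ahead; order 1 or 2
# points beyond the node itself (falls back near the boundary).
d1_upwind_1d <- function(x, direction = c("bw", "fw"), order = 2) {
  direction <- match.arg(direction)
  n <- length(x)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (i in seq_len(n)) {
    s <- if (direction == "bw") max(1, i - order):i else i:min(n, i + order)
    if (length(s) == 1) s <- if (direction == "bw") i:min(n, i + 1) else max(1, i - 1):i
    w <- fd_weights(x[s], x[i], 1)
    ii <- c(ii, rep(i, length(s))); jj <- c(jj, s); vv <- c(vv, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

sdiag <- function(v) Matrix::Diagonal(x = v)

# All sparse operators and metric fields for a mesh; cached on the mesh by
# the solvers.
grid_operators <- function(mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  Iz <- Matrix::Diagonal(nz); Ir <- Matrix::Diagonal(nr)
  d1z <- d_matrix_1d(mesh$z, 1);  d2z <- d_matrix_1d(mesh$z, 2)
  d1e <- d_matrix_1d(mesh$eta, 1, 5); d2e <- d_matrix_1d(mesh$eta, 2, 5)
  Dxi <- Matrix::kronecker(d1z, Ir);  Dxixi <- Matrix::kronecker(d2z, Ir)
  Deta <- Matrix::kronecker(Iz, d1e); Detaeta <- Matrix::kronecker(Iz, d2e)
  Dxieta <- Matrix::kronecker(d1z, d1e)

  Rn <- rep(mesh$R, each = nr)
  Rpn <- rep(mesh$Rp, each = nr)
  eta_n <- rep(mesh$eta, nz)
  e <- -eta_n * Rpn / Rn
  ez <- eta_n * (2 * Rpn^2 / Rn^2 - rep(mesh$Rpp, each = nr) / Rn)
  r <- mesh$r_nodes
  rsafe <- r
  rsafe[r == 0] <- 1   # axis rows are always replaced by boundary rows

  Dr <- sdiag(1 / Rn) %*% Deta
  Dz <- Dxi + sdiag(e) %*% Deta
  Drr <- sdiag(1 / Rn^2) %*% Detaeta
  Dzz <- Dxixi + sdiag(2 * e) %*% Dxieta + sdiag(e^2) %*% Detaeta +
    sdiag(ez) %*% Deta
  Lap <- Drr + sdiag(1 / rsafe) %*% Dr + Dzz       # axisymmetric scalar
  Eop <- Drr - sdiag(1 / rsafe) %*% Dr + Dzz       # Stokes-stream operator

  up <- list(
    z_bw1 = Matrix::kronecker(d1_upwind_1d(mesh$z, "bw", 1), Ir),
    z_fw1 = Matrix::kronecker(d1_upwind_1d(mesh$z, "fw", 1), Ir),
    z_bw2 = Matrix::kronecker(d1_upwind_1d(mesh$z, "bw", 2), Ir),
    z_fw2 = Matrix::kronecker(d1_upwind_1d(mesh$z, "fw", 2), Ir),
    e_bw1 = Matrix::kronecker(Iz, d1_upwind_1d(mesh$eta, "bw", 1)),
    e_fw1 = Matrix::kronecker(Iz, d1_upwind_1d(mesh$eta, "fw", 1)),
    e_bw2 = Matrix::kronecker(Iz, d1_upwind_1d(mesh$eta, "bw", 2)),
    e_fw2 = Matrix::kronecker(Iz, d1_upwind_1d(mesh$eta, "fw", 2)))

  list(Dxi = Dxi, Deta = Deta, Dxixi = Dxixi, Detaeta = Detaeta,
       Dxieta = Dxieta, Dr = Dr, Dz = Dz, Drr = Drr, Dzz = Dzz,
       Lap = Lap, Eop = Eop, up = up,
       Rn = Rn, Rpn = Rpn, eta_n = eta_n, e = e, ez = ez,
       r = r, rsafe = rsafe)
}

get_ops <- function(mesh) {
  if (is.null(attr(mesh, "ops"))) grid_operators(mesh) else attr(mesh, "ops")
}

# Upwinded advection operator c_xi d/dxi + c_eta d/deta built from the
# per-node sign of the contravariant velocities. order 1 (robust, used for
# Jacobians) or 2 (used for defect-corrected residuals).
advection_operator <- function(ops, c_xi, c_eta, order = 1) {
  pz <- as.numeric(c_xi >= 0); pe <- as.numeric(c_eta >= 0)
  if (order == 1) {
    Dz_up <- sdiag(pz) %*% ops$up$z_bw1 + sdiag(1 - pz) %*% ops$up$z_fw1
    De_up <- sdiag(pe) %*% ops$up$e_bw1 + sdiag(1 - pe) %*% ops$up$e_fw1
  } else {
    Dz_up <- sdiag(pz) %*% ops$up$z_bw2 + sdiag(1 - pz) %*% ops$up$z_fw2
    De_up <- sdiag(pe) %*% ops$up$e_bw2 + sdiag(1 - pe) %*% ops$up$e_fw2
  }
  sdiag(c_xi) %*% Dz_up + sdiag(c_eta) %*% De_up
}
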