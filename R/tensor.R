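#' Planar configuration tensor
#'
#' The state variable of the FENE-P model: the symmetric, positive-definite
#' second moment \eqn{A_{ij} = \langle r_i r_j \rangle} of the protein
#' end-to-end vector, stored through its three unique components. The same
#' container serves Cartesian `(x, y)` components in homogeneous flows and
#' `(r, z)` components in the axisymmetric plane.
#'
#' @param a_11,a_12,a_22 Tensor components (dimensionless).
#' @param L_max Optional finite-extensibility bound; when supplied the
#'   constructor also rejects tensors at or beyond `Tr(A) >= L_max^2`.
#' @return An object of class `conf_tensor`.
#' @export
conf_tensor <- function(a_11, a_12, a_22, L_max = NULL) {
  if (!all(is.finite(c(a_11, a_12, a_22))))
    stop("tensor components must be finite")
  if (a_11 <= 0 || a_22 <= 0 || a_11 * a_22 - a_12^2 <= 0)
    stop("configuration tensor must be positive definite")
  if (!is.null(L_max) && a_11 + a_22 >= (1 - 1e-10) * L_max^2)
    stop("tensor at/beyond finite extensibility: Tr(A) >= L_max^2")
  structure(list(a_11 = a_11, a_12 = a_12, a_22 = a_22),
            class = "conf_tensor")
}

#' @export
print.conf_tensor <- function(x, ...) {
  cat(sprintf("conf_tensor  [%.6g %.6g; %.6g %.6g]  Tr = %.6g, length = %.6g\n",
              x$a_11, x$a_12, x$a_12, x$a_22, x$a_11 + x$a_22, vwf_length(x)))
  invisible(x)
}

#' @export
as.matrix.conf_tensor <- function(x, ...) {
  matrix(c(x$a_11, x$a_12, x$a_12, x$a_22), 2, 2)
}

tr_conf <- function(A) A$a_11 + A$a_22

#' Peterlin spring factor and its natural-state constant
#'
#' `fene_factor()` evaluates \eqn{f(A) = L^2/(L^2 - Tr(A))}, the nonlinear
#' spring stiffening that keeps the protein length below `L`.
#' `natural_constant()` evaluates \eqn{a = L^2/(L^2 - Tr(I))} with
#' `Tr(I) = 2` in the planar convention; `f(I) = a` makes `A = I` the exact
#' flow-free equilibrium.
#'
#' @param A A [conf_tensor()].
#' @param L_max Maximum length parameter `L`.
#' @return Dimensionless factor, `> 0`.
#' @export
fene_factor <- function(A, L_max) {
  stopifnot(inherits(A, "conf_tensor"))
  if (!is.finite(L_max)) return(1)   # Oldroyd-B limit
  trA <- tr_conf(A)
  if (trA >= (1 - 1e-10) * L_max^2)
    stop("tensor at/beyond finite extensibility: Tr(A) >= L_max^2")
  L_max^2 / (L_max^2 - trA)
}

#' @rdname fene_factor
#' @export
natural_constant <- function(L_max) {
  if (L_max^2 <= 2) stop("L_max^2 must exceed Tr(I) = 2")
  if (!is.finite(L_max)) return(1)   # Oldroyd-B limit
  L_max^2 / (L_max^2 - 2)
}

#' Normalised protein length and extension
#'
#' The normalised length is \eqn{\mathcal{L} = \sqrt{Tr(A)/Tr(I)}} (so
#' \eqn{\mathcal{L} = 1} for the natural, globular state) and the extension
#' is \eqn{\mathcal{E} = \mathcal{L} - 1}. With the planar convention the
#' saturation values are \eqn{\mathcal{L}_{max} = L/\sqrt{2}} and
#' \eqn{\mathcal{E}_{max} = L/\sqrt{2} - 1}.
#'
#' @param A A [conf_tensor()].
#' @return Dimensionless length (or extension).
#' @export
vwf_length <- function(A) {
  stopifnot(inherits(A, "conf_tensor"))
  sqrt(tr_conf(A) / 2)
}

#' @rdname vwf_length
#' @export
vwf_extension <- function(A) vwf_length(A) - 1

#' Planar velocity gradient
#'
#' Stores \eqn{L_{ij} = \partial u_i / \partial x_j}; the stretching terms
#' of the configuration-tensor evolution are \eqn{L A + A L^T}. Helper
#' constructors give the canonical homogeneous flows at scalar shear rate
#' `gamma_dot`: simple shear \eqn{u = \dot\gamma y \hat x}, planar
#' elongation \eqn{u = \dot\gamma(x, -y)/2} and rigid rotation
#' \eqn{u = \dot\omega(y, -x)}.
#'
#' @param g_11,g_12,g_21,g_22 Gradient entries (1/s, or dimensionless).
#' @return An object of class `flow_gradient`.
#' @export
flow_gradient <- function(g_11, g_12, g_21, g_22) {
  if (!all(is.finite(c(g_11, g_12, g_21, g_22))))
    stop("gradient entries must be finite")
  structure(list(g_11 = g_11, g_12 = g_12, g_21 = g_21, g_22 = g_22),
            class = "flow_gradient")
}

#' @rdname flow_gradient
#' @param gamma_dot Scalar shear rate (1/s).
#' @export
shear_gradient <- function(gamma_dot) flow_gradient(0, gamma_dot, 0, 0)

#' @rdname flow_gradient
#' @export
elongation_gradient <- function(gamma_dot)
  flow_gradient(gamma_dot / 2, 0, 0, -gamma_dot / 2)

#' @rdname flow_gradient
#' @param omega_dot Rotation rate (1/s).
#' @export
rotation_gradient <- function(omega_dot)
  flow_gradient(0, omega_dot, -omega_dot, 0)

#' Scalar shear and rotation rates of a planar velocity gradient
#'
#' Decomposes the gradient into its symmetric part `D` and antisymmetric
#' part `W` and returns \eqn{\dot\gamma = \sqrt{2 D:D}} and
#' \eqn{\dot\omega = \sqrt{2 W:W}}. Simple shear gives equal rates
#' (equal parts elongation and rotation); pure strain gives
#' \eqn{(\dot\gamma, 0)}; rigid rotation gives \eqn{(0, \dot\omega > 0)}.
#'
#' @param G A [flow_gradient()].
#' @return Named numeric vector `c(gamma_dot, omega_dot)`, both `>= 0`.
#' @export
scalar_rates <- function(G) {
  stopifnot(inherits(G, "flow_gradient"))
  d12 <- (G$g_12 + G$g_21) / 2
  w12 <- (G$g_12 - G$g_21) / 2
  c(gamma_dot = sqrt(2 * (G$g_11^2 + G$g_22^2 + 2 * d12^2)),
    omega_dot = sqrt(4 * w12^2))
}
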