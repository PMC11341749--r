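#' Constitutive parameters of the VWF unfolding model
#'
#' Bundles the dimensional parameters of the shear-rate-dependent relaxation
#' time together with the finite-extensibility parameter of the FENE spring.
#' The relaxation time is
#' \deqn{\tau(\dot\gamma) = \alpha\left(\tfrac12(\tanh(\beta(\dot\gamma-\gamma^*))+1)+\delta\right),}
#' a saturating function of the scalar shear rate: it rises from
#' \eqn{\alpha\delta} (globular protein, fast recoil) to \eqn{\alpha(1+\delta)}
#' (unfolded protein, slow recoil) around the centre shear rate
#' \eqn{\gamma^*}, with steepness \eqn{\beta}.
#'
#' @param alpha Relaxation-time scale (s); the maximum relaxation time is
#'   `alpha * (1 + delta)`.
#' @param beta Transition steepness (s); larger values make unfolding switch
#'   on more abruptly around `gamma_star`.
#' @param delta Dimensionless floor; the minimum relaxation time is
#'   `alpha * delta`.
#' @param gamma_star Centre shear rate of the relaxation-time transition
#'   (1/s).
#' @param L_max Maximum dimensionless protein length `L`. The configuration
#'   tensor trace is confined to `Tr(A) < L_max^2`; must satisfy
#'   `L_max^2 > 2` (the planar identity trace) so the Peterlin constant is
#'   finite.
#' @return An object of class `vwf_params`.
#' @examples
#' p <- vwf_params()      # defaults: fitted dimensional values, L = 22.6
#' relaxation_time(0, p)  # folded-state relaxation time, about 1.4e-4 s
#' @export
vwf_params <- function(alpha = 0.069, beta = 3.44e-4, delta = 9.70e-4,
                       gamma_star = 1.0e4, L_max = 22.6) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(delta),
            is.numeric(gamma_star), is.numeric(L_max))
  if (alpha <= 0 || beta <= 0 || delta <= 0 || gamma_star <= 0)
    stop("alpha, beta, delta and gamma_star must all be positive")
  if (L_max^2 <= 2)
    stop("L_max^2 must exceed Tr(I) = 2 for a finite Peterlin constant")
  structure(list(alpha = alpha, beta = beta, delta = delta,
                 gamma_star = gamma_star, L_max = L_max),
            class = "vwf_params")
}

#' @export
print.vwf_params <- function(x, ...) {
  cat("VWF constitutive parameters\n")
  cat(sprintf("  alpha      %.4g s   (tau range %.3g .. %.3g s)\n",
              x$alpha, x$alpha * x$delta, x$alpha * (1 + x$delta)))
  cat(sprintf("  beta       %.4g s\n", x$beta))
  cat(sprintf("  delta      %.4g\n", x$delta))
  cat(sprintf("  gamma_star %.4g 1/s\n", x$gamma_star))
  cat(sprintf("  L_max      %.4g   (max extension %.3g)\n",
              x$L_max, x$L_max / sqrt(2) - 1))
  invisible(x)
}

#' Shear-rate-dependent relaxation time
#'
#' Evaluates \eqn{\tau(\dot\gamma)}, the saturating relaxation time of the
#' unfolding model (see [vwf_params()]). Strictly increasing in the shear
#' rate and bounded in \eqn{(\alpha\delta, \alpha(1+\delta))}.
#'
#' @param gamma_dot Non-negative scalar shear rate(s) (1/s); vectorised.
#' @param params A [vwf_params()] object.
#' @return Relaxation time(s) in seconds.
#' @export
relaxation_time <- function(gamma_dot, params) {
  stopifnot(inherits(params, "vwf_params"))
  if (any(gamma_dot < 0)) stop("gamma_dot must be non-negative")
  params$alpha *
    (0.5 * (tanh(params$beta * (gamma_dot - params$gamma_star)) + 1) +
       params$delta)
}

#' Reference scales and dimensionless groups of the stenotic-flow problem
#'
#' Lengths are scaled with the unstenosed pipe radius `d`, velocities with
#' the maximum inlet velocity `U`, and pressure with `rho * U^2` about the
#' outlet gauge `p_a`. The groups are
#' `Re = rho*U*d/mu`, `xi = alpha*mu/(d^2*rho)` (so that `xi*Re` is the
#' Deborah number), `beta_hat = beta*mu/(d^2*rho)` and
#' `gamma_star_hat = gamma_star*rho*d^2/mu`.
#'
#' @param params A [vwf_params()] object (dimensional).
#' @param d Pipe radius (m).
#' @param U Maximum inlet velocity (m/s).
#' @param rho Fluid density (kg/m^3).
#' @param mu Dynamic viscosity (Pa s).
#' @param p_a Outlet gauge pressure (Pa); enters only as a reference.
#' @return An object of class `dimensionless_groups` with fields `Re`, `xi`,
#'   `beta_hat`, `gamma_star_hat`, `delta`, `L_max` and the stored scales.
#' @seealso [groups_from_table()] for the published dimensionless defaults,
#'   [dimensionalize()] for the inverse map.
#' @export
nondimensionalize <- function(params, d, U, rho = 1050, mu = 0.0025,
                              p_a = 0) {
  stopifnot(inherits(params, "vwf_params"))
  if (d <= 0 || U < 0 || rho <= 0 || mu <= 0)
    stop("reference scales d, rho, mu must be positive and U non-negative")
  structure(list(
    Re = rho * U * d / mu,
    xi = params$alpha * mu / (d^2 * rho),
    beta_hat = params$beta * mu / (d^2 * rho),
    gamma_star_hat = params$gamma_star * rho * d^2 / mu,
    delta = params$delta,
    L_max = params$L_max,
    d = d, U = U, rho = rho, mu = mu, p_a = p_a),
    class = "dimensionless_groups")
}

#' Recover dimensional parameters from dimensionless groups
#'
#' Inverse of [nondimensionalize()]: rebuilds the [vwf_params()] object from
#' the stored reference scales. The round trip is an identity to machine
#' precision.
#'
#' @param groups A `dimensionless_groups` object.
#' @return A [vwf_params()] object.
#' @export
dimensionalize <- function(groups) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  nu <- groups$mu / groups$rho
  vwf_params(alpha = groups$xi * groups$d^2 / nu,
             beta = groups$beta_hat * groups$d^2 / nu,
             delta = groups$delta,
             gamma_star = groups$gamma_star_hat * nu / groups$d^2,
             L_max = groups$L_max)
}

#' Published dimensionless parameter set
#'
#' The dimensionless groups used for the arterial simulations:
#' `xi = 0.043`, `beta_hat = 2.16e-4`, `gamma_star_hat = 1.60e4`,
#' `delta = 9.7e-4`, `L = 22.6`, at a chosen Reynolds number. The implied
#' radius `d = sqrt(alpha*mu/(xi*rho))` (about 1.95 mm for blood) and
#' velocity scale `U = Re*mu/(rho*d)` are stored so dimensional conversions
#' remain available.
#'
#' @param Re Reynolds number (default 400).
#' @param params Dimensional [vwf_params()] used to derive the scales.
#' @param rho,mu Blood density (kg/m^3) and viscosity (Pa s).
#' @param xi,beta_hat,gamma_star_hat Dimensionless relaxation groups.
#' @return A `dimensionless_groups` object.
#' @export
groups_from_table <- function(Re = 400, params = vwf_params(),
                              rho = 1050, mu = 0.0025, xi = 0.043,
                              beta_hat = 2.16e-4, gamma_star_hat = 1.60e4) {
  d <- sqrt(params$alpha * mu / (xi * rho))
  U <- Re * mu / (rho * d)
  g <- nondimensionalize(params, d = d, U = U, rho = rho, mu = mu)
  # keep the published rounded groups rather than the re-derived ones
  g$xi <- xi; g$beta_hat <- beta_hat; g$gamma_star_hat <- gamma_star_hat
  g
}

#' Dimensionless relaxation time
#'
#' Evaluates \eqn{\hat\tau(\hat{\dot\gamma}) =
#' \tfrac12(\tanh(\hat\beta Re(\hat{\dot\gamma}-\hat\gamma^*/Re))+1)+\delta}
#' on dimensionless shear rates (the dimensional \eqn{\alpha} is absorbed
#' into \eqn{\xi}).
#'
#' @param gamma_dot_hat Dimensionless scalar shear rate(s), non-negative.
#' @param groups A `dimensionless_groups` object.
#' @return Dimensionless relaxation time(s) in \eqn{(\delta, 1+\delta)}.
#' @export
relaxation_time_hat <- function(gamma_dot_hat, groups) {
  stopifnot(inherits(groups, "dimensionless_groups"))
  if (any(gamma_dot_hat < 0)) stop("gamma_dot_hat must be non-negative")
  0.5 * (tanh(groups$beta_hat * groups$Re *
                (gamma_dot_hat - groups$gamma_star_hat / groups$Re)) + 1) +
    groups$delta
}

#' Read model configuration from a YAML file
#'
#' Sections `vwf:` (alpha, beta, delta, gamma_star, L_max) and `fluid:`
#' (rho, mu, d and either U or Re, optional p_a). Missing keys fall back to
#' the package defaults (the fitted dimensional set and blood properties).
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `params` ([vwf_params()]) and, when a
#'   `fluid:` section is present, `groups` (`dimensionless_groups`), plus
#'   any further sections verbatim.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  v <- cfg$vwf %||% list()
  params <- vwf_params(alpha = v$alpha %||% 0.069,
                       beta = v$beta %||% 3.44e-4,
                       delta = v$delta %||% 9.70e-4,
                       gamma_star = v$gamma_star %||% 1.0e4,
                       L_max = v$L_max %||% 22.6)
  out <- list(params = params)
  if (!is.null(cfg$fluid)) {
    f <- cfg$fluid
    rho <- f$rho %||% 1050; mu <- f$mu %||% 0.0025
    if (!is.null(f$d) && !is.null(f$U)) {
      out$groups <- nondimensionalize(params, d = f$d, U = f$U, rho = rho,
                                      mu = mu, p_a = f$p_a %||% 0)
    } else {
      out$groups <- groups_from_table(Re = f$Re %||% 400, params = params,
                                      rho = rho, mu = mu)
    }
  }
  out <- c(out, cfg[setdiff(names(cfg), c("vwf", "fluid"))])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
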