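# Steady homogeneous solutions of the modified FENE-P model.
#
# Both printed algebraic systems reduce exactly to a cubic in the Peterlin
# factor x = f(A), with s = gamma_dot * tau(gamma_dot):
#   shear:      L^2 x^3 - (L^2 + 2a) x^2 - 2 a s^2            = 0
#   elongation: L^2 x^3 - (L^2 + 2a) x^2 - 4 L^2 s^2 x + 4 L^2 s^2 = 0
# The admissible root is the largest real one (>= a, and > 2s for
# elongation), which exists and is unique for every s >= 0.

# Largest real root of c3 x^3 + c2 x^2 + c1 x + c0, vectorised, polished by
# two Newton steps.
solve_cubic_largest <- function(c3, c2, c1, c0) {
  B <- c2 / c3; C <- c1 / c3; D <- c0 / c3
  p <- C - B^2 / 3
  q <- 2 * B^3 / 27 - B * C / 3 + D
  disc <- (q / 2)^2 + (p / 3)^3
  y <- ifelse(disc > 0,
              {
                u <- -q / 2 + sqrt(pmax(disc, 0))
                v <- -q / 2 - sqrt(pmax(disc, 0))
                sign(u) * abs(u)^(1 / 3) + sign(v) * abs(v)^(1 / 3)
              },
              {
                m <- 2 * sqrt(pmax(-p / 3, 0))
                arg <- pmin(pmax(3 * q / (p * m + (m == 0)), -1), 1)
                m * cos(acos(arg) / 3)
              })
  x <- y - B / 3
  for (i in 1:3) {
    fx <- ((c3 * x + c2) * x + c1) * x + c0
    dfx <- (3 * c3 * x + 2 * c2) * x + c1
    x <- x - fx / dfx
  }
  x
}

# Components of the steady simple-shear solution at Weissenberg product s,
# vectorised over s. L may be Inf (Oldroyd-B limit f = a = 1).
shear_components <- function(s, L) {
  if (!is.finite(L)) {
    return(list(a_11 = 1 + 2 * s^2, a_12 = s, a_22 = rep(1, length(s)), f = rep(1, length(s))))
  }
  a <- natural_constant(L)
  f <- solve_cubic_largest(L^2, -(L^2 + 2 * a), 0, -2 * a * s^2)
  a_22 <- a / f
  a_12 <- s * a_22 / f
  a_11 <- (a + 2 * s * a_12) / f
  list(a_11 = a_11, a_12 = a_12, a_22 = a_22, f = f)
}

# Components of the steady elongation solution (printed system: growing
# principal component has coefficient +2 s).
elongation_components <- function(s, L) {
  if (!is.finite(L)) {
    if (any(2 * s >= 1))
      stop("Oldroyd-B elongation requires 2*gamma_dot*tau < 1")
    return(list(a_11 = 1 / (1 - 2 * s), a_12 = rep(0, length(s)),
                a_22 = 1 / (1 + 2 * s), f = rep(1, length(s))))
  }
  a <- natural_constant(L)
  f <- solve_cubic_largest(L^2, -(L^2 + 2 * a), -4 * L^2 * s^2, 4 * L^2 * s^2)
  list(a_11 = a / (f - 2 * s), a_12 = rep(0, length(s)),
       a_22 = a / (f + 2 * s), f = f)
}

weissenberg <- function(gamma_dot, params, tau = NULL) {
  if (is.null(tau)) tau <- relaxation_time(gamma_dot, params)
  gamma_dot * tau
}

check_residual <- function(comp, s, L, type, tol = 1e-10) {
  a <- if (is.finite(L)) natural_constant(L) else 1
  f <- comp$f
  res <- if (type == "shear") {
    c(2 * s * comp$a_12 - (f * comp$a_11 - a),
      s * comp$a_22 - f * comp$a_12,
      f * comp$a_22 - a)
  } else {
    c(2 * s * comp$a_11 - (f * comp$a_11 - a),          # growing component
      (f * comp$a_22 - a) + 2 * s * comp$a_22,          # shrinking component
      comp$a_12)
  }
  scale <- max(abs(c(1, s, f * comp$a_11)))
  if (max(abs(res)) > tol * scale)
    stop(sprintf("steady %s solve did not meet residual tolerance: max |res| = %.3g",
                 type, max(abs(res))))
  invisible(max(abs(res)) / scale)
}

#' Steady configuration tensor in homogeneous simple shear
#'
#' Exact steady, spatially uniform solution of the configuration-tensor
#' model in simple shear \eqn{u = \dot\gamma y \hat x}. The algebraic system
#' \deqn{2\dot\gamma\tau A_{xy} = f A_{xx} - a,\quad
#'       \dot\gamma\tau A_{yy} = f A_{xy},\quad f A_{yy} = a}
#' is reduced to a cubic in the Peterlin factor and solved in closed form;
#' the residuals of all three equations are verified to 1e-10 (relative).
#'
#' @param gamma_dot Shear rate (1/s), non-negative scalar.
#' @param params A [vwf_params()]; `params$L_max` may be `Inf` for the
#'   infinitely extensible (Oldroyd-B) limit.
#' @param tau Optional fixed relaxation time (s) overriding
#'   [relaxation_time()].
#' @return A [conf_tensor()] with attribute `"f"` (Peterlin factor).
#' @export
steady_pure_shear <- function(gamma_dot, params, tau = NULL) {
  stopifnot(length(gamma_dot) == 1)
  if (gamma_dot < 0) stop("gamma_dot must be non-negative")
  s <- weissenberg(gamma_dot, params, tau)
  comp <- shear_components(s, params$L_max)
  check_residual(comp, s, params$L_max, "shear")
  A <- conf_tensor(comp$a_11, comp$a_12, comp$a_22, L_max = params$L_max)
  attr(A, "f") <- comp$f
  A
}

#' Steady configuration tensor in homogeneous elongational flow
#'
#' Exact steady solution of the printed planar-elongation system
#' \deqn{2\dot\gamma\tau A_{xx} = f A_{xx} - a,\quad
#'       -2\dot\gamma\tau A_{yy} = f A_{yy} - a,\quad A_{xy} = 0,}
#' oriented so the first component is the growing principal direction. The
#' nonlinear spring guarantees a bounded solution for every elongation rate
#' (no infinite coil-stretch catastrophe).
#'
#' @inheritParams steady_pure_shear
#' @return A diagonal [conf_tensor()] with attribute `"f"`.
#' @export
steady_pure_elongation <- function(gamma_dot, params, tau = NULL) {
  stopifnot(length(gamma_dot) == 1)
  if (gamma_dot < 0) stop("gamma_dot must be non-negative")
  s <- weissenberg(gamma_dot, params, tau)
  comp <- elongation_components(s, params$L_max)
  check_residual(comp, s, params$L_max, "elongation")
  A <- conf_tensor(comp$a_11, comp$a_12, comp$a_22, L_max = params$L_max)
  attr(A, "f") <- comp$f
  A
}

#' Steady state by time integration for an arbitrary constant gradient
#'
#' Integrates the homogeneous evolution
#' \deqn{dA/dt = L A + A L^T - (f(A) A - a I)/\tau(\dot\gamma)}
#' from the natural state `A = I` with a stiff solver until the right-hand
#' side falls below `tol`. Serves as the independent oracle for the
#' algebraic solvers and handles any planar gradient (including rotation,
#' which leaves `A = I`).
#'
#' @param G A [flow_gradient()], constant in time.
#' @param params A [vwf_params()].
#' @param t_max Maximum integration time (s).
#' @param tol Steady-state tolerance on `max |dA/dt|` (1/s).
#' @param gamma_dot Optional override of the scalar shear rate used to
#'   evaluate the relaxation time (defaults to [scalar_rates()] of `G`).
#' @return A [conf_tensor()]; attribute `"t_steady"` records the time
#'   reached. Errors if `tol` is not met by `t_max`, carrying the last
#'   state in the condition.
#' @export
steady_general <- function(G, params, t_max = NULL, tol = 1e-9,
                           gamma_dot = NULL) {
  stopifnot(inherits(G, "flow_gradient"), inherits(params, "vwf_params"))
  if (tol <= 0) stop("tol must be positive")
  if (is.null(gamma_dot)) gamma_dot <- scalar_rates(G)[["gamma_dot"]]
  tau <- relaxation_time(gamma_dot, params)
  L2 <- params$L_max^2
  a <- natural_constant(params$L_max)
  deriv <- function(t, y, p) {
    A <- matrix(c(y[1], y[2], y[2], y[3]), 2, 2)
    f <- L2 / (L2 - (y[1] + y[3]))
    Lm <- matrix(c(G$g_11, G$g_21, G$g_12, G$g_22), 2, 2)
    dA <- Lm %*% A + A %*% t(Lm) - (f * A - a * diag(2)) / tau
    list(c(dA[1, 1], dA[1, 2], dA[2, 2]))
  }
  if (is.null(t_max)) t_max <- 5e3 * tau
  y <- c(1, 0, 1)
  t0 <- 0
  chunk <- 20 * tau
  repeat {
    out <- deSolve::ode(y, c(t0, t0 + chunk), deriv, NULL, method = "bdf",
                        rtol = 1e-11, atol = 1e-12)
    y <- as.numeric(out[nrow(out), 2:4])
    t0 <- t0 + chunk
    # steady-state measure relative to the size of the competing terms
    # (stretching ~ gamma_dot*|A|, recoil ~ |A|/tau), which grow large
    # near saturation
    scale <- max(1, gamma_dot * max(abs(y)), max(abs(y)) / tau)
    rate <- max(abs(unlist(deriv(t0, y, NULL)))) / scale
    if (rate <= tol) break
    if (t0 >= t_max) {
      cond <- simpleError(sprintf(
        "steady_general: |dA/dt| = %.3g > tol at t_max = %.3g", rate, t_max))
      cond$last_state <- y
      stop(cond)
    }
  }
  A <- conf_tensor(y[1], y[2], y[3], L_max = params$L_max)
  attr(A, "t_steady") <- t0
  A
}

#' Unfolding curve over a grid of shear rates
#'
#' Sweeps the steady homogeneous solution over a grid of scalar shear
#' rates and tabulates the normalised length \eqn{\mathcal{L}}, extension
#' \eqn{\mathcal{E}} and the extension normalised by the analytic saturation
#' value \eqn{\mathcal{E}_{max} = L/\sqrt{2} - 1} (so the curve tends to 1).
#'
#' @param flow_type One of `"shear"`, `"elongation"`, `"rotation"`.
#' @param grid Strictly increasing, non-negative shear rates (1/s).
#' @param params A [vwf_params()].
#' @return A data frame of class `unfolding_curve` with columns
#'   `gamma_dot`, `a_11`, `a_12`, `a_22`, `length`, `extension`,
#'   `normalized_extension`.
#' @export
unfolding_curve <- function(flow_type = c("shear", "elongation", "rotation"),
                            grid, params) {
  flow_type <- match.arg(flow_type)
  if (any(diff(grid) <= 0) || any(grid < 0))
    stop("grid must be strictly increasing and non-negative")
  s <- weissenberg(grid, params)
  comp <- switch(flow_type,
                 shear = shear_components(s, params$L_max),
                 elongation = elongation_components(s, params$L_max),
                 rotation = list(a_11 = rep(1, length(grid)),
                                 a_12 = rep(0, length(grid)),
                                 a_22 = rep(1, length(grid))))
  len <- sqrt((comp$a_11 + comp$a_22) / 2)
  e_max <- params$L_max / sqrt(2) - 1
  out <- data.frame(gamma_dot = grid, a_11 = comp$a_11, a_12 = comp$a_12,
                    a_22 = comp$a_22, length = len, extension = len - 1,
                    normalized_extension = (len - 1) / e_max)
  attr(out, "flow_type") <- flow_type
  attr(out, "params") <- params
  class(out) <- c("unfolding_curve", "data.frame")
  out
}

#' Shear rate at which the protein is half unfolded
#'
#' Root of \eqn{\mathcal{L}(\dot\gamma) = \tfrac12 L/\sqrt{2}} (half the
#' saturation length) for the chosen flow type, found by bracketed
#' root-finding; unique because \eqn{\mathcal{L}} is non-decreasing in the
#' shear rate.
#'
#' @param flow_type `"shear"` or `"elongation"` (`"rotation"` has no
#'   threshold: the length is identically 1).
#' @param params A [vwf_params()].
#' @param bracket Search interval (1/s).
#' @param tol Relative tolerance of the root.
#' @return Threshold shear rate (1/s).
#' @export
half_unfolding_threshold <- function(flow_type = c("shear", "elongation",
                                                   "rotation"),
                                     params, bracket = c(1e2, 1e5),
                                     tol = 1e-6) {
  flow_type <- match.arg(flow_type)
  if (flow_type == "rotation")
    stop("threshold undefined: rotational flow never extends the protein")
  L_half <- params$L_max / (2 * sqrt(2))
  len_at <- function(g) {
    s <- weissenberg(g, params)
    comp <- switch(flow_type, shear = shear_components(s, params$L_max),
                   elongation = elongation_components(s, params$L_max))
    sqrt((comp$a_11 + comp$a_22) / 2)
  }
  flo <- len_at(bracket[1]) - L_half
  fhi <- len_at(bracket[2]) - L_half
  if (flo >= 0 || fhi <= 0)
    stop(sprintf("bracket failure: L(%g) = %.4g, L(%g) = %.4g do not straddle %.4g",
                 bracket[1], flo + L_half, bracket[2], fhi + L_half, L_half))
  stats::uniroot(function(g) len_at(g) - L_half, bracket,
                 f.lower = flo, f.upper = fhi, tol = tol * bracket[1])$root
}
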