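# Calibration of the unfolding parameters against a target
# normalised-extension curve (shear flow, fixed L).

#' Synthetic sigmoidal unfolding target
#'
#' Generates a smooth stand-in for an experimental normalised-extension
#' curve: \eqn{\tfrac12(1 + \tanh((\dot\gamma - \dot\gamma_{1/2})/w))}. The
#' default half-point of 5122 1/s matches the published shear unfolding
#' threshold the model is calibrated against; the default width places the
#' 10--90% transition roughly between 3000 and 8000 1/s.
#'
#' @param half_point Shear rate of half-unfolding (1/s).
#' @param width Transition width (1/s), `> 0`.
#' @param grid Strictly increasing shear rates (1/s).
#' @return A data frame with columns `gamma_dot` and
#'   `normalized_extension` (values in `[0, 1]`).
#' @export
sigmoid_target_curve <- function(half_point = 5122, width = 1500,
                                 grid = exp(seq(log(1e2), log(1e5),
                                                length.out = 50))) {
  if (width <= 0) stop("width must be positive")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  data.frame(gamma_dot = grid,
             normalized_extension = 0.5 * (1 + tanh((grid - half_point) / width)))
}

#' Configuration of an unfolding-curve fit
#'
#' @param L_fixed Maximum length parameter held fixed during the fit.
#' @param grid Shear rates (1/s) on which the objective is evaluated;
#'   defaults to 50 log-spaced points on `[1e2, 1e5]`.
#' @param n_starts Number of multistart initial points (`>= 1`).
#' @param seed Integer seed making the multistart sample reproducible.
#' @param lower,upper Named bounds (on the natural scale) for `alpha` (s),
#'   `beta` (s), `delta` and `gamma_star` (1/s); optimisation runs in log
#'   space within these boxes.
#' @param tol Relative convergence tolerance passed to the optimiser.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(L_fixed = 22.6,
                       grid = exp(seq(log(1e2), log(1e5), length.out = 50)),
                       n_starts = 8, seed = 0,
                       lower = c(alpha = 1e-3, beta = 1e-5, delta = 1e-5,
                                 gamma_star = 1e3),
                       upper = c(alpha = 1, beta = 1e-2, delta = 1e-1,
                                 gamma_star = 1e5),
                       tol = 1e-10) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (n_starts < 1) stop("n_starts must be >= 1")
  stopifnot(all(lower > 0), all(is.finite(upper)), all(upper > lower))
  structure(list(L_fixed = L_fixed, grid = grid, n_starts = n_starts,
                 seed = as.integer(seed), lower = lower, upper = upper,
                 tol = tol),
            class = "fit_config")
}

# Model normalised extension in shear flow on a grid, for parameter vector
# theta = c(alpha, beta, delta, gamma_star) at fixed L.
model_normalized_extension <- function(theta, grid, L) {
  p <- vwf_params(theta[1], theta[2], theta[3], theta[4], L)
  s <- grid * relaxation_time(grid, p)
  comp <- shear_components(s, L)
  len <- sqrt((comp$a_11 + comp$a_22) / 2)
  (len - 1) / (L / sqrt(2) - 1)
}

#' Fit the unfolding parameters to a target curve
#'
#' Estimates `alpha`, `beta`, `delta` and `gamma_star` at fixed `L` by
#' minimising the mean absolute error between the model's normalised
#' extension in steady shear flow and a target curve. The optimisation runs
#' in log-parameter space (L-BFGS-B) from a seeded Latin-hypercube
#' multistart, guarding against the local minima a single descent can fall
#' into; the best start wins. Deterministic for a fixed seed.
#'
#' @param target Data frame with columns `gamma_dot` and
#'   `normalized_extension` covering the unfolding transition (values
#'   spanning below 0.1 and above 0.9). Evaluated on `config$grid` by
#'   monotone interpolation when the grids differ.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: `params` ([vwf_params()]),
#'   `objective_value` (mean absolute error), `starts` (per-start summary),
#'   `traces` (monotone best-so-far objective per start) and `converged`.
#' @export
fit_params <- function(target, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (!all(c("gamma_dot", "normalized_extension") %in% names(target)))
    stop("target must have columns gamma_dot and normalized_extension")
  y <- target$normalized_extension
  if (min(y) > 0.1 || max(y) < 0.9)
    stop("transition not covered: target must span normalised extension < 0.1 and > 0.9")
  grid <- config$grid
  y_t <- stats::approx(target$gamma_dot, y, xout = grid, rule = 2)$y
  L <- config$L_fixed
  lo <- log(config$lower); hi <- log(config$upper)

  traces <- vector("list", config$n_starts)
  obj_factory <- function(k) {
    best <- Inf
    function(lt) {
      th <- exp(lt)
      val <- tryCatch(mean(abs(model_normalized_extension(th, grid, L) - y_t)),
                      error = function(e) 1e3)
      if (val < best) {
        best <<- val
        traces[[k]][[length(traces[[k]]) + 1L]] <<- val
      }
      val
    }
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config$seed)
  u <- lhs::randomLHS(config$n_starts, 4)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)

  starts <- matrix(rep(lo, each = config$n_starts), ncol = 4) +
    u * matrix(rep(hi - lo, each = config$n_starts), ncol = 4)
  fits <- vector("list", config$n_starts)
  for (k in seq_len(config$n_starts)) {
    traces[[k]] <- list()
    fits[[k]] <- tryCatch(
      stats::optim(starts[k, ], obj_factory(k), method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(factr = config$tol / .Machine$double.eps,
                                  maxit = 500)),
      error = function(e) list(value = Inf, par = starts[k, ],
                               convergence = 99L, message = conditionMessage(e)))
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(vals))) {
    cond <- simpleError("all optimiser starts diverged")
    cond$traces <- traces
    stop(cond)
  }
  best <- which.min(vals)
  th <- exp(fits[[best]]$par)
  structure(list(
    params = vwf_params(th[1], th[2], th[3], th[4], L),
    objective_value = vals[best],
    converged = fits[[best]]$convergence == 0L,
    best_start = best,
    starts = data.frame(start = seq_along(vals), objective = vals,
                        convergence = vapply(fits, function(f)
                          as.integer(f$convergence %||% 99L), integer(1))),
    traces = lapply(traces, function(tr) unlist(tr)),
    config = config),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("unfolding-curve fit: MAE = %.3e (start %d of %d, %s)\n",
              x$objective_value, x$best_start, nrow(x$starts),
              if (x$converged) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}

#' Unfolding thresholds as the maximum length parameter varies
#'
#' Refits the unfolding parameters to the same target for each value of `L`
#' and reports the shear and elongation half-unfolding thresholds of the
#' fitted model. Proteins allowed larger maximum lengths unfold in
#' elongational flow at lower rates, so the elongation threshold decreases
#' along an increasing `L_grid`.
#'
#' @param L_grid Values of `L` (each `> sqrt(2)`).
#' @param target Target curve as in [fit_params()].
#' @param config A [fit_config()]; its `L_fixed` is overridden per row.
#' @return A data frame with one row per `L`: fitted parameters, objective,
#'   and `shear_threshold` / `elongation_threshold` (1/s).
#' @export
threshold_vs_L <- function(L_grid, target, config = fit_config()) {
  if (any(L_grid <= sqrt(2))) stop("every L must exceed sqrt(2)")
  rows <- lapply(L_grid, function(L) {
    cfg <- config; cfg$L_fixed <- L
    fit <- fit_params(target, cfg)
    p <- fit$params
    data.frame(L = L, alpha = p$alpha, beta = p$beta, delta = p$delta,
               gamma_star = p$gamma_star, objective = fit$objective_value,
               shear_threshold = half_unfolding_threshold("shear", p),
               elongation_threshold = half_unfolding_threshold("elongation", p))
  })
  do.call(rbind, rows)
}
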