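test_that("relaxation time saturates between alpha*delta and alpha*(1+delta)", {
  p <- table1_params()
  # limits of the tanh saturation
  expect_equal(relaxation_time(1e9, p), p$alpha * (1 + p$delta), tolerance = 1e-10)
  expect_equal(relaxation_time(1e9, p), 0.069067, tolerance = 1e-4)
  # centre of the transition: tanh vanishes at gamma_star
  expect_equal(relaxation_time(p$gamma_star, p), p$alpha * (0.5 + p$delta))
  # folded-state value, frozen from direct evaluation of the law
  expect_equal(relaxation_time(0, p), 1.377991e-4, tolerance = 1e-6)
  g <- seq(0, 5e4, length.out = 200)
  tau <- relaxation_time(g, p)
  expect_true(all(diff(tau) > 0))
  expect_true(all(tau > p$alpha * p$delta & tau < p$alpha * (1 + p$delta)))
  expect_error(relaxation_time(-1, p), "non-negative")
})

test_that("parameter validation rejects non-physical values", {
  expect_error(vwf_params(alpha = -1), "positive")
  expect_error(vwf_params(L_max = 1.2), "Tr\\(I\\)")
  expect_error(vwf_params(delta = 0), "positive")
})

test_that("Peterlin factor pins A = I as the flow-free equilibrium", {
  I2 <- conf_tensor(1, 0, 1)
  expect_equal(fene_factor(I2, 22.6), natural_constant(22.6))
  expect_equal(natural_constant(22.6), 510.76 / 508.76, tolerance = 1e-12)
  # infinite extensibility reduces to the Oldroyd-B constant
  expect_equal(fene_factor(I2, Inf), 1)
  expect_equal(natural_constant(Inf), 1)
  # pole guarded
  big <- conf_tensor(300, 0, 300)
  expect_error(fene_factor(big, 22.6), "finite extensibility")
  expect_error(conf_tensor(300, 0, 300, L_max = 22.6), "finite extensibility")
})

test_that("normalised length and extension follow the trace", {
  expect_equal(vwf_length(conf_tensor(1, 0, 1)), 1)
  expect_equal(vwf_extension(conf_tensor(1, 0, 1)), 0)
  expect_equal(vwf_length(conf_tensor(4, 0, 4)), 2)
  # saturation: Tr(A) -> L^2 gives the paper-rounded maximum extension of 15
  L <- 22.6
  A_sat <- conf_tensor(L^2 / 2, 0, L^2 / 2 - 1e-9)
  expect_equal(vwf_length(A_sat), L / sqrt(2), tolerance = 1e-9)
  expect_equal(vwf_extension(A_sat), 14.98, tolerance = 1e-3)
  expect_error(conf_tensor(1, 2, 1), "positive definite")
})

test_that("length is invariant under rotation of the tensor frame", {
  set.seed(42)
  for (rep in 1:20) {
    M <- matrix(rnorm(4), 2)
    S <- crossprod(M) + diag(2) * 0.1
    th <- runif(1, 0, 2 * pi)
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    Sr <- Q %*% S %*% t(Q)
    expect_equal(vwf_length(conf_tensor(S[1, 1], S[1, 2], S[2, 2])),
                 vwf_length(conf_tensor(Sr[1, 1], Sr[1, 2], Sr[2, 2])),
                 tolerance = 1e-12)
  }
})

test_that("scalar rates classify shear, strain and rotation", {
  # simple shear: equal parts elongation and rotation
  expect_equal(scalar_rates(shear_gradient(7)), c(gamma_dot = 7, omega_dot = 7))
  # planar pure strain: no rotation
  expect_equal(scalar_rates(elongation_gradient(7)),
               c(gamma_dot = 7, omega_dot = 0))
  # rigid rotation u = w (y, -x): gamma = 0, omega = 2 w
  expect_equal(scalar_rates(rotation_gradient(3)),
               c(gamma_dot = 0, omega_dot = 6))
  # brute-force decomposition check over random gradients
  set.seed(7)
  for (rep in 1:25) {
    g <- rnorm(4)
    G <- flow_gradient(g[1], g[2], g[3], g[4])
    D <- matrix(c(g[1], (g[2] + g[3]) / 2, (g[2] + g[3]) / 2, g[4]), 2)
    W <- matrix(c(0, (g[2] - g[3]) / 2, (g[3] - g[2]) / 2, 0), 2)
    expect_equal(unname(scalar_rates(G)),
                 c(sqrt(2 * sum(D * D)), sqrt(2 * sum(W * W))),
                 tolerance = 1e-12)
  }
})

test_that("nondimensionalisation round-trips and matches the published groups", {
  p <- table1_params()
  # Table 2's xi fixes the implied radius near 1.95 mm
  d <- sqrt(p$alpha * 0.0025 / (0.043 * 1050))
  expect_equal(d, 1.95e-3, tolerance = 2e-3)
  g <- nondimensionalize(p, d = d, U = 0.5)
  expect_equal(g$Re, 1050 * 0.5 * d / 0.0025, tolerance = 1e-12)
  expect_equal(g$xi * g$Re, p$alpha * 0.5 / d, tolerance = 1e-12)  # Deborah number
  p2 <- dimensionalize(g)
  for (f in names(unclass(p))) expect_equal(p2[[f]], p[[f]], tolerance = 1e-12)
  # dimensionless parameters pass through unchanged
  expect_equal(g$delta, p$delta)
  expect_equal(g$L_max, p$L_max)
  expect_equal(nondimensionalize(p, d = d, U = 0)$Re, 0)
  expect_error(nondimensionalize(p, d = -1, U = 1), "positive")
  # published Table 2 values are mutually consistent with the derived scales
  gt <- groups_from_table(Re = 400)
  expect_equal(gt$beta_hat, 2.16e-4, tolerance = 0.02)
  expect_equal(gt$gamma_star_hat, 1.60e4, tolerance = 0.01)
})

test_that("dimensionless relaxation time matches its dimensional counterpart", {
  p <- table1_params()
  g <- groups_from_table(Re = 400, params = p)
  gd_hat <- c(0, 10, 40, 55)
  gd_dim <- gd_hat * g$U / g$d
  expect_equal(relaxation_time_hat(gd_hat, g),
               relaxation_time(gd_dim, p) / p$alpha, tolerance = 0.02)
})

test_that("YAML config reading fills defaults and builds groups", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("vwf:", "  L_max: 10.0", "fluid:", "  Re: 300"), path)
  cfg <- read_config(path)
  expect_equal(cfg$params$L_max, 10)
  expect_equal(cfg$params$alpha, 0.069)
  expect_equal(cfg$groups$Re, 300)
})
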