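test_that("steady shear solution satisfies the printed algebraic system", {
  p <- table1_params()
  a <- natural_constant(p$L_max)
  for (g in c(0, 10, 500, 5096, 2e4, 1e5)) {
    A <- steady_pure_shear(g, p)
    s <- g * relaxation_time(g, p)
    f <- attr(A, "f")
    scale <- max(1, abs(f * A$a_11))
    expect_lt(abs(2 * s * A$a_12 - (f * A$a_11 - a)) / scale, 1e-10)
    expect_lt(abs(s * A$a_22 - f * A$a_12) / scale, 1e-10)
    expect_lt(abs(f * A$a_22 - a) / scale, 1e-10)
    expect_lt(A$a_11 + A$a_22, p$L_max^2)
  }
  expect_equal(as.matrix(steady_pure_shear(0, p)), diag(2))
})

test_that("half of the maximum length is reached near the published shear rate", {
  p <- table1_params()
  A <- steady_pure_shear(5096, p)
  expect_equal(vwf_length(A), p$L_max / (2 * sqrt(2)), tolerance = 0.02)
})

test_that("Oldroyd-B closed forms are recovered as L -> Inf", {
  pI <- vwf_params(L_max = Inf)
  tau <- 2e-3
  for (g in c(0, 50, 300)) {
    A <- steady_pure_shear(g, pI, tau = tau)
    s <- g * tau
    expect_equal(A$a_22, 1, tolerance = 1e-12)
    expect_equal(A$a_12, s, tolerance = 1e-12)
    expect_equal(A$a_11, 1 + 2 * s^2, tolerance = 1e-12)
  }
  for (g in c(0, 50, 200)) {       # needs 2 g tau < 1
    A <- steady_pure_elongation(g, pI, tau = tau)
    s <- g * tau
    expect_equal(A$a_11, 1 / (1 - 2 * s), tolerance = 1e-12)
    expect_equal(A$a_22, 1 / (1 + 2 * s), tolerance = 1e-12)
    expect_equal(A$a_12, 0)
  }
  expect_error(steady_pure_elongation(300, pI, tau = tau), "2\\*gamma")
})

test_that("elongation solution is diagonal and satisfies the printed system", {
  p <- table1_params()
  a <- natural_constant(p$L_max)
  for (g in c(0, 100, 1947, 1e4)) {
    A <- steady_pure_elongation(g, p)
    s <- g * relaxation_time(g, p)
    f <- attr(A, "f")
    expect_equal(A$a_12, 0)
    scale <- max(1, abs(f * A$a_11))
    expect_lt(abs(2 * s * A$a_11 - (f * A$a_11 - a)) / scale, 1e-10)
    expect_lt(abs((f * A$a_22 - a) + 2 * s * A$a_22) / scale, 1e-10)
  }
  A <- steady_pure_elongation(1947, p)
  expect_equal(vwf_length(A), p$L_max / (2 * sqrt(2)), tolerance = 0.02)
})

test_that("time-march oracle agrees with the algebraic shear solution", {
  p <- table1_params()
  grid <- exp(seq(log(50), log(5e4), length.out = 30))
  for (g in grid) {
    A_alg <- steady_pure_shear(g, p)
    A_ode <- steady_general(shear_gradient(g), p, tol = 1e-10)
    for (comp in c("a_11", "a_12", "a_22"))
      expect_equal(A_ode[[comp]], A_alg[[comp]],
                   tolerance = 1e-6)
  }
})

test_that("rotation leaves the protein at its natural length", {
  p <- table1_params()
  for (w in c(10, 1e3, 2e4)) {
    A <- steady_general(rotation_gradient(w), p)
    expect_equal(as.matrix(A), diag(2), tolerance = 1e-8)
  }
  A0 <- steady_general(flow_gradient(0, 0, 0, 0), p)
  expect_equal(as.matrix(A0), diag(2), tolerance = 1e-10)
})

test_that("unfolding curves are monotone and saturate at L/sqrt(2)", {
  p <- table1_params()
  grid <- exp(seq(log(10), log(1e5), length.out = 40))
  for (ft in c("shear", "elongation")) {
    uc <- unfolding_curve(ft, grid, p)
    expect_true(all(diff(uc$length) >= -1e-12))
    expect_true(all(uc$normalized_extension >= 0 & uc$normalized_extension <= 1))
    expect_true(all(uc$length <= p$L_max / sqrt(2)))
  }
  # low shear leaves the protein globular
  expect_equal(unfolding_curve("shear", 10, p)$length, 1, tolerance = 1e-3)
  # saturation at extreme shear
  expect_equal(unfolding_curve("shear", 1e8, p)$normalized_extension, 1,
               tolerance = 1e-2)
  # elongational flow unfolds at lower rates than shear, pointwise
  mid <- exp(seq(log(500), log(5000), length.out = 15))
  sh <- unfolding_curve("shear", mid, p)
  el <- unfolding_curve("elongation", mid, p)
  expect_true(all(el$length >= sh$length - 1e-12))
  # rotation never extends
  expect_true(all(unfolding_curve("rotation", mid, p)$extension == 0))
  expect_error(unfolding_curve("shear", c(3, 2, 1), p), "increasing")
})

test_that("the transverse component shrinks at large shear rates", {
  p <- table1_params()
  grid <- exp(seq(log(1e3), log(1e6), length.out = 25))
  ayy <- unfolding_curve("shear", grid, p)$a_22
  expect_true(all(diff(ayy) < 0))
  expect_lt(ayy[length(ayy)], 0.05)
})

test_that("half-unfolding thresholds reproduce the published values", {
  p <- table1_params()
  th_s <- half_unfolding_threshold("shear", p)
  th_e <- half_unfolding_threshold("elongation", p)
  expect_equal(th_s, 5096, tolerance = 0.02)
  expect_equal(th_e, 1947, tolerance = 0.02)
  # the model's own claim: within 1% of the experimental 5122 1/s
  expect_lt(abs(th_s - 5122) / 5122, 0.01)
  expect_error(half_unfolding_threshold("rotation", p), "undefined")
  expect_error(half_unfolding_threshold("shear", p, bracket = c(1, 2)),
               "bracket")
})

test_that("elongation threshold lies below the shear threshold for random parameters", {
  set.seed(11)
  for (rep in 1:12) {
    p <- vwf_params(alpha = 10^runif(1, -2, -0.5),
                    beta = 10^runif(1, -4.5, -2.5),
                    delta = 10^runif(1, -4, -2),
                    gamma_star = 10^runif(1, 3.3, 4.5),
                    L_max = runif(1, 5, 40))
    br <- c(1e-2, 1e8)
    th_s <- half_unfolding_threshold("shear", p, bracket = br)
    th_e <- half_unfolding_threshold("elongation", p, bracket = br)
    expect_lt(th_e, th_s)
  }
})

test_that("steady_general reports non-convergence with the last state attached", {
  p <- table1_params()
  err <- tryCatch(steady_general(shear_gradient(5000), p, t_max = 1e-7,
                                 tol = 1e-14),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_false(is.null(err$last_state))
})
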