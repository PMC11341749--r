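test_that("Poiseuille flow is recovered exactly in the straight pipe", {
  flow <- cached_flow(h = 0, l2 = 2, Re = 400, spec = coarse_mesh_spec())
  mesh <- flow$mesh
  expect_lt(max(abs(flow$w - (1 - mesh$r_nodes^2))), 1e-8)
  expect_lt(max(abs(flow$u)), 1e-8)
  rates <- rate_fields(flow)
  # analytic rates: gamma = 2r, and simple shear means gamma = omega
  expect_lt(max(abs(rates$gamma_dot - 2 * mesh$r_nodes)), 1e-6)
  expect_lt(max(abs(rates$gamma_dot - rates$omega_dot)), 1e-7)
  # scaled wall shear rate 2 Re everywhere on the wall
  wall <- mesh$boundary$wall
  expect_equal(flow$Re * rates$gamma_dot[wall], rep(2 * 400, mesh$nz),
               tolerance = 1e-6)
  expect_false(detect_recirculation(flow)$exists)
  # discrete divergence vanishes
  expect_lt(max(abs(rates$div)), 1e-6)
})

test_that("inlet and wall boundary conditions hold on the stenosed mesh", {
  flow <- cached_flow(h = 0.5, l2 = 2, Re = 400)
  mesh <- flow$mesh
  inlet <- c(mesh$boundary$inlet, 1L, mesh$nr)
  expect_lt(max(abs(flow$w[inlet] - (1 - mesh$r_nodes[inlet]^2))), 1e-7)
  expect_lt(max(abs(flow$u[inlet])), 1e-7)
  wall <- mesh$boundary$wall
  expect_lt(max(abs(flow$w[wall])), 1e-7)
  expect_lt(max(abs(flow$u[wall])), 1e-7)
  expect_lt(max(abs(flow$u[mesh$boundary$axis])), 1e-12)
})

test_that("volumetric flux is conserved through cross-sections", {
  flow <- cached_flow(h = 0.5, l2 = 2, Re = 400)
  mesh <- flow$mesh
  flux <- vapply(round(seq(2, mesh$nz - 1, length.out = 6)), function(i) {
    ks <- ((i - 1) * mesh$nr + 1):(i * mesh$nr)
    r <- mesh$r_nodes[ks]; rw <- r * flow$w[ks]
    sum(diff(r) * (rw[-1] + rw[-length(rw)]) / 2)
  }, numeric(1))
  # the streamfunction conserves flux identically; the residual spread is
  # the trapezoid quadrature error of this coarse radial grid
  expect_lt(diff(range(flux)) / mean(flux), 5e-3)
  # and equals the inlet flux of the parabolic profile, 1/4
  expect_equal(mean(flux), 0.25, tolerance = 5e-3)
})

test_that("the stenosis accelerates and shears the flow as expected", {
  flow <- cached_flow(h = 0.5, l2 = 2, Re = 400)
  mesh <- flow$mesh
  rates <- rate_fields(flow)
  # peak shear rate at the leading edge of the stenosis near z = -2
  k <- which.max(rates$gamma_dot)
  expect_equal(rates$gamma_dot[k], 55, tolerance = 0.15)
  expect_lt(abs(mesh$z_nodes[k] - (-2)), 1)
  # bulk velocity through the throat ~4x the inlet bulk velocity
  bulk <- function(i) {
    ks <- ((i - 1) * mesh$nr + 1):(i * mesh$nr)
    r <- mesh$r_nodes[ks]; rw <- r * flow$w[ks]
    2 * sum(diff(r) * (rw[-1] + rw[-length(rw)]) / 2) / max(r)^2
  }
  i0 <- which.min(abs(mesh$z)); i_in <- 2L
  expect_equal(bulk(i0) / bulk(i_in), 4, tolerance = 0.1)
  expect_true(detect_recirculation(flow)$exists)
})

test_that("flow solution is independent of the VWF parameters (one-way coupling)", {
  # the flow solver takes only the mesh and Re; the constitutive model
  # never enters, so two transport solves with different proteins share
  # the identical flow
  flow <- cached_flow(h = 0.5, l2 = 2, Re = 400)
  expect_null(flow$params)
  expect_named(flow[c("psi", "omega", "u", "w")])
})

test_that("higher Reynolds number raises the wall shear rate", {
  f200 <- cached_flow(h = 0.5, l2 = 2, Re = 200)
  f400 <- cached_flow(h = 0.5, l2 = 2, Re = 400)
  wall <- f200$mesh$boundary$wall
  wsr200 <- 200 * rate_fields(f200)$gamma_dot[wall]
  wsr400 <- 400 * rate_fields(f400)$gamma_dot[wall]
  expect_gt(max(wsr400), max(wsr200))
})

test_that("recirculation appears for tall stenoses and not for shallow ones", {
  expect_true(detect_recirculation(cached_flow(h = 0.5, l2 = 2, Re = 400))$exists)
  rec <- detect_recirculation(cached_flow(h = 0.5, l2 = 2, Re = 400))
  # recirculation ends before the outlet (domain long enough)
  expect_lt(rec$extent[2], max(cached_flow(h = 0.5, l2 = 2, Re = 400)$mesh$z))
  expect_false(detect_recirculation(cached_flow(h = 0.1, l2 = 2, Re = 400))$exists)
})

test_that("peak shear rate is stable under mesh refinement", {
  fine <- cached_flow(h = 0.5, l2 = 2, Re = 400)                  # dz 0.08, nr 40
  coarser <- cached_flow(h = 0.5, l2 = 2, Re = 400,
                         spec = mesh_spec(dz = 0.12, dz_max = 0.8, nr = 30))
  g_fine <- max(rate_fields(fine)$gamma_dot)
  g_coarse <- max(rate_fields(coarser)$gamma_dot)
  expect_lt(abs(g_fine - g_coarse) / g_fine, 0.02)
})

test_that("Re outside the laminar steady regime is rejected", {
  mesh <- build_mesh(stenosis_geometry(h = 0), coarse_mesh_spec())
  expect_error(solve_flow(mesh, Re = 900), "laminar")
  expect_error(solve_flow(mesh, Re = 0), "laminar")
})
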