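# Shared, lazily computed PDE cases. Flow and transport solves are the
# expensive part of the suite, so each distinct case is solved once and
# reused across test files. The test meshes are coarser than the package
# defaults but fine enough for the quoted tolerances.

.case_cache <- new.env(parent = emptyenv())

test_mesh_spec <- function() mesh_spec(dz = 0.08, dz_max = 0.7, nr = 40)

coarse_mesh_spec <- function() mesh_spec(dz = 0.15, dz_max = 1, nr = 26)

cached_flow <- function(h, l2, Re, spec = test_mesh_spec(), l1 = 1.5) {
  key <- sprintf("flow_%g_%g_%g_%g_%d", h, l2, Re, spec$dz, spec$nr)
  if (is.null(.case_cache[[key]])) {
    mesh <- build_mesh(stenosis_geometry(h = h, l1 = l1, l2 = l2), spec)
    .case_cache[[key]] <- solve_flow(mesh, Re = Re)
  }
  .case_cache[[key]]
}

cached_case <- function(h, l2, Re, spec = test_mesh_spec(), Pe = 1e3) {
  key <- sprintf("case_%g_%g_%g_%g_%d_%g", h, l2, Re, spec$dz, spec$nr, Pe)
  if (is.null(.case_cache[[key]])) {
    flow <- cached_flow(h, l2, Re, spec)
    tf <- solve_vwf_field(flow, groups_from_table(Re = Re), Pe = Pe)
    .case_cache[[key]] <- list(flow = flow, tensor = tf,
                               wall = wall_series(flow, tf))
  }
  .case_cache[[key]]
}

table1_params <- function() vwf_params()
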