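# Wall series, elongational-flow regions, and field export.

#' Wall shear-rate and extension series
#'
#' Samples the scaled wall shear rate (WSR, the dimensionless shear rate
#' multiplied by Re) and the VWF extension along the wall boundary, ordered
#' by axial position, and reports the maxima and their locations. The
#' extension is also expressed as a percentage of the maximum achievable
#' extension \eqn{\mathcal{E}_{max} = L/\sqrt{2} - 1}.
#'
#' @param flow A [solve_flow()] result.
#' @param tensor_field A [solve_vwf_field()] result on the same mesh.
#' @return A data frame (class `wall_series`) with columns `z`, `r_wall`,
#'   `gamma_dot`, `wsr`, `extension`, `extension_pct`; attributes `max_wsr`,
#'   `max_extension_pct`, `z_max_wsr`, `z_max_extension`.
#' @export
wall_series <- function(flow, tensor_field) {
  stopifnot(inherits(flow, "flow_field"), inherits(tensor_field, "tensor_field"))
  if (!identical(flow$mesh$z, tensor_field$mesh$z) ||
      !identical(flow$mesh$eta, tensor_field$mesh$eta))
    stop("flow and tensor field live on different meshes")
  mesh <- flow$mesh
  wall <- mesh$boundary$wall
  rates <- rate_fields(flow)
  e_max <- tensor_field$groups$L_max / sqrt(2) - 1
  out <- data.frame(z = mesh$z, r_wall = mesh$R,
                    gamma_dot = rates$gamma_dot[wall],
                    wsr = flow$Re * rates$gamma_dot[wall],
                    extension = tensor_field$extension[wall],
                    extension_pct = 100 * tensor_field$extension[wall] / e_max)
  attr(out, "max_wsr") <- max(out$wsr)
  attr(out, "z_max_wsr") <- out$z[which.max(out$wsr)]
  attr(out, "max_extension_pct") <- max(out$extension_pct)
  attr(out, "z_max_extension") <- out$z[which.max(out$extension_pct)]
  class(out) <- c("wall_series", "data.frame")
  out
}

# 4-connected components of a logical mask on the structured grid.
grid_components <- function(mask, nz, nr) {
  lab <- integer(length(mask))
  cur <- 0L
  idx <- function(i, j) (i - 1L) * nr + j
  for (k0 in which(mask)) {
    if (lab[k0] > 0L) next
    cur <- cur + 1L
    stack <- k0
    while (length(stack)) {
      k <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[k] > 0L || !mask[k]) next
      lab[k] <- cur
      i <- (k - 1L) %/% nr + 1L; j <- (k - 1L) %% nr + 1L
      nb <- c(if (i > 1) idx(i - 1L, j), if (i < nz) idx(i + 1L, j),
              if (j > 1) idx(i, j - 1L), if (j < nr) idx(i, j + 1L))
      stack <- c(stack, nb[mask[nb] & lab[nb] == 0L])
    }
  }
  lab
}

#' Highly elongational flow regions
#'
#' Flow is classified as highly elongational where the scalar shear rate
#' exceeds the rotation rate by at least `threshold`
#' (\eqn{\dot\gamma - \dot\omega \ge} threshold) *and* elongation
#' dominates rotation (\eqn{\dot\omega \le \dot\gamma/2}). The second
#' condition excludes the wall shear layer, where both rates are large and
#' nearly equal (locally simple shear, \eqn{\dot\gamma \approx \dot\omega})
#' but their small difference can still exceed an absolute threshold; what
#' remains is the elongation-dominated core where the flow accelerates
#' into the constriction. Connected components touching the wall layer
#' (one cell ring) are dropped as a final guard.
#'
#' @param flow A [solve_flow()] result.
#' @param tensor_field Optional [solve_vwf_field()] result; when supplied
#'   the report includes the extension attained inside the region.
#' @param threshold Positive threshold on `gamma_dot - omega_dot`
#'   (dimensionless; default 0.2).
#' @param dominance Maximum admissible `omega_dot / gamma_dot` ratio
#'   (default 0.5).
#' @return A list of class `region_report`: `exists`, node index set
#'   `nodes`, `max_gamma_dot`, and (with a tensor field) `max_length`,
#'   `max_extension` and `extension_pct_of_max`.
#' @export
elongational_region <- function(flow, tensor_field = NULL, threshold = 0.2,
                                dominance = 0.5) {
  stopifnot(inherits(flow, "flow_field"))
  if (threshold <= 0) stop("threshold must be positive")
  mesh <- flow$mesh
  rates <- rate_fields(flow)
  excess <- rates$gamma_dot - rates$omega_dot
  mask <- excess >= threshold & rates$omega_dot <= dominance * rates$gamma_dot
  j_of <- rep(seq_len(mesh$nr), mesh$nz)
  wall_layer <- j_of >= mesh$nr - 1L          # wall nodes + one cell ring
  lab <- grid_components(mask, mesh$nz, mesh$nr)
  bad <- unique(lab[mask & wall_layer])
  keep <- mask & !(lab %in% bad)
  if (!any(keep)) {
    return(structure(list(exists = FALSE, threshold = threshold,
                          nodes = integer(0), max_gamma_dot = NA_real_),
                     class = "region_report"))
  }
  rep_out <- list(exists = TRUE, threshold = threshold,
                  nodes = which(keep),
                  max_gamma_dot = max(rates$gamma_dot[keep]))
  if (!is.null(tensor_field)) {
    stopifnot(inherits(tensor_field, "tensor_field"))
    e_max <- tensor_field$groups$L_max / sqrt(2) - 1
    rep_out$max_length <- max(tensor_field$length[keep])
    rep_out$max_extension <- max(tensor_field$extension[keep])
    rep_out$extension_pct_of_max <- 100 * rep_out$max_extension / e_max
  }
  structure(rep_out, class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  if (!x$exists) {
    cat(sprintf("elongational region (threshold %.3g): empty\n", x$threshold))
  } else {
    cat(sprintf("elongational region (threshold %.3g): %d nodes, max gamma_dot %.4g\n",
                x$threshold, length(x$nodes), x$max_gamma_dot))
    if (!is.null(x$max_extension))
      cat(sprintf("  max extension %.4g (%.3g%% of achievable)\n",
                  x$max_extension, x$extension_pct_of_max))
  }
  invisible(x)
}

#' Export fields on the body-fitted mesh as legacy VTK
#'
#' Writes an ASCII legacy-VTK structured-grid file of the flow (and
#' optionally tensor) fields for inspection in ParaView or similar tools.
#'
#' @param path Output file path (`.vtk`).
#' @param flow A [solve_flow()] result.
#' @param tensor_field Optional [solve_vwf_field()] result.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, flow, tensor_field = NULL) {
  mesh <- flow$mesh
  con <- file(path, "w")
  on.exit(close(con))
  n <- mesh$n
  writeLines(c("# vtk DataFile Version 3.0",
               "vwflow axisymmetric solution", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", mesh$nr, mesh$nz),
               sprintf("POINTS %d double", n)), con)
  pts <- cbind(mesh$r_nodes, mesh$z_nodes, 0)
  utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POINT_DATA %d", n), con)
  wr_scalar <- function(name, v) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(v, digits = 9), con)
  }
  rates <- rate_fields(flow)
  wr_scalar("psi", flow$psi); wr_scalar("omega", flow$omega)
  wr_scalar("u", flow$u); wr_scalar("w", flow$w)
  wr_scalar("gamma_dot", rates$gamma_dot)
  wr_scalar("omega_dot", rates$omega_dot)
  if (!is.null(tensor_field)) {
    wr_scalar("A_rr", tensor_field$a_rr)
    wr_scalar("A_rz", tensor_field$a_rz)
    wr_scalar("A_zz", tensor_field$a_zz)
    wr_scalar("vwf_length", tensor_field$length)
    wr_scalar("vwf_extension", tensor_field$extension)
  }
  invisible(path)
}
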