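#' Per-face wall fields: shear stress, temperature and heat flux
#'
#' Enumerates every mucosal wall face of the solved domain and evaluates the
#' one-sided wall shear stress `tau = mu du_t/dn` (tangential cell-centre
#' velocity over the half-cell distance), and - when a temperature solution
#' is supplied - the local mucosal surface temperature and the Robin heat
#' flux `q = h_m (T_body - T_w)`. Faces are tagged by anatomical region:
#' `"airway"` (nostril to nasopharynx) or `"extension"` (the artificial
#' outlet duct, excluded from anatomical metrics).
#'
#' @param domain a `flow_domain`.
#' @param flow a converged `flow_solution`.
#' @param temperature optional `temperature_solution`.
#' @param props a `fluid_properties`.
#' @param bc a `boundary_conditions` (needed with `temperature`).
#' @return a `wall_field` data frame: face centroid (mm), area (m^2),
#'   outward normal axis/sign, shear vector and magnitude (Pa), and - if
#'   temperature was supplied - `Tcell`, `Tw` (K) and `q` (W/m^2).
#' @export
wall_field <- function(domain, flow, temperature = NULL,
                       props = fluid_properties(), bc = NULL) {
  stopifnot(inherits(domain, "flow_domain"))
  if (!isTRUE(flow$converged)) stopf("wall fields require a converged flow")
  d_m <- domain$spacing * 1e-3
  Tf <- NULL; h_m <- 0; T_body <- 310.15
  if (!is.null(temperature)) {
    Tf <- as.vector(temperature$T)
    h_m <- temperature$h_m
    T_body <- temperature$T_body
  }
  M <- .wall_fields(as.vector(domain$flag), dim(domain$flag),
                    as.vector(flow$u), as.vector(flow$v), as.vector(flow$w),
                    d_m, props$mu, props$k, h_m, T_body, Tf)
  df <- as.data.frame(M)
  df$area <- d_m^2
  df$x_mm <- domain$origin[1] + df$cx * domain$spacing
  df$y_mm <- domain$origin[2] + df$cy * domain$spacing
  df$z_mm <- domain$origin[3] + df$cz * domain$spacing
  df$region <- ifelse(df$y_mm <= domain$nasopharynx_mm, "airway", "extension")
  class(df) <- c("wall_field", "data.frame")
  df
}

#' @rdname wall_field
#' @export
wall_shear_field <- function(domain, flow, props = fluid_properties()) {
  wall_field(domain, flow, temperature = NULL, props = props)
}

#' Select the operated anterior turbinate region on the wall
#'
#' The operated region of each inferior turbinate is the wall surface
#' 5-20 mm posterior of the anterior peak of the turbinate (closed band,
#' measured along the posterior axis) and below the superior cutoff at the
#' lowest level of the middle turbinates. Sides are selected by the septum
#' midline and the two selections are reported together.
#'
#' @param wall a `wall_field`.
#' @param anterior_peak_y anterior peak position(s), mm; a single value or
#'   `c(left, right)`.
#' @param superior_cutoff_z superior cutoff (mm).
#' @param septum_x midline x (mm) separating left and right.
#' @param band posterior distance band, mm.
#' @return logical selection vector over the wall faces (both sides).
#' @export
define_roi <- function(wall, anterior_peak_y, superior_cutoff_z, septum_x,
                       band = c(5, 20)) {
  stopifnot(inherits(wall, "wall_field"))
  if (length(anterior_peak_y) == 1)
    anterior_peak_y <- rep(anterior_peak_y, 2)
  if (band[1] >= band[2]) stopf("ROI band lower bound must be below upper")
  left <- wall$x_mm < septum_x
  dist <- ifelse(left, wall$y_mm - anterior_peak_y[1],
                 wall$y_mm - anterior_peak_y[2])
  sel <- dist >= band[1] & dist <= band[2] &
    wall$z_mm < superior_cutoff_z & wall$region == "airway"
  if (!any(sel)) stopf("ROI selection is empty")
  sel
}

#' Integrated wall shear force
#'
#' The total wall shear force over a face selection: the area integral of
#' the shear-stress magnitude, `sum |tau| A` (N). Both sides of the nasal
#' cavities are summed when the selection spans both.
#'
#' @param wall a `wall_field`.
#' @param selection logical face selection; defaults to every anatomical
#'   airway face.
#' @return force in newtons.
#' @export
integrate_wall_force <- function(wall, selection = wall$region == "airway") {
  stopifnot(inherits(wall, "wall_field"))
  sum(wall$taumag[selection] * wall$area[selection])
}

#' Integrated wall heat transfer
#'
#' The total heat transfer from the mucosa to the air over a face selection:
#' `sum q A` (W).
#'
#' @inheritParams integrate_wall_force
#' @return heat transfer in watts.
#' @export
integrate_heat_transfer <- function(wall,
                                    selection = wall$region == "airway") {
  stopifnot(inherits(wall, "wall_field"))
  if (all(is.na(wall$q))) stopf("wall field carries no heat-flux data; supply a temperature solution")
  sum(wall$q[selection] * wall$area[selection])
}

#' Area-weighted mean mucosal surface temperature
#'
#' @param wall a `wall_field` with temperature data.
#' @param domain unused; kept for interface symmetry.
#' @param region faces to average over (default the anatomical airway).
#' @return mean wall temperature (K).
#' @export
mean_wall_temperature <- function(wall, domain = NULL, region = "airway") {
  sel <- wall$region %in% region
  sum(wall$Tw[sel] * wall$area[sel]) / sum(wall$area[sel])
}

#' Pressure loss from ambient to the nasopharynx
#'
#' The drop from the ambient total pressure at the nostrils (gauge 0) to the
#' area-averaged static pressure on the nasopharynx plane; positive during
#' inspiration.
#'
#' @param domain a `flow_domain`.
#' @param flow a converged `flow_solution`.
#' @param plane_mm y position of the evaluation plane (mm); defaults to the
#'   nasopharynx plane recorded in the domain.
#' @return pressure loss in Pa.
#' @export
pressure_loss <- function(domain, flow, plane_mm = NULL) {
  stopifnot(inherits(domain, "flow_domain"))
  if (!isTRUE(flow$converged)) stopf("pressure loss requires a converged flow")
  plane_mm <- plane_mm %||% domain$nasopharynx_mm
  j <- round((plane_mm - domain$origin[2]) / domain$spacing)
  j <- min(max(j, 1L), dim(domain$flag)[2])
  fl <- domain$flag[, j, ] == 1L
  if (!any(fl)) stopf("nasopharynx plane does not intersect the fluid")
  pslice <- flow$p[, j, ]
  0 - mean(pslice[fl])
}

#' Whole-domain energy balance
#'
#' Compares the integrated wall heat input with the enthalpy rise of the air
#' stream, `rho cp Q (T_bulk,out - T_amb)`; the relative mismatch is a
#' convergence diagnostic of the coupled solve.
#'
#' @param domain a `flow_domain`.
#' @param flow a converged `flow_solution`.
#' @param temperature a `temperature_solution`.
#' @param wall the matching `wall_field` (all regions).
#' @param props a `fluid_properties`.
#' @return list with `wall_heat_W`, `enthalpy_rise_W`, `relative_error` and
#'   `T_bulk_out_K`.
#' @export
energy_balance <- function(domain, flow, temperature, wall,
                           props = fluid_properties()) {
  d <- dim(domain$flag)
  jout <- d[2]
  fl <- domain$flag[, jout, ] == 1L
  vo <- flow$v[, jout + 1, ]
  Tout <- temperature$T[, jout, ]
  A <- (domain$spacing * 1e-3)^2
  flux <- vo[fl] * A
  Tbulk <- sum(flux * Tout[fl]) / sum(flux)
  Qh <- props$rho * props$cp * sum(flux) * (Tbulk - temperature$T_amb)
  Qw <- sum(wall$q * wall$area, na.rm = TRUE)
  list(wall_heat_W = Qw, enthalpy_rise_W = Qh,
       relative_error = abs(Qw - Qh) / max(abs(Qh), 1e-300),
       T_bulk_out_K = Tbulk)
}

#' Export wall faces as VTK polydata
#'
#' Writes the wall-face centroids with shear magnitude, heat flux and wall
#' temperature as a legacy ASCII VTK polydata point cloud for inspection in
#' ParaView-like tools.
#'
#' @param wall a `wall_field`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_wall_vtk <- function(wall, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(wall)
  writeLines(c("# vtk DataFile Version 3.0", "rhinoflow wall field",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%g %g %g", wall$x_mm, wall$y_mm, wall$z_mm), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines(c("SCALARS wss float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", wall$taumag), con)
  if (!all(is.na(wall$q))) {
    writeLines(c("SCALARS heat_flux float 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", wall$q), con)
    writeLines(c("SCALARS wall_temp float 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", wall$Tw), con)
  }
  invisible(path)
}

#' Export cell fields as legacy VTK structured points
#'
#' @param domain a `flow_domain`.
#' @param flow a `flow_solution`.
#' @param temperature optional `temperature_solution`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_fields_vtk <- function(domain, flow, temperature = NULL, path) {
  d <- dim(domain$flag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "rhinoflow cell fields",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", domain$origin[1],
                       domain$origin[2], domain$origin[3]),
               sprintf("SPACING %g %g %g", domain$spacing, domain$spacing,
                       domain$spacing),
               sprintf("POINT_DATA %d", prod(d))), con)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", as.vector(flow$p)), con)
  # cell-centre velocity
  ucc <- 0.5 * (flow$u[1:d[1], , ] + flow$u[2:(d[1] + 1), , ])
  vcc <- 0.5 * (flow$v[, 1:d[2], ] + flow$v[, 2:(d[2] + 1), ])
  wcc <- 0.5 * (flow$w[, , 1:d[3]] + flow$w[, , 2:(d[3] + 1)])
  writeLines("VECTORS velocity float", con)
  writeLines(sprintf("%g %g %g", as.vector(ucc), as.vector(vcc),
                     as.vector(wcc)), con)
  if (!is.null(temperature)) {
    writeLines(c("SCALARS temperature float 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", as.vector(temperature$T)), con)
  }
  invisible(path)
}
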