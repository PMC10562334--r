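#' Physical properties of the inspired air
#'
#' Air at room temperature, treated as constant: temperature is carried as a
#' passive scalar (no buoyancy), consistent with the incompressible laminar
#' flow model.
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @param k thermal conductivity (W/m K).
#' @param cp specific heat capacity (J/kg K).
#' @return a `fluid_properties` object.
#' @export
fluid_properties <- function(rho = 1.18, mu = 1.85e-5, k = 0.0262,
                             cp = 1006) {
  stopifnot(rho > 0, mu > 0, k > 0, cp > 0)
  structure(list(rho = rho, mu = mu, k = k, cp = cp),
            class = "fluid_properties")
}

#' Boundary conditions for the nasal flow solve
#'
#' A uniform total-pressure condition (gauge 0) over the nostril faces, a
#' flow-rate-enforcing uniform-velocity outlet, no-slip rigid mucosal walls,
#' ambient inlet air and a Robin mucosal heat-transfer law
#' `q = h_m (T_body - T_mucous)`.
#'
#' @param Q target volumetric flow rate (m^3/s); see
#'   [simulation_flow_rate()].
#' @param T_amb ambient (inhaled) air temperature (K).
#' @param T_body deep body temperature (K).
#' @param h_m mucosal heat-transfer coefficient (W/m^2 K), uniform over the
#'   mucosa; `h_m = 0` gives adiabatic walls.
#' @return a `boundary_conditions` object.
#' @export
boundary_conditions <- function(Q, T_amb = 293.15, T_body = 310.15,
                                h_m = 50) {
  stopifnot(Q > 0, h_m >= 0)
  if (T_amb >= T_body) stopf("ambient temperature must be below body temperature")
  structure(list(Q = Q, T_amb = T_amb, T_body = T_body, h_m = h_m),
            class = "boundary_conditions")
}

#' Patient-specific mean inspiratory flow rate
#'
#' Allometric minute-ventilation model by sex and body weight:
#' males `1.36 * M^0.44` and females `1.89 * M^0.32` litres per minute.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param weight body weight M in kg.
#' @return mean inspiratory flow rate, L/min.
#' @export
patient_flow_rate <- function(sex, weight) {
  if (any(weight <= 0)) stopf("weight must be positive")
  sex <- match.arg(tolower(sex), c("male", "female"), several.ok = TRUE)
  ifelse(sex == "male", 1.36 * weight^0.44, 1.89 * weight^0.32)
}

#' Steady simulation flow rate
#'
#' The steady-state inspiratory rate used in the solver is twice the mean
#' flow rate (peak inspiration of a sinusoidal breath), converted to SI. The
#' same rate is used for a subject's pre- and postoperative runs.
#'
#' @param mean_rate mean inspiratory flow rate, L/min.
#' @return volumetric flow rate Q in m^3/s.
#' @export
simulation_flow_rate <- function(mean_rate) {
  stopifnot(all(mean_rate > 0))
  2 * mean_rate / 6e4
}

#' Build a staggered-grid flow domain from an airway mask
#'
#' Converts a cleaned, cropped and extended airway mask into the voxel-native
#' finite-volume domain: fluid/solid cell flags with one layer of solid
#' padding in x and z, inlet faces on the first y slice, outlet faces on the
#' last, and every other fluid boundary face a no-slip mucosal wall.
#' Selected lateral sides can be marked as free-slip symmetry walls
#' (used by duct validation cases).
#'
#' @param mask an `airway_mask` whose first y slice is the nostril plane and
#'   last y slice the outlet.
#' @param slip character vector among `"x"`, `"z"`: treat the solid padding
#'   along those axes as free-slip symmetry planes.
#' @return a `flow_domain`.
#' @export
build_domain <- function(mask, slip = character()) {
  stopifnot(inherits(mask, "airway_mask"))
  m <- mask$mask
  d <- dim(m)
  if (!any(m[, 1, ])) stopf("inlet face set empty: no airway on the first y slice")
  if (!any(m[, d[2], ])) stopf("outlet face set empty: no airway on the last y slice")
  flag <- array(0L, d + c(2, 0, 2))
  flag[2:(d[1] + 1), , 2:(d[3] + 1)] <- ifelse(m, 1L, 0L)
  if ("x" %in% slip) {
    flag[1, , ][flag[2, , ] == 1L] <- 2L
    flag[d[1] + 2, , ][flag[d[1] + 1, , ] == 1L] <- 2L
  }
  if ("z" %in% slip) {
    flag[, , 1][flag[, , 2] == 1L] <- 2L
    flag[, , d[3] + 2][flag[, , d[3] + 1] == 1L] <- 2L
  }
  # reject fluid cells unreachable from the inlet
  lab <- .cc_label6(as.vector(flag == 1L), dim(flag))
  lab <- array(lab, dim = dim(flag))
  inlet_labs <- setdiff(unique(as.vector(lab[, 1, ])), 0L)
  stray <- sum(flag == 1L & !(lab %in% inlet_labs))
  if (stray > 0)
    stopf("%d fluid cells are not connected to the inlet; clean the mask first",
          stray)
  origin <- mask$origin - c(mask$spacing, 0, mask$spacing)
  np <- attr(mask, "nasopharynx_mm") %||%
    mask$provenance$crop$nasopharynx_y %||%
    (mask$origin[2] + d[2] * mask$spacing)
  structure(list(flag = flag, spacing = mask$spacing, origin = origin,
                 nasopharynx_mm = np,
                 n_fluid = sum(flag == 1L)),
            class = "flow_domain")
}

#' @export
print.flow_domain <- function(x, ...) {
  d <- dim(x$flag)
  cat(sprintf("flow domain: %d x %d x %d cells at %.3g mm, %d fluid cells\n",
              d[1], d[2], d[3], x$spacing, x$n_fluid))
  invisible(x)
}

#' Solve steady laminar incompressible flow
#'
#' SIMPLE pressure-velocity coupling on the staggered voxel grid with
#' first-order upwind convection and central diffusion. The nostril inlet
#' carries a uniform total-pressure condition (static pressure
#' `-rho |u|^2 / 2`, gauge total pressure 0); the outlet imposes the uniform
#' velocity that delivers the target flow rate `bc$Q`; walls are rigid and
#' no-slip.
#'
#' @param domain a `flow_domain`.
#' @param props a `fluid_properties`.
#' @param bc a `boundary_conditions`.
#' @param tol convergence tolerance on the scaled momentum residual.
#' @param tol_continuity tolerance on the scaled continuity residual.
#' @param max_iter maximum outer SIMPLE iterations.
#' @param relax_u,relax_p under-relaxation factors for velocity and pressure.
#' @param verbose print residuals every 50 iterations.
#' @return a `flow_solution` with staggered face velocities (m/s), cell
#'   pressures (Pa), residual history and achieved flow rate.
#' @export
solve_flow <- function(domain, props = fluid_properties(), bc,
                       tol = 1e-5, tol_continuity = 1e-7,
                       max_iter = 20000, relax_u = 0.5, relax_p = 0.2,
                       verbose = FALSE) {
  stopifnot(inherits(domain, "flow_domain"), inherits(bc, "boundary_conditions"))
  d_m <- domain$spacing * 1e-3
  A <- d_m^2
  n_out <- sum(domain$flag[, dim(domain$flag)[2], ] == 1L)
  vout <- bc$Q / (n_out * A)
  run_once <- function(ru, rp) {
    .simple_solve(as.vector(domain$flag), dim(domain$flag), d_m,
                  props$rho, props$mu, vout, ru, rp,
                  tol, tol_continuity, as.integer(max_iter), 2L,
                  80L, 3e-2, verbose)
  }
  res <- run_once(relax_u, relax_p)
  # a divergent transient (sharp stair-step constrictions at coarse spacing)
  # is retried with stronger under-relaxation
  tries <- 0
  while (!res$converged && !is.finite(tail_(res$res_mom)) && tries < 2) {
    tries <- tries + 1
    relax_u <- relax_u * 0.6
    relax_p <- relax_p * 0.6
    res <- run_once(relax_u, relax_p)
  }
  if (!res$converged) {
    e <- simpleError(sprintf(
      "flow solve did not converge in %d iterations (momentum %.3g, continuity %.3g)",
      length(res$res_mom), tail_(res$res_mom), tail_(res$res_cont)))
    e$residual_history <- list(momentum = res$res_mom,
                               continuity = res$res_cont)
    stop(e)
  }
  achieved <- res$Q_in
  if (abs(achieved - bc$Q) / bc$Q > 1e-3)
    warning(sprintf("achieved flow rate off target by %.2g%%",
                    100 * abs(achieved - bc$Q) / bc$Q))
  dd <- dim(domain$flag)
  structure(list(
    u = array(res$u, dd + c(1, 0, 0)),
    v = array(res$v, dd + c(0, 1, 0)),
    w = array(res$w, dd + c(0, 0, 1)),
    p = array(res$p, dd),
    residuals = list(momentum = res$res_mom, continuity = res$res_cont),
    Q_target = bc$Q, Q_achieved = achieved, v_out = vout,
    converged = TRUE, domain_dim = dd),
    class = "flow_solution")
}

tail_ <- function(x) if (length(x)) x[length(x)] else NA_real_

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow solution: %d outer iterations, Q = %.4g m3/s (target %.4g)\n",
              length(x$residuals$momentum), x$Q_achieved, x$Q_target))
  cat(sprintf("  final residuals: momentum %.2e, continuity %.2e\n",
              tail_(x$residuals$momentum), tail_(x$residuals$continuity)))
  invisible(x)
}

#' Solve the steady temperature field with Robin mucosal walls
#'
#' Advection-diffusion of temperature on the converged flow: inlet air enters
#' at ambient temperature, the outlet is zero-gradient, and at every mucosal
#' wall face the Robin flux `q = h_m (T_body - T_w)` is balanced against the
#' one-sided conductive flux into the near-wall air, which determines the
#' local mucosal surface temperature. An upwind scheme keeps the field inside
#' `[T_amb, T_body]`.
#'
#' @param domain a `flow_domain`.
#' @param flow a converged `flow_solution`.
#' @param props a `fluid_properties`.
#' @param bc a `boundary_conditions` (uses `T_amb`, `T_body`, `h_m`).
#' @param tol relative residual tolerance.
#' @param max_sweeps Gauss-Seidel sweep limit.
#' @return a `temperature_solution` with the cell temperature array (K) and
#'   solver diagnostics.
#' @export
solve_temperature <- function(domain, flow, props = fluid_properties(), bc,
                              tol = 1e-8, max_sweeps = 20000) {
  stopifnot(inherits(domain, "flow_domain"))
  if (!isTRUE(flow$converged))
    stopf("temperature solve requires a converged flow solution")
  d_m <- domain$spacing * 1e-3
  res <- .temp_solve(as.vector(domain$flag), dim(domain$flag),
                     as.vector(flow$u), as.vector(flow$v), as.vector(flow$w),
                     d_m, props$rho, props$cp, props$k,
                     bc$h_m, bc$T_amb, bc$T_body, tol,
                     as.integer(max_sweeps))
  structure(list(T = array(res$T, dim(domain$flag)),
                 residual = res$residual, sweeps = res$sweeps,
                 h_m = bc$h_m, T_amb = bc$T_amb, T_body = bc$T_body),
            class = "temperature_solution")
}

#' Mucosal surface temperature from the Robin heat-flux law
#'
#' Inverts `q = h_m (T_body - T_mucous)` for the local mucosal surface
#' temperature. With zero local heat flux the mucosa sits at deep body
#' temperature (37 C).
#'
#' @param q local heat flux from mucosa to air (W/m^2).
#' @param h_m mucosal heat-transfer coefficient (W/m^2 K), > 0.
#' @param T_body body temperature (K).
#' @return mucosal surface temperature (K).
#' @export
robin_wall_temperature <- function(q, h_m = 50, T_body = 310.15) {
  stopifnot(h_m > 0)
  T_body - q / h_m
}

#' Calibrate the mucosal heat-transfer coefficient
#'
#' Bisection on `h_m` until the area-weighted mean mucosal surface
#' temperature over the anatomical airway matches a clinical target
#' (by default 32 C = 305.15 K). The flow field is independent of `h_m`
#' (passive scalar), so only the temperature equation is re-solved.
#'
#' @param domain a `flow_domain`.
#' @param flow a converged `flow_solution`.
#' @param props a `fluid_properties`.
#' @param bc a `boundary_conditions` (its `h_m` is ignored).
#' @param target target mean mucosal temperature (K).
#' @param range bisection bracket for `h_m` (W/m^2 K).
#' @param tol_K accept when the mean is within this many kelvin of target.
#' @param max_iter bisection iteration limit.
#' @return list with `h_m`, `mean_wall_K`, achievable `range_K`, and the
#'   number of temperature solves.
#' @export
calibrate_h_m <- function(domain, flow, props = fluid_properties(), bc,
                          target = 305.15, range = c(5, 500),
                          tol_K = 0.1, max_iter = 40) {
  stopifnot(inherits(domain, "flow_domain"))
  if (target >= bc$T_body)
    stopf("target %.2f K is unreachable: Robin walls approach body temperature (%.2f K) only as h_m -> Inf",
          target, bc$T_body)
  mean_at <- function(h) {
    bch <- bc; bch$h_m <- h
    tmp <- solve_temperature(domain, flow, props, bch)
    wf <- wall_field(domain, flow, tmp, props, bch)
    mean_wall_temperature(wf, domain)
  }
  lo <- range[1]; hi <- range[2]
  mlo <- mean_at(lo); mhi <- mean_at(hi)
  nev <- 2
  if (target < mlo || target > mhi)
    stopf("target %.2f K outside achievable mean wall temperature [%.2f, %.2f] K for h_m in [%g, %g]",
          target, mlo, mhi, lo, hi)
  mid <- NA_real_; mmid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    mmid <- mean_at(mid); nev <- nev + 1
    if (abs(mmid - target) <= tol_K) break
    if (mmid < target) lo <- mid else hi <- mid
  }
  list(h_m = mid, mean_wall_K = mmid, range_K = c(mlo, mhi),
       n_solves = nev)
}
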