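# shared fixtures, memoised so expensive solves run once per test session

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# plane Poiseuille channel: gap `nx` cells across x, slip walls in z
channel_case <- function(nx = 20, nz = 4, aspect = 3, d = 0.5, U = 0.002) {
  ny <- nx * aspect
  mask <- rhinoflow:::airway_mask(array(TRUE, c(nx, ny, nz)), d)
  dom <- build_domain(mask, slip = "z")
  h <- nx * d * 1e-3
  W <- nz * d * 1e-3
  list(dom = dom, h = h, W = W, L = ny * d * 1e-3, U = U,
       Q = U * h * W, nx = nx, ny = ny, d = d)
}

channel_solution <- function(nx = 20, U = 0.002) {
  memo(sprintf("chan_%d_%g", nx, U), {
    cc <- channel_case(nx = nx, U = U)
    bc <- boundary_conditions(Q = cc$Q, h_m = 50)
    props <- fluid_properties()
    fs <- solve_flow(cc$dom, props, bc)
    tmp <- solve_temperature(cc$dom, fs, props, bc)
    c(cc, list(flow = fs, temp = tmp, bc = bc, props = props,
               wall = wall_field(cc$dom, fs, tmp, props, bc)))
  })
}

# developed-region pressure gradient of a channel solution
channel_gradient <- function(cs) {
  j1 <- round(0.4 * cs$ny); j2 <- round(0.75 * cs$ny)
  fl1 <- cs$dom$flag[, j1, ] == 1L
  fl2 <- cs$dom$flag[, j2, ] == 1L
  (mean(cs$flow$p[, j1, ][fl1]) - mean(cs$flow$p[, j2, ][fl2])) /
    ((j2 - j1) * cs$d * 1e-3)
}

# default nasal phantom solved at the doubled 70-kg-male flow rate, h_m = 50
default_solution <- function(reduction = 0) {
  memo(sprintf("phantom_r%g", reduction), {
    ph <- generate_phantom(phantom_params(), reduction = reduction)
    lm <- ph$truth$landmarks
    mask <- remove_isolated_regions(threshold_airway(ph$volume),
                                    lm$nostril_plane, lm$nasopharynx_plane)
    mask <- crop_domain(mask, lm$nostril_plane, lm$nasopharynx_plane, 50)
    dom <- build_domain(mask)
    Q <- simulation_flow_rate(patient_flow_rate("male", 70))
    bc <- boundary_conditions(Q = Q, h_m = 50)
    props <- fluid_properties()
    fs <- solve_flow(dom, props, bc)
    tmp <- solve_temperature(dom, fs, props, bc)
    wf <- wall_field(dom, fs, tmp, props, bc)
    roi <- define_roi(wf, lm$anterior_peak$left["y"],
                      lm$middle_turbinate_z, lm$septum_x)
    list(phantom = ph, dom = dom, bc = bc, props = props,
         flow = fs, temp = tmp, wall = wf, roi = roi,
         roi_force = integrate_wall_force(wf, roi),
         roi_volume = measure_volume(
           rhinoflow:::airway_mask(ph$truth$airway, ph$params$spacing),
           y_range = lm$anterior_peak$left["y"] + ph$truth$roi_band,
           z_range = c(0, lm$middle_turbinate_z)),
         dp = pressure_loss(dom, fs))
  })
}

surgery_sweep <- function(rs = c(0, 0.3, 0.6, 0.9)) {
  memo("sweep", lapply(rs, default_solution))
}
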