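#' Parameters of the synthetic nasal phantom
#'
#' Defines an idealized bilateral nasal airway used as a stand-in for patient
#' cone-beam CT data: two mirror-image channels separated by a septum, each
#' carrying a smooth inferior-turbinate-like bump on its lateral wall, merging
#' posteriorly into a common nasopharynx. All lengths are millimetres.
#'
#' @param spacing isotropic voxel spacing (mm).
#' @param length nostril plane to nasopharynx plane distance (mm).
#' @param channel_width width of each nasal channel in x (mm).
#' @param channel_height height of each channel in z (mm).
#' @param septum septum thickness (mm).
#' @param turbinate_amplitude bump amplitude per side (mm, length 2:
#'   left, right); must stay below `channel_width`.
#' @param turbinate_peak anterior peak position, mm posterior of the nostril
#'   plane (onset of the turbinate bump).
#' @param turbinate_length posterior extent of the bump (mm).
#' @param turbinate_height vertical extent of the bump above the channel
#'   floor (mm); also the ground-truth level of the lowest point of the
#'   middle turbinates (the superior cutoff of the operated region).
#' @param merge_length posterior segment over which the septum is absent and
#'   the two channels merge (mm).
#' @param margin_x,margin_z_bottom,margin_z_top tissue padding (mm).
#' @param sinus_pocket logical; add an isolated air pocket (emulating a
#'   paranasal sinus) disconnected from the airway.
#' @param air_hu,tissue_hu Hounsfield values of air and soft tissue.
#' @param noise_sd Gaussian image noise, HU.
#' @param seed integer seed controlling the noise field.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(spacing = 0.5,
                           length = 55,
                           channel_width = 5,
                           channel_height = 18,
                           septum = 2,
                           turbinate_amplitude = c(2.5, 2.5),
                           turbinate_peak = 10,
                           turbinate_length = 25,
                           turbinate_height = 12,
                           merge_length = 10,
                           margin_x = 2,
                           margin_z_bottom = 2,
                           margin_z_top = 5,
                           sinus_pocket = FALSE,
                           air_hu = -1000,
                           tissue_hu = 40,
                           noise_sd = 30,
                           seed = 1L) {
  if (length(turbinate_amplitude) == 1)
    turbinate_amplitude <- rep(turbinate_amplitude, 2)
  p <- list(spacing = spacing, length = length,
            channel_width = channel_width, channel_height = channel_height,
            septum = septum, turbinate_amplitude = turbinate_amplitude,
            turbinate_peak = turbinate_peak,
            turbinate_length = turbinate_length,
            turbinate_height = turbinate_height,
            merge_length = merge_length, margin_x = margin_x,
            margin_z_bottom = margin_z_bottom, margin_z_top = margin_z_top,
            sinus_pocket = sinus_pocket, air_hu = air_hu,
            tissue_hu = tissue_hu, noise_sd = noise_sd, seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$spacing <= 0) stopf("spacing must be positive")
  dims <- c(p$length, p$channel_width, p$channel_height, p$septum,
            p$turbinate_length, p$turbinate_height, p$merge_length)
  if (any(dims <= 0)) stopf("all phantom dimensions must be positive")
  if (any(p$turbinate_amplitude < 0))
    stopf("turbinate amplitude must be non-negative")
  if (any(p$turbinate_amplitude >= p$channel_width))
    stopf("turbinate bump (%.2f mm) would occlude the %.2f mm channel",
          max(p$turbinate_amplitude), p$channel_width)
  if (p$turbinate_height > p$channel_height)
    stopf("turbinate height exceeds channel height")
  if (p$noise_sd < 0) stopf("noise sd must be non-negative")
  invisible(p)
}

# grid dimensions (voxels) implied by phantom parameters
phantom_dims <- function(p) {
  sx <- 2 * p$margin_x + 2 * p$channel_width + p$septum
  sy <- p$length
  sz <- p$margin_z_bottom + p$channel_height + p$margin_z_top
  round(c(sx, sy, sz) / p$spacing)
}

# turbinate bump amplitude profile a(y) for one side, after scaling the
# operated 5-20 mm band by (1 - r)
bump_profile <- function(y, amp, peak, len, r = 0, band = c(5, 20)) {
  a <- numeric(length(y))
  inb <- y > peak & y < peak + len
  a[inb] <- amp * sin(pi * (y[inb] - peak) / len)^2
  if (r > 0) {
    op <- y >= peak + band[1] & y <= peak + band[2]
    a[op] <- a[op] * (1 - r)
  }
  a
}

# voxel-centre membership of the airway (and pocket); returns logical arrays
phantom_geometry <- function(p, r = c(0, 0)) {
  d <- phantom_dims(p)
  s <- p$spacing
  xc <- (seq_len(d[1]) - 0.5) * s
  yc <- (seq_len(d[2]) - 0.5) * s
  zc <- (seq_len(d[3]) - 0.5) * s

  xl0 <- p$margin_x                      # left channel lateral wall
  xl1 <- xl0 + p$channel_width
  xr1 <- xl1 + p$septum                  # right channel medial wall
  xr0 <- xr1 + p$channel_width           # right channel lateral wall
  z0 <- p$margin_z_bottom
  z1 <- z0 + p$channel_height
  zmt <- z0 + p$turbinate_height
  ymerge <- p$length - p$merge_length

  aL <- bump_profile(yc, p$turbinate_amplitude[1], p$turbinate_peak,
                     p$turbinate_length, r[1])
  aR <- bump_profile(yc, p$turbinate_amplitude[2], p$turbinate_peak,
                     p$turbinate_length, r[2])

  X <- array(rep(xc, times = d[2] * d[3]), dim = d)
  Z <- array(rep(zc, each = d[1] * d[2]), dim = d)
  Y <- array(rep(rep(yc, each = d[1]), times = d[3]), dim = d)
  AY_L <- array(rep(rep(aL, each = d[1]), times = d[3]), dim = d)
  AY_R <- array(rep(rep(aR, each = d[1]), times = d[3]), dim = d)

  inz <- Z > z0 & Z < z1
  bumpz <- Z > z0 & Z < zmt
  left <- X > xl0 & X < xl1
  right <- X > xr1 & X < xr0
  merged <- Y > ymerge & X > xl0 & X < xr0

  air <- inz & (left | right | merged)
  # carve the turbinate bumps (lateral walls protrude inward below zmt)
  air[bumpz & left & (X - xl0 < AY_L)] <- FALSE
  air[bumpz & right & (xr0 - X < AY_R)] <- FALSE

  pocket <- array(FALSE, dim = d)
  if (isTRUE(p$sinus_pocket)) {
    ctr <- c((xl0 + xl1) / 2, p$length * 0.5, z1 + (p$margin_z_top) / 2)
    rad <- c(1.5, 3, min(1.0, p$margin_z_top / 2 - 1))
    pocket <- ((X - ctr[1]) / rad[1])^2 + ((Y - ctr[2]) / rad[2])^2 +
      ((Z - ctr[3]) / rad[3])^2 < 1
    pocket <- pocket & !air
  }
  list(air = air, pocket = pocket, dims = d,
       landmarks = list(
         nostril_plane = 0, nasopharynx_plane = p$length,
         anterior_peak = list(
           left = c(x = xl0, y = p$turbinate_peak, z = z0),
           right = c(x = xr0, y = p$turbinate_peak, z = z0)),
         middle_turbinate_z = zmt,
         septum_x = (xl1 + xr1) / 2))
}

#' Generate a synthetic CBCT-like nasal volume with ground truth
#'
#' Builds the bilateral channel phantom described by [phantom_params()],
#' voxelizes it at the requested spacing, assigns Hounsfield units (air near
#' -1000, soft tissue near +40) with additive Gaussian noise, and returns the
#' image together with the exact geometric ground truth. HU values are
#' clipped to the scanner range [-1000, 3000], so noisy air voxels never
#' leave the air segmentation window.
#'
#' @param params a `phantom_params` object.
#' @param reduction surgical reduction fraction per side in \[0, 1\]
#'   (0 = preoperative anatomy).
#' @return a `nasal_phantom`: list with `volume` (an `hu_volume`), `truth`
#'   (ground-truth masks and landmarks), `params` and `reduction`.
#' @export
generate_phantom <- function(params = phantom_params(), reduction = c(0, 0)) {
  if (length(reduction) == 1) reduction <- rep(reduction, 2)
  if (any(reduction < 0 | reduction > 1))
    stopf("reduction fraction must lie in [0, 1]")
  validate_phantom_params(params)
  g <- phantom_geometry(params, reduction)
  d <- g$dims
  base <- array(params$tissue_hu, dim = d)
  base[g$air | g$pocket] <- params$air_hu
  vals <- base
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed,
                       array(rnorm(prod(d), 0, params$noise_sd), dim = d))
    vals <- base + noise
  }
  vals[vals < -1000] <- -1000
  vals[vals > 3000] <- 3000

  band <- c(5, 20)
  yb <- c(params$turbinate_peak + band[1], params$turbinate_peak + band[2])
  yc <- (seq_len(d[2]) - 0.5) * params$spacing
  zc <- (seq_len(d[3]) - 0.5) * params$spacing
  xc <- (seq_len(d[1]) - 0.5) * params$spacing
  inband <- yc >= yb[1] & yc <= yb[2]
  belowmt <- zc < g$landmarks$middle_turbinate_z
  sel <- g$air &
    array(rep(rep(inband, each = d[1]), times = d[3]), dim = d) &
    array(rep(belowmt, each = d[1] * d[2]), dim = d)
  leftx <- xc < g$landmarks$septum_x
  roi_left <- sel & array(leftx, dim = d)
  roi_right <- sel & !array(leftx, dim = d)
  vox_cm3 <- (params$spacing / 10)^3

  truth <- list(
    airway = g$air,
    pocket = g$pocket,
    roi_left = roi_left,
    roi_right = roi_right,
    roi_band = band,
    landmarks = g$landmarks,
    roi_volume_cm3 = sum(sel) * vox_cm3
  )
  out <- list(
    volume = hu_volume(vals, spacing = params$spacing),
    truth = truth,
    params = params,
    reduction = reduction
  )
  class(out) <- "nasal_phantom"
  out
}

#' Apply virtual turbinate reduction surgery to a phantom
#'
#' Rescales the turbinate bump by `1 - r` inside the operated band 5-20 mm
#' posterior of the anterior peak and regenerates the volume with the same
#' noise realization, so voxels outside the operated band are bit-identical
#' to the preoperative image.
#'
#' @param phantom a `nasal_phantom`.
#' @param r reduction fraction per side (scalar or length 2) in \[0, 1\].
#' @return the postoperative `nasal_phantom`.
#' @export
apply_surgery <- function(phantom, r) {
  stopifnot(inherits(phantom, "nasal_phantom"))
  if (length(r) == 1) r <- rep(r, 2)
  if (any(r < 0 | r > 1)) stopf("reduction fraction must lie in [0, 1]")
  generate_phantom(phantom$params, reduction = r)
}

#' @export
print.nasal_phantom <- function(x, ...) {
  d <- dim(x$volume$values)
  cat(sprintf("nasal phantom: %d x %d x %d voxels at %.2g mm\n",
              d[1], d[2], d[3], x$volume$spacing))
  cat(sprintf("  airway voxels: %d  (%.2f cm3)\n", sum(x$truth$airway),
              sum(x$truth$airway) * (x$volume$spacing / 10)^3))
  cat(sprintf("  reduction: left %.2f right %.2f\n",
              x$reduction[1], x$reduction[2]))
  invisible(x)
}

#' Outcome-coupling parameters for the synthetic cohort
#'
#' Controls how simulated patient-reported outcomes are statistically coupled
#' to the true geometric effect of surgery. The visual analogue scale (VAS)
#' change is tied to the change in a wall-shear-force surrogate through a
#' Gaussian copula whose Pearson parameter is chosen so the population
#' Spearman rank correlation matches `target_rho`.
#'
#' @param target_rho target Spearman correlation between the VAS change and
#'   the wall-shear-force change (positive: larger force decrease goes with
#'   larger symptom relief).
#' @param delta_vas_mean,delta_vas_sd mean and sd of the VAS change score
#'   (negative mean = average improvement).
#' @param ghsi_slope,ghsi_noise_sd linear dependence of the GHSI change on
#'   the VAS change, plus independent noise (GHSI rises as VAS falls).
#' @param rhinometry_noise_sd measurement noise of the acoustic-rhinometry
#'   volume proxy (cm^3).
#' @return a `coupling_params` object.
#' @export
coupling_params <- function(target_rho = 0.4,
                            delta_vas_mean = -2.5,
                            delta_vas_sd = 1.5,
                            ghsi_slope = -3,
                            ghsi_noise_sd = 6,
                            rhinometry_noise_sd = 0.3) {
  if (abs(target_rho) > 1) stopf("|target_rho| must be <= 1")
  structure(list(target_rho = target_rho,
                 delta_vas_mean = delta_vas_mean,
                 delta_vas_sd = delta_vas_sd,
                 ghsi_slope = ghsi_slope,
                 ghsi_noise_sd = ghsi_noise_sd,
                 rhinometry_noise_sd = rhinometry_noise_sd),
            class = "coupling_params")
}

#' Analytic wall-shear-force surrogate for a phantom geometry
#'
#' A one-dimensional lubrication estimate of the integrated wall shear force
#' in the operated 5-20 mm band: each side is treated as a plane channel
#' whose local gap follows the turbinate profile, the flow split between the
#' sides follows their viscous resistances, and the local shear is the
#' fully developed plane-channel value 6 mu q / (H g(y)^2). Used by the
#' cohort generator to couple outcome scores to geometry without running the
#' full solver, and as an independent fast stand-in for the solver metric in
#' statistical recovery checks.
#'
#' @param params a `phantom_params`.
#' @param r reduction fraction per side.
#' @param Q total volumetric flow rate (m^3/s).
#' @param mu dynamic viscosity (Pa s).
#' @param band operated band, mm posterior of the anterior peak.
#' @return integrated shear force over the band, both sides summed (N).
#' @export
wall_force_surrogate <- function(params, r = c(0, 0), Q = 2.9e-4,
                                 mu = 1.85e-5, band = c(5, 20)) {
  if (length(r) == 1) r <- rep(r, 2)
  dy <- 0.1e-3
  y <- seq(dy / 2, params$length * 1e-3 - dy / 2, by = dy)
  H <- params$channel_height * 1e-3
  bh <- params$turbinate_height * 1e-3
  w <- params$channel_width * 1e-3
  gap <- function(side) {
    a <- bump_profile(y * 1e3, params$turbinate_amplitude[side],
                      params$turbinate_peak, params$turbinate_length,
                      r[side]) * 1e-3
    # area-equivalent gap: bump occupies only the lower bh of the channel
    w - a * bh / H
  }
  gL <- gap(1); gR <- gap(2)
  RL <- sum(12 * mu / (H * gL^3)) * dy
  RR <- sum(12 * mu / (H * gR^3)) * dy
  qL <- Q * (1 / RL) / (1 / RL + 1 / RR)
  qR <- Q - qL
  yb <- params$turbinate_peak + band
  inb <- y * 1e3 >= yb[1] & y * 1e3 <= yb[2]
  tauL <- 6 * mu * qL / (H * gL[inb]^2)
  tauR <- 6 * mu * qR / (H * gR[inb]^2)
  sum((tauL + tauR) * 2 * H * dy)
}

# analytic airway volume (cm^3) of one side in a y band [lo, hi] mm
band_volume_analytic <- function(params, r = c(0, 0), lo, hi) {
  dy <- 0.01
  y <- seq(lo + dy / 2, hi - dy / 2, by = dy)
  vol <- 0
  for (side in 1:2) {
    a <- bump_profile(y, params$turbinate_amplitude[side],
                      params$turbinate_peak, params$turbinate_length, r[side])
    vol <- vol + sum(params$channel_width * params$channel_height -
                       a * params$turbinate_height) * dy
  }
  vol / 1000
}

#' Generate a synthetic surgical cohort
#'
#' Emulates the design of a paired pre/post turbinate-surgery study: `n`
#' subjects with sex, weight, per-subject turbinate anatomy and a surgical
#' reduction fraction, evaluated at two timepoints. Outcome scores are
#' statistically coupled to the geometric effect of surgery (see
#' [coupling_params()]): the VAS obstruction change tracks the change in the
#' wall-shear-force surrogate, the GHSI quality-of-life change tracks the VAS
#' change, and the acoustic-rhinometry V2-5 proxy is the airway volume in the
#' 20-50 mm band plus noise. Fully reproducible from `seed`.
#'
#' @param n number of subjects (>= 3).
#' @param coupling a `coupling_params` object.
#' @param params_base baseline `phantom_params` shared by the cohort.
#' @param seed cohort seed.
#' @param reduction_range range of the uniform distribution of per-subject
#'   reduction fractions.
#' @return a `nasal_cohort`: list with `subjects` (a long data frame, one row
#'   per subject x timepoint), `geometry` (per-subject phantom parameters and
#'   reduction), `coupling` and `seed`.
#' @export
generate_cohort <- function(n = 25, coupling = coupling_params(),
                            params_base = phantom_params(), seed = 1L,
                            reduction_range = c(0.2, 0.8)) {
  if (n < 3) stopf("need at least 3 subjects for rank statistics")
  with_seed(seed, {
    sex <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
    weight <- ifelse(sex == "male", rnorm(n, 80, 12), rnorm(n, 67, 11))
    weight <- pmin(pmax(weight, 45), 120)
    ampL <- pmin(pmax(rnorm(n, 2.8, 0.4), 1.5), 3.8)
    ampR <- pmin(pmax(ampL + rnorm(n, 0, 0.2), 1.5), 3.8)
    red <- runif(n, reduction_range[1], reduction_range[2])
    subj_seed <- sample.int(1e8, n)

    geometry <- vector("list", n)
    f_pre <- f_post <- v25_pre <- v25_post <- numeric(n)
    for (i in seq_len(n)) {
      p <- params_base
      p$turbinate_amplitude <- c(ampL[i], ampR[i])
      p$seed <- subj_seed[i]
      geometry[[i]] <- list(params = p, reduction = red[i])
      Q <- simulation_flow_rate(patient_flow_rate(sex[i], weight[i]))
      f_pre[i] <- wall_force_surrogate(p, r = 0, Q = Q)
      f_post[i] <- wall_force_surrogate(p, r = red[i], Q = Q)
      v25_pre[i] <- band_volume_analytic(p, r = c(0, 0), 20, 50)
      v25_post[i] <- band_volume_analytic(p, r = rep(red[i], 2), 20, 50)
    }
    dforce <- f_post - f_pre

    # Gaussian copula on the force change: normal scores -> correlated latent
    rho_s <- coupling$target_rho
    r_pear <- 2 * sin(pi * rho_s / 6)
    zf <- qnorm((rank(dforce) - 0.5) / n)
    zv <- r_pear * zf + sqrt(max(0, 1 - r_pear^2)) * rnorm(n)
    dvas <- coupling$delta_vas_mean + coupling$delta_vas_sd * zv
    vas_pre <- pmin(pmax(rnorm(n, 7, 1.5), 0), 10)
    vas_post <- pmin(pmax(vas_pre + dvas, 0), 10)
    ghsi_pre <- pmin(pmax(rnorm(n, 55, 12), 0), 100)
    dghsi <- coupling$ghsi_slope * (vas_post - vas_pre) +
      rnorm(n, 0, coupling$ghsi_noise_sd)
    ghsi_post <- pmin(pmax(ghsi_pre + dghsi, 0), 100)
    v25n_pre <- pmax(v25_pre + rnorm(n, 0, coupling$rhinometry_noise_sd), 0.1)
    v25n_post <- pmax(v25_post + rnorm(n, 0, coupling$rhinometry_noise_sd), 0.1)

    subjects <- data.frame(
      id = rep(sprintf("S%03d", seq_len(n)), each = 2),
      sex = rep(sex, each = 2),
      weight = rep(round(weight, 1), each = 2),
      timepoint = rep(c("pre", "post"), n),
      vas = as.vector(rbind(vas_pre, vas_post)),
      ghsi = as.vector(rbind(ghsi_pre, ghsi_post)),
      v25 = as.vector(rbind(v25n_pre, v25n_post)),
      reduction = rep(red, each = 2),
      force_surrogate = as.vector(rbind(f_pre, f_post)),
      stringsAsFactors = FALSE
    )
    subjects$reduction[subjects$timepoint == "pre"] <- 0
    structure(list(subjects = subjects, geometry = geometry,
                   coupling = coupling, seed = as.integer(seed)),
              class = "nasal_cohort")
  })
}

#' @export
print.nasal_cohort <- function(x, ...) {
  n <- length(x$geometry)
  cat(sprintf("nasal cohort: %d subjects x 2 timepoints (seed %d)\n",
              n, x$seed))
  cat(sprintf("  target Spearman coupling (dVAS ~ dForce): %.2f\n",
              x$coupling$target_rho))
  invisible(x)
}
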