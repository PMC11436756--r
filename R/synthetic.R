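#' Configuration for a synthetic static neuron scene
#'
#' Describes a two-channel fixed-cell image of a cultured neuron: an
#' elliptical soma with radiating processes, a thin primary cilium abutting
#' the soma, punctate endosomes inside the soma, and a 1-px plasma-membrane
#' rim. Channel 1 is the compartment-marker channel: by default it
#' emulates an endosomal marker (bright endosomes over a dim cytoplasmic
#' fill); raise `marker_cilium` to emulate a ciliary-marker stain instead.
#' Channel 2 is the protein of interest (e.g. a tagged adenylyl cyclase),
#' painted at `base_cell` photons/px over the cell and multiplied by the
#' per-compartment enrichment factors.
#'
#' All compartments are hard-edged (a pixel belongs to a compartment when
#' its centre falls inside the ideal shape), so ground-truth masks are
#' exact. Camera noise is Poisson on signal + background followed by
#' additive Gaussian read noise, clipped at zero.
#'
#' @param image_shape (y, x) size in pixels.
#' @param pixel_size um/px.
#' @param soma_center,soma_radii Soma ellipse centre and (y, x) radii, px.
#' @param n_processes Number of radiating processes.
#' @param process_length,process_width Process geometry, px.
#' @param cilium_length,cilium_width Cilium geometry, px; the cilium is a
#'   thin vertical capsule extending upward from the top of the soma.
#' @param n_endosomes Number of endosomal puncta inside the soma.
#' @param endosome_radius_range (min, max) endosome radius, px.
#' @param base_cell Channel-2 cytoplasmic level, photons/px.
#' @param cilium_factor,endosome_factor,plasma_membrane_factor Channel-2
#'   multiplicative enrichment of each compartment relative to `base_cell`.
#' @param marker_base,marker_cilium,marker_endosome Channel-1 levels,
#'   photons/px.
#' @param background Camera background level added everywhere, photons/px.
#' @param poisson_on Apply Poisson (shot) noise?
#' @param gaussian_sd Read-noise standard deviation, photons.
#' @param seed Integer seed; identical (config, seed) gives bit-identical
#'   scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_shape = c(160L, 160L),
                         pixel_size = 0.1,
                         soma_center = NULL,
                         soma_radii = c(28, 22),
                         n_processes = 3L,
                         process_length = 45, process_width = 4,
                         cilium_length = 30, cilium_width = 3,
                         n_endosomes = 12L,
                         endosome_radius_range = c(2, 3),
                         base_cell = 100,
                         cilium_factor = 1,
                         endosome_factor = 1,
                         plasma_membrane_factor = 1,
                         marker_base = 20,
                         marker_cilium = 20,
                         marker_endosome = 300,
                         background = 10,
                         poisson_on = TRUE,
                         gaussian_sd = 2,
                         seed = 1L) {
  if (is.null(soma_center)) soma_center <- image_shape / 2 + c(10, 0)
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              soma_center = soma_center, soma_radii = soma_radii,
              n_processes = as.integer(n_processes),
              process_length = process_length, process_width = process_width,
              cilium_length = cilium_length, cilium_width = cilium_width,
              n_endosomes = as.integer(n_endosomes),
              endosome_radius_range = endosome_radius_range,
              base_cell = base_cell, cilium_factor = cilium_factor,
              endosome_factor = endosome_factor,
              plasma_membrane_factor = plasma_membrane_factor,
              marker_base = marker_base, marker_cilium = marker_cilium,
              marker_endosome = marker_endosome,
              background = background, poisson_on = poisson_on,
              gaussian_sd = gaussian_sd, seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  lv <- c("base_cell", "marker_base", "marker_cilium", "marker_endosome",
          "background", "gaussian_sd")
  for (f in lv) if (cfg[[f]] < 0) stop(sprintf("'%s' must be >= 0", f))
  for (f in c("cilium_factor", "endosome_factor", "plasma_membrane_factor"))
    if (cfg[[f]] <= 0) stop(sprintf("'%s' must be > 0", f))
  if (cfg$pixel_size <= 0) stop("'pixel_size' must be > 0")
  sh <- cfg$image_shape
  if (cfg$soma_center[1] + cfg$soma_radii[1] > sh[1] ||
      cfg$soma_center[1] - cfg$soma_radii[1] < 1 ||
      cfg$soma_center[2] + cfg$soma_radii[2] > sh[2] ||
      cfg$soma_center[2] - cfg$soma_radii[2] < 1)
    stop("geometry exceeds image bounds: 'soma_radii'")
  top <- cfg$soma_center[1] - cfg$soma_radii[1] - cfg$cilium_length
  if (top < 1)
    stop("geometry exceeds image bounds: 'cilium_length' ",
         "(cilium extends above row 1)")
  if (cfg$endosome_radius_range[1] > cfg$endosome_radius_range[2] ||
      cfg$endosome_radius_range[1] <= 0)
    stop("'endosome_radius_range' must be increasing and positive")
  invisible(cfg)
}

# pixel-centre containment helpers ------------------------------------------

pixel_grid <- function(shape) {
  list(y = matrix(rep(seq_len(shape[1]), shape[2]), shape[1], shape[2]),
       x = matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2]))
}

ellipse_mask <- function(shape, center, radii) {
  g <- pixel_grid(shape)
  ((g$y - center[1]) / radii[1])^2 + ((g$x - center[2]) / radii[2])^2 <= 1
}

disk_mask <- function(shape, center, radius) {
  g <- pixel_grid(shape)
  (g$y - center[1])^2 + (g$x - center[2])^2 <= radius^2
}

# capsule (thick segment) between p1 and p2 with given half-width
segment_mask <- function(shape, p1, p2, width) {
  g <- pixel_grid(shape)
  v <- p2 - p1
  len2 <- sum(v^2)
  ty <- g$y - p1[1]; tx <- g$x - p1[2]
  tt <- pmin(1, pmax(0, (ty * v[1] + tx * v[2]) / len2))
  dy <- ty - tt * v[1]; dx <- tx - tt * v[2]
  dy^2 + dx^2 <= (width / 2)^2
}

# 1-px inner boundary ring of a mask (pixels with a 4-neighbour outside)
boundary_ring <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  m & !interior
}

# Place n non-overlapping disks inside the soma (away from its rim),
# with at least `gap` px between boundaries. Rejection sampling.
place_endosomes <- function(cfg) {
  rr <- cfg$endosome_radius_range
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  tries <- 0L
  while (length(radii) < cfg$n_endosomes && tries < 100000L) {
    tries <- tries + 1L
    r <- runif(1, rr[1], rr[2])
    # sample inside a shrunken soma ellipse so disks stay off the membrane
    th <- runif(1, 0, 2 * pi); u <- sqrt(runif(1))
    cy <- cfg$soma_center[1] + u * (cfg$soma_radii[1] - r - 3) * sin(th)
    cx <- cfg$soma_center[2] + u * (cfg$soma_radii[2] - r - 3) * cos(th)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
      if (any(d < radii + r + 3)) next  # 3-px gap: closing cannot bridge
    }
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
  }
  if (length(radii) < cfg$n_endosomes)
    stop("could not place ", cfg$n_endosomes, " non-overlapping endosomes; ",
         "reduce 'n_endosomes' or radii")
  list(centers = centers, radii = radii)
}

# Paint the noiseless scene; returns masks and per-channel signal images
# (photons/px above background).
paint_scene <- function(cfg) {
  sh <- cfg$image_shape
  soma <- ellipse_mask(sh, cfg$soma_center, cfg$soma_radii)
  cell <- soma
  if (cfg$n_processes > 0) {
    angles <- seq(0, 2 * pi, length.out = cfg$n_processes + 1L)[-1] + pi / 7
    for (a in angles) {
      dir <- c(sin(a), cos(a))
      p1 <- cfg$soma_center + dir * (c(cfg$soma_radii[1], cfg$soma_radii[2]) * 0.8)
      p2 <- cfg$soma_center + dir * (sqrt(sum((cfg$soma_radii * dir)^2)) +
                                       cfg$process_length)
      p2 <- pmin(pmax(p2, 2), sh - 1)
      cell <- cell | segment_mask(sh, p1, p2, cfg$process_width)
    }
  }
  top <- c(cfg$soma_center[1] - cfg$soma_radii[1], cfg$soma_center[2])
  cil <- segment_mask(sh, top, top - c(cfg$cilium_length, 0), cfg$cilium_width)
  cil <- cil & !cell
  endo_mask <- matrix(FALSE, sh[1], sh[2])
  endo <- place_endosomes(cfg)
  for (i in seq_along(endo$radii))
    endo_mask <- endo_mask | disk_mask(sh, endo$centers[i, ], endo$radii[i])
  cell_all <- cell | cil
  membrane <- boundary_ring(cell) & !endo_mask
  endo_mask <- endo_mask & cell

  ac <- matrix(0, sh[1], sh[2])
  ac[cell_all] <- cfg$base_cell
  ac[cil] <- cfg$base_cell * cfg$cilium_factor
  ac[membrane] <- cfg$base_cell * cfg$plasma_membrane_factor
  ac[endo_mask] <- cfg$base_cell * cfg$endosome_factor

  marker <- matrix(0, sh[1], sh[2])
  marker[cell_all] <- cfg$marker_base
  marker[cil] <- cfg$marker_cilium
  marker[endo_mask] <- cfg$marker_endosome

  list(masks = list(cell = cell_all, soma = soma, cilium = cil,
                    endosomes = endo_mask, membrane = membrane),
       endosome_centers = endo$centers, endosome_radii = endo$radii,
       marker = marker, ac = ac)
}

add_camera_noise <- function(signal, background, poisson_on, gaussian_sd) {
  img <- signal + background
  if (poisson_on) img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
  if (gaussian_sd > 0) img <- img + rnorm(length(img), 0, gaussian_sd)
  pmax(img, 0)
}

# analytic enrichment of a painted channel for a compartment, both
# conventions, computed on the noiseless signal image with the true masks
true_enrichment <- function(signal, comp_mask, cell_mask) {
  data.frame(
    convention = c("mean-ratio", "integrated-ratio"),
    index = c(mean(signal[comp_mask]) / mean(signal[cell_mask]),
              sum(signal[comp_mask]) / sum(signal[cell_mask])))
}

#' Simulate a two-channel static neuron scene with ground truth
#'
#' Renders the scene described by a [scene_config()] and packages it as a
#' single-timepoint [image_stack()] (channel 1 = marker, channel 2 = AC)
#' plus a ground-truth record holding the true compartment masks, the true
#' enrichment indices of the AC channel (computed from the painted,
#' noiseless intensities under both ratio conventions), and the painted
#' noiseless images.
#'
#' @param config A [scene_config()].
#' @return A list with elements `stack` ([image_stack()]) and `truth`.
#' @export
simulate_static_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  with_seed(config$seed, {
    sc <- paint_scene(config)
    marker <- add_camera_noise(sc$marker, config$background,
                               config$poisson_on, config$gaussian_sd)
    ac <- add_camera_noise(sc$ac, config$background,
                           config$poisson_on, config$gaussian_sd)
    sh <- config$image_shape
    px <- array(0, c(1, 1, 2, sh[1], sh[2]))
    px[1, 1, 1, , ] <- marker
    px[1, 1, 2, , ] <- ac
    stack <- image_stack(px, calibration(config$pixel_size))
    truth <- list(
      masks = sc$masks,
      endosome_centers = sc$endosome_centers,
      endosome_radii = sc$endosome_radii,
      n_endosomes = config$n_endosomes,
      enrichment = list(
        cilium = true_enrichment(sc$ac, sc$masks$cilium, sc$masks$cell),
        endosome = true_enrichment(sc$ac, sc$masks$endosomes, sc$masks$cell)),
      noiseless = list(marker = sc$marker, ac = sc$ac),
      config = unclass(config))
    list(stack = stack, truth = truth)
  })
}

#' Configuration for kinetic simulations
#'
#' Timing and model parameters for receptor-trafficking movies and
#' biosensor traces. Times are supplied in seconds (acquisition units);
#' model time constants in minutes (reporting units). Defaults mirror the
#' live-cell protocol: 20 s frames, 1 min baseline, 30 min of agonist.
#'
#' The internalized receptor fraction follows first-order kinetics
#' `f(t) = surface_fraction_mobile * (1 - exp(-k_internalize * t))` for
#' t >= 0 (minutes) and 0 before agonist. The biosensor response is
#' `r(t) = A * (1 - exp(-t/tau_r)) * (p + (1 - p) * exp(-t/tau_d))`,
#' a saturating rise multiplied by a partial decay to a plateau fraction
#' `p`; with the defaults the noiseless peak falls between 2 and 5 min.
#'
#' @param frame_interval Seconds between frames.
#' @param baseline_duration Seconds of pre-agonist baseline.
#' @param total_duration Seconds of post-agonist follow-up.
#' @param k_internalize First-order internalization rate, 1/min.
#' @param surface_fraction_mobile Fraction of the surface pool that can
#'   internalize, in [0, 1].
#' @param amplitude Biosensor response amplitude A, dF/F0 units.
#' @param tau_rise,tau_decay Rise and decay time constants, minutes.
#' @param plateau_fraction Plateau fraction p in [0, 1].
#' @param noise_sd Per-frame Gaussian noise on biosensor traces, dF/F0
#'   units (0 = noiseless).
#' @param amplitude_cv Cell-to-cell coefficient of variation of A when
#'   simulating populations of traces.
#' @param fsk_epoch_duration Seconds of terminal Fsk/IBMX saturation epoch.
#' @param fsk_level Saturation level S during that epoch, dF/F0 units.
#' @param seed Integer seed.
#' @return A `kinetic_config` list.
#' @export
kinetic_config <- function(frame_interval = 20,
                           baseline_duration = 60,
                           total_duration = 1800,
                           k_internalize = 0.2,
                           surface_fraction_mobile = 0.8,
                           amplitude = 1,
                           tau_rise = 1.2,
                           tau_decay = 4,
                           plateau_fraction = 0.4,
                           noise_sd = 0.05,
                           amplitude_cv = 0.10,
                           fsk_epoch_duration = 120,
                           fsk_level = 2.5,
                           seed = 1L) {
  cfg <- list(frame_interval = frame_interval,
              baseline_duration = baseline_duration,
              total_duration = total_duration,
              k_internalize = k_internalize,
              surface_fraction_mobile = surface_fraction_mobile,
              amplitude = amplitude, tau_rise = tau_rise,
              tau_decay = tau_decay, plateau_fraction = plateau_fraction,
              noise_sd = noise_sd, amplitude_cv = amplitude_cv,
              fsk_epoch_duration = fsk_epoch_duration, fsk_level = fsk_level,
              seed = as.integer(seed))
  if (cfg$frame_interval <= 0) stop("'frame_interval' must be > 0")
  for (f in c("baseline_duration", "total_duration", "fsk_epoch_duration"))
    if (cfg[[f]] < 0) stop(sprintf("'%s' must be >= 0", f))
  if (cfg$tau_rise <= 0 || cfg$tau_decay <= 0)
    stop("'tau_rise' and 'tau_decay' must be > 0")
  if (cfg$plateau_fraction < 0 || cfg$plateau_fraction > 1)
    stop("'plateau_fraction' must be in [0, 1]")
  if (cfg$amplitude < 0) stop("'amplitude' must be >= 0")
  if (cfg$surface_fraction_mobile < 0 || cfg$surface_fraction_mobile > 1)
    stop("'surface_fraction_mobile' must be in [0, 1]")
  if (cfg$k_internalize < 0) stop("'k_internalize' must be >= 0")
  structure(cfg, class = "kinetic_config")
}

# frame times in minutes (t = 0 at agonist addition); baseline frames at
# negative times. Durations must tile into whole frames.
kinetic_times_min <- function(kin, include_fsk = FALSE) {
  if (abs(kin$total_duration / kin$frame_interval -
          round(kin$total_duration / kin$frame_interval)) > 1e-9)
    stop("'total_duration' must be a whole number of frames")
  n_base <- round(kin$baseline_duration / kin$frame_interval)
  n_post <- round(kin$total_duration / kin$frame_interval)
  tt <- seq(-n_base, n_post) * kin$frame_interval / 60
  if (include_fsk && kin$fsk_epoch_duration > 0) {
    n_fsk <- round(kin$fsk_epoch_duration / kin$frame_interval)
    tt <- c(tt, max(tt) + seq_len(n_fsk) * kin$frame_interval / 60)
  }
  tt
}

#' True internalized fraction under first-order kinetics
#'
#' @param t_min Time in minutes (vectorized); negative times give 0.
#' @param kin A [kinetic_config()].
#' @return `surface_fraction_mobile * (1 - exp(-k_internalize * t))`,
#'   clamped to 0 before agonist.
#' @export
internalized_fraction <- function(t_min, kin) {
  ifelse(t_min < 0, 0,
         kin$surface_fraction_mobile * (1 - exp(-kin$k_internalize * t_min)))
}

#' True biosensor response model
#'
#' Evaluates the noiseless response `r(t)` (dF/F0 units): a saturating
#' rise times a partial exponential decay to a sustained plateau; 0 before
#' agonist.
#'
#' @inheritParams internalized_fraction
#' @return Numeric vector.
#' @export
biosensor_response <- function(t_min, kin) {
  ifelse(t_min < 0, 0,
         kin$amplitude * (1 - exp(-t_min / kin$tau_rise)) *
           (kin$plateau_fraction +
              (1 - kin$plateau_fraction) * exp(-t_min / kin$tau_decay)))
}

#' Simulate a receptor-trafficking movie with ground truth
#'
#' Builds a time-lapse in which a surface-labelled receptor (channel 2)
#' redistributes from the plasma membrane to stationary marker-positive
#' endosomes (channel 1) after agonist addition at t = 0, following
#' first-order kinetics. Total receptor fluorescence is conserved frame to
#' frame in the noiseless movie: what leaves the membrane appears in the
#' endosomes. A dim cytoplasmic receptor pool gives endosome pixels a
#' nonzero pre-agonist baseline, as out-of-focus fluorescence does in real
#' movies.
#'
#' @param scene A [scene_config()] describing the cell geometry. Its
#'   `endosome_factor` is ignored for the receptor channel; channel levels
#'   are taken from the membrane/base fields.
#' @param kin A [kinetic_config()].
#' @return List with `stack` (t-frames, 2 channels), and `truth` holding
#'   `f_t` (internalized fraction per frame), `accumulation` (the expected
#'   baseline-normalized endosomal receptor trace), frame `times_min`,
#'   masks, and both configs.
#' @export
simulate_trafficking_movie <- function(scene, kin) {
  stopifnot(inherits(scene, "scene_config"), inherits(kin, "kinetic_config"))
  validate_scene_config(scene)
  with_seed(kin$seed, {
    sc <- paint_scene(scene)
    times <- kinetic_times_min(kin)
    f_t <- internalized_fraction(times, kin)
    memb <- sc$masks$membrane
    endo <- sc$masks$endosomes
    cyto <- sc$masks$cell & !memb & !endo
    a_m <- sum(memb); a_e <- sum(endo)
    i_m0 <- scene$base_cell * scene$plasma_membrane_factor  # surface receptor
    r_base <- scene$base_cell * 0.2                          # cytosolic pool
    sh <- scene$image_shape
    px <- array(0, c(length(times), 1, 2, sh[1], sh[2]))
    for (i in seq_along(times)) {
      rec <- matrix(0, sh[1], sh[2])
      rec[sc$masks$cell] <- r_base
      rec[memb] <- r_base + i_m0 * (1 - f_t[i])
      rec[endo] <- r_base + i_m0 * a_m * f_t[i] / a_e
      px[i, 1, 1, , ] <- add_camera_noise(sc$marker, scene$background,
                                          scene$poisson_on, scene$gaussian_sd)
      px[i, 1, 2, , ] <- add_camera_noise(rec, scene$background,
                                          scene$poisson_on, scene$gaussian_sd)
    }
    agonist_frame <- which(times >= 0)[1]
    cal <- calibration(scene$pixel_size, kin$frame_interval, agonist_frame)
    truth <- list(times_min = times, f_t = f_t,
                  accumulation = 1 + (i_m0 * a_m / a_e) * f_t / r_base,
                  masks = sc$masks, receptor_cyto_level = r_base,
                  receptor_surface_level = i_m0,
                  scene = unclass(scene), kin = unclass(kin))
    list(stack = image_stack(px, cal), truth = truth)
  })
}

#' Simulate a biosensor time course with ground truth
#'
#' Generates a dF/F0 trace from the response model of [kinetic_config()]:
#' zero during the pre-agonist baseline, the rise/partial-decay/plateau
#' response for t in (0, total], then a terminal Fsk/IBMX saturation epoch
#' at `fsk_level`. Optional per-frame Gaussian noise.
#'
#' @param kin A [kinetic_config()]. Set `noise_sd = 0` for a noiseless
#'   trace; `amplitude_cv > 0` draws the cell's amplitude from a normal
#'   distribution around `amplitude`.
#' @return List with `trace` (a [fluor_trace()], state `"dF/F0"`) and
#'   `truth` (model parameters, the noiseless `r_t`, and the Fsk frame
#'   indices).
#' @export
simulate_biosensor_trace <- function(kin) {
  stopifnot(inherits(kin, "kinetic_config"))
  with_seed(kin$seed, {
    times <- kinetic_times_min(kin, include_fsk = TRUE)
    n_all <- length(times)
    n_main <- length(kinetic_times_min(kin, include_fsk = FALSE))
    amp <- kin$amplitude
    if (kin$amplitude_cv > 0)
      amp <- max(0, rnorm(1, kin$amplitude, kin$amplitude_cv * kin$amplitude))
    kin_cell <- kin; kin_cell$amplitude <- amp
    r <- biosensor_response(times, kin_cell)
    fsk_frames <- if (n_all > n_main) seq(n_main + 1L, n_all) else integer()
    r[fsk_frames] <- kin$fsk_level
    vals <- r
    if (kin$noise_sd > 0) vals <- vals + rnorm(n_all, 0, kin$noise_sd)
    trace <- fluor_trace(times, vals, state = "dF/F0",
                         fsk_frames = fsk_frames)
    truth <- list(amplitude = amp, tau_rise = kin$tau_rise,
                  tau_decay = kin$tau_decay,
                  plateau_fraction = kin$plateau_fraction,
                  fsk_level = kin$fsk_level, r_t = r, times_min = times,
                  fsk_frames = fsk_frames, kin = unclass(kin))
    list(trace = trace, truth = truth)
  })
}
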