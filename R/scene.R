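#' Specify one strain class for the synthetic scene generator
#'
#' A strain couples a sensor localization (compartment) with the oxidation
#' state of its glutathione pool under the two growth conditions. Objects of
#' the `cytosol` compartment are measured over whole cells (diffuse signal);
#' `carboxysome` and `procarboxysome` strains carry the probe in bright
#' intracellular puncta; `wt` cells carry no probe and provide the
#' autofluorescence background used for subtraction.
#'
#' Oxidation state is modeled per measured object as a latent mean that
#' relaxes first-order toward the current condition's target, plus a
#' persistent per-object deviation (`oxd_sd`) and small per-frame jitter.
#' Under elevated CO2, a fraction `bimodal_fraction_high` of puncta is
#' assigned to a second, reduced mode at `oxd_high_reduced`, producing the
#' bimodal population structure of partially encapsulated puncta; the mode
#' disappears on return to air. `oxd_return_offset` shifts the air target
#' after a cell has experienced elevated CO2 (hysteresis: the population does
#' not return exactly to its pre-shift state).
#'
#' @param name strain label.
#' @param compartment one of `"cytosol"`, `"carboxysome"`, `"procarboxysome"`,
#'   `"wt"`.
#' @param n_cells number of cells to place.
#' @param oxd_air,oxd_high mean oxidation fraction in air / elevated CO2.
#' @param oxd_sd persistent per-object standard deviation of oxidation state.
#' @param bimodal_fraction_high fraction of puncta in the reduced mode under
#'   elevated CO2.
#' @param oxd_high_reduced oxidation target of the reduced mode.
#' @param oxd_return_offset additive shift of the air target after elevated
#'   CO2 exposure (negative = remains more reduced).
#' @param start_offset initial oxidation offset that decays as cells settle
#'   onto the imaging pad (the early acquisition transient).
#' @param puncta_per_cell puncta per cell (0 for cytosol/wt).
#' @param puncta_radius_px punctum radius, pixels.
#' @param puncta_shaft_px punctum capsule shaft length (0 = circular).
#' @param cell_radius_range,cell_shaft_range rod half-width and shaft-length
#'   sampling ranges, pixels.
#' @param division_rate per-frame division probability per cell.
#' @param apply_size_filter whether the minimum-puncta-area filter applies to
#'   this strain class during analysis (default: procarboxysome only,
#'   following the size-based exclusion of misidentified puncta in that
#'   mutant).
#' @return validated list of class `"strain_spec"`.
#' @export
strain_spec <- function(name, compartment = c("cytosol", "carboxysome",
                                              "procarboxysome", "wt"),
                        n_cells = 25,
                        oxd_air = 0.5, oxd_high = 0.5, oxd_sd = 0.05,
                        bimodal_fraction_high = 0, oxd_high_reduced = 0.30,
                        oxd_return_offset = 0, start_offset = 0.08,
                        puncta_per_cell = 0, puncta_radius_px = 5,
                        puncta_shaft_px = 0,
                        cell_radius_range = c(6, 8),
                        cell_shaft_range = c(20, 40),
                        division_rate = 0.02,
                        apply_size_filter = identical(compartment, "procarboxysome")) {
  compartment <- match.arg(compartment)
  for (nm in c("oxd_air", "oxd_high", "oxd_sd", "bimodal_fraction_high",
               "oxd_high_reduced"))
    stopifnot_scalar(get(nm), nm, lo = 0, hi = 1)
  stopifnot_scalar(division_rate, "division_rate", 0, 1)
  stopifnot(n_cells >= 1)
  if (compartment %in% c("wt", "cytosol") && puncta_per_cell > 0)
    stop("only puncta compartments may carry puncta")
  out <- list(name = name, compartment = compartment, n_cells = n_cells,
              oxd_air = oxd_air, oxd_high = oxd_high, oxd_sd = oxd_sd,
              bimodal_fraction_high = bimodal_fraction_high,
              oxd_high_reduced = oxd_high_reduced,
              oxd_return_offset = oxd_return_offset,
              start_offset = start_offset,
              puncta_per_cell = puncta_per_cell,
              puncta_radius_px = puncta_radius_px,
              puncta_shaft_px = puncta_shaft_px,
              cell_radius_range = cell_radius_range,
              cell_shaft_range = cell_shaft_range,
              division_rate = division_rate,
              apply_size_filter = isTRUE(apply_size_filter))
  class(out) <- "strain_spec"
  out
}

#' Default strain panel of the synthetic study
#'
#' Encodes the population structure the analysis is designed to resolve:
#' carboxysomes more oxidized than cytosol and procarboxysomes in air;
#' a reductive shift in every compartment under elevated CO2; a reduced
#' (procarboxysome-like) carboxysome subpopulation appearing only under
#' elevated CO2; and a hysteretic carboxysome return to air. Absolute
#' oxidation fractions are a modeling choice (only orderings and shifts are
#' constrained by the biology); the chosen values are documented in the
#' methods vignette.
#'
#' @param n_cells cells per sensor strain.
#' @param n_wt wild-type (autofluorescence-only) cells.
#' @return list of [strain_spec()] objects.
#' @export
default_strains <- function(n_cells = 26, n_wt = 10) {
  list(
    strain_spec("Grx1-roGFP2", "cytosol", n_cells = n_cells,
                oxd_air = 0.35, oxd_high = 0.20),
    strain_spec("RbcL-Grx1-roGFP2", "carboxysome", n_cells = n_cells,
                oxd_air = 0.90, oxd_high = 0.70,
                bimodal_fraction_high = 0.35, oxd_high_reduced = 0.30,
                oxd_return_offset = -0.05,
                puncta_per_cell = 3, puncta_radius_px = 5,
                cell_shaft_range = c(36, 46)),
    strain_spec("dccmO RbcL-Grx1-roGFP2", "procarboxysome", n_cells = n_cells,
                oxd_air = 0.45, oxd_high = 0.25,
                puncta_per_cell = 2, puncta_radius_px = 5.5,
                cell_shaft_range = c(28, 40), division_rate = 0.01),
    strain_spec("WT", "wt", n_cells = n_wt)
  )
}

#' Specify a synthetic timelapse scene
#'
#' Geometry, timing and environmental schedule of one imaging field:
#' non-overlapping rod-shaped (capsule) cells on a pad, imaged at a fixed
#' frame interval, with the CO2 condition switching at scheduled frames.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param n_frames number of timepoints.
#' @param frame_interval_min minutes between frames (default 20).
#' @param strains list of [strain_spec()] objects (at least one).
#' @param co2_schedule data frame with columns `frame` (1-based, strictly
#'   increasing, first = 1) and `condition` (`"air"` or `"high"`).
#' @param rng_seed integer seed; two calls with the same spec and seed yield
#'   bit-identical scenes.
#' @param tau_co2_min relaxation time constant of oxidation state after a CO2
#'   switch, minutes (the population shift plays out over several hours).
#' @param tau_settle_min decay time constant of the initial settling
#'   transient, minutes.
#' @param tau_obj_min decorrelation time constant of per-object oxidation
#'   deviations, minutes: deviations are mean-reverting with stationary
#'   standard deviation `oxd_sd`, so daughter cells inherit their mother's
#'   state but lineages decorrelate over a few hours.
#' @param oxd_frame_sd per-frame oxidation jitter (sd).
#' @param min_gap_px minimum surface-to-surface gap enforced between cells.
#' @param border_margin_px minimum distance from cell surface to image edge.
#' @param max_place_tries placement attempts per cell before the scene is
#'   declared too crowded (explicit error, never silent truncation).
#' @param blur_sigma optional Gaussian optical blur (pixels; 0 = off).
#' @return validated list of class `"scene_spec"`.
#' @export
scene_spec <- function(image_shape = c(512, 512), n_frames = 30,
                       frame_interval_min = 20,
                       strains = default_strains(),
                       co2_schedule = data.frame(frame = 1, condition = "air"),
                       rng_seed = 1,
                       tau_co2_min = 150, tau_settle_min = 45,
                       tau_obj_min = 120, oxd_frame_sd = 0.02,
                       min_gap_px = 3, border_margin_px = 2,
                       max_place_tries = 5000, blur_sigma = 0) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 32),
            n_frames >= 1, frame_interval_min > 0, length(strains) >= 1)
  if (!all(vapply(strains, inherits, logical(1), "strain_spec")))
    stop("'strains' must be a list of strain_spec objects")
  co2_schedule <- as.data.frame(co2_schedule)
  stopifnot(all(c("frame", "condition") %in% names(co2_schedule)),
            all(co2_schedule$condition %in% c("air", "high")))
  if (co2_schedule$frame[1] != 1 || any(diff(co2_schedule$frame) <= 0))
    stop("co2_schedule frames must start at 1 and be strictly increasing")
  if (any(co2_schedule$frame > n_frames))
    stop("co2_schedule frames must lie within n_frames")
  out <- list(image_shape = as.integer(image_shape), n_frames = as.integer(n_frames),
              frame_interval_min = frame_interval_min, strains = strains,
              co2_schedule = co2_schedule, rng_seed = as.integer(rng_seed),
              tau_co2_min = tau_co2_min, tau_settle_min = tau_settle_min,
              tau_obj_min = tau_obj_min,
              oxd_frame_sd = oxd_frame_sd, min_gap_px = min_gap_px,
              border_margin_px = border_margin_px,
              max_place_tries = as.integer(max_place_tries),
              blur_sigma = blur_sigma)
  class(out) <- "scene_spec"
  out
}

condition_per_frame <- function(spec) {
  cond <- character(spec$n_frames)
  sch <- spec$co2_schedule
  for (i in seq_len(nrow(sch))) {
    upto <- if (i < nrow(sch)) sch$frame[i + 1] - 1 else spec$n_frames
    cond[sch$frame[i]:upto] <- sch$condition[i]
  }
  cond
}

## ---- geometry helpers -------------------------------------------------

# linear pixel indices (column-major) of a capsule: all pixel centers within
# distance r of the segment p1--p2 (x = column, y = row)
capsule_pixels <- function(H, W, p1, p2, r) {
  x0 <- max(1L, floor(min(p1[1], p2[1]) - r)); x1 <- min(W, ceiling(max(p1[1], p2[1]) + r))
  y0 <- max(1L, floor(min(p1[2], p2[2]) - r)); y1 <- min(H, ceiling(max(p1[2], p2[2]) + r))
  if (x1 < x0 || y1 < y0) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  v <- p2 - p1; L2 <- sum(v^2)
  if (L2 == 0) {
    d2 <- (px - p1[1])^2 + (py - p1[2])^2
  } else {
    t <- clamp(((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / L2, 0, 1)
    d2 <- (px - (p1[1] + t * v[1]))^2 + (py - (p1[2] + t * v[2]))^2
  }
  keep <- d2 <= r^2
  (py[keep] + (px[keep] - 1L) * H)
}

# minimum distance between two segments (for capsule overlap tests)
segment_distance <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    v <- b - a; L2 <- sum(v^2)
    if (L2 == 0) return(sqrt(sum((p - a)^2)))
    t <- clamp(sum((p - a) * v) / L2, 0, 1)
    sqrt(sum((p - (a + t * v))^2))
  }
  segs_intersect <- function(a, b, c, d) {
    cr <- function(o, u, v) (u[1] - o[1]) * (v[2] - o[2]) - (u[2] - o[2]) * (v[1] - o[1])
    d1 <- cr(c, d, a); d2 <- cr(c, d, b); d3 <- cr(a, b, c); d4 <- cr(a, b, d)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (segs_intersect(p1, p2, q1, q2)) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2), pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

## ---- oxidation-state dynamics ----------------------------------------

.oxd_target <- function(strain, condition, mode, seen_high) {
  if (condition == "high") {
    if (identical(mode, "reduced")) strain$oxd_high_reduced else strain$oxd_high
  } else {
    strain$oxd_air + if (seen_high) strain$oxd_return_offset else 0
  }
}

# one relaxation step of the latent mean toward the current target
.oxd_step <- function(m, target, dt, tau) {
  target + (m - target) * exp(-dt / tau)
}

# mean-reverting (OU) step for per-object deviations; stationary sd = sd0
.delta_step <- function(delta, dt, tau, sd0) {
  a <- exp(-dt / tau)
  delta * a + stats::rnorm(length(delta), 0, sd0 * sqrt(1 - a^2))
}

#' Simulate per-object oxidation/ratio trajectories without imaging
#'
#' Runs the same latent oxidation-state dynamics the image generator uses
#' (first-order relaxation toward condition targets, settling transient,
#' persistent per-object deviations, reduced-mode assignment under elevated
#' CO2, hysteretic return) and maps them through the optical model to
#' measurement-like ratios. Useful for testing the population-level
#' statistics at scale without rendering images.
#'
#' @param strain a [strain_spec()].
#' @param n_objects number of objects to simulate.
#' @param n_frames,frame_interval_min,co2_schedule,tau_co2_min,tau_settle_min,tau_obj_min,oxd_frame_sd
#'   as in [scene_spec()].
#' @param optics an [optical_model()] (for the oxd-to-ratio mapping).
#' @param ratio_noise_sd additive measurement noise on the ratio.
#' @param seed integer seed.
#' @return data frame with `object_id`, `frame`, `time_min`, `condition`,
#'   `true_oxd`, `ratio`.
#' @export
simulate_population_series <- function(strain, n_objects = 100, n_frames = 30,
                                       frame_interval_min = 20,
                                       co2_schedule = data.frame(frame = 1, condition = "air"),
                                       tau_co2_min = 150, tau_settle_min = 45,
                                       tau_obj_min = 120, oxd_frame_sd = 0.02,
                                       optics = optical_model(),
                                       ratio_noise_sd = 0.01, seed = 1) {
  spec <- scene_spec(n_frames = n_frames, frame_interval_min = frame_interval_min,
                     strains = list(strain), co2_schedule = co2_schedule,
                     rng_seed = seed, tau_co2_min = tau_co2_min,
                     tau_settle_min = tau_settle_min, oxd_frame_sd = oxd_frame_sd)
  cond <- condition_per_frame(spec)
  set.seed(seed)
  delta <- rnorm(n_objects, 0, strain$oxd_sd)
  mode <- rep("main", n_objects); seen_high <- rep(FALSE, n_objects)
  if (cond[1] == "high") {
    mode <- ifelse(runif(n_objects) < strain$bimodal_fraction_high, "reduced", "main")
    seen_high <- rep(TRUE, n_objects)
  }
  m <- vapply(seq_len(n_objects), function(i)
    .oxd_target(strain, cond[1], mode[i], seen_high[i]), numeric(1))
  out <- vector("list", n_frames)
  dt <- frame_interval_min
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      entering_high <- cond[f] == "high" & cond[f - 1] != "high"
      if (entering_high) {
        mode <- ifelse(runif(n_objects) < strain$bimodal_fraction_high, "reduced", "main")
        seen_high <- rep(TRUE, n_objects)
      }
      if (cond[f] != "high") mode <- rep("main", n_objects)
      tgt <- vapply(seq_len(n_objects), function(i)
        .oxd_target(strain, cond[f], mode[i], seen_high[i]), numeric(1))
      m <- .oxd_step(m, tgt, dt, tau_co2_min)
      delta <- .delta_step(delta, dt, tau_obj_min, strain$oxd_sd)
    }
    s <- strain$start_offset * exp(-((f - 1) * dt) / tau_settle_min)
    oxd <- reflect01(m + s + delta + rnorm(n_objects, 0, oxd_frame_sd))
    out[[f]] <- data.frame(object_id = seq_len(n_objects), frame = f,
                           time_min = (f - 1) * dt, condition = cond[f],
                           true_oxd = oxd,
                           ratio = pmax(0, oxd_to_ratio(oxd, optics) +
                                          rnorm(n_objects, 0, ratio_noise_sd)))
  }
  do.call(rbind, out)
}

## ---- scene generation -------------------------------------------------

place_cells <- function(spec) {
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  placed <- list(); tries_budget <- spec$max_place_tries
  for (si in seq_along(spec$strains)) {
    st <- spec$strains[[si]]
    for (k in seq_len(st$n_cells)) {
      ok <- FALSE
      for (try in seq_len(tries_budget)) {
        r <- runif(1, st$cell_radius_range[1], st$cell_radius_range[2])
        L <- runif(1, st$cell_shaft_range[1], st$cell_shaft_range[2])
        th <- runif(1, 0, pi)
        u <- c(cos(th), sin(th))
        half <- L / 2 + r + spec$border_margin_px
        cx <- runif(1, 1 + half, W - half)
        cy <- runif(1, 1 + half, H - half)
        p1 <- c(cx, cy) - u * L / 2; p2 <- c(cx, cy) + u * L / 2
        clash <- FALSE
        for (cell in placed) {
          if (segment_distance(p1, p2, cell$p1, cell$p2) <=
              r + cell$r + spec$min_gap_px) { clash <- TRUE; break }
        }
        if (!clash) {
          placed[[length(placed) + 1L]] <-
            list(strain_idx = si, p1 = p1, p2 = p2, r = r)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(paste0("cell placement failed after %d tries (strain '%s'):",
                            " scene too crowded for the requested cell count"),
                     tries_budget, st$name))
    }
  }
  placed
}

make_puncta <- function(cell, strain, next_id) {
  k <- strain$puncta_per_cell
  if (k == 0) return(list(puncta = list(), next_id = next_id))
  shaft <- sqrt(sum((cell$p2 - cell$p1)^2))
  pitch <- 2 * strain$puncta_radius_px + strain$puncta_shaft_px + 2
  k_eff <- max(0L, min(k, floor(shaft / pitch)))
  puncta <- vector("list", k_eff)
  for (j in seq_len(k_eff)) {
    frac <- (j - 0.5) / k_eff
    puncta[[j]] <- list(id = next_id, frac = frac,
                        r = strain$puncta_radius_px,
                        shaft = strain$puncta_shaft_px,
                        delta = rnorm(1, 0, strain$oxd_sd),
                        mode = "main",
                        m = NA_real_)  # latent mean filled by caller
    next_id <- next_id + 1L
  }
  list(puncta = puncta, next_id = next_id)
}

punctum_geometry <- function(cell, punctum) {
  u <- (cell$p2 - cell$p1); L <- sqrt(sum(u^2)); u <- u / L
  c0 <- cell$p1 + u * (punctum$frac * L)
  if (punctum$shaft > 0) {
    list(p1 = c0 - u * punctum$shaft / 2, p2 = c0 + u * punctum$shaft / 2,
         r = punctum$r)
  } else {
    list(p1 = c0, p2 = c0, r = punctum$r)
  }
}

apply_noise <- function(img, optics) {
  n <- length(img)
  switch(optics$noise_model,
         none = img,
         gaussian = pmax(0, round(img + rnorm(n, 0, optics$noise_scale))),
         poisson_gaussian = {
           x <- rpois(n, img) + rnorm(n, 0, optics$noise_scale)
           pmax(0, round(x))
         })
}

#' Generate a synthetic multichannel timelapse with ground truth
#'
#' Renders a field of non-overlapping rod-shaped cells over time into four
#' channels (395-nm excitation, 470-nm excitation, chlorophyll
#' autofluorescence, brightfield), together with oracle label maps (the exact
#' rendered geometry, separate from anything the segmentation module
#' produces) and a per-object-per-frame ground-truth table.
#'
#' Probe-carrying pixels receive `gain * probe * (oxd * s_ox_c +
#' (1 - oxd) * s_red_c)` on top of autofluorescence and camera background;
#' wild-type cells receive autofluorescence and background only. Cells divide
#' with per-frame probability `division_rate`, the mother label disappearing
#' and two daughter labels appearing in its footprint. Identical spec and
#' seed give bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @param optics an [optical_model()].
#' @return object of class `"redox_scene"`: list with `frames` (list of
#'   H x W x 4 arrays, channels named `ex395`, `ex470`, `chl`, `bf`),
#'   `cell_labels` and `puncta_labels` (lists of integer matrices),
#'   `truth` (data frame), `condition` (per frame), `spec`, `optics`.
#' @export
generate_scene <- function(spec, optics = optical_model()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(optics, "optical_model"))
  set.seed(spec$rng_seed)
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  cond <- condition_per_frame(spec)
  dt <- spec$frame_interval_min

  placed <- place_cells(spec)
  next_id <- 1L
  cells <- vector("list", length(placed))
  for (i in seq_along(placed)) {
    st <- spec$strains[[placed[[i]]$strain_idx]]
    cell <- placed[[i]]
    cell$id <- next_id; next_id <- next_id + 1L
    cell$chl <- max(0.2, rnorm(1, 1, optics$autofluor_cv))
    cell$delta <- rnorm(1, 0, st$oxd_sd)
    cell$mode <- "main"; cell$seen_high <- cond[1] == "high"
    cell$m <- .oxd_target(st, cond[1], "main", cell$seen_high)
    pk <- make_puncta(cell, st, next_id); next_id <- pk$next_id
    cell$puncta <- lapply(pk$puncta, function(p) {
      if (cond[1] == "high")
        p$mode <- if (runif(1) < st$bimodal_fraction_high) "reduced" else "main"
      p$m <- .oxd_target(st, cond[1], p$mode, cell$seen_high)
      p
    })
    cells[[i]] <- cell
  }

  frames <- vector("list", spec$n_frames)
  cell_labels <- vector("list", spec$n_frames)
  puncta_labels <- vector("list", spec$n_frames)
  truth <- vector("list", spec$n_frames)

  for (f in seq_len(spec$n_frames)) {
    if (f > 1) {
      # divisions
      new_cells <- list()
      for (cell in cells) {
        st <- spec$strains[[cell$strain_idx]]
        Ltot <- sqrt(sum((cell$p2 - cell$p1)^2)) + 2 * cell$r
        if (runif(1) < st$division_rate && Ltot >= 4 * cell$r + 10) {
          u <- (cell$p2 - cell$p1) / sqrt(sum((cell$p2 - cell$p1)^2))
          a <- cell$p1 - u * cell$r; b <- cell$p2 + u * cell$r
          mid <- (a + b) / 2; gap <- 1
          for (side in 1:2) {
            tip1 <- if (side == 1) a else mid + u * gap
            tip2 <- if (side == 1) mid - u * gap else b
            d <- cell
            d$p1 <- tip1 + u * cell$r; d$p2 <- tip2 - u * cell$r
            d$id <- next_id; next_id <- next_id + 1L
            d$chl <- max(0.2, cell$chl + rnorm(1, 0, 0.02))
            pk <- make_puncta(d, st, next_id); next_id <- pk$next_id
            d$puncta <- lapply(pk$puncta, function(p) {
              # daughters inherit the state of a random mother punctum
              if (length(cell$puncta)) {
                src <- cell$puncta[[sample.int(length(cell$puncta), 1)]]
                p$m <- src$m; p$mode <- src$mode; p$delta <- src$delta
              } else p$m <- d$m
              p
            })
            new_cells[[length(new_cells) + 1L]] <- d
          }
        } else {
          new_cells[[length(new_cells) + 1L]] <- cell
        }
      }
      cells <- new_cells

      # oxidation-state dynamics
      entering_high <- cond[f] == "high" && cond[f - 1] != "high"
      for (i in seq_along(cells)) {
        st <- spec$strains[[cells[[i]]$strain_idx]]
        if (entering_high) cells[[i]]$seen_high <- TRUE
        tgt <- .oxd_target(st, cond[f], cells[[i]]$mode, cells[[i]]$seen_high)
        cells[[i]]$m <- .oxd_step(cells[[i]]$m, tgt, dt, spec$tau_co2_min)
        cells[[i]]$delta <- .delta_step(cells[[i]]$delta, dt, spec$tau_obj_min,
                                        st$oxd_sd)
        if (length(cells[[i]]$puncta)) {
          cells[[i]]$puncta <- lapply(cells[[i]]$puncta, function(p) {
            if (entering_high)
              p$mode <- if (runif(1) < st$bimodal_fraction_high) "reduced" else "main"
            if (cond[f] != "high" && cond[f - 1] == "high") p$mode <- "main"
            ptgt <- .oxd_target(st, cond[f], p$mode, cells[[i]]$seen_high)
            p$m <- .oxd_step(p$m, ptgt, dt, spec$tau_co2_min)
            p$delta <- .delta_step(p$delta, dt, spec$tau_obj_min, st$oxd_sd)
            p
          })
        }
      }
    }

    settle <- exp(-((f - 1) * dt) / spec$tau_settle_min)

    ex395 <- matrix(optics$background_mean, H, W)
    ex470 <- matrix(optics$background_mean, H, W)
    chl <- matrix(optics$background_mean, H, W)
    bf <- matrix(optics$brightfield_level, H, W)
    clab <- matrix(0L, H, W)
    plab <- matrix(0L, H, W)
    rows <- list()

    for (cell in cells) {
      st <- spec$strains[[cell$strain_idx]]
      px <- capsule_pixels(H, W, cell$p1, cell$p2, cell$r)
      clab[px] <- cell$id
      af <- optics$autofluor_mean * cell$chl
      ex395[px] <- ex395[px] + af
      ex470[px] <- ex470[px] + af
      chl[px] <- chl[px] + optics$chl_gain * cell$chl
      bf[px] <- bf[px] - optics$brightfield_contrast

      cell_oxd <- NA_real_
      if (st$compartment == "cytosol") {
        cell_oxd <- reflect01(cell$m + st$start_offset * settle + cell$delta +
                              rnorm(1, 0, spec$oxd_frame_sd))
        mx <- mixture_efficiency(cell_oxd, optics)
        ex395[px] <- ex395[px] + optics$gain * optics$probe_level * mx$mix_395
        ex470[px] <- ex470[px] + optics$gain * optics$probe_level * mx$mix_470
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, object_id = cell$id, type = "cell",
        parent_cell_id = NA_integer_, strain = st$name,
        compartment = st$compartment, true_oxd = cell_oxd,
        true_ratio = if (is.na(cell_oxd)) NA_real_ else oxd_to_ratio(cell_oxd, optics),
        area_px = length(px),
        centroid_x = mean((cell$p1[1] + cell$p2[1]) / 2),
        centroid_y = mean((cell$p1[2] + cell$p2[2]) / 2),
        condition = cond[f], time_min = (f - 1) * dt)

      for (p in cell$puncta) {
        geom <- punctum_geometry(cell, p)
        ppx <- capsule_pixels(H, W, geom$p1, geom$p2, geom$r)
        plab[ppx] <- p$id
        p_oxd <- reflect01(p$m + st$start_offset * settle + p$delta +
                           rnorm(1, 0, spec$oxd_frame_sd))
        mx <- mixture_efficiency(p_oxd, optics)
        amp <- optics$gain * optics$probe_level * optics$puncta_brightness
        ex395[ppx] <- ex395[ppx] + amp * mx$mix_395
        ex470[ppx] <- ex470[ppx] + amp * mx$mix_470
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, object_id = p$id, type = "punctum",
          parent_cell_id = cell$id, strain = st$name,
          compartment = st$compartment, true_oxd = p_oxd,
          true_ratio = oxd_to_ratio(p_oxd, optics),
          area_px = length(ppx),
          centroid_x = (geom$p1[1] + geom$p2[1]) / 2,
          centroid_y = (geom$p1[2] + geom$p2[2]) / 2,
          condition = cond[f], time_min = (f - 1) * dt)
      }
    }

    if (spec$blur_sigma > 0) {
      ex395 <- as.matrix(EBImage::gblur(EBImage::Image(ex395), spec$blur_sigma))
      ex470 <- as.matrix(EBImage::gblur(EBImage::Image(ex470), spec$blur_sigma))
      chl <- as.matrix(EBImage::gblur(EBImage::Image(chl), spec$blur_sigma))
    }
    ex395 <- matrix(apply_noise(ex395, optics), H, W)
    ex470 <- matrix(apply_noise(ex470, optics), H, W)
    chl <- matrix(apply_noise(chl, optics), H, W)
    if (optics$noise_model != "none")
      bf <- matrix(pmax(0, round(bf + rnorm(length(bf), 0, optics$brightfield_noise))), H, W)

    arr <- array(c(ex395, ex470, chl, bf), dim = c(H, W, 4),
                 dimnames = list(NULL, NULL, c("ex395", "ex470", "chl", "bf")))
    frames[[f]] <- arr
    cell_labels[[f]] <- clab
    puncta_labels[[f]] <- plab
    truth[[f]] <- do.call(rbind, rows)
  }

  out <- list(frames = frames, cell_labels = cell_labels,
              puncta_labels = puncta_labels,
              truth = do.call(rbind, truth),
              condition = cond, spec = spec, optics = optics)
  class(out) <- "redox_scene"
  out
}

#' @export
print.redox_scene <- function(x, ...) {
  cat("Synthetic redox imaging scene\n")
  cat(sprintf("  %d x %d px, %d frames at %g min\n",
              x$spec$image_shape[1], x$spec$image_shape[2],
              x$spec$n_frames, x$spec$frame_interval_min))
  cat(sprintf("  strains: %s\n",
              paste(vapply(x$spec$strains, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  objects tracked: %d cell-frames, %d punctum-frames\n",
              sum(x$truth$type == "cell"), sum(x$truth$type == "punctum")))
  invisible(x)
}
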