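#' Configuration for an end-to-end synthetic redox study
#'
#' Bundles the scene/optics specification, segmentation parameters and
#' analysis settings for [run_timelapse_study()] and [run_bulk_study()].
#' A study images several independent fields (as a microscopy session
#' acquires multiple XY positions) and pools their measurements; each field
#' gets a seed derived deterministically from the study seed.
#'
#' @param n_fields number of imaging fields.
#' @param image_shape,n_frames,frame_interval_min,strains,co2_schedule passed
#'   to [scene_spec()].
#' @param optics an [optical_model()].
#' @param seg_params a [segmentation_params()]; the default inverts the
#'   brightfield channel (cells are darker than the pad).
#' @param burn_in_hours settling window excluded from condition statistics.
#' @param background_scope `"global"` or `"per_frame"` wild-type background.
#' @param min_match_iou minimum intersection-over-union for accepting a
#'   match between a segmented object and a ground-truth object.
#' @param bimodality list of [detect_bimodality()] settings.
#' @param star_thresholds p-value cutoffs for star annotations.
#' @param n_replicates bulk-assay replicates per group.
#' @param spectrum_noise_sd per-wavelength noise of bulk traces, counts.
#' @param seed study master seed.
#' @return list of class `"study_config"`.
#' @export
study_config <- function(n_fields = 4, image_shape = c(512, 512),
                         n_frames = 30, frame_interval_min = 20,
                         strains = default_strains(),
                         co2_schedule = data.frame(frame = 1, condition = "air"),
                         optics = optical_model(),
                         seg_params = segmentation_params(invert = TRUE),
                         burn_in_hours = 3,
                         background_scope = "global",
                         min_match_iou = 0.3,
                         bimodality = list(min_n = 50, delta_bic_threshold = 10,
                                           min_ashman_d = 2),
                         star_thresholds = c(0.05, 0.001, 1e-4),
                         n_replicates = 4,
                         spectrum_noise_sd = 0.5,
                         seed = 1) {
  out <- as.list(environment())
  class(out) <- "study_config"
  out
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "hash")], f)
  unname(tools::md5sum(f))
}

#' Run the timelapse imaging study end to end
#'
#' For each field: simulate the scene, segment cells on the inverted
#' brightfield channel, curate the masks, identify each segmented object
#' against the ground-truth labels (simulation-mode strain identity), segment
#' puncta per puncta-strain with that strain's size-filter setting, estimate
#' the wild-type background, and quantify background-subtracted ratios from
#' the original images. Measurements are pooled across fields and aggregated
#' into per-compartment time series and post-burn-in bimodality calls. Rerun
#' with the same config is bit-identical at the table level.
#'
#' @param config a [study_config()].
#' @return object of class `"redox_study"`: `measurements` (one row per
#'   object per frame), `series` (per-compartment [aggregate_timeseries()]),
#'   `bimodality` (per compartment, post-burn-in pooled), `qc` (counts at
#'   each filter stage), `background` (per field), `config_hash`, `config`.
#' @export
run_timelapse_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  strains <- config$strains
  strain_by_name <- stats::setNames(strains, vapply(strains, `[[`, "", "name"))
  qc <- c(cells_segmented = 0, cells_removed_curation = 0,
          cells_unmatched = 0, puncta_found = 0,
          puncta_removed_size = 0, ratios_undefined = 0)
  all_meas <- list()
  backgrounds <- list()

  for (field in seq_len(config$n_fields)) {
    spec <- scene_spec(image_shape = config$image_shape,
                       n_frames = config$n_frames,
                       frame_interval_min = config$frame_interval_min,
                       strains = strains, co2_schedule = config$co2_schedule,
                       rng_seed = config$seed + 1000L * field)
    scene <- generate_scene(spec, config$optics)
    truth <- scene$truth
    rows <- list()

    for (f in seq_len(config$n_frames)) {
      frame <- scene$frames[[f]]
      seg <- segment_cells(frame[, , "bf"], config$seg_params, f)
      qc["cells_segmented"] <- qc["cells_segmented"] +
        length(setdiff(unique(as.vector(seg$labels)), 0L))
      cur <- curate_cells(seg, frame[, , "chl"], frame_index = f)
      qc["cells_removed_curation"] <- qc["cells_removed_curation"] + nrow(cur$log)
      lab <- cur$labels$labels

      mt <- match_labels(lab, scene$cell_labels[[f]])
      mt <- mt[mt$ref != 0 & mt$iou >= config$min_match_iou, , drop = FALSE]
      qc["cells_unmatched"] <- qc["cells_unmatched"] +
        (length(setdiff(unique(as.vector(lab)), 0L)) - nrow(mt))

      tcells <- truth[truth$frame == f & truth$type == "cell", ]
      strain_of <- stats::setNames(tcells$strain, tcells$object_id)
      gfp <- frame[, , "ex395"] + frame[, , "ex470"]

      for (k in seq_len(nrow(mt))) {
        seg_id <- mt$seg[k]; truth_id <- mt$ref[k]
        st <- strain_by_name[[strain_of[[as.character(truth_id)]]]]
        if (is.null(st)) next
        if (st$compartment %in% c("cytosol", "wt")) {
          idx <- which(lab == seg_id)
          rows[[length(rows) + 1L]] <- data.frame(
            field = field, frame = f, strain = st$name,
            compartment = st$compartment, type = "cell",
            truth_id = truth_id,
            i_395 = mean(frame[, , "ex395"][idx]),
            i_470 = mean(frame[, , "ex470"][idx]),
            area_px = length(idx))
        }
      }

      # puncta, segmented per strain class with that class's size filter
      for (st in strains) {
        if (!st$compartment %in% c("carboxysome", "procarboxysome")) next
        ids <- mt$seg[strain_of[as.character(mt$ref)] == st$name]
        if (!length(ids)) next
        lab_s <- lab; lab_s[!(lab_s %in% ids)] <- 0L
        pm <- tryCatch(
          segment_puncta(gfp, lab_s, config$seg_params,
                         size_filter = st$apply_size_filter, frame_index = f),
          error = function(e) NULL)
        if (is.null(pm)) next
        parents <- attr(pm, "parents")
        qc["puncta_found"] <- qc["puncta_found"] + nrow(parents) +
          (attr(pm, "n_size_filtered") %||% 0)
        qc["puncta_removed_size"] <- qc["puncta_removed_size"] +
          (attr(pm, "n_size_filtered") %||% 0)
        if (!nrow(parents)) next
        pmt <- match_labels(pm, scene$puncta_labels[[f]])
        pmt <- pmt[pmt$ref != 0, , drop = FALSE]
        pxl <- object_pixel_list(pm$labels)
        for (k in seq_len(nrow(pmt))) {
          idx <- pxl[[as.character(pmt$seg[k])]]
          rows[[length(rows) + 1L]] <- data.frame(
            field = field, frame = f, strain = st$name,
            compartment = st$compartment, type = "punctum",
            truth_id = pmt$ref[k],
            i_395 = mean(frame[, , "ex395"][idx]),
            i_470 = mean(frame[, , "ex470"][idx]),
            area_px = length(idx))
        }
      }
    }

    meas <- do.call(rbind, rows)
    wt <- meas[meas$compartment == "wt", ]
    bg <- estimate_background(wt, scope = config$background_scope)
    backgrounds[[field]] <- bg
    sens <- meas[meas$compartment != "wt", ]
    sens <- compute_ratio(sens, bg)
    qc["ratios_undefined"] <- qc["ratios_undefined"] + sum(!sens$ratio_defined)
    sens$time_min <- (sens$frame - 1) * config$frame_interval_min
    sens$condition <- scene$condition[sens$frame]
    tr <- truth[truth$frame == 1 | TRUE,
                c("frame", "object_id", "true_oxd", "true_ratio")]
    sens <- merge(sens, tr, by.x = c("frame", "truth_id"),
                  by.y = c("frame", "object_id"), all.x = TRUE, sort = FALSE)
    sens$object_uid <- paste0("f", field, ":", sens$truth_id)
    all_meas[[field]] <- sens
    rm(scene)
  }

  measurements <- do.call(rbind, all_meas)
  measurements <- measurements[order(measurements$field, measurements$frame), ]
  rownames(measurements) <- NULL

  series <- aggregate_timeseries(measurements, group_by = "compartment",
                                 frame_interval_min = config$frame_interval_min,
                                 burn_in_hours = config$burn_in_hours)
  post <- measurements[measurements$time_min >= config$burn_in_hours * 60 &
                         measurements$ratio_defined, ]
  bimod <- lapply(split(post$ratio, post$compartment), function(x)
    do.call(detect_bimodality, c(list(x = x), config$bimodality,
                                 list(seed = config$seed))))

  out <- list(measurements = measurements, series = series,
              bimodality = bimod, qc = qc, background = backgrounds,
              config = config, config_hash = config_hash(config))
  class(out) <- "redox_study"
  out
}

#' Per-object time-averaged ratios after burn-in
#'
#' One row per tracked object: its mean defined ratio over post-burn-in
#' frames. This is the unit of replication used for condition comparisons
#' (objects, not object-frames).
#'
#' @param study a `"redox_study"`.
#' @return data frame with `object_uid`, `strain`, `compartment`,
#'   `mean_ratio`, `n_frames`.
#' @export
per_object_means <- function(study) {
  m <- study$measurements
  m <- m[m$time_min >= study$config$burn_in_hours * 60 & m$ratio_defined, ]
  out <- do.call(rbind, lapply(split(m, m$object_uid), function(d)
    data.frame(object_uid = d$object_uid[1], strain = d$strain[1],
               compartment = d$compartment[1], mean_ratio = mean(d$ratio),
               n_frames = nrow(d))))
  rownames(out) <- NULL
  out
}

#' Compare per-compartment redox state between two studies (conditions)
#'
#' Unpaired two-tailed Student's t-tests on per-object time-averaged ratios,
#' one comparison per compartment present in both studies.
#'
#' @param study_a,study_b two `"redox_study"` objects (e.g. air and elevated
#'   CO2).
#' @param labels names for the two conditions in the output.
#' @return data frame with `compartment`, group means, `t`, `p_value`,
#'   `stars`.
#' @export
compare_study_conditions <- function(study_a, study_b,
                                     labels = c("air", "high")) {
  pa <- per_object_means(study_a); pb <- per_object_means(study_b)
  comps <- intersect(unique(pa$compartment), unique(pb$compartment))
  out <- do.call(rbind, lapply(comps, function(cp) {
    r <- compare_groups(pa$mean_ratio[pa$compartment == cp],
                        pb$mean_ratio[pb$compartment == cp],
                        study_a$config$star_thresholds)
    d <- data.frame(compartment = cp, mean_a = r$mean_a, mean_b = r$mean_b,
                    t = r$t, p_value = r$p_value, stars = r$stars)
    names(d)[2:3] <- paste0("mean_", labels)
    d
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.redox_study <- function(x, ...) {
  cat("Redox timelapse study\n")
  cat(sprintf("  fields: %d, frames: %d, config %s\n", x$config$n_fields,
              x$config$n_frames, substr(x$config_hash, 1, 8)))
  cat("  QC funnel:\n")
  for (nm in names(x$qc)) cat(sprintf("    %-24s %d\n", nm, x$qc[[nm]]))
  post <- x$measurements[x$measurements$time_min >=
                           x$config$burn_in_hours * 60 &
                           x$measurements$ratio_defined, ]
  if (nrow(post)) {
    agg <- stats::aggregate(ratio ~ compartment, post, mean)
    cat("  post-burn-in mean R395/470 by compartment:\n")
    for (i in seq_len(nrow(agg)))
      cat(sprintf("    %-16s %.4f\n", agg$compartment[i], agg$ratio[i]))
  } else {
    cat("  (no post-burn-in frames)\n")
  }
  for (cp in names(x$bimodality)) {
    b <- x$bimodality[[cp]]
    if (isTRUE(b$sufficient))
      cat(sprintf("  bimodality [%s]: %d component(s)\n", cp, b$n_components))
  }
  invisible(x)
}

#' Run the bulk spectrofluorometer study
#'
#' Generates replicate excitation spectra for each sensor strain under each
#' growth condition (each biological replicate drawing its own oxidation
#' state around the strain mean), computes wild-type-subtracted bulk ratios,
#' compares strains within condition and conditions within strain, and runs
#' the redox-agent response panel (reductant DTT, oxidant H2O2) with
#' compartment-specific agent sensitivities reflecting shell permeability:
#' the cytosol responds to both agents, carboxysomes respond to the
#' reductant but barely to the oxidant, procarboxysomes (already reduced in
#' their permissive high-CO2 condition) respond to neither appreciably.
#'
#' Procarboxysome strains are high-CO2-requiring and are not grown in air,
#' so they appear only under the `"high"` condition.
#'
#' @param config a [study_config()].
#' @param dtt_sensitivity,h2o2_sensitivity named per-compartment fractions in
#'   [0, 1] scaling how far each agent pulls the oxidation state toward its
#'   extreme (0.02 for DTT, 0.95 for H2O2).
#' @return object of class `"bulk_study"`: `ratios` (strain x condition
#'   table), `comparisons` (within/between condition t-tests), `treatments`
#'   (response panels), `config_hash`, `config`.
#' @export
run_bulk_study <- function(config = study_config(),
                           dtt_sensitivity = c(cytosol = 0.95,
                                               carboxysome = 0.80,
                                               procarboxysome = 0.15),
                           h2o2_sensitivity = c(cytosol = 0.90,
                                                carboxysome = 0.03,
                                                procarboxysome = 0.03)) {
  stopifnot(inherits(config, "study_config"))
  em <- config$optics$endmembers
  sensors <- Filter(function(s) s$compartment != "wt", config$strains)
  nrep <- config$n_replicates
  set.seed(config$seed + 77L)

  gen_group <- function(st, condition, treatment = "none") {
    oxd0 <- if (condition == "air") st$oxd_air else st$oxd_high
    traces <- list()
    for (r in seq_len(nrep)) {
      oxd <- clamp01(oxd0 + rnorm(1, 0, st$oxd_sd))
      if (treatment == "DTT") {
        s <- dtt_sensitivity[[st$compartment]]
        oxd <- oxd * (1 - s) + 0.02 * s
      } else if (treatment == "H2O2") {
        s <- h2o2_sensitivity[[st$compartment]]
        oxd <- oxd * (1 - s) + 0.95 * s
      }
      tr <- generate_spectrum(oxd, n_replicates = 1, amplitude = 100,
                              amplitude_cv = 0.05,
                              noise_sd = config$spectrum_noise_sd,
                              endmembers = em, strain = st$name,
                              condition = condition, treatment = treatment)
      tr$replicate <- r
      traces[[r]] <- tr
    }
    combined <- do.call(rbind, traces)
    list(sensor = combined[combined$strain != "WT", ],
         blank = combined[combined$strain == "WT", ])
  }

  grown_in <- function(st, condition) {
    # high-CO2-requiring strains (procarboxysome class) cannot grow in air
    !(st$compartment == "procarboxysome" && condition == "air")
  }

  ratios <- list(); groups <- list()
  for (condition in c("air", "high")) {
    for (st in sensors) {
      if (!grown_in(st, condition)) next
      g <- gen_group(st, condition)
      br <- bulk_ratio(g$sensor, g$blank)
      key <- paste(st$name, condition, sep = "|")
      groups[[key]] <- br
      ratios[[key]] <- data.frame(strain = st$name,
                                  compartment = st$compartment,
                                  condition = condition,
                                  mean_ratio = br$mean_ratio,
                                  sd_ratio = br$sd_ratio, n = br$n_used)
    }
  }
  ratios <- do.call(rbind, ratios); rownames(ratios) <- NULL

  cmp <- list()
  for (condition in c("air", "high")) {
    sub <- ratios[ratios$condition == condition, ]
    comps <- sub$compartment
    if (all(c("carboxysome", "cytosol") %in% comps)) {
      ra <- groups[[paste(sub$strain[sub$compartment == "carboxysome"], condition, sep = "|")]]$ratios
      rb <- groups[[paste(sub$strain[sub$compartment == "cytosol"], condition, sep = "|")]]$ratios
      r <- compare_groups(ra[!is.na(ra)], rb[!is.na(rb)], config$star_thresholds)
      cmp[[length(cmp) + 1L]] <- data.frame(
        comparison = paste0("carboxysome_vs_cytosol_", condition),
        mean_a = r$mean_a, mean_b = r$mean_b, p_value = r$p_value,
        stars = r$stars)
    }
    if (condition == "high" &&
        all(c("procarboxysome", "cytosol") %in% comps)) {
      ra <- groups[[paste(sub$strain[sub$compartment == "procarboxysome"], "high", sep = "|")]]$ratios
      rb <- groups[[paste(sub$strain[sub$compartment == "cytosol"], "high", sep = "|")]]$ratios
      r <- compare_groups(ra[!is.na(ra)], rb[!is.na(rb)], config$star_thresholds)
      cmp[[length(cmp) + 1L]] <- data.frame(
        comparison = "procarboxysome_vs_cytosol_high",
        mean_a = r$mean_a, mean_b = r$mean_b, p_value = r$p_value,
        stars = r$stars)
    }
  }
  for (st in sensors) {
    if (!grown_in(st, "air")) next
    ka <- paste(st$name, "air", sep = "|"); kh <- paste(st$name, "high", sep = "|")
    if (is.null(groups[[ka]]) || is.null(groups[[kh]])) next
    r <- compare_groups(groups[[ka]]$ratios[!is.na(groups[[ka]]$ratios)],
                        groups[[kh]]$ratios[!is.na(groups[[kh]]$ratios)],
                        config$star_thresholds)
    cmp[[length(cmp) + 1L]] <- data.frame(
      comparison = paste0(st$compartment, "_air_vs_high"),
      mean_a = r$mean_a, mean_b = r$mean_b, p_value = r$p_value,
      stars = r$stars)
  }
  comparisons <- do.call(rbind, cmp); rownames(comparisons) <- NULL

  treatments <- list()
  for (st in sensors) {
    condition <- if (st$compartment == "procarboxysome") "high" else "air"
    parts <- lapply(c("none", "DTT", "H2O2"),
                    function(tr) gen_group(st, condition, tr))
    sensor <- do.call(rbind, lapply(parts, `[[`, "sensor"))
    blank <- parts[[1]]$blank
    treatments[[st$name]] <- treatment_response(sensor, blank)
  }

  out <- list(ratios = ratios, comparisons = comparisons,
              treatments = treatments, config = config,
              config_hash = config_hash(config))
  class(out) <- "bulk_study"
  out
}

#' @export
print.bulk_study <- function(x, ...) {
  cat("Bulk spectrofluorometer study\n")
  cat("  mean R395/470 (sd) by strain and condition:\n")
  for (i in seq_len(nrow(x$ratios)))
    cat(sprintf("    %-26s %-5s %.3f (%.3f), n = %d\n",
                x$ratios$strain[i], x$ratios$condition[i],
                x$ratios$mean_ratio[i], x$ratios$sd_ratio[i], x$ratios$n[i]))
  cat("  comparisons:\n")
  for (i in seq_len(nrow(x$comparisons)))
    cat(sprintf("    %-34s %.3f vs %.3f  p = %.3g %s\n",
                x$comparisons$comparison[i], x$comparisons$mean_a[i],
                x$comparisons$mean_b[i], x$comparisons$p_value[i],
                x$comparisons$stars[i]))
  invisible(x)
}

#' Plot a population time series with standard errors
#'
#' @param x a `"population_series"`.
#' @param group_by grouping column used when the series was built.
#' @param ... passed to [graphics::matplot()]-style base plotting.
#' @export
plot.population_series <- function(x, group_by = "compartment", ...) {
  s <- as.data.frame(x)
  groups <- unique(s[[group_by]])
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")
  ylim <- range(c(s$mean_ratio - s$sem, s$mean_ratio + s$sem), na.rm = TRUE)
  graphics::plot(NA, xlim = range(s$time_min) / 60, ylim = ylim,
                 xlab = "time (h)", ylab = expression(R[395 / 470]), ...)
  for (i in seq_along(groups)) {
    d <- s[s[[group_by]] == groups[i], ]
    graphics::lines(d$time_min / 60, d$mean_ratio, col = cols[i], lwd = 2)
    graphics::arrows(d$time_min / 60, d$mean_ratio - d$sem,
                     d$time_min / 60, d$mean_ratio + d$sem,
                     length = 0.02, angle = 90, code = 3, col = cols[i])
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(x)
}
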