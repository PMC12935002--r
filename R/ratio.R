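#' Estimate background from wild-type object intensities
#'
#' The background subtracted from both excitation channels is the averaged
#' intensity of wild-type (sensor-free) objects, which carry the same
#' autofluorescence and camera offset as sensor strains but no probe signal.
#'
#' @param wt_means data frame of wild-type object means with columns `i_395`,
#'   `i_470` and (for per-frame scope) `frame`.
#' @param scope `"global"` (one model per dataset, the default: background is
#'   averaged once) or `"per_frame"` (one model per frame, for drift).
#' @return object of class `"background_model"`: for global scope scalars
#'   `b_395`, `b_470`; for per-frame scope a data frame `per_frame` with one
#'   row per frame. Raises an error when no wild-type objects are supplied
#'   (never a silent zero background).
#' @export
estimate_background <- function(wt_means, scope = c("global", "per_frame")) {
  scope <- match.arg(scope)
  if (is.null(wt_means) || nrow(wt_means) == 0)
    stop("no wild-type objects available for background estimation")
  stopifnot(all(c("i_395", "i_470") %in% names(wt_means)))
  out <- list(scope = scope, n_wt_objects = nrow(wt_means))
  if (scope == "global") {
    out$b_395 <- mean(wt_means$i_395)
    out$b_470 <- mean(wt_means$i_470)
  } else {
    stopifnot("frame" %in% names(wt_means))
    agg <- stats::aggregate(cbind(i_395, i_470) ~ frame, wt_means, mean)
    names(agg) <- c("frame", "b_395", "b_470")
    out$per_frame <- agg
  }
  class(out) <- "background_model"
  out
}

background_at <- function(bg, frame) {
  if (bg$scope == "global") return(c(b_395 = bg$b_395, b_470 = bg$b_470))
  i <- match(frame, bg$per_frame$frame)
  if (any(is.na(i))) stop("no background model for frame(s) ",
                          paste(unique(frame[is.na(i)]), collapse = ", "))
  cbind(b_395 = bg$per_frame$b_395[i], b_470 = bg$per_frame$b_470[i])
}

#' @export
print.background_model <- function(x, ...) {
  if (x$scope == "global")
    cat(sprintf("<background_model: global, b395 = %.2f, b470 = %.2f, %d WT objects>\n",
                x$b_395, x$b_470, x$n_wt_objects))
  else
    cat(sprintf("<background_model: per_frame over %d frames, %d WT objects>\n",
                nrow(x$per_frame), x$n_wt_objects))
  invisible(x)
}

#' Per-object mean intensities from a label map
#'
#' Object means are computed over each object's own pixel set only, from the
#' original (unmasked) images.
#'
#' @param frame_array H x W x channel array with dimnames including `ex395`
#'   and `ex470` (as produced by [generate_scene()]), or a list with those
#'   two matrices.
#' @param labels `"label_map"` or label matrix.
#' @return data frame with `object_id`, `i_395`, `i_470`, `area_px`.
#' @export
measure_objects <- function(frame_array, labels) {
  lab <- as_label_matrix(labels)
  if (is.list(frame_array) && !is.array(frame_array)) {
    im395 <- frame_array$ex395; im470 <- frame_array$ex470
  } else {
    im395 <- frame_array[, , "ex395"]; im470 <- frame_array[, , "ex470"]
  }
  px <- object_pixel_list(lab)
  if (!length(px))
    return(data.frame(object_id = integer(0), i_395 = numeric(0),
                      i_470 = numeric(0), area_px = integer(0)))
  data.frame(object_id = as.integer(names(px)),
             i_395 = vapply(px, function(i) mean(im395[i]), numeric(1)),
             i_470 = vapply(px, function(i) mean(im470[i]), numeric(1)),
             area_px = vapply(px, length, integer(1)),
             row.names = NULL)
}

#' Background-subtracted R395/470 redox ratio
#'
#' Implements the ratiometric readout: `ratio = (i_395 - b_395) / (i_470 -
#' b_470)`, with each background-subtracted term clipped at zero (an object
#' below zero after background subtraction is brought to zero, which guards
#' against low 470-nm signal). A zero denominator leaves the ratio undefined;
#' such objects carry `ratio_defined = FALSE` and are excluded from every
#' downstream aggregate, where they are counted rather than imputed.
#'
#' The defined ratios are invariant to rescaling all intensities and
#' backgrounds by a common positive factor, which is what makes the readout
#' independent of sensor concentration.
#'
#' @param measurements data frame with `i_395`, `i_470` (and `frame` when the
#'   background model is per-frame). Negative raw intensities are an error
#'   (corrupt input).
#' @param bg a [estimate_background()] model, or `NULL` for zero background.
#' @return the input with columns `b_395`, `b_470`, `num`, `den`, `ratio`,
#'   `ratio_defined` appended.
#' @export
compute_ratio <- function(measurements, bg = NULL) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("i_395", "i_470") %in% names(m)))
  if (any(m$i_395 < 0 | m$i_470 < 0))
    stop("negative raw intensities: corrupt input")
  if (is.null(bg)) {
    b <- cbind(b_395 = rep(0, nrow(m)), b_470 = rep(0, nrow(m)))
  } else {
    stopifnot(inherits(bg, "background_model"))
    b <- if (bg$scope == "global")
      cbind(b_395 = rep(bg$b_395, nrow(m)), b_470 = rep(bg$b_470, nrow(m)))
    else background_at(bg, m$frame)
  }
  m$b_395 <- b[, "b_395"]; m$b_470 <- b[, "b_470"]
  m$num <- pmax(m$i_395 - m$b_395, 0)
  m$den <- pmax(m$i_470 - m$b_470, 0)
  m$ratio_defined <- m$den > 0
  m$ratio <- ifelse(m$ratio_defined, m$num / m$den, NA_real_)
  m
}

#' Render a ratiometric overlay image
#'
#' Fills each labeled object with the colormap entry for its (clipped) ratio,
#' leaves the background black, and paints objects with undefined ratios in a
#' sentinel color. Display limits default to the 0--0.3 span used for
#' timelapse overview figures; 0--0.5 suits puncta close-ups.
#'
#' @param labels `"label_map"` or label matrix.
#' @param measurements output of [compute_ratio()] whose `object_id` matches
#'   the labels.
#' @param limits `c(lo, hi)` ratio display limits, `lo < hi`.
#' @param colormap vector of colors (low to high).
#' @param undefined_color color for objects with undefined ratio.
#' @return H x W x 3 RGB array in [0, 1].
#' @export
render_ratiometric <- function(labels, measurements, limits = c(0, 0.3),
                               colormap = grDevices::hcl.colors(256, "viridis"),
                               undefined_color = "grey50") {
  if (limits[1] >= limits[2]) stop("limits must satisfy lo < hi")
  lab <- as_label_matrix(labels)
  H <- nrow(lab); W <- ncol(lab)
  out <- array(0, dim = c(H, W, 3))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids)) return(out)
  mm <- as.data.frame(measurements)
  missing_ids <- setdiff(ids, mm$object_id)
  if (length(missing_ids))
    stop("labels without measurements: ", paste(missing_ids, collapse = ", "))
  px <- object_pixel_list(lab)
  ncol_map <- length(colormap)
  und_rgb <- grDevices::col2rgb(undefined_color)[, 1] / 255
  for (id in ids) {
    row <- mm[mm$object_id == id, ][1, ]
    idx <- px[[as.character(id)]]
    if (!isTRUE(row$ratio_defined)) {
      rgbv <- und_rgb
    } else {
      v <- clamp(row$ratio, limits[1], limits[2])
      k <- 1 + floor((v - limits[1]) / diff(limits) * (ncol_map - 1) + 0.5)
      rgbv <- grDevices::col2rgb(colormap[k])[, 1] / 255
    }
    for (c3 in 1:3) {
      plane <- out[, , c3]; plane[idx] <- rgbv[c3]; out[, , c3] <- plane
    }
  }
  out
}
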