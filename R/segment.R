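#' Parameters for cell and puncta segmentation
#'
#' Defaults follow the reproducible, parameter-free route: per-image Otsu
#' threshold (with a fixed-threshold override), distance-transform-seeded
#' watershed splitting of touching cells, 8-connectivity for thick rods and
#' 4-connectivity for small compact puncta, and the 62-pixel minimum puncta
#' area below which puncta are excluded as likely background noise.
#'
#' @param threshold_method `"otsu"` or `"fixed"` for the cell channel.
#' @param fixed_threshold cell threshold in counts (used when `"fixed"`).
#' @param invert invert the channel before thresholding (set for brightfield,
#'   where cells are darker than the background).
#' @param connectivity pixel connectivity for cell labeling, 4 or 8.
#' @param watershed_tolerance minimum distance-transform depth separating two
#'   watershed seeds, pixels; seeds closer in height merge.
#' @param min_cell_area cell objects smaller than this are removed, pixels.
#' @param border_policy `"drop"` (default; partial border cells bias
#'   per-object means) or `"keep"`.
#' @param puncta_threshold_method,puncta_fixed_threshold same, for puncta.
#' @param puncta_connectivity connectivity for puncta labeling.
#' @param puncta_min_area minimum retained punctum area, pixels; strictly
#'   smaller puncta are excluded when the size filter is enabled (62-pixel
#'   default; 62 itself is retained).
#' @return validated list of class `"segmentation_params"`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                invert = FALSE,
                                connectivity = 8,
                                watershed_tolerance = 1,
                                min_cell_area = 100,
                                border_policy = c("drop", "keep"),
                                puncta_threshold_method = c("otsu", "fixed"),
                                puncta_fixed_threshold = NA_real_,
                                puncta_connectivity = 4,
                                puncta_min_area = 62) {
  threshold_method <- match.arg(threshold_method)
  puncta_threshold_method <- match.arg(puncta_threshold_method)
  border_policy <- match.arg(border_policy)
  stopifnot(connectivity %in% c(4, 8), puncta_connectivity %in% c(4, 8),
            puncta_min_area >= 1, min_cell_area >= 0)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, invert = invert,
                 connectivity = connectivity,
                 watershed_tolerance = watershed_tolerance,
                 min_cell_area = min_cell_area, border_policy = border_policy,
                 puncta_threshold_method = puncta_threshold_method,
                 puncta_fixed_threshold = puncta_fixed_threshold,
                 puncta_connectivity = puncta_connectivity,
                 puncta_min_area = puncta_min_area),
            class = "segmentation_params")
}

label_map <- function(labels, provenance, frame_index = NA_integer_) {
  structure(list(labels = labels, provenance = provenance,
                 frame_index = frame_index),
            class = "label_map")
}

as_label_matrix <- function(x) {
  if (inherits(x, "label_map")) x$labels else x
}

#' @export
print.label_map <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$labels)), 0L))
  cat(sprintf("<label_map: %s, %d objects, %d x %d px>\n",
              x$provenance, n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# relabel nonzero labels as 1..n in raster-scan order of first occurrence
relabel_sequential <- function(labels) {
  nz <- which(labels != 0)
  if (!length(nz)) return(labels)
  first <- nz[!duplicated(labels[nz])]
  old <- labels[first]
  map <- integer(max(old)); map[old] <- seq_along(old)
  labels[nz] <- map[labels[nz]]
  labels
}

#' Connected-component labeling with explicit connectivity
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix (0 = background), components numbered in
#'   raster-scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  fg <- which(m)
  if (!length(fg)) return(matrix(0L, H, W))
  rank <- integer(H * W); rank[fg] <- seq_along(fg)
  row <- ((fg - 1L) %% H) + 1L; col <- ((fg - 1L) %/% H) + 1L
  edges <- integer(0)
  add_pairs <- function(off, valid) {
    a <- fg[valid]; b <- a + off
    keep <- m[b]
    if (any(keep)) rbind(rank[a[keep]], rank[b[keep]]) else NULL
  }
  pairs <- list(add_pairs(1L, row < H),               # down
                add_pairs(H, col < W))                # right
  if (connectivity == 8) {
    pairs <- c(pairs, list(add_pairs(H + 1L, row < H & col < W),   # down-right
                           add_pairs(H - 1L, row > 1L & col < W))) # up-right
  }
  pairs <- Filter(Negate(is.null), pairs)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(pairs))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, pairs)))
  memb <- igraph::components(g)$membership
  out <- matrix(0L, H, W)
  out[fg] <- memb
  relabel_sequential(out)
}

choose_threshold <- function(image, method, fixed) {
  if (method == "fixed") {
    if (!is.finite(fixed)) stop("fixed_threshold must be set for method 'fixed'")
    return(fixed)
  }
  rng <- range(image)
  if (diff(rng) == 0)
    stop("degenerate threshold: image is constant, Otsu is undefined")
  norm <- (image - rng[1]) / diff(rng)
  t_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  rng[1] + t_norm * diff(rng)
}

drop_small_and_border <- function(labels, min_area, border_policy) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (!length(ids)) return(labels)
  area <- tabulate(labels[labels != 0], nbins = max(ids))
  drop <- ids[area[ids] < min_area]
  if (border_policy == "drop") {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, setdiff(border, 0L))
  }
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_sequential(labels)
}

#' Segment cells by intensity threshold and watershed
#'
#' Foreground is the set of pixels above an Otsu (or fixed) threshold;
#' touching objects are split by a watershed on the Euclidean distance
#' transform of the foreground; objects below the minimum area and (by
#' default) objects touching the image border are removed.
#'
#' @param image 2D numeric matrix (finite values), e.g. the brightfield
#'   channel (use `invert = TRUE` in the params since cells appear dark).
#' @param params a [segmentation_params()].
#' @param frame_index carried into the returned map.
#' @return a `"label_map"` with provenance `"cell"`. An all-background image
#'   yields an empty map (not an error); a constant image with Otsu raises a
#'   degenerate-threshold error.
#' @export
segment_cells <- function(image, params = segmentation_params(),
                          frame_index = NA_integer_) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("image contains non-finite values")
  work <- if (isTRUE(params$invert)) max(image) - image else image
  thr <- choose_threshold(work, params$threshold_method, params$fixed_threshold)
  fg <- work > thr
  if (!any(fg))
    return(label_map(matrix(0L, nrow(image), ncol(image)), "cell", frame_index))
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
  labels <- relabel_sequential(matrix(as.integer(ws), nrow(image), ncol(image)))
  labels <- drop_small_and_border(labels, params$min_cell_area, params$border_policy)
  label_map(labels, "cell", frame_index)
}

object_pixel_list <- function(labels) {
  idx <- which(labels != 0)
  split(idx, labels[idx])
}

# solidity = pixel area / (convex hull area, lattice-adjusted)
object_solidity <- function(labels) {
  px <- object_pixel_list(labels)
  H <- nrow(labels)
  vapply(px, function(idx) {
    if (length(idx) <= 8) return(1)
    y <- ((idx - 1L) %% H) + 1L; x <- ((idx - 1L) %/% H) + 1L
    h <- grDevices::chull(x, y)
    hx <- x[h]; hy <- y[h]
    n <- length(h)
    if (n < 3) return(1)
    j <- c(2:n, 1)
    area_hull <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
    perim <- sum(sqrt((hx[j] - hx)^2 + (hy[j] - hy)^2))
    min(1, length(idx) / (area_hull + perim / 2 + 1))
  }, numeric(1))
}

object_channel_means <- function(labels, image) {
  px <- object_pixel_list(labels)
  vapply(px, function(idx) mean(image[idx]), numeric(1))
}

#' Rule-based curation of cell masks
#'
#' Replaces manual mask correction with two documented rules: objects whose
#' mean chlorophyll signal falls below a configured fraction of the frame's
#' median object chlorophyll are removed as dead; objects with solidity below
#' a cutoff (or area above a cap) are removed as overlapping/merged cells.
#' Every removal is logged with its reason. Externally edited label maps can
#' be passed straight to the quantification step instead, as an escape hatch.
#'
#' @param cells a `"label_map"` (or label matrix) of cells for one frame.
#' @param chl_image matching chlorophyll channel.
#' @param dead_chl_frac dead cutoff as a fraction of the median object
#'   chlorophyll mean.
#' @param min_solidity overlap cutoff on convex solidity.
#' @param max_area optional area cap, pixels.
#' @param frame_index for the log.
#' @return list with `labels` (curated `"label_map"`) and `log` (data frame
#'   of removed labels with `reason`). Empty input passes through.
#' @export
curate_cells <- function(cells, chl_image, dead_chl_frac = 0.5,
                         min_solidity = 0.8, max_area = Inf,
                         frame_index = NA_integer_) {
  labels <- as_label_matrix(cells)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  log <- data.frame(frame = integer(0), label = integer(0),
                    reason = character(0))
  if (length(ids)) {
    chl_means <- object_channel_means(labels, chl_image)
    med <- stats::median(chl_means)
    sol <- object_solidity(labels)
    area <- vapply(object_pixel_list(labels), length, integer(1))
    ord <- as.integer(names(chl_means))
    dead <- ord[chl_means < dead_chl_frac * med]
    overlap <- ord[sol < min_solidity | area > max_area]
    overlap <- setdiff(overlap, dead)
    if (length(dead) || length(overlap)) {
      log <- rbind(
        if (length(dead)) data.frame(frame = frame_index, label = dead,
                                     reason = "dead"),
        if (length(overlap)) data.frame(frame = frame_index, label = overlap,
                                        reason = "overlap"))
      labels[labels %in% c(dead, overlap)] <- 0L
    }
  }
  list(labels = label_map(labels, "cell", frame_index), log = log)
}

#' Segment puncta within cells from the GFP signal
#'
#' Bright connected regions above an Otsu (or fixed) threshold, restricted to
#' pixels inside the cell mask; each punctum is assigned the parent cell
#' whose label contains its centroid (falling back to majority pixel overlap
#' when the centroid lands on background, with ties broken toward the lower
#' label id). When the size filter is enabled, puncta strictly smaller than
#' `puncta_min_area` pixels are excluded.
#'
#' @param gfp_image 2D numeric matrix (e.g. the summed excitation channels).
#' @param cells `"label_map"` or label matrix of parent cells.
#' @param params a [segmentation_params()].
#' @param size_filter apply the minimum-area filter (enable for the strain
#'   classes it is scoped to; see [strain_spec()]'s `apply_size_filter`).
#' @param frame_index carried through.
#' @return a `"label_map"` with provenance `"puncta"` and attribute
#'   `"parents"`: data frame with `punctum`, `parent_cell`, `area_px`,
#'   `assigned_by`.
#' @export
segment_puncta <- function(gfp_image, cells, params = segmentation_params(),
                           size_filter = TRUE, frame_index = NA_integer_) {
  cell_labels <- as_label_matrix(cells)
  stopifnot(all(dim(gfp_image) == dim(cell_labels)))
  inside <- cell_labels != 0
  empty <- label_map(matrix(0L, nrow(gfp_image), ncol(gfp_image)), "puncta",
                     frame_index)
  attr(empty, "parents") <- data.frame(punctum = integer(0),
                                       parent_cell = integer(0),
                                       area_px = integer(0),
                                       assigned_by = character(0))
  attr(empty, "n_size_filtered") <- 0L
  if (!any(inside)) return(empty)
  vals <- gfp_image[inside]
  thr <- if (params$puncta_threshold_method == "fixed") {
    if (!is.finite(params$puncta_fixed_threshold))
      stop("puncta_fixed_threshold must be set for method 'fixed'")
    params$puncta_fixed_threshold
  } else {
    if (diff(range(vals)) == 0)
      stop("degenerate threshold: in-cell GFP signal is constant")
    rng <- range(vals)
    rng[1] + EBImage::otsu(EBImage::Image((vals - rng[1]) / diff(rng)),
                           range = c(0, 1)) * diff(rng)
  }
  mask <- (gfp_image > thr) & inside
  if (!any(mask)) return(empty)
  labels <- label_components(mask, params$puncta_connectivity)

  H <- nrow(labels)
  px <- object_pixel_list(labels)
  keep <- labels
  parents <- lapply(names(px), function(id) {
    idx <- px[[id]]
    area <- length(idx)
    if (size_filter && area < params$puncta_min_area) return(NULL)
    y <- ((idx - 1L) %% H) + 1L; x <- ((idx - 1L) %/% H) + 1L
    cy <- round(mean(y)); cx <- round(mean(x))
    parent <- 0L; how <- "centroid"
    if (cy >= 1 && cy <= H && cx >= 1 && cx <= ncol(labels))
      parent <- cell_labels[cy, cx]
    if (parent == 0L || !(parent %in% cell_labels[idx])) {
      ov <- table(cell_labels[idx])
      ov <- ov[names(ov) != "0"]
      best <- as.integer(names(ov)[ov == max(ov)])
      parent <- min(best)  # tie -> lower label id
      how <- if (length(best) > 1) "majority_tie" else "majority"
    }
    data.frame(punctum = as.integer(id), parent_cell = parent,
               area_px = area, assigned_by = how)
  })
  dropped <- names(px)[vapply(parents, is.null, logical(1))]
  if (length(dropped)) keep[keep %in% as.integer(dropped)] <- 0L
  keep <- relabel_sequential(keep)
  parents <- do.call(rbind, Filter(Negate(is.null), parents))
  if (is.null(parents)) {
    attr(empty, "n_size_filtered") <- length(dropped)
    return(empty)
  }
  # relabel parent table to the compacted ids
  parents$punctum <- seq_len(nrow(parents))
  out <- label_map(keep, "puncta", frame_index)
  attr(out, "parents") <- parents
  attr(out, "n_size_filtered") <- length(dropped)
  out
}

#' Match labels between two segmentations by maximal overlap
#'
#' @param seg,ref label matrices (or `"label_map"`s).
#' @return data frame with `seg`, `ref` (0 = unmatched), `overlap_px`, `iou`.
#' @export
match_labels <- function(seg, ref) {
  s <- as_label_matrix(seg); r <- as_label_matrix(ref)
  stopifnot(all(dim(s) == dim(r)))
  ids <- setdiff(unique(as.vector(s)), 0L)
  px <- object_pixel_list(s)
  ref_area <- table(r[r != 0])
  out <- lapply(ids, function(id) {
    idx <- px[[as.character(id)]]
    ov <- table(r[idx])
    ov <- ov[names(ov) != "0"]
    if (!length(ov))
      return(data.frame(seg = id, ref = 0L, overlap_px = 0L, iou = 0))
    best <- names(ov)[which.max(ov)]
    inter <- as.integer(ov[best])
    uni <- length(idx) + as.integer(ref_area[best]) - inter
    data.frame(seg = id, ref = as.integer(best), overlap_px = inter,
               iou = inter / uni)
  })
  if (!length(out))
    return(data.frame(seg = integer(0), ref = integer(0),
                      overlap_px = integer(0), iou = numeric(0)))
  do.call(rbind, out)
}
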