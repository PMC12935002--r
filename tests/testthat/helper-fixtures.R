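# In-code fixtures shared across test files.

# a single-cell, noise-free scene for exact-recovery checks
noise_free_scene <- function(oxd, seed = 1, n_cells = 1,
                             compartment = "cytosol", ...) {
  st <- strain_spec("probe", compartment, n_cells = n_cells,
                    oxd_air = oxd, oxd_sd = 0, start_offset = 0,
                    division_rate = 0, ...)
  wt <- strain_spec("WT", "wt", n_cells = 2, division_rate = 0)
  spec <- scene_spec(image_shape = c(160, 160), n_frames = 1,
                     strains = list(st, wt), rng_seed = seed,
                     oxd_frame_sd = 0)
  optics <- optical_model(noise_model = "none", autofluor_cv = 0)
  list(scene = generate_scene(spec, optics), optics = optics)
}

# exact background of a noise-free scene (autofluorescence + camera offset)
exact_background <- function(optics) optics$background_mean + optics$autofluor_mean

# serpentine (boustrophedon) fill: the first `area` pixels form a
# 4-connected blob inside a width x width block anchored at (row0, col0)
serpentine_blob <- function(area, row0, col0, width) {
  stopifnot(area <= width^2)
  coords <- matrix(NA_integer_, area, 2)
  k <- 1L
  for (r in seq_len(width)) {
    cols <- if (r %% 2 == 1) seq_len(width) else rev(seq_len(width))
    for (cc in cols) {
      if (k > area) break
      coords[k, ] <- c(row0 + r - 1L, col0 + cc - 1L)
      k <- k + 1L
    }
    if (k > area) break
  }
  coords
}

# draw a filled disc into a matrix, returning the modified matrix
draw_disc <- function(m, cy, cx, r, value = 1) {
  for (i in max(1, cy - r):min(nrow(m), cy + r))
    for (j in max(1, cx - r):min(ncol(m), cx + r))
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- value
  m
}

# compare two label matrices as partitions of the foreground (label ids may
# differ; the grouping of pixels must not)
same_partition <- function(a, b) {
  pa <- split(which(a != 0), a[a != 0])
  pb <- split(which(b != 0), b[b != 0])
  if (length(pa) != length(pb)) return(FALSE)
  key <- function(p) sort(vapply(p, function(v) paste(sort(v), collapse = ","),
                                 character(1)))
  identical(key(pa), key(pb))
}
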