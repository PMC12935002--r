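test_that("noise-free scenes hit the spectral endmember ratios exactly", {
  for (oxd in c(0, 1)) {
    nf <- noise_free_scene(oxd)
    sc <- nf$scene; op <- nf$optics
    lab <- sc$cell_labels[[1]]
    truth <- sc$truth[sc$truth$type == "cell" & sc$truth$compartment != "wt", ]
    b <- exact_background(op)
    idx <- which(lab == truth$object_id[1])
    ratio <- (mean(sc$frames[[1]][, , "ex395"][idx]) - b) /
      (mean(sc$frames[[1]][, , "ex470"][idx]) - b)
    expected <- if (oxd == 0) op$s_red_395 / op$s_red_470 else
      op$s_ox_395 / op$s_ox_470
    expect_equal(ratio, expected, tolerance = 1e-12)
    expect_equal(truth$true_ratio[1], expected, tolerance = 1e-12)
  }
})

test_that("identical spec and seed give bit-identical scenes", {
  spec <- scene_spec(image_shape = c(300, 300), n_frames = 3,
                     strains = default_strains(n_cells = 3, n_wt = 2),
                     rng_seed = 7)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cell_labels, b$cell_labels)
})

test_that("wild-type objects carry no oxidation-dependent signal", {
  wt <- strain_spec("WT", "wt", n_cells = 3, division_rate = 0)
  spec <- scene_spec(image_shape = c(128, 128), n_frames = 1,
                     strains = list(wt), rng_seed = 3)
  op <- optical_model(noise_model = "none", autofluor_cv = 0)
  sc <- generate_scene(spec, op)
  lab <- sc$cell_labels[[1]]
  for (ch in c("ex395", "ex470")) {
    vals <- sc$frames[[1]][, , ch][lab != 0]
    expect_true(all(vals == op$background_mean + op$autofluor_mean))
  }
  expect_true(all(is.na(sc$truth$true_oxd)))
})

test_that("true ratio is invariant to probe concentration", {
  base <- noise_free_scene(0.6, seed = 5)$scene
  st <- strain_spec("probe", "cytosol", n_cells = 1, oxd_air = 0.6,
                    oxd_sd = 0, start_offset = 0, division_rate = 0)
  wt <- strain_spec("WT", "wt", n_cells = 2, division_rate = 0)
  spec <- scene_spec(image_shape = c(160, 160), n_frames = 1,
                     strains = list(st, wt), rng_seed = 5, oxd_frame_sd = 0)
  op2 <- optical_model(noise_model = "none", autofluor_cv = 0,
                       probe_level = 2)  # double the probe amount
  doubled <- generate_scene(spec, op2)
  b <- exact_background(op2)
  measure <- function(sc) {
    id <- sc$truth$object_id[sc$truth$compartment == "cytosol"][1]
    idx <- which(sc$cell_labels[[1]] == id)
    (mean(sc$frames[[1]][, , "ex395"][idx]) - b) /
      (mean(sc$frames[[1]][, , "ex470"][idx]) - b)
  }
  expect_equal(measure(base), measure(doubled), tolerance = 1e-12)
  # intensities themselves did change
  expect_gt(max(doubled$frames[[1]][, , "ex470"]),
            max(base$frames[[1]][, , "ex470"]))
})

test_that("every labeled pixel maps to exactly one ground-truth record", {
  spec <- scene_spec(image_shape = c(200, 200), n_frames = 2,
                     strains = default_strains(n_cells = 4, n_wt = 2),
                     rng_seed = 11)
  sc <- generate_scene(spec)
  for (f in 1:2) {
    tf <- sc$truth[sc$truth$frame == f, ]
    cell_ids <- setdiff(unique(as.vector(sc$cell_labels[[f]])), 0L)
    punct_ids <- setdiff(unique(as.vector(sc$puncta_labels[[f]])), 0L)
    expect_setequal(cell_ids, tf$object_id[tf$type == "cell"])
    expect_setequal(punct_ids, tf$object_id[tf$type == "punctum"])
    # recorded areas agree with the rendered label maps
    for (id in cell_ids)
      expect_equal(sum(sc$cell_labels[[f]] == id),
                   tf$area_px[tf$object_id == id])
  }
})

test_that("divisions replace the mother with two new labels", {
  st <- strain_spec("c", "cytosol", n_cells = 3, division_rate = 1,
                    cell_shaft_range = c(36, 44))
  spec <- scene_spec(image_shape = c(256, 256), n_frames = 2,
                     strains = list(st), rng_seed = 2)
  sc <- generate_scene(spec)
  f1 <- sc$truth$object_id[sc$truth$frame == 1]
  f2 <- sc$truth$object_id[sc$truth$frame == 2]
  expect_length(f2, 6)                 # every mother divided
  expect_length(intersect(f1, f2), 0)  # mothers gone, daughters are new ids
})

test_that("an overcrowded scene fails with an explicit placement error", {
  st <- strain_spec("c", "cytosol", n_cells = 60)
  spec <- scene_spec(image_shape = c(64, 64), n_frames = 1,
                     strains = list(st), rng_seed = 1, max_place_tries = 50)
  expect_error(generate_scene(spec), "too crowded")
})

test_that("generated spectra are exact linear mixtures of the endmembers", {
  em <- spectral_endmembers()
  tr1 <- generate_spectrum(1, n_replicates = 1, amplitude = 50,
                           amplitude_cv = 0, noise_sd = 0, seed = 1)
  sensor <- tr1[tr1$strain != "WT", ]
  expect_length(sensor$intensity, 131)
  expect_equal(sensor$intensity, em$blank_level + 50 * em$s_ox)

  tr_mid <- generate_spectrum(0.5, n_replicates = 1, amplitude = 50,
                              amplitude_cv = 0, noise_sd = 0, seed = 1)
  tr_red <- generate_spectrum(0, n_replicates = 1, amplitude = 50,
                              amplitude_cv = 0, noise_sd = 0, seed = 1)
  mid <- tr_mid[tr_mid$strain != "WT", "intensity"]
  lo <- tr_red[tr_red$strain != "WT", "intensity"]
  hi <- sensor$intensity
  expect_equal(mid, (lo + hi) / 2)  # exact midpoint of the two endmembers

  # replicates differ only by their noise realization
  reps <- generate_spectrum(0.4, n_replicates = 3, amplitude_cv = 0,
                            noise_sd = 0, seed = 2)
  s <- reps[reps$strain != "WT", ]
  expect_equal(s$intensity[s$replicate == 1], s$intensity[s$replicate == 2])
  expect_error(generate_spectrum(1.4), "oxd")
})
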