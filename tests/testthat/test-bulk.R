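test_that("chlorophyll quantification is exactly linear", {
  expect_equal(chlorophyll_concentration(1.0)$chl_conc, 16.29)
  expect_equal(chlorophyll_concentration(0)$chl_conc, 0)
  expect_equal(chlorophyll_concentration(0.5)$chl_conc, 8.145)
  # round trip conc -> abs -> conc is the identity
  conc <- 11.7
  expect_equal(chlorophyll_concentration(conc / 16.29)$chl_conc, conc)
  r <- chlorophyll_concentration(1.0)
  expect_equal(r$dilution_factor, 16.29 / 3)
  expect_equal(chlorophyll_concentration(0.1)$dilution_factor, 1)
  expect_error(chlorophyll_concentration(-0.2), "non-negative")
})

flat_trace <- function(i395, i470, replicate = 1, strain = "s") {
  data.frame(excitation_nm = c(395, 470), intensity = c(i395, i470),
             strain = strain, replicate = replicate)
}

test_that("bulk ratio subtracts averaged wild-type emission before dividing", {
  strain <- flat_trace(110, 60)
  wt <- rbind(flat_trace(8, 12, 1, "WT"), flat_trace(12, 8, 2, "WT"))
  r <- bulk_ratio(strain, wt)
  expect_equal(r$b_395, 10)
  expect_equal(r$b_470, 10)
  expect_equal(r$mean_ratio, (110 - 10) / (60 - 10))  # = 2.0
})

test_that("a strain indistinguishable from wild type is flagged undefined", {
  wt <- flat_trace(10, 10, 1, "WT")
  strain <- flat_trace(10, 10)
  expect_warning(r <- bulk_ratio(strain, wt), "non-positive")
  expect_true(is.na(r$mean_ratio))
  expect_equal(r$n_excluded, 1L)
})

test_that("oxidized spectra yield higher bulk ratios than reduced spectra", {
  ox <- generate_spectrum(1, n_replicates = 3, amplitude_cv = 0,
                          noise_sd = 0, seed = 1)
  red <- generate_spectrum(0, n_replicates = 3, amplitude_cv = 0,
                           noise_sd = 0, seed = 1)
  r_ox <- bulk_ratio(ox[ox$strain != "WT", ], ox[ox$strain == "WT", ])
  r_red <- bulk_ratio(red[red$strain != "WT", ], red[red$strain == "WT", ])
  expect_gt(r_ox$mean_ratio, r_red$mean_ratio)
  op <- optical_model()
  expect_equal(r_ox$mean_ratio, op$s_ox_395 / op$s_ox_470, tolerance = 1e-10)
  expect_equal(r_red$mean_ratio, op$s_red_395 / op$s_red_470, tolerance = 1e-10)
})

test_that("bulk ratio agrees with the imaging ratio for the same oxidation", {
  # cross-module consistency in the noise-free limit
  for (oxd in c(0.25, 0.6, 0.85)) {
    tr <- generate_spectrum(oxd, n_replicates = 2, amplitude_cv = 0,
                            noise_sd = 0, seed = 1)
    r <- bulk_ratio(tr[tr$strain != "WT", ], tr[tr$strain == "WT", ])
    expect_equal(r$mean_ratio, oxd_to_ratio(oxd), tolerance = 1e-10)
  }
})

test_that("bulk ratio is invariant to a common scale when blanks scale too", {
  tr <- generate_spectrum(0.5, n_replicates = 3, amplitude_cv = 0.05,
                          noise_sd = 0.3, seed = 6)
  s <- tr[tr$strain != "WT", ]; w <- tr[tr$strain == "WT", ]
  r1 <- bulk_ratio(s, w)
  s2 <- s; w2 <- w
  s2$intensity <- s2$intensity * 4.2; w2$intensity <- w2$intensity * 4.2
  r2 <- bulk_ratio(s2, w2)
  expect_equal(r2$mean_ratio, r1$mean_ratio)
  expect_equal(r2$ratios, r1$ratios)
})

test_that("the order-of-operations option changes the estimator, not the target", {
  tr <- generate_spectrum(0.5, n_replicates = 4, amplitude_cv = 0.1,
                          noise_sd = 0.5, seed = 8)
  s <- tr[tr$strain != "WT", ]; w <- tr[tr$strain == "WT", ]
  mor <- bulk_ratio(s, w, method = "mean_of_ratios")
  rom <- bulk_ratio(s, w, method = "ratio_of_means")
  expect_equal(mor$mean_ratio, oxd_to_ratio(0.5), tolerance = 0.05)
  expect_equal(rom$mean_ratio, oxd_to_ratio(0.5), tolerance = 0.05)
  expect_false(isTRUE(all.equal(mor$mean_ratio, rom$mean_ratio)))
})

test_that("treatment response reproduces the agent-sensitivity pattern", {
  em <- spectral_endmembers()
  mk <- function(oxd, treatment, n = 3, seed) {
    tr <- generate_spectrum(oxd, n_replicates = n, amplitude_cv = 0.05,
                            noise_sd = 0.3, treatment = treatment,
                            seed = seed, endmembers = em)
    tr
  }
  # cytosol-like: strong response to both agents, ordered DTT < none < H2O2
  parts <- list(mk(0.3, "none", seed = 1), mk(0.05, "DTT", seed = 2),
                mk(0.9, "H2O2", seed = 3))
  sensor <- do.call(rbind, lapply(parts, function(p) p[p$strain != "WT", ]))
  wt <- parts[[1]][parts[[1]]$strain == "WT", ]
  res <- treatment_response(sensor, wt)
  r <- stats::setNames(res$mean_ratio, res$treatment)
  expect_lt(r[["DTT"]], r[["none"]])
  expect_lt(r[["none"]], r[["H2O2"]])
  expect_lt(res$p_vs_baseline[res$treatment == "DTT"], 0.05)

  # carboxysome-like: already fully oxidized, no oxidant response
  parts2 <- list(mk(0.9, "none", seed = 4), mk(0.9, "H2O2", seed = 5))
  sensor2 <- do.call(rbind, lapply(parts2, function(p) p[p$strain != "WT", ]))
  res2 <- treatment_response(sensor2, parts2[[1]][parts2[[1]]$strain == "WT", ])
  expect_gt(res2$p_vs_baseline[res2$treatment == "H2O2"], 0.05)

  expect_error(treatment_response(sensor[sensor$treatment != "none", ], wt),
               "baseline")
})
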