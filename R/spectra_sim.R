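#' Generate bulk excitation-spectrum traces with matched blanks
#'
#' Emulates a spectrofluorometer scan of a chlorophyll-normalized culture:
#' excitation swept 350--480 nm at 1-nm steps (131 points), emission read at
#' a fixed wavelength. The sensor trace is the two-state linear mixture
#' `amplitude * (oxd * S_ox + (1 - oxd) * S_red) + blank + noise`; matched
#' wild-type blanks contain `blank + noise` only and are what the ratio
#' workflow subtracts as background.
#'
#' @param oxd degree of oxidation in [0, 1].
#' @param n_replicates replicate traces (and matched blanks) to generate.
#' @param amplitude overall sensor signal amplitude (culture density x
#'   expression level); replicate-to-replicate amplitude varies by
#'   `amplitude_cv`, which the ratio is insensitive to by design.
#' @param amplitude_cv coefficient of variation of amplitude.
#' @param noise_sd additive Gaussian noise per wavelength point (counts).
#' @param endmembers [spectral_endmembers()] supplying S_ox, S_red and the
#'   blank level.
#' @param strain,condition,treatment annotations carried into the output.
#' @param seed integer seed (set once; `NULL` to use the current RNG state).
#' @return data frame with columns `excitation_nm`, `intensity`, `strain`,
#'   `treatment`, `condition`, `replicate`, one row per wavelength per
#'   replicate; sensor traces first, then matched `"WT"` blanks.
#' @export
generate_spectrum <- function(oxd, n_replicates = 3, amplitude = 100,
                              amplitude_cv = 0.05, noise_sd = 0,
                              endmembers = spectral_endmembers(),
                              strain = "roGFP2", condition = "air",
                              treatment = "none", seed = NULL) {
  stopifnot_scalar(oxd, "oxd", 0, 1)
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  wl <- endmembers$wavelengths
  mix <- oxd * endmembers$s_ox + (1 - oxd) * endmembers$s_red
  one <- function(strain_name, is_blank, rep_id) {
    amp <- amplitude * max(0, 1 + if (amplitude_cv > 0) rnorm(1, 0, amplitude_cv) else 0)
    base <- endmembers$blank_level + if (is_blank) 0 else amp * mix
    data.frame(excitation_nm = wl,
               intensity = base + if (noise_sd > 0) rnorm(length(wl), 0, noise_sd) else 0,
               strain = strain_name, treatment = treatment,
               condition = condition, replicate = rep_id)
  }
  traces <- do.call(rbind, lapply(seq_len(n_replicates), function(r) one(strain, FALSE, r)))
  blanks <- do.call(rbind, lapply(seq_len(n_replicates), function(r) one("WT", TRUE, r)))
  rbind(traces, blanks)
}
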