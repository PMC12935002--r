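#' Synthetic excitation endmember spectra for a redox-sensitive GFP
#'
#' roGFP2-type sensors interconvert between two spectral forms. The fully
#' oxidized form has a bimodal excitation spectrum with its major peak near
#' 395 nm and a minor peak near 470 nm; the fully reduced form is monomodal
#' with its major peak near 470 nm. Any intermediate degree of oxidation is a
#' linear mixture of the two endmembers, which is what makes the
#' \eqn{R_{395/470}} excitation ratio a monotone readout of oxidation state.
#'
#' The curves here are smooth Gaussian composites chosen to match that
#' qualitative shape; coefficients are fixed so tests can pin exact values.
#' They are sampled on the 350--480 nm grid at 1-nm steps (131 points) used by
#' the bulk spectrum workflow.
#'
#' @param wavelengths excitation wavelengths in nm.
#' @param ox_heights,ox_centers,ox_widths Gaussian parameters of the oxidized
#'   endmember (two components: major ~395 nm, minor ~470 nm).
#' @param red_heights,red_centers,red_widths Gaussian parameters of the
#'   reduced endmember (small 395-nm shoulder plus major ~470 nm peak).
#' @param blank_level flat instrument/medium blank added to every trace.
#' @return list with `wavelengths`, `s_ox`, `s_red` (relative excitation
#'   efficiencies) and `blank_level`; class `"spectral_endmembers"`.
#' @export
spectral_endmembers <- function(wavelengths = 350:480,
                                ox_heights = c(1.00, 0.45),
                                ox_centers = c(394, 467),
                                ox_widths = c(17, 14),
                                red_heights = c(0.12, 1.00),
                                red_centers = c(397, 466),
                                red_widths = c(20, 15),
                                blank_level = 2) {
  stopifnot(all(diff(wavelengths) > 0))
  gsum <- function(h, mu, sd) {
    rowSums(vapply(seq_along(h),
                   function(k) h[k] * exp(-(wavelengths - mu[k])^2 / (2 * sd[k]^2)),
                   numeric(length(wavelengths))))
  }
  out <- list(wavelengths = wavelengths,
              s_ox = gsum(ox_heights, ox_centers, ox_widths),
              s_red = gsum(red_heights, red_centers, red_widths),
              blank_level = blank_level)
  class(out) <- "spectral_endmembers"
  out
}

endmember_at <- function(em, nm, which = c("s_ox", "s_red")) {
  which <- match.arg(which)
  i <- match(nm, em$wavelengths)
  if (is.na(i)) stop("wavelength ", nm, " nm not on the endmember grid")
  em[[which]][i]
}

#' Optical model of the imaging system
#'
#' Collects everything needed to turn a per-object oxidation fraction into
#' pixel counts: relative excitation efficiencies of the fully oxidized and
#' fully reduced sensor at the two excitation lines, camera gain, chlorophyll
#' autofluorescence bleed-through, camera background, and the noise model.
#' Efficiency defaults are the endmember spectra evaluated at 395 and 470 nm,
#' so image-based and spectrum-based ratios agree exactly in the noise-free
#' limit.
#'
#' Pixel intensity of a probe-carrying object at excitation channel c is
#' `gain * probe * (oxd * s_ox_c + (1 - oxd) * s_red_c) + autofluorescence +
#' background (+ noise)`.
#'
#' @param s_ox_395,s_ox_470,s_red_395,s_red_470 relative excitation
#'   efficiencies (> 0) of the two sensor forms at the two lines. The oxidized
#'   form must have the higher 395/470 ratio.
#' @param gain counts per probe-unit per unit excitation efficiency.
#' @param probe_level relative probe amount for diffuse cytosolic signal.
#' @param puncta_brightness probe concentration factor inside puncta relative
#'   to diffuse signal (puncta are high-intensity in these strains).
#' @param autofluor_mean mean chlorophyll autofluorescence bleed-through into
#'   the GFP channels, in counts.
#' @param autofluor_cv cell-to-cell coefficient of variation of pigment
#'   content (scales autofluorescence and the chlorophyll channel together).
#' @param background_mean camera offset + stray light, counts (all channels).
#' @param chl_gain counts per pigment-unit in the chlorophyll channel.
#' @param brightfield_level,brightfield_contrast,brightfield_noise brightfield
#'   background level, darkening inside cells, and Gaussian noise sd (counts).
#' @param noise_model `"poisson_gaussian"` (shot noise plus additive Gaussian
#'   read noise, digitized to integer counts -- matches an sCMOS camera),
#'   `"gaussian"`, or `"none"` (exact expected values, no digitization).
#' @param noise_scale read-noise standard deviation in counts.
#' @param endmembers `spectral_endmembers` object the efficiency defaults are
#'   read from.
#' @return list of validated parameters, class `"optical_model"`.
#' @export
optical_model <- function(s_ox_395 = endmember_at(endmembers, 395, "s_ox"),
                          s_ox_470 = endmember_at(endmembers, 470, "s_ox"),
                          s_red_395 = endmember_at(endmembers, 395, "s_red"),
                          s_red_470 = endmember_at(endmembers, 470, "s_red"),
                          gain = 1500,
                          probe_level = 1,
                          puncta_brightness = 3,
                          autofluor_mean = 40,
                          autofluor_cv = 0.2,
                          background_mean = 100,
                          chl_gain = 800,
                          brightfield_level = 1000,
                          brightfield_contrast = 300,
                          brightfield_noise = 20,
                          noise_model = c("poisson_gaussian", "gaussian", "none"),
                          noise_scale = 2,
                          endmembers = spectral_endmembers()) {
  noise_model <- match.arg(noise_model)
  for (nm in c("s_ox_395", "s_ox_470", "s_red_395", "s_red_470", "gain", "noise_scale"))
    stopifnot_scalar(get(nm), nm, lo = .Machine$double.eps)
  stopifnot_scalar(autofluor_mean, "autofluor_mean", lo = 0)
  stopifnot_scalar(background_mean, "background_mean", lo = 0)
  if (s_ox_395 / s_ox_470 <= s_red_395 / s_red_470)
    stop("invalid optical model: the oxidized form must yield the higher 395/470 ratio")
  out <- list(s_ox_395 = s_ox_395, s_ox_470 = s_ox_470,
              s_red_395 = s_red_395, s_red_470 = s_red_470,
              gain = gain, probe_level = probe_level,
              puncta_brightness = puncta_brightness,
              autofluor_mean = autofluor_mean, autofluor_cv = autofluor_cv,
              background_mean = background_mean, chl_gain = chl_gain,
              brightfield_level = brightfield_level,
              brightfield_contrast = brightfield_contrast,
              brightfield_noise = brightfield_noise,
              noise_model = noise_model, noise_scale = noise_scale,
              endmembers = endmembers)
  class(out) <- "optical_model"
  out
}

#' Expected excitation-channel mixture for a given oxidation fraction
#'
#' @param oxd oxidation fraction(s) in [0, 1].
#' @param optics an [optical_model()].
#' @return list with `mix_395` and `mix_470`, the relative excitation
#'   efficiencies of the oxd/(1-oxd) two-state mixture at each line.
#' @keywords internal
mixture_efficiency <- function(oxd, optics) {
  list(mix_395 = oxd * optics$s_ox_395 + (1 - oxd) * optics$s_red_395,
       mix_470 = oxd * optics$s_ox_470 + (1 - oxd) * optics$s_red_470)
}

#' Theoretical R395/470 ratio for an oxidation fraction
#'
#' The ratio of background-free channel intensities implied by the two-state
#' spectral mixture; strictly increasing in `oxd` and independent of probe
#' amount, which is the property that makes ratiometric imaging comparable
#' across strains of different sensor expression level.
#'
#' @param oxd oxidation fraction(s) in [0, 1].
#' @param optics an [optical_model()].
#' @return numeric vector of ratios.
#' @export
oxd_to_ratio <- function(oxd, optics = optical_model()) {
  if (any(oxd < 0 | oxd > 1, na.rm = TRUE)) stop("oxd must lie in [0, 1]")
  m <- mixture_efficiency(oxd, optics)
  m$mix_395 / m$mix_470
}
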