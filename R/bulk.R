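#' Chlorophyll a concentration from methanol-extract absorbance
#'
#' Linear conversion from absorbance at 665 nm to chlorophyll a
#' concentration, `chl (ug/mL) = 16.29 * Abs665`, together with the dilution
#' factor needed to reach the working concentration used for spectrum
#' acquisition (3 ug/mL by default). The formula's reference optical density
#' is carried as metadata only.
#'
#' @param abs_665 absorbance at 665 nm (>= 0).
#' @param target_chl working concentration to dilute to, ug/mL.
#' @return object of class `"chlorophyll_result"`: `abs_665`, `chl_conc`
#'   (ug/mL), `dilution_factor` (1 when already at or below target),
#'   `target_chl`.
#' @export
chlorophyll_concentration <- function(abs_665, target_chl = 3) {
  if (any(abs_665 < 0)) stop("absorbance must be non-negative")
  chl <- 16.29 * abs_665
  out <- list(abs_665 = abs_665, chl_conc = chl,
              dilution_factor = ifelse(chl > target_chl, chl / target_chl, 1),
              target_chl = target_chl, reference_od730 = 0.233)
  class(out) <- "chlorophyll_result"
  out
}

#' @export
print.chlorophyll_result <- function(x, ...) {
  cat(sprintf("Chlorophyll a: %.4g ug/mL (Abs665 = %.3g); dilute %.3gx to %g ug/mL\n",
              x$chl_conc[1], x$abs_665[1], x$dilution_factor[1], x$target_chl))
  invisible(x)
}

trace_at <- function(traces, nm) {
  v <- traces$intensity[traces$excitation_nm == nm]
  if (!length(v)) stop("traces do not cover ", nm, " nm")
  v
}

#' Bulk R395/470 ratio from excitation-spectrum traces
#'
#' Wild-type emission at 395- and 470-nm excitation is averaged across the
#' wild-type replicates (b395, b470) and subtracted from each sensor
#' replicate's emission at the same two lines before dividing; the
#' per-replicate ratios are then averaged across samples
#' (`method = "mean_of_ratios"`, the default order of operations). A
#' ratio-of-mean-intensities variant is available. Replicates whose
#' background-subtracted denominator is not positive are flagged and
#' excluded with a warning.
#'
#' @param strain_traces data frame with `excitation_nm`, `intensity`,
#'   `replicate` for the sensor strain.
#' @param wt_traces same, for the wild-type blanks.
#' @param method `"mean_of_ratios"` or `"ratio_of_means"`.
#' @return list with `mean_ratio`, `sd_ratio`, `ratios` (per replicate, NA
#'   where excluded), `b_395`, `b_470`, `n_used`, `n_excluded`.
#' @export
bulk_ratio <- function(strain_traces, wt_traces,
                       method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  stopifnot(nrow(strain_traces) > 0, nrow(wt_traces) > 0)
  b_395 <- mean(trace_at(wt_traces, 395))
  b_470 <- mean(trace_at(wt_traces, 470))
  reps <- sort(unique(strain_traces$replicate))
  i395 <- vapply(reps, function(r)
    mean(trace_at(strain_traces[strain_traces$replicate == r, ], 395)), numeric(1))
  i470 <- vapply(reps, function(r)
    mean(trace_at(strain_traces[strain_traces$replicate == r, ], 470)), numeric(1))
  if (method == "ratio_of_means") {
    num <- mean(i395) - b_395; den <- mean(i470) - b_470
    if (den <= 0) {
      warning("mean denominator not positive; bulk ratio undefined")
      return(list(mean_ratio = NA_real_, sd_ratio = NA_real_,
                  ratios = rep(NA_real_, length(reps)),
                  b_395 = b_395, b_470 = b_470, n_used = 0L,
                  n_excluded = length(reps)))
    }
    return(list(mean_ratio = num / den, sd_ratio = NA_real_,
                ratios = rep(NA_real_, length(reps)),
                b_395 = b_395, b_470 = b_470, n_used = length(reps),
                n_excluded = 0L))
  }
  num <- i395 - b_395; den <- i470 - b_470
  ok <- den > 0
  if (any(!ok))
    warning(sum(!ok), " replicate(s) with non-positive denominator excluded")
  ratios <- ifelse(ok, num / den, NA_real_)
  used <- ratios[ok]
  list(mean_ratio = if (length(used)) mean(used) else NA_real_,
       sd_ratio = if (length(used) >= 2) stats::sd(used) else NA_real_,
       ratios = ratios, b_395 = b_395, b_470 = b_470,
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Redox-agent response panel from bulk spectra
#'
#' Computes the bulk ratio per treatment (untreated baseline, reductant,
#' oxidant) and compares each treatment against the untreated baseline with
#' the unpaired two-tailed Student's t-test over per-replicate ratios.
#'
#' @param traces data frame of sensor traces with columns `excitation_nm`,
#'   `intensity`, `treatment`, `replicate`.
#' @param wt_traces wild-type blank traces (pooled across treatments).
#' @param baseline treatment level to compare against (must be present).
#' @return data frame with one row per treatment: `treatment`, `mean_ratio`,
#'   `sd_ratio`, `n`, `p_vs_baseline`, `stars`.
#' @export
treatment_response <- function(traces, wt_traces, baseline = "none") {
  trts <- unique(traces$treatment)
  if (!baseline %in% trts)
    stop("missing untreated baseline '", baseline, "'")
  per <- lapply(trts, function(tr)
    bulk_ratio(traces[traces$treatment == tr, ], wt_traces))
  names(per) <- trts
  base_ratios <- per[[baseline]]$ratios
  base_ratios <- base_ratios[!is.na(base_ratios)]
  out <- do.call(rbind, lapply(trts, function(tr) {
    r <- per[[tr]]
    p <- NA_real_
    if (tr != baseline) {
      rr <- r$ratios[!is.na(r$ratios)]
      if (length(rr) >= 2 && length(base_ratios) >= 2)
        p <- compare_groups(rr, base_ratios)$p_value
    }
    data.frame(treatment = tr, mean_ratio = r$mean_ratio,
               sd_ratio = r$sd_ratio, n = r$n_used, p_vs_baseline = p,
               stars = ifelse(is.na(p), "", p_stars(p)))
  }))
  rownames(out) <- NULL
  out
}
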