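#' Aggregate per-object ratios into population time series
#'
#' Per group (e.g. strain or compartment) and frame: mean ratio, standard
#' error of the mean (sample sd / sqrt(n), undefined for n < 2), and n over
#' the objects with defined ratios. n is expected to vary across frames as
#' cells divide. Frames inside the burn-in window -- the initial settling
#' period while cells adjust to the imaging conditions -- are flagged; they
#' stay in the emitted table but are excluded from condition-comparison
#' statistics downstream.
#'
#' @param measurements data frame with `ratio`, `ratio_defined`, `frame`, and
#'   (optionally) `time_min`; grouping columns per `group_by`.
#' @param group_by character vector of grouping column names.
#' @param frame_interval_min minutes per frame, used when `time_min` absent.
#' @param burn_in_hours initial window to flag (default 3 h, the upper end of
#'   the settling period).
#' @return data frame of class `"population_series"`: one row per group per
#'   frame with `time_min`, `mean_ratio`, `sem`, `n`, `burn_in`.
#' @export
aggregate_timeseries <- function(measurements, group_by = "compartment",
                                 frame_interval_min = 20, burn_in_hours = 3) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("ratio", "frame") %in% names(m)))
  if (!"ratio_defined" %in% names(m)) m$ratio_defined <- !is.na(m$ratio)
  if (!length(group_by)) { m$.group <- "all"; group_by <- ".group" }
  missing_groups <- setdiff(group_by, names(m))
  if (length(missing_groups))
    stop("grouping columns not found: ", paste(missing_groups, collapse = ", "))
  m <- m[m$ratio_defined & !is.na(m$ratio), , drop = FALSE]
  if (!nrow(m)) {
    warning("no defined ratios to aggregate; returning empty series")
    out <- data.frame()
    class(out) <- c("population_series", class(out))
    return(out)
  }
  if (!"time_min" %in% names(m)) m$time_min <- (m$frame - 1) * frame_interval_min
  key <- do.call(paste, c(unname(m[group_by]), list(m$frame), sep = "\r"))
  pieces <- split(m, key)
  out <- do.call(rbind, lapply(pieces, function(d) {
    n <- nrow(d)
    res <- d[1, group_by, drop = FALSE]
    res$frame <- d$frame[1]
    res$time_min <- d$time_min[1]
    res$mean_ratio <- mean(d$ratio)
    res$sem <- if (n >= 2) stats::sd(d$ratio) / sqrt(n) else NA_real_
    res$n <- n
    res
  }))
  out$burn_in <- out$time_min < burn_in_hours * 60
  out <- out[do.call(order, c(unname(out[group_by]), list(out$frame))), ]
  rownames(out) <- NULL
  class(out) <- c("population_series", class(out))
  out
}

#' Histogram of redox ratios over fixed bins
#'
#' @param measurements data frame with `ratio` (and optionally
#'   `ratio_defined`), or a numeric vector of ratios.
#' @param bins number of bins (positive).
#' @param range `c(lo, hi)` bin span; ratios above `hi` land in an overflow
#'   bucket, below `lo` in an underflow bucket (both reported).
#' @return list with `table` (bin_lo, bin_hi, count, frequency),
#'   `n_underflow`, `n_overflow`, `n_undefined`; frequencies are normalized
#'   over all finite ratios including over/underflow.
#' @export
ratio_histogram <- function(measurements, bins = 30, range = c(0, 0.3)) {
  if (bins <= 0) stop("bins must be positive")
  if (is.data.frame(measurements)) {
    def <- if ("ratio_defined" %in% names(measurements))
      measurements$ratio_defined else !is.na(measurements$ratio)
    x <- measurements$ratio[def & !is.na(measurements$ratio)]
    n_undef <- sum(!def | is.na(measurements$ratio))
  } else {
    x <- measurements[!is.na(measurements)]
    n_undef <- sum(is.na(measurements))
  }
  if (!length(x)) stop("no defined ratios to histogram")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  under <- sum(x < range[1]); over <- sum(x > range[2])
  inside <- x[x >= range[1] & x <= range[2]]
  counts <- if (length(inside))
    as.integer(table(cut(inside, edges, include.lowest = TRUE))) else
      integer(bins)
  n_total <- length(x)
  list(table = data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                          count = counts, frequency = counts / n_total),
       n_underflow = under, n_overflow = over, n_undefined = n_undef)
}

#' Detect bimodality in a population of redox ratios
#'
#' Fits 1- and 2-component Gaussian mixtures (deterministic model-based
#' initialization) and reports two modes only when both gates pass: the BIC
#' improvement of the 2-component model exceeds `delta_bic_threshold`, and
#' the fitted modes are separated by at least `min_ashman_d` (Ashman's D), so
#' that a heavy tail alone cannot count as bimodal. ΔBIC is reported on the
#' smaller-is-better convention (BIC1 - BIC2 > threshold means two modes).
#' Hartigan's dip test is available as an alternative decision statistic.
#'
#' By default the mixtures are fitted on the log-ratio scale: the oxidation
#' fraction maps to the excitation ratio through a convex function, so even
#' a symmetric unimodal population is right-skewed on the ratio scale, which
#' a Gaussian mixture would misread as two components; the log transform is
#' monotone (mode counts are preserved) and near-linearizing. Zero ratios
#' (produced by the clip-at-zero rule) cannot be log-transformed; they are
#' excluded from the fit and counted in `n_nonpositive`.
#'
#' @param x numeric vector of ratios (NAs dropped).
#' @param min_n minimum sample size; below it an explicit insufficient-data
#'   result is returned, never a guess.
#' @param delta_bic_threshold BIC gate (default 10, decisive evidence).
#' @param min_ashman_d separation gate (default 2), evaluated on the fitting
#'   scale.
#' @param scale `"log"` (default) or `"linear"` fitting scale.
#' @param method `"gmm"` (default) or `"dip"` (dip-style unimodality
#'   statistic with a Monte-Carlo null; still reports GMM parameters).
#' @param dip_alpha significance level for the dip test.
#' @param seed seed for the (deterministic-given-seed) fits.
#' @return object of class `"bimodality_result"`: `n_components` (1 or 2; NA
#'   when insufficient), component `means` and `weights` on the ratio scale
#'   (geometric means for the log scale; ascending order), `sds` on the
#'   fitting scale, `delta_bic`, `ashman_d`, `threshold`, `n`,
#'   `n_nonpositive`, `sufficient`.
#' @export
detect_bimodality <- function(x, min_n = 50, delta_bic_threshold = 10,
                              min_ashman_d = 2, scale = c("log", "linear"),
                              method = c("gmm", "dip"),
                              dip_alpha = 0.05, seed = 1) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  x <- x[!is.na(x)]
  n_nonpos <- if (scale == "log") sum(x <= 0) else 0L
  y <- if (scale == "log") log(x[x > 0]) else x
  res <- list(n = length(y), n_nonpositive = n_nonpos,
              threshold = delta_bic_threshold,
              min_ashman_d = min_ashman_d, method = method, scale = scale)
  back <- if (scale == "log") exp else identity
  if (length(y) < min_n) {
    res$sufficient <- FALSE
    res$n_components <- NA_integer_
    class(res) <- "bimodality_result"
    return(res)
  }
  res$sufficient <- TRUE
  set.seed(seed)
  f1 <- Mclust(y, G = 1, modelNames = "V", verbose = FALSE)
  f2 <- Mclust(y, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(f2)) f2 <- Mclust(y, G = 2, modelNames = "E", verbose = FALSE)
  # mclust BIC is larger-is-better; convert to BIC1 - BIC2 (smaller-is-better)
  res$delta_bic <- if (is.null(f2)) -Inf else as.numeric(f2$bic - f1$bic)
  if (!is.null(f2)) {
    mu <- as.numeric(f2$parameters$mean)
    sd2 <- sqrt(as.numeric(f2$parameters$variance$sigmasq))
    if (length(sd2) == 1) sd2 <- rep(sd2, 2)
    w <- as.numeric(f2$parameters$pro)
    o <- order(mu)
    res$means <- back(mu[o]); res$sds <- sd2[o]; res$weights <- w[o]
    res$ashman_d <- ashman_d(mu[o][1], mu[o][2], sd2[o][1], sd2[o][2])
  } else {
    res$means <- back(mean(y)); res$sds <- stats::sd(y); res$weights <- 1
    res$ashman_d <- 0
  }
  two <- if (method == "gmm") {
    res$delta_bic > delta_bic_threshold && res$ashman_d >= min_ashman_d
  } else {
    dip <- dip_statistic(sort(y))
    res$dip <- dip
    res$dip_p <- dip_null_p(dip, length(y), seed = seed)
    res$dip_p < dip_alpha && res$ashman_d >= min_ashman_d
  }
  res$n_components <- if (two) 2L else 1L
  if (res$n_components == 1L) {
    res$means <- back(mean(y)); res$sds <- stats::sd(y); res$weights <- 1
  }
  class(res) <- "bimodality_result"
  res
}

# Dip-style unimodality statistic: for each candidate mode position, the ECDF
# of a unimodal sample should be convex to the left of the mode and concave to
# the right; the statistic is the smallest (over mode positions) worst-case
# deviation of the ECDF from that shape. Its null distribution is calibrated
# by Monte Carlo on uniform samples with the same statistic.
dip_statistic <- function(xs) {
  n <- length(xs)
  f <- (seq_len(n) - 0.5) / n
  devs <- vapply(seq_len(n), function(m) {
    left <- if (m > 2) gcm_dev(xs[1:m], f[1:m]) else 0
    right <- if (m < n - 1) lcm_dev(xs[m:n], f[m:n]) else 0
    max(left, right)
  }, numeric(1))
  min(devs) / 2
}

# max deviation of f above its greatest convex minorant on x (lower hull)
gcm_dev <- function(x, f) {
  n <- length(x)
  if (n <= 2) return(0)
  hull <- 1L
  for (i in 2:n) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((f[b] - f[a]) * (x[i] - x[b]) >= (f[i] - f[b]) * (x[b] - x[a]))
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  interp <- stats::approx(x[hull], f[hull], xout = x, rule = 2,
                          ties = "ordered")$y
  max(f - interp)
}

# max deviation of f below its least concave majorant
lcm_dev <- function(x, f) gcm_dev(x, -f)

dip_null_p <- function(dip, n, n_sim = 200, seed = 1) {
  set.seed(seed + 1L)
  sims <- replicate(n_sim, dip_statistic(sort(stats::runif(n))))
  mean(sims >= dip)
}

#' @export
print.bimodality_result <- function(x, ...) {
  if (!x$sufficient) {
    cat(sprintf("<bimodality: insufficient data (n = %d)>\n", x$n))
    return(invisible(x))
  }
  cat(sprintf("<bimodality: %d component(s), n = %d, dBIC = %.1f, Ashman D = %.2f>\n",
              x$n_components, x$n, x$delta_bic, x$ashman_d))
  if (x$n_components == 2)
    cat(sprintf("  modes %.3f (w = %.2f) / %.3f (w = %.2f)\n",
                x$means[1], x$weights[1], x$means[2], x$weights[2]))
  invisible(x)
}

#' Assess hysteresis of a population series after a reversed perturbation
#'
#' Compares the mean ratio over a pre-shift steady-state window against an
#' equal-length window at the end of the series, after the condition has been
#' returned to its original state. The difference is reported as pre minus
#' post (positive = the population was more oxidized before the shift, i.e.
#' it did not return to its pre-shift state), with a two-tailed Welch test
#' across the per-frame means (window variances differ by construction).
#'
#' @param series a `"population_series"` for one group.
#' @param shift_frame frame at which the condition was first changed.
#' @param return_frame frame at which the condition was changed back.
#' @param window number of frames per comparison window.
#' @return object of class `"hysteresis_result"` with `pre_mean`,
#'   `post_mean`, `difference`, `p_value`, `pre_window`, `post_window`.
#' @export
assess_hysteresis <- function(series, shift_frame, return_frame, window = 6) {
  s <- as.data.frame(series)
  stopifnot(all(c("frame", "mean_ratio") %in% names(s)))
  s <- s[order(s$frame), ]
  pre <- (shift_frame - window):(shift_frame - 1)
  last <- max(s$frame)
  post <- (last - window + 1):last
  if (any(pre < min(s$frame)) || any(post > last) || min(post) <= return_frame)
    stop("comparison windows must fit within the series and after the return")
  if (max(pre) >= min(post)) stop("comparison windows overlap")
  if ("burn_in" %in% names(s) && any(s$burn_in[s$frame %in% pre]))
    stop("pre-shift window overlaps the burn-in period")
  a <- s$mean_ratio[s$frame %in% pre]
  b <- s$mean_ratio[s$frame %in% post]
  if (length(a) < window || length(b) < window)
    stop("window longer than available frames")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  out <- list(pre_mean = mean(a), post_mean = mean(b),
              difference = mean(a) - mean(b),
              p_value = tt$p.value, pre_window = range(pre),
              post_window = range(post))
  class(out) <- "hysteresis_result"
  out
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf(paste0("<hysteresis: pre %.4f vs post %.4f, difference %+.4f ",
                     "(p = %.3g, %s)>\n"),
              x$pre_mean, x$post_mean, x$difference, x$p_value,
              p_stars(x$p_value)))
  invisible(x)
}

#' Unpaired two-tailed Student's t comparison of two groups
#'
#' Classical equal-variance t-test with star annotations. When both groups
#' have zero variance and equal means (a degenerate comparison a t-test
#' cannot evaluate), p = 1 is returned by convention and flagged.
#'
#' @param a,b numeric vectors, each of length >= 2 (NAs dropped).
#' @param star_thresholds decreasing p cutoffs for *, **, ***.
#' @return list with `t`, `df`, `p_value`, `stars`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
compare_groups <- function(a, b, star_thresholds = c(0.05, 0.001, 1e-4)) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  stars = "ns", mean_a = mean(a), mean_b = mean(b),
                  degenerate = TRUE))
    }
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p_value = 0, stars = "***",
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, stars = p_stars(tt$p.value, star_thresholds),
       mean_a = mean(a), mean_b = mean(b), degenerate = FALSE)
}
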