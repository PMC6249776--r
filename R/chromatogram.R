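## HILIC-UPLC chromatogram quantification. Retention times are mapped to
## glucose units (GU) through a monotone interpolant fitted to a
## hydrolysed-glucose-oligomer (dextran) ladder, and peaks are quantified
## by trapezoidal integration inside fixed GU windows shared by all
## samples. Real window boundaries are instrument-specific; the bundled
## schemes are synthetic placeholders with the right panel sizes.

#' Construct a chromatogram object
#'
#' @param time strictly increasing time grid in minutes
#' @param signal non-negative fluorescence intensity at each time point
#' @param sample_id optional identifier
#' @return an object of class `chromatogram`
#' @export
chromatogram <- function(time, signal, sample_id = NA_character_) {
  assert_that(length(time) == length(signal),
              "time and signal must have equal length")
  assert_that(all(diff(time) > 0), "time must be strictly increasing")
  assert_that(all(is.finite(signal)) && all(signal >= 0),
              "signal must be finite and non-negative")
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 sample_id = sample_id), class = "chromatogram")
}

#' A synthetic glucose-oligomer calibration ladder
#'
#' Retention times follow a smooth concave curve in GU, qualitatively like
#' a dextran ladder on a HILIC gradient. Purely synthetic: real ladders
#' must be measured per run.
#'
#' @param K number of rungs (integer GU 1..K), at least 4
#' @return data frame with columns `gu`, `rt`
#' @export
synthetic_glucose_ladder <- function(K = 15) {
  assert_that(K >= 4, "ladder needs at least 4 rungs")
  gu <- seq_len(K)
  data.frame(gu = gu, rt = 2 + 1.4 * gu - 0.02 * gu^2)
}

#' Fit a glucose-unit calibration from a ladder standard
#'
#' Fits a shape-preserving monotone piecewise-cubic interpolant (Hyman
#' filtered spline) mapping GU to retention time; the inverse map is
#' obtained by numeric inversion, so `rt_to_gu(gu_to_rt(g)) == g` to
#' numerical precision across the calibrated range. Queries outside the
#' ladder range use linear extrapolation and are flagged.
#'
#' @param ladder data frame with columns `gu` (integer glucose units) and
#'   `rt` (retention time, minutes), strictly increasing in `gu`
#' @return a `gu_calibration` object with functions `gu_to_rt(gu)` and
#'   `rt_to_gu(rt)`; the latter carries an `extrapolated` logical
#'   attribute on its result
#' @export
fit_gu_calibration <- function(ladder) {
  assert_that(all(c("gu", "rt") %in% names(ladder)),
              "ladder needs columns gu and rt")
  ladder <- ladder[order(ladder$gu), ]
  assert_that(nrow(ladder) >= 4, "ladder needs at least 4 rungs")
  assert_that(all(diff(ladder$gu) > 0) && all(diff(ladder$rt) > 0),
              "ladder must be strictly increasing in gu and rt")
  fwd <- splinefun(ladder$gu, ladder$rt, method = "hyman")
  gu_rng <- range(ladder$gu)
  rt_rng <- range(ladder$rt)
  slope_lo <- fwd(gu_rng[1], deriv = 1)
  slope_hi <- fwd(gu_rng[2], deriv = 1)

  gu_to_rt <- function(gu) {
    out <- numeric(length(gu))
    lo <- gu < gu_rng[1]; hi <- gu > gu_rng[2]; mid <- !lo & !hi
    out[mid] <- fwd(gu[mid])
    out[lo] <- rt_rng[1] + slope_lo * (gu[lo] - gu_rng[1])
    out[hi] <- rt_rng[2] + slope_hi * (gu[hi] - gu_rng[2])
    attr(out, "extrapolated") <- lo | hi
    out
  }
  rt_to_gu <- function(rt) {
    out <- numeric(length(rt))
    lo <- rt < rt_rng[1]; hi <- rt > rt_rng[2]; mid <- !lo & !hi
    out[lo] <- gu_rng[1] + (rt[lo] - rt_rng[1]) / slope_lo
    out[hi] <- gu_rng[2] + (rt[hi] - rt_rng[2]) / slope_hi
    out[mid] <- vapply(rt[mid], function(r) {
      if (r == rt_rng[1]) return(gu_rng[1])
      if (r == rt_rng[2]) return(gu_rng[2])
      uniroot(function(g) fwd(g) - r, interval = gu_rng,
              tol = 1e-12)$root
    }, numeric(1))
    attr(out, "extrapolated") <- lo | hi
    out
  }
  structure(list(gu_to_rt = gu_to_rt, rt_to_gu = rt_to_gu,
                 gu_range = gu_rng, rt_range = rt_rng, ladder = ladder),
            class = "gu_calibration")
}

#' Bundled synthetic integration schemes
#'
#' Fixed, shared GU windows (half-open `[lo, hi)`) defining GP1-GP39 or
#' IGP1-IGP24. The published analyses keep the same integration intervals
#' for all samples; the exact boundaries are instrument- and run-specific
#' and are not public, so these bundled schemes are synthetic equal-width
#' placeholders -- substitute a measured scheme for real data.
#'
#' @param panel `"plasma"` (39 windows) or `"igg"` (24 windows)
#' @param file optional CSV with columns `name`, `gu_lo`, `gu_hi`
#' @return an `integration_scheme` data frame (`name`, `gu_lo`, `gu_hi`)
#' @export
default_integration_scheme <- function(panel = c("plasma", "igg"),
                                       file = NULL) {
  panel <- match.arg(panel)
  if (!is.null(file)) {
    sch <- read.csv(file, stringsAsFactors = FALSE)
  } else {
    nm <- peak_names(panel)
    start <- if (panel == "plasma") 2.4 else 4.0
    k <- seq_along(nm)
    sch <- data.frame(name = nm, gu_lo = start + 0.25 * (k - 1),
                      gu_hi = start + 0.25 * k)
  }
  validate_scheme(sch)
}

validate_scheme <- function(sch) {
  assert_that(all(c("name", "gu_lo", "gu_hi") %in% names(sch)),
              "scheme needs columns name, gu_lo, gu_hi")
  assert_that(!anyDuplicated(sch$name), "scheme peak names must be unique")
  sch <- sch[order(sch$gu_lo), ]
  assert_that(all(sch$gu_hi > sch$gu_lo), "windows must have gu_hi > gu_lo")
  assert_that(all(sch$gu_lo[-1] >= sch$gu_hi[-nrow(sch)] - 1e-12),
              "windows must be non-overlapping and ordered")
  class(sch) <- c("integration_scheme", "data.frame")
  sch
}

## trapezoidal integral of (time, signal) over [a, b] with linear
## interpolation of the signal at the window edges
trapz_window <- function(time, signal, a, b) {
  if (b <= time[1] || a >= time[length(time)]) return(0)
  a <- max(a, time[1]); b <- min(b, time[length(time)])
  ya <- stats::approx(time, signal, xout = a)$y
  yb <- stats::approx(time, signal, xout = b)$y
  inside <- which(time > a & time < b)
  xs <- c(a, time[inside], b)
  ys <- c(ya, signal[inside], yb)
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Integrate chromatogram peaks inside fixed GU windows
#'
#' Window boundaries in glucose units are mapped to retention times with
#' the calibration, and the signal is integrated by the trapezoidal rule
#' with linear interpolation at window edges. Returns raw areas
#' (signal x minutes); normalisation to percent of total area is a
#' separate stage ([total_area_normalize()]).
#'
#' @param chrom a [chromatogram()]
#' @param cal a calibration from [fit_gu_calibration()]
#' @param scheme an integration scheme (see
#'   [default_integration_scheme()])
#' @return named numeric vector of raw peak areas
#' @export
integrate_peaks <- function(chrom, cal, scheme) {
  scheme <- validate_scheme(scheme)
  rt_lo <- cal$gu_to_rt(scheme$gu_lo)
  rt_hi <- cal$gu_to_rt(scheme$gu_hi)
  assert_that(rt_lo[1] >= chrom$time[1] - 1e-9 &&
              rt_hi[length(rt_hi)] <= chrom$time[length(chrom$time)] + 1e-9,
              "chromatogram does not span all integration windows")
  areas <- mapply(function(a, b) trapz_window(chrom$time, chrom$signal, a, b),
                  rt_lo, rt_hi)
  setNames(areas, scheme$name)
}

#' Render a synthetic chromatogram from peak areas
#'
#' Builds a sum-of-Gaussians fluorescence trace: one Gaussian per peak
#' with the requested integrated area, centred at a GU position mapped to
#' retention time, plus optional Gaussian noise (clipped at zero). Used to
#' generate test fixtures resembling real profiles.
#'
#' @param areas named numeric vector of target areas (signal x minutes)
#' @param centers_gu Gaussian centres in GU; default the midpoints of
#'   `scheme` windows
#' @param widths_min Gaussian standard deviations in minutes (recycled)
#' @param noise_sd standard deviation of additive noise (0 for none)
#' @param seed integer seed for the noise draw
#' @param cal calibration from [fit_gu_calibration()]
#' @param scheme integration scheme (for default centres and the check
#'   that each centre lies inside its window)
#' @param dt time-grid step in minutes
#' @return a [chromatogram()]
#' @export
render_chromatogram <- function(areas, centers_gu = NULL,
                                widths_min = 0.03, noise_sd = 0,
                                seed = 1L, cal, scheme, dt = 0.002) {
  scheme <- validate_scheme(scheme)
  assert_that(length(areas) == nrow(scheme),
              "need one area per scheme window")
  if (is.null(centers_gu)) centers_gu <- (scheme$gu_lo + scheme$gu_hi) / 2
  assert_that(all(centers_gu >= scheme$gu_lo & centers_gu < scheme$gu_hi),
              "every centre must lie inside its window")
  widths_min <- rep_len(widths_min, length(areas))
  ctr_rt <- cal$gu_to_rt(centers_gu)
  time <- seq(cal$rt_range[1] - 0.5, cal$rt_range[2] + 0.5, by = dt)
  signal <- rep(0, length(time))
  for (i in seq_along(areas)) {
    signal <- signal + areas[i] * dnorm(time, ctr_rt[i], widths_min[i])
  }
  if (noise_sd > 0) {
    signal <- signal + withr::with_seed(seed,
      rnorm(length(time), 0, noise_sd))
  }
  chromatogram(time, pmax(signal, 0))
}

#' Annotate integration windows with candidate structures by GU
#'
#' For each window `[lo, hi)` lists every reference structure whose GU
#' value lies within `[lo - tol, hi + tol)`, emulating GU-based lookup
#' against a structure database.
#'
#' @param scheme an integration scheme
#' @param reference data frame with columns `name` (structure) and `gu`
#' @param tol non-negative GU tolerance
#' @return named list (one element per window) of character vectors
#' @export
annotate_by_gu <- function(scheme, reference, tol = 0.1) {
  scheme <- validate_scheme(scheme)
  assert_that(tol >= 0, "tolerance must be non-negative")
  assert_that(all(c("name", "gu") %in% names(reference)),
              "reference needs columns name and gu")
  assert_that(all(is.finite(reference$gu)), "reference GU must be finite")
  out <- lapply(seq_len(nrow(scheme)), function(i) {
    hit <- reference$gu >= scheme$gu_lo[i] - tol &
           reference$gu < scheme$gu_hi[i] + tol
    reference$name[hit]
  })
  setNames(out, scheme$name)
}
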