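#' Beta-galactosidase activity in Miller units
#'
#' `Miller units = 1000 * (OD420 - 1.75 * OD550) / (2 * t * OD600)` with
#' `t` the reaction time in minutes. The factor `2` is part of the assay's
#' own volume convention and is applied literally; supply your own factor
#' through `volume_factor` if your protocol differs.
#'
#' @param od420,od550,od600 Absorbance readings.
#' @param t_min Reaction time (minutes, > 0).
#' @param volume_factor Multiplier on `t * OD600` in the denominator.
#' @return Miller units (vectorized).
#' @export
miller_units <- function(od420, od550 = 0, od600, t_min, volume_factor = 2) {
  if (any(t_min <= 0)) stop("reaction time must be positive")
  if (any(od600 <= 0)) stop("OD600 must be positive")
  1000 * (od420 - 1.75 * od550) / (volume_factor * t_min * od600)
}

#' Express assay values as percent of the wild-type control
#'
#' @param values Numeric vector of assay readouts.
#' @param wt_value The wild-type readout (> 0).
#' @return `100 * values / wt_value`.
#' @export
normalize_to_wt <- function(values, wt_value) {
  if (wt_value <= 0) stop("wild-type value must be positive")
  100 * values / wt_value
}

#' Folded-reporter ratio from the ER-GFP assay
#'
#' Fluorescence reports folded GFP only; dividing by total GFP protein
#' (itself normalized to a loading control) isolates folding capacity.
#'
#' @param fluorescence Mean fluorescence intensity.
#' @param total_gfp_level Total GFP protein from quantitative immunoblot.
#' @param loading_ref Loading-control signal (default 1 if `total_gfp_level`
#'   is already loading-normalized).
#' @return Fluorescence per unit of total GFP.
#' @export
ergfp_ratio <- function(fluorescence, total_gfp_level, loading_ref = 1) {
  if (any(total_gfp_level <= 0) || any(loading_ref <= 0)) {
    stop("protein levels must be positive")
  }
  fluorescence / (total_gfp_level / loading_ref)
}

#' @rdname ergfp_ratio
#' @param wt_ratio The wild-type strain's ratio; output is percent of WT
#'   (WT = 100%).
#' @export
normalized_ergfp <- function(fluorescence, total_gfp_level, loading_ref = 1,
                             wt_ratio) {
  normalize_to_wt(ergfp_ratio(fluorescence, total_gfp_level, loading_ref),
                  wt_ratio)
}

#' Summarise a pulse-chase series and fit a half-life
#'
#' Converts intensities to percent remaining (100 at each replicate's own
#' time 0), averages across replicates with the between-replicate SD, and
#' fits the half-life by log-linear least squares on the mean percent
#' remaining — the estimator implied by a single-exponential decay.
#'
#' @param series Tibble `replicate`, `time_min`, `intensity` (see
#'   [simulate_decay()]); every replicate must include time 0 with positive
#'   intensity.
#' @return List with `replicates` (per-replicate percent remaining),
#'   `curve` (`time_min`, `mean_percent`, `sd_percent`), and
#'   `half_life_min`.
#' @export
pulse_chase_turnover <- function(series) {
  reps <- split(series, series$replicate)
  pct <- lapply(reps, function(r) {
    i0 <- r$intensity[r$time_min == 0]
    if (length(i0) != 1 || i0 <= 0) {
      stop("each replicate needs a single positive time-0 intensity")
    }
    tibble::tibble(replicate = r$replicate, time_min = r$time_min,
                   percent_remaining = 100 * r$intensity / i0)
  })
  pct <- dplyr::bind_rows(pct)
  times <- sort(unique(pct$time_min))
  mean_p <- vapply(times, function(t) {
    mean(pct$percent_remaining[pct$time_min == t]) }, numeric(1))
  sd_p <- vapply(times, function(t) {
    stats::sd(pct$percent_remaining[pct$time_min == t]) }, numeric(1))
  fit_ok <- mean_p > 0
  if (sum(fit_ok) < 2) stop("need at least two timepoints with signal")
  slope <- stats::coef(stats::lm(log(mean_p[fit_ok]) ~ times[fit_ok]))[[2]]
  list(
    replicates = pct,
    curve = tibble::tibble(time_min = times, mean_percent = mean_p,
                           sd_percent = sd_p),
    half_life_min = if (slope < 0) -log(2) / slope else Inf
  )
}

#' Compare two strains at the final chase timepoint
#'
#' Two-tailed, unpaired Student's t test (pooled variance,
#' `df = nA + nB - 2`) on percent remaining at the last timepoint, with
#' the conventional significance bands.
#'
#' @param a,b Numeric vectors (one value per replicate).
#' @return List `t`, `df`, `p`, `stars` (`"***"` p < 0.001, `"**"` < 0.01,
#'   `"*"` < 0.05, `""` otherwise).
#' @export
compare_final <- function(a, b) {
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, stars = significance_stars(ht$p.value))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-tailed — used where group sizes differ.
#'
#' @param x,y Numeric samples.
#' @return List `t`, `df`, `p`, `stars`.
#' @export
welch_t <- function(x, y) {
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, stars = significance_stars(ht$p.value))
}

#' @rdname compare_final
#' @param p A p-value.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Fraction of spliced HAC1 transcript
#'
#' Spliced fraction = spliced / (spliced + unspliced). Band intensities
#' may first be normalized to an ACT1 loading control; the control cancels
#' in the ratio, so the fraction is invariant to it.
#'
#' @param spliced_intensity,unspliced_intensity Band intensities (>= 0,
#'   not both 0).
#' @param act1_intensity Loading-control intensity (> 0).
#' @return Fraction in \[0, 1\].
#' @export
hac1_splice_fraction <- function(spliced_intensity, unspliced_intensity,
                                 act1_intensity = 1) {
  if (any(act1_intensity <= 0)) stop("ACT1 control must be positive")
  if (any(spliced_intensity < 0) || any(unspliced_intensity < 0)) {
    stop("band intensities must be non-negative")
  }
  s <- spliced_intensity / act1_intensity
  u <- unspliced_intensity / act1_intensity
  if (any(s + u == 0)) stop("total HAC1 signal is zero")
  s / (s + u)
}

#' Doubling time from an exponential growth curve
#'
#' Fits `ln(OD600)` against time by least squares over the configured
#' window and returns `ln(2) / slope`.
#'
#' @param time_h Time (hours).
#' @param od600 Optical density (> 0).
#' @param window Optional `c(min, max)` time window for the fit; at least
#'   3 points must remain.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(time_h, od600, window = range(time_h)) {
  if (any(od600 <= 0)) stop("OD600 must be positive")
  keep <- time_h >= window[1] & time_h <= window[2]
  if (sum(keep) < 3) stop("need at least 3 points in the fitted window")
  slope <- stats::coef(stats::lm(log(od600[keep]) ~ time_h[keep]))[[2]]
  if (slope <= 0) stop("no growth in the fitted window")
  log(2) / slope
}

#' Correlation of doubling time with extra ORF burden
#'
#' Pearson product-moment correlation between strain doubling times and
#' the number of additional duplicated open reading frames each strain
#' carries.
#'
#' @param doubling_times,extra_orf_counts Numeric vectors of equal length.
#' @return Pearson r.
#' @export
orf_burden_correlation <- function(doubling_times, extra_orf_counts) {
  stats::cor(doubling_times, extra_orf_counts, method = "pearson")
}
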