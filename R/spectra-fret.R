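#' Trapezoid area under an emission band
#'
#' Integrates a spectrum over a wavelength window by the trapezoid rule,
#' interpolating linearly at the window edges when they fall between grid
#' points.  Negative intensities are floored at zero before integration
#' (background-subtracted spectra can dip below zero in the wings).
#'
#' @param wavelength_nm strictly increasing wavelength grid.
#' @param intensity spectrum intensities.
#' @param from,to integration window in nm (default 550-700, the acceptor
#'   emission region).
#' @param floor_zero floor negatives at zero first (default `TRUE`).
#' @return Area in intensity x nm units.
#' @export
auc_spectrum <- function(wavelength_nm, intensity, from = 550, to = 700,
                         floor_zero = TRUE) {
  check_spectrum(wavelength_nm, intensity)
  if (from >= to) stop("'from' must be below 'to'")
  y <- if (floor_zero) pmax(intensity, 0) else intensity
  lo <- max(from, min(wavelength_nm)); hi <- min(to, max(wavelength_nm))
  if (lo >= hi) return(0)
  inside <- wavelength_nm > lo & wavelength_nm < hi
  xs <- c(lo, wavelength_nm[inside], hi)
  ys <- c(stats::approx(wavelength_nm, y, lo)$y, y[inside],
          stats::approx(wavelength_nm, y, hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

check_spectrum <- function(wavelength_nm, intensity) {
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength_nm and intensity must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength_nm must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  invisible(TRUE)
}

intensity_at <- function(wavelength_nm, intensity, nm) {
  i <- which.min(abs(wavelength_nm - nm))
  intensity[i]
}

#' Donor level in a mixed spectrum via a two-wavelength ratio standard curve
#'
#' Estimates how much of a reference donor (eGFP) spectrum is present in a
#' measured spectrum that also contains cellular background.  A standard
#' curve of the 510:545 nm emission intensity ratio is built from synthetic
#' sums `background + alpha * donor_ref` over a grid of donor scales
#' `alpha`; the observed ratio of the mixed spectrum is then inverted on
#' that monotone curve (bracketed root refinement, so noiseless mixtures
#' invert to machine precision).  510 and 545 nm are the peak maxima of the
#' donor and background references; single nearest-grid-point intensities
#' are used, not band integrals.
#'
#' @param mixed,background,donor_ref spectra as data frames with
#'   `wavelength_nm`, `intensity`, on a common grid covering 510 and
#'   545 nm.
#' @param alpha_max upper end of the donor-scale grid for the standard
#'   curve.
#' @param n_grid grid resolution of the standard curve.
#' @return The estimated donor scale `alpha >= 0`.
#' @examples
#' s <- sim_spectra(donor_scale = 0.37, acceptor_amp = 0, noise = 0)
#' donor_level_from_ratio_curve(s$coexpressing, s$background, s$donor)
#' @export
donor_level_from_ratio_curve <- function(mixed, background, donor_ref,
                                         alpha_max = 10, n_grid = 201) {
  wl <- mixed$wavelength_nm
  if (!identical(wl, background$wavelength_nm) ||
      !identical(wl, donor_ref$wavelength_nm))
    stop("all spectra must share one wavelength grid")
  if (min(wl) > 510 || max(wl) < 545)
    stop("grid must cover 510 and 545 nm")
  ratio_of <- function(alpha) {
    y <- background$intensity + alpha * donor_ref$intensity
    intensity_at(wl, y, 510) / intensity_at(wl, y, 545)
  }
  alphas <- seq(0, alpha_max, length.out = n_grid)
  curve <- vapply(alphas, ratio_of, numeric(1))
  dr <- diff(curve)
  if (!(all(dr > 0) || all(dr < 0)))
    stop("ratio standard curve is not monotone in the donor scale")
  obs <- intensity_at(wl, mixed$intensity, 510) /
    intensity_at(wl, mixed$intensity, 545)
  if (obs < min(curve) || obs > max(curve))
    stop("observed 510:545 ratio lies outside the standard curve; cannot interpolate")
  # bracket from the grid cell containing the observed ratio
  ix <- which(diff(sign(curve - obs)) != 0)
  if (length(ix) == 0) {
    hit <- which(curve == obs)[1]
    return(alphas[hit])
  }
  lo <- alphas[ix[1]]; hi <- alphas[ix[1] + 1]
  stats::uniroot(function(a) ratio_of(a) - obs, c(lo, hi),
                 tol = 1e-12)$root
}

#' Acceptor FRET spectrum by donor subtraction
#'
#' Subtracts a scaled donor-only spectrum from the spectrum of
#' co-expressing cells, leaving the sensitized acceptor (mCherry) emission.
#' The residual's peak inside 550-700 nm is checked against the expected
#' acceptor maximum at 609 nm; a residual peaking more than 5 nm away (or a
#' residual with no positive signal) is returned with `off_peak = TRUE` for
#' QC.  Optionally the residual is rescaled so its 550-700 nm maximum is 1.
#'
#' @param coexpressing,donor_only spectra (data frames `wavelength_nm`,
#'   `intensity`) on one grid containing 609 nm.
#' @param donor_scale scale applied to `donor_only` before subtraction.
#' @param normalize_amplitude rescale the residual peak to 1 (default
#'   `FALSE`; the flag-based QC is always performed).
#' @return Data frame `wavelength_nm`, `intensity` with attributes
#'   `off_peak` (logical) and `peak_nm`.
#' @export
acceptor_fret_spectrum <- function(coexpressing, donor_only,
                                   donor_scale = 1,
                                   normalize_amplitude = FALSE) {
  wl <- coexpressing$wavelength_nm
  if (!identical(wl, donor_only$wavelength_nm))
    stop("spectra must share one wavelength grid")
  if (min(wl) > 609 || max(wl) < 609) stop("grid must contain 609 nm")
  res <- coexpressing$intensity - donor_scale * donor_only$intensity
  if (max(res) < 0)
    stop("donor subtraction left an all-negative residual")
  win <- wl >= 550 & wl <= 700
  peak_nm <- NA_real_; off <- TRUE
  if (any(win) && max(res[win]) > 0) {
    peak_nm <- wl[win][which.max(res[win])]
    off <- abs(peak_nm - 609) > 5
  }
  if (normalize_amplitude && any(win) && max(res[win]) > 0)
    res <- res / max(res[win])
  out <- data.frame(wavelength_nm = wl, intensity = res)
  attr(out, "off_peak") <- off
  attr(out, "peak_nm") <- peak_nm
  out
}

#' Two-channel FRET ratios and acceptor-band areas
#'
#' Computes the two ratio metrics used for bulk-cell FRET comparisons, each
#' from trapezoid areas over the acceptor emission window (550-700 nm by
#' default, negatives floored at zero):
#' the *emission* ratio divides the sensitized acceptor area by the donor
#' component area, and the *excitation* ratio divides it by the total
#' acceptor area measured under direct acceptor excitation.
#'
#' @param acceptor_fret sensitized acceptor spectrum (e.g. from
#'   [acceptor_fret_spectrum()]).
#' @param donor_component donor emission component spectrum.
#' @param total_acceptor total acceptor spectrum under direct excitation.
#' @param window integration window, nm.
#' @return List of class `fret_result`: `emission_ratio`,
#'   `excitation_ratio`, `auc_acceptor_fret`, `auc_donor`,
#'   `auc_total_acceptor` (the 550-700 nm band areas).
#' @export
fret_ratios <- function(acceptor_fret, donor_component, total_acceptor,
                        window = c(550, 700)) {
  a <- auc_spectrum(acceptor_fret$wavelength_nm, acceptor_fret$intensity,
                    window[1], window[2])
  d <- auc_spectrum(donor_component$wavelength_nm,
                    donor_component$intensity, window[1], window[2])
  t <- auc_spectrum(total_acceptor$wavelength_nm,
                    total_acceptor$intensity, window[1], window[2])
  if (d <= 0) stop("donor component has zero area in the window")
  if (t <= 0) stop("total acceptor spectrum has zero area in the window")
  structure(list(emission_ratio = a / d,
                 excitation_ratio = a / t,
                 auc_acceptor_fret = a, auc_donor = d,
                 auc_total_acceptor = t),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("FRET ratios: emission %.4f, excitation %.4f\n",
              x$emission_ratio, x$excitation_ratio))
  cat(sprintf("  band areas (550-700 nm): acceptor-FRET %.4g, donor %.4g, total acceptor %.4g\n",
              x$auc_acceptor_fret, x$auc_donor, x$auc_total_acceptor))
  invisible(x)
}
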