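#' Optical constants for light-scattering analysis
#'
#' @param n0 solvent refractive index (default 1.331, aqueous buffer).
#' @param lambda_nm vacuum wavelength of the laser, nm (default 658).
#' @param dndc refractive index increment of the solute; numerically the
#'   conventional protein value 0.185 (so that concentration in g/L is
#'   `dRI / dndc`).
#' @return List of class `mals_optics`.
#' @export
mals_optics <- function(n0 = 1.331, lambda_nm = 658, dndc = 0.185) {
  if (dndc <= 0) stop("dndc must be positive")
  structure(list(n0 = n0, lambda_nm = lambda_nm, dndc = dndc),
            class = "mals_optics")
}

# Scattering contrast constant K* = 4 pi^2 n0^2 (dn/dc)^2 / (Na lambda^4),
# cgs units (lambda in cm, dn/dc in mL/g, c in g/mL, R in 1/cm) so that
# M [g/mol] = R(0) / (K* c).
kstar <- function(optics) {
  na <- 6.02214076e23
  lambda_cm <- optics$lambda_nm * 1e-7
  4 * pi^2 * optics$n0^2 * optics$dndc^2 / (na * lambda_cm^4)
}

#' Slice concentration from the differential refractive index
#'
#' Standard RI-based concentration detection: `c = dRI / dndc` in g/L.
#' Negative baseline noise passes through unchanged (flag downstream).
#'
#' @param dRI differential refractive index per slice (dimensionless).
#' @param dndc refractive index increment (default 0.185).
#' @return Concentration in g/L, linear in `dRI`.
#' @export
slice_concentration <- function(dRI, dndc = 0.185) {
  if (!is.finite(dndc) || dndc <= 0) stop("dndc must be positive")
  dRI / dndc
}

#' Molecular weight of one chromatogram slice by Zimm zero-angle analysis
#'
#' For each slice, the reduced scattering \eqn{R(\theta)/(K^* c)} is
#' regressed linearly on \eqn{\sin^2(\theta/2)} and extrapolated to zero
#' angle; the intercept is the molar mass (second virial coefficient taken
#' as zero, the dilute SEC regime).  For an isotropically small scatterer
#' the angular slope is ~0 and the estimate reduces to the mean of
#' \eqn{R/(K^* c)} over detectors.
#'
#' @param r_theta excess Rayleigh ratios, one per detector angle (1/cm).
#' @param angles_deg detector angles in degrees, strictly inside (0, 180);
#'   at least 3.
#' @param c_g_L slice concentration, g/L.
#' @param optics a [mals_optics()].
#' @param conc_floor_g_L minimum concentration for a defined MW; below it
#'   `NA` is returned.
#' @return Slice molecular weight in kDa (`NA` if below the concentration
#'   floor or if the zero-angle intercept is not positive, with a warning in
#'   the latter case).
#' @export
slice_mw <- function(r_theta, angles_deg, c_g_L, optics = mals_optics(),
                     conc_floor_g_L = 0) {
  if (length(r_theta) != length(angles_deg))
    stop("r_theta and angles_deg must have equal length")
  if (length(angles_deg) < 3) stop("at least 3 detector angles are required")
  if (any(angles_deg <= 0) || any(angles_deg >= 180))
    stop("angles must lie strictly between 0 and 180 degrees")
  if (!is.finite(c_g_L) || c_g_L <= conc_floor_g_L) return(NA_real_)
  c_g_ml <- c_g_L / 1000
  y <- r_theta / (kstar(optics) * c_g_ml)
  x <- sin(angles_deg * pi / 360)^2  # sin^2(theta/2)
  m0 <- unname(stats::coef(stats::lm(y ~ x))[1])
  if (!is.finite(m0) || m0 <= 0) {
    warning("negative zero-angle intercept; slice flagged (NA)")
    return(NA_real_)
  }
  m0 / 1000  # g/mol -> kDa
}

#' Per-slice molecular weight profile of a SEC-MALS chromatogram
#'
#' Applies [slice_concentration()] and [slice_mw()] across a chromatogram
#' and locates the dominant elution peak: the contiguous run of slices
#' around the concentration maximum that stay above
#' `conc_floor_frac` of the peak concentration (default 5 percent, which
#' suppresses noise-dominated peak wings).
#'
#' @param chrom list or data frame with `volume_mL`, `dRI`, and an
#'   `r_theta` matrix (slices x angles) plus `angles_deg`; the structure
#'   produced by [sim_mals()] or [read_mals_csv()].
#' @param optics a [mals_optics()]; defaults to `chrom$optics` when present.
#' @param conc_floor_frac concentration floor as a fraction of the peak
#'   maximum.
#' @return Object of class `mw_profile`: data frame with per-slice
#'   `volume_mL`, `conc_g_L`, `mw_kda`, plus attributes `peak_window`
#'   (volume range of the dominant peak) and `peak_mw_kda`
#'   (weight-average MW over that window).
#' @export
mals_mw_profile <- function(chrom, optics = NULL,
                            conc_floor_frac = 0.05) {
  if (is.null(optics)) optics <- chrom$optics
  if (is.null(optics)) optics <- mals_optics()
  conc <- slice_concentration(chrom$dRI, optics$dndc)
  floor_ <- conc_floor_frac * max(conc)
  mw <- vapply(seq_along(conc), function(i) {
    slice_mw(chrom$r_theta[i, ], chrom$angles_deg, conc[i], optics,
             conc_floor_g_L = floor_)
  }, numeric(1))
  prof <- data.frame(volume_mL = chrom$volume_mL, conc_g_L = conc,
                     mw_kda = mw)
  # dominant peak: contiguous above-floor run containing the apex
  apex <- which.max(conc)
  above <- conc > floor_
  lo <- apex; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- apex; while (hi < length(conc) && above[hi + 1]) hi <- hi + 1
  window <- c(chrom$volume_mL[lo], chrom$volume_mL[hi])
  attr(prof, "peak_window") <- window
  attr(prof, "peak_mw_kda") <- peak_average_mw(prof, window)
  class(prof) <- c("mw_profile", "data.frame")
  prof
}

#' Weight-average molecular weight over an elution window
#'
#' \eqn{\bar M_w = \sum_i c_i M_i / \sum_i c_i} over slices inside the
#' window that carry a defined per-slice MW.
#'
#' @param profile a `mw_profile` (or data frame with `volume_mL`,
#'   `conc_g_L`, `mw_kda`).
#' @param window length-2 numeric volume range, mL; defaults to the
#'   profile's dominant-peak window.
#' @return Weight-average MW in kDa.
#' @export
peak_average_mw <- function(profile, window = attr(profile, "peak_window")) {
  if (is.null(window) || length(window) != 2)
    stop("window must be a length-2 volume range")
  i <- profile$volume_mL >= window[1] & profile$volume_mL <= window[2] &
    is.finite(profile$mw_kda)
  if (sum(i) < 3) stop("fewer than 3 usable slices in the window")
  sum(profile$conc_g_L[i] * profile$mw_kda[i]) / sum(profile$conc_g_L[i])
}

#' @export
print.mw_profile <- function(x, ...) {
  w <- attr(x, "peak_window")
  cat(sprintf("SEC-MALS MW profile: %d slices; dominant peak %.2f-%.2f mL\n",
              nrow(x), w[1], w[2]))
  cat(sprintf("  weight-average MW over peak: %.3f kDa\n",
              attr(x, "peak_mw_kda")))
  invisible(x)
}
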