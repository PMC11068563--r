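# Seeded generators for every input modality the analyzers consume.
# Each generator draws from its own stream: a caller seed plus a fixed
# per-generator offset, applied in a local RNG scope, so adding or
# reordering generators never perturbs another generator's draws.

SEED_OFFSETS <- c(titration = 101L, melt = 211L, nmr = 307L, mals = 401L,
                  image = 503L, spectra = 601L, ca = 701L)

# evaluate expr with a locally set seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

gen_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + SEED_OFFSETS[[stream]]) %% .Machine$integer.max
}

mult_noise <- function(x, noise) {
  if (noise == 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, noise))
}

#' Simulate a binding titration
#'
#' Generates signal from the one-site ligand-depletion model
#' \eqn{S(L) = S_{free} + (S_{sat} - S_{free}) B(K_D, P, L)/P} with optional
#' multiplicative Gaussian noise (relative sigma `noise`).  Presets fix the
#' experimental conditions of the three supported modalities:
#' \describe{
#'   \item{fluorescein}{labeled protein 0.1 uM, decreasing fluorescence,
#'     12-point quasi-geometric grid from 0 to 2 uM.}
#'   \item{mst}{labeled protein 0.1 uM, signal on the F/F0 scale
#'     (1 -> 0.85), 16-point 2-fold dilution series from 100 uM.}
#'   \item{ans}{protein 5.204 uM (0.0625 mg/mL at 12.0098 kDa) as the
#'     depleted partner, increasing net ANS fluorescence, 12 points from 0
#'     to 50 uM.}
#' }
#' Any preset value can be overridden explicitly.
#'
#' @param preset `"fluorescein"`, `"mst"` or `"ans"`.
#' @param kd_uM true dissociation constant, uM.
#' @param labeled_conc_uM depleted-species concentration, uM (preset
#'   default).
#' @param titrant_uM titrant grid, uM (preset default).
#' @param s_free,s_sat endpoint signals (preset defaults).
#' @param noise relative multiplicative noise sigma (default 0.02).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return List with `titrant_uM`, `signal`, `labeled_conc_uM`, `modality`,
#'   `truth` (the generating parameters).
#' @export
sim_titration <- function(preset = c("fluorescein", "mst", "ans"),
                          kd_uM = NULL, labeled_conc_uM = NULL,
                          titrant_uM = NULL, s_free = NULL, s_sat = NULL,
                          noise = 0.02, seed = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    fluorescein = list(kd = 0.125, p = 0.1,
                       l = c(0, 0.025, 0.05, 0.1, 0.15, 0.25, 0.4, 0.6,
                             0.9, 1.2, 1.6, 2.0),
                       s_free = 100, s_sat = 35),
    mst = list(kd = 4.65, p = 0.1, l = 100 / 2^(15:0),
               s_free = 1, s_sat = 0.85),
    ans = list(kd = 1.5, p = 5.204, l = c(0, 1, 2, 3.5, 5, 7.5, 10, 15,
                                          20, 30, 40, 50),
               s_free = 0, s_sat = 400))
  kd <- if (is.null(kd_uM)) defaults$kd else kd_uM
  p <- if (is.null(labeled_conc_uM)) defaults$p else labeled_conc_uM
  l <- if (is.null(titrant_uM)) defaults$l else titrant_uM
  sf <- if (is.null(s_free)) defaults$s_free else s_free
  ss <- if (is.null(s_sat)) defaults$s_sat else s_sat
  mu <- sf + (ss - sf) * fraction_bound(kd, p, l) / p
  sig <- with_seed(gen_seed(seed, "titration"), mult_noise(mu, noise))
  list(titrant_uM = l, signal = sig, labeled_conc_uM = p, modality = preset,
       truth = list(kd_uM = kd, s_free = sf, s_sat = ss, noise = noise))
}

#' Simulate a thermal melt curve
#'
#' One or two Boltzmann transitions on a flat baseline over a 20-95 degC
#' scan at 1 degC pitch, normalized to `[0, 1]` when noiseless (additive
#' Gaussian noise of sigma `noise` x amplitude otherwise).
#'
#' @param tm_C transition midpoints (length 1 or 2), degC.
#' @param slope_C transition slopes, degC (recycled).
#' @param amplitude transition amplitudes (recycled; normalized to sum 1).
#' @param temperature_C scan grid (default `seq(20, 95, 1)`).
#' @param noise additive noise sigma relative to total amplitude.
#' @param seed integer seed.
#' @return List with `temperature_C`, `signal`, `truth`.
#' @export
sim_melt <- function(tm_C = 92, slope_C = 2, amplitude = 1,
                     temperature_C = seq(20, 95, by = 1),
                     noise = 0.02, seed = NULL) {
  k <- length(tm_C)
  slope_C <- rep_len(slope_C, k)
  amplitude <- rep_len(amplitude, k)
  amplitude <- amplitude / sum(amplitude)
  y <- rep(0, length(temperature_C))
  for (j in seq_len(k))
    y <- y + amplitude[j] / (1 + exp((tm_C[j] - temperature_C) / slope_C[j]))
  y <- with_seed(gen_seed(seed, "melt"), {
    if (noise > 0) y + stats::rnorm(length(y), 0, noise) else y
  })
  list(temperature_C = temperature_C, signal = y,
       truth = list(tm_C = tm_C, slope_C = slope_C, amplitude = amplitude,
                    noise = noise))
}

#' Simulate slow-exchange NMR peak-intensity series
#'
#' Free- and bound-state cross-peak intensities from the depletion-model
#' bound fraction at a fixed labeled-protein concentration, with per-peak
#' scales and multiplicative Gaussian noise.  The default titrant grid
#' `{0, 25, 50, 100, 150}` uM at 100 uM labeled protein mirrors a typical
#' HSQC titration of a tight complex.
#'
#' @param kd_uM true shared dissociation constant, uM.
#' @param labeled_conc_uM labeled protein concentration, uM.
#' @param titrant_uM titrant grid, uM.
#' @param n_peaks number of peaks per state.
#' @param states `"free"`, `"bound"` or both.
#' @param scales per-peak scales (I0 / Imax); default `1` for all.
#' @param noise relative multiplicative noise sigma (default 0.05).
#' @param seed integer seed.
#' @return Long data frame `peak_id`, `state`, `titrant_uM`, `intensity`.
#' @export
sim_nmr_series <- function(kd_uM = 0.18, labeled_conc_uM = 100,
                           titrant_uM = c(0, 25, 50, 100, 150),
                           n_peaks = 6, states = c("free", "bound"),
                           scales = NULL, noise = 0.05, seed = NULL) {
  states <- match.arg(states, several.ok = TRUE)
  fb <- fraction_bound(kd_uM, labeled_conc_uM, titrant_uM) / labeled_conc_uM
  if (is.null(scales)) scales <- rep(1, n_peaks)
  scales <- rep_len(scales, n_peaks)
  rows <- list()
  for (st in states) {
    x <- if (st == "free") 1 - fb else fb
    for (i in seq_len(n_peaks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = sprintf("%s_peak%02d", st, i), state = st,
        titrant_uM = titrant_uM, intensity = scales[i] * x)
    }
  }
  out <- do.call(rbind, rows)
  out$intensity <- with_seed(gen_seed(seed, "nmr"),
                             mult_noise(out$intensity, noise))
  rownames(out) <- NULL
  out
}

#' Simulate a SEC-MALS chromatogram
#'
#' Gaussian elution peak(s) with `dRI = dndc * c` and multi-angle excess
#' Rayleigh ratios `R(theta) = K* c M P(theta)`, where the particle form
#' factor uses the Guinier expansion
#' \eqn{P(\theta) = 1 - (16\pi^2 n_0^2 / 3\lambda^2) R_g^2
#' \sin^2(\theta/2)} (flat for `rg_nm = 0`).  Several components may
#' co-elute (vectorized `mw_kda`, `peak_center_mL`, ...).
#'
#' @param mw_kda true molecular weight(s), kDa.
#' @param peak_center_mL elution peak center(s), mL.
#' @param peak_sigma_mL elution peak width(s), mL.
#' @param cmax_g_L peak concentration(s), g/L.
#' @param rg_nm radius of gyration, nm (0 = isotropic scatterer).
#' @param volume_mL elution grid (default 10-15 mL at 0.01 mL).
#' @param angles_deg detector angles (default 8 of the usual 16-angle set).
#' @param optics a [mals_optics()].
#' @param noise relative multiplicative noise on dRI and R.
#' @param seed integer seed.
#' @return List (`mals_chromatogram`): `volume_mL`, `dRI`, `r_theta`
#'   (slices x angles), `angles_deg`, `optics`, `truth`.
#' @export
sim_mals <- function(mw_kda = 21.7, peak_center_mL = 12.5,
                     peak_sigma_mL = 0.3, cmax_g_L = 0.5, rg_nm = 0,
                     volume_mL = seq(10, 15, by = 0.01),
                     angles_deg = c(34.8, 50.1, 61.1, 80.1, 100.2, 121.2,
                                    132.2, 147.0),
                     optics = mals_optics(), noise = 0, seed = NULL) {
  k <- length(mw_kda)
  peak_center_mL <- rep_len(peak_center_mL, k)
  peak_sigma_mL <- rep_len(peak_sigma_mL, k)
  cmax_g_L <- rep_len(cmax_g_L, k)
  rg_nm <- rep_len(rg_nm, k)
  conc <- matrix(0, length(volume_mL), k)
  for (j in seq_len(k))
    conc[, j] <- cmax_g_L[j] *
      exp(-(volume_mL - peak_center_mL[j])^2 / (2 * peak_sigma_mL[j]^2))
  dri <- rowSums(conc) * optics$dndc
  ks <- kstar(optics)
  lambda_nm_in_solvent <- optics$lambda_nm / optics$n0
  s2 <- sin(angles_deg * pi / 360)^2
  r_theta <- matrix(0, length(volume_mL), length(angles_deg))
  for (j in seq_len(k)) {
    pfac <- 1 - (16 * pi^2 / (3 * (lambda_nm_in_solvent)^2)) *
      rg_nm[j]^2 * s2
    r_theta <- r_theta +
      outer(ks * (conc[, j] / 1000) * mw_kda[j] * 1000, pfac)
  }
  out <- with_seed(gen_seed(seed, "mals"), {
    list(dRI = mult_noise(dri, noise),
         r_theta = matrix(mult_noise(as.vector(r_theta), noise),
                          nrow = nrow(r_theta)))
  })
  structure(list(volume_mL = volume_mL, dRI = out$dRI,
                 r_theta = out$r_theta, angles_deg = angles_deg,
                 optics = optics,
                 truth = list(mw_kda = mw_kda, rg_nm = rg_nm,
                              cmax_g_L = cmax_g_L)),
            class = "mals_chromatogram")
}

#' Simulate a two-channel colocalization image pair
#'
#' Two-population pixel model: a bright "mitochondrial" population of
#' `n_red` red-positive pixels of which a designed fraction `overlap` also
#' carry green signal (plus optional extra green-only pixels), over an
#' independent dim noise background.  In `binary` mode intensities are 0/1
#' and Manders M1 with zero thresholds equals `overlap` exactly (a counting
#' identity); in `continuous` mode bright pixels get correlated lognormal
#' intensities and the background is dim uniform noise.
#'
#' @param overlap designed fraction of red-positive pixels that co-occur
#'   with green.
#' @param n_red number of red-positive pixels.
#' @param n_green_only extra green-only pixels.
#' @param dim dimensions of the image (rows, cols).
#' @param mode `"binary"` or `"continuous"`.
#' @param bg_level background intensity ceiling for continuous mode (dim
#'   independent uniform noise; 0 in binary mode).
#' @param seed integer seed.
#' @return List with matrices `red`, `green` and the design `truth`.
#' @export
sim_image_pair <- function(overlap = 0.83, n_red = 100, n_green_only = 20,
                           dim = c(64, 64), mode = c("binary", "continuous"),
                           bg_level = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  npix <- prod(dim)
  n_ov <- round(overlap * n_red)
  if (n_red + n_green_only > npix) stop("image too small for the design")
  with_seed(gen_seed(seed, "image"), {
    idx <- sample.int(npix, n_red + n_green_only)
    red_idx <- idx[seq_len(n_red)]
    green_idx <- c(red_idx[seq_len(n_ov)],
                   idx[n_red + seq_len(n_green_only)])
    red <- matrix(0, dim[1], dim[2]); green <- matrix(0, dim[1], dim[2])
    if (mode == "binary") {
      red[red_idx] <- 1
      green[green_idx] <- 1
    } else {
      red[] <- stats::runif(npix, 0, bg_level)
      green[] <- stats::runif(npix, 0, bg_level)
      base <- stats::rlnorm(n_red, 0, 0.25)
      red[red_idx] <- base
      green[red_idx[seq_len(n_ov)]] <-
        base[seq_len(n_ov)] * stats::rlnorm(n_ov, 0, 0.1)
      green[idx[n_red + seq_len(n_green_only)]] <-
        stats::rlnorm(n_green_only, 0, 0.25)
    }
    list(red = red, green = green,
         truth = list(overlap = n_ov / n_red, n_red = n_red,
                      n_green_only = n_green_only, mode = mode))
  })
}

gaussian_band <- function(wavelength_nm, center, width, amp) {
  amp * exp(-(wavelength_nm - center)^2 / (2 * width^2))
}

#' Simulate bulk-cell FRET emission spectra
#'
#' Gaussian emission bands on a 488-750 nm grid: a donor band at 510 nm, an
#' acceptor band at 609 nm and a broad cellular background band.  Returns
#' the spectrum set consumed by the FRET pipeline: background only, donor
#' reference, total-acceptor, and the coexpressing spectrum
#' `background + donor_scale * donor + acceptor`.
#'
#' @param donor_scale amount of donor reference present in the
#'   coexpressing spectrum.
#' @param donor_amp,acceptor_amp,bg_amp peak amplitudes of the three bands.
#' @param acceptor_center_nm acceptor band center (default 609).
#' @param wavelength_nm grid (default 488-750 nm at 1 nm).
#' @param noise relative multiplicative noise.
#' @param seed integer seed.
#' @return Named list of data frames (`wavelength_nm`, `intensity`):
#'   `background`, `donor`, `acceptor`, `coexpressing`, `total_acceptor`,
#'   plus `truth`.
#' @export
sim_spectra <- function(donor_scale = 1, donor_amp = 100,
                        acceptor_amp = 40, bg_amp = 20,
                        acceptor_center_nm = 609,
                        wavelength_nm = seq(488, 750, by = 1),
                        noise = 0, seed = NULL) {
  wl <- wavelength_nm
  bg <- gaussian_band(wl, 545, 60, bg_amp)
  donor <- gaussian_band(wl, 510, 15, donor_amp)
  acceptor <- gaussian_band(wl, acceptor_center_nm, 20, acceptor_amp)
  co <- bg + donor_scale * donor + acceptor
  total_acc <- gaussian_band(wl, acceptor_center_nm, 20, 1.6 * acceptor_amp)
  spectra <- with_seed(gen_seed(seed, "spectra"), {
    lapply(list(background = bg, donor = donor, acceptor = acceptor,
                coexpressing = co, total_acceptor = total_acc),
           function(y) data.frame(wavelength_nm = wl,
                                  intensity = mult_noise(y, noise)))
  })
  spectra$truth <- list(donor_scale = donor_scale, donor_amp = donor_amp,
                        acceptor_amp = acceptor_amp, bg_amp = bg_amp,
                        acceptor_center_nm = acceptor_center_nm)
  spectra
}

#' Simulate a GCaMP6f calcium uptake trace
#'
#' Flat baseline for `stim_time_s` seconds at `rate_hz` sampling, then a
#' sigmoidal rise to a plateau `amplitude` (in F/F_min units) with slow
#' exponential decay, plus Gaussian noise, emulating histamine-evoked
#' mitochondrial Ca2+ uptake recordings.
#'
#' @param amplitude designed response amplitude in F/F_min units.
#' @param baseline baseline fluorescence, a.u.
#' @param stim_time_s stimulus (perfusion) time, s (default 60).
#' @param duration_s total duration, s (default 300).
#' @param rate_hz sampling rate, points per second (default 5).
#' @param rise_s rise time constant of the sigmoid, s.
#' @param decay_s plateau decay time constant, s.
#' @param noise relative Gaussian noise sigma.
#' @param seed integer seed.
#' @return List with `time_s`, `fluorescence`, `stim_time_s`, `truth`.
#' @export
sim_ca_trace <- function(amplitude = 0.5, baseline = 100, stim_time_s = 60,
                         duration_s = 300, rate_hz = 5, rise_s = 3,
                         decay_s = 120, noise = 0.01, seed = NULL) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  dt <- pmax(t - stim_time_s, 0)
  shape <- (1 - exp(-dt / rise_s)) * exp(-dt / decay_s)
  shape[t < stim_time_s] <- 0
  # scale so the designed amplitude is the actual peak of the response
  resp <- if (max(shape) > 0) amplitude * shape / max(shape) else shape
  mu <- baseline * (1 + resp)
  f <- with_seed(gen_seed(seed, "ca"), mult_noise(mu, noise))
  list(time_s = t, fluorescence = f, stim_time_s = stim_time_s,
       truth = list(amplitude = amplitude, baseline = baseline,
                    noise = noise))
}
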