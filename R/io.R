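# CSV / TIFF / JSON boundary. All tables are UTF-8, header row, '.' decimal.
# Readers validate the column contract and name any missing column in the
# error, so batch callers never fail silently on a malformed export.

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stop("input file does not exist: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, cols, path)
  df
}

#' Read a titration table
#'
#' Expects columns `titrant_uM`, `signal` (one file per titration); the
#' labeled-species concentration and modality travel separately (sidecar or
#' function arguments).
#'
#' @param path CSV file path.
#' @return Data frame with the validated columns.
#' @export
read_titration_csv <- function(path) {
  read_checked_csv(path, c("titrant_uM", "signal"))
}

#' Write a binding-fit results table
#'
#' One row per fit: `Kd_uM`, `Kd_stderr`, `S_free`, `S_sat`, `n_points`,
#' `converged`, `identifiable`, `modality`.
#'
#' @param fits a `binding_fit` or list of them.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_binding_fit_csv <- function(fits, path) {
  if (inherits(fits, "binding_fit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(Kd_uM = f$kd, Kd_stderr = unname(f$stderr["kd"]),
               S_free = f$s_free, S_sat = f$s_sat, n_points = f$n,
               converged = f$converged, identifiable = f$identifiable,
               modality = f$modality)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read a thermal-melt table (`temp_C`, `ellipticity_mdeg`)
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_melt_csv <- function(path) {
  read_checked_csv(path, c("temp_C", "ellipticity_mdeg"))
}

#' Write a melt-fit results table (per-transition rows plus reported Tm)
#' @param fit a `melt_fit`.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_melt_fit_csv <- function(fit, path) {
  tab <- fit$transitions
  tab$reported_tm <- fit$reported_tm
  tab$converged <- fit$converged
  tab$boundary_flag <- fit$boundary_flag
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read NMR peak-intensity series (`peak_id`, `state`, `titrant_uM`,
#' `intensity`)
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_nmr_peaks_csv <- function(path) {
  read_checked_csv(path, c("peak_id", "state", "titrant_uM", "intensity"))
}

#' Read a chemical-shift table and compute CSPs
#'
#' Expects `residue`, `dH_ppm`, `dN_ppm`; appends the combined `csp` and
#' the mean + 1 SD `flagged` classification.
#'
#' @param path CSV file path.
#' @return Data frame with added `csp` and `flagged` columns.
#' @export
read_csp_csv <- function(path) {
  df <- read_checked_csv(path, c("residue", "dH_ppm", "dN_ppm"))
  df$csp <- csp_total(df$dH_ppm, df$dN_ppm)
  df$flagged <- classify_large_csp(df$csp)$flagged
  df
}

#' Read a SEC-MALS chromatogram
#'
#' Expects `volume_mL`, `dRI` and one light-scattering column per detector
#' angle, named `LS_<angle>` with the angle in degrees (e.g. `LS_34.8`).
#'
#' @param path CSV file path.
#' @param optics a [mals_optics()] attached to the result.
#' @return A `mals_chromatogram` list as produced by [sim_mals()].
#' @export
read_mals_csv <- function(path, optics = mals_optics()) {
  df <- read_checked_csv(path, c("volume_mL", "dRI"))
  ls_cols <- grep("^LS_", names(df), value = TRUE)
  if (length(ls_cols) < 3)
    stop(path, ": need at least 3 LS_<angle> detector columns", call. = FALSE)
  angles <- as.numeric(sub("^LS_", "", ls_cols))
  if (any(is.na(angles)))
    stop(path, ": LS column names must encode the angle in degrees",
         call. = FALSE)
  structure(list(volume_mL = df$volume_mL, dRI = df$dRI,
                 r_theta = as.matrix(df[ls_cols]), angles_deg = angles,
                 optics = optics),
            class = "mals_chromatogram")
}

#' Write a SEC-MALS chromatogram in the `LS_<angle>` CSV dialect
#' @param chrom a `mals_chromatogram`.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_mals_csv <- function(chrom, path) {
  tab <- data.frame(volume_mL = chrom$volume_mL, dRI = chrom$dRI)
  ls <- as.data.frame(chrom$r_theta)
  names(ls) <- paste0("LS_", chrom$angles_deg)
  tab <- cbind(tab, ls)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read a two-channel image pair from single-channel TIFF files
#'
#' @param red_path,green_path single-channel 8- or 16-bit grayscale TIFFs.
#' @return List with intensity matrices `red`, `green` (values as stored,
#'   scaled to `[0, 1]` by the TIFF reader).
#' @export
read_image_pair <- function(red_path, green_path) {
  red <- tiff::readTIFF(red_path)
  green <- tiff::readTIFF(green_path)
  if (length(dim(red)) > 2 || length(dim(green)) > 2)
    stop("expected single-channel grayscale TIFFs")
  check_image_pair(red, green)
  list(red = red, green = green)
}

#' Write a two-channel image pair as grayscale TIFF files
#'
#' Intensities are rescaled to `[0, 1]` by the joint maximum so relative
#' channel scaling is preserved.
#'
#' @param pair list with matrices `red`, `green`.
#' @param red_path,green_path output file paths.
#' @param bits_per_sample 8 or 16.
#' @return Invisibly, the scale factor applied.
#' @export
write_image_pair <- function(pair, red_path, green_path,
                             bits_per_sample = 16) {
  mx <- max(pair$red, pair$green, 1e-12)
  tiff::writeTIFF(pair$red / mx, red_path,
                  bits.per.sample = bits_per_sample)
  tiff::writeTIFF(pair$green / mx, green_path,
                  bits.per.sample = bits_per_sample)
  invisible(mx)
}

#' Read an emission spectrum (`wavelength_nm`, `intensity`)
#' @param path CSV file path.
#' @return Validated data frame (extra metadata columns pass through).
#' @export
read_spectrum_csv <- function(path) {
  df <- read_checked_csv(path, c("wavelength_nm", "intensity"))
  check_spectrum(df$wavelength_nm, df$intensity)
  df
}

#' Read a calcium trace (`time_s`, `fluorescence`)
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_ca_trace_csv <- function(path) {
  read_checked_csv(path, c("time_s", "fluorescence"))
}

#' Write a JSON run record
#'
#' Records what produced a result: input paths, parameters, seed and the
#' package version, so any output can be reproduced bit-identically.
#'
#' @param path output JSON path.
#' @param inputs character vector of input paths (may be empty).
#' @param parameters named list of analysis parameters.
#' @param seed integer seed used (or `NULL`).
#' @param overwrite allow overwriting an existing record (default `FALSE`;
#'   outputs never overwrite silently).
#' @return The record list, invisibly.
#' @export
write_run_record <- function(path, inputs = character(0),
                             parameters = list(), seed = NULL,
                             overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing run record: ", path,
         " (set overwrite = TRUE)", call. = FALSE)
  rec <- list(inputs = inputs, parameters = parameters, seed = seed,
              package = "mcubind",
              version = as.character(utils::packageVersion("mcubind")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(rec)
}
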