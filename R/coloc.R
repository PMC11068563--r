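#' Manders co-occurrence coefficients
#'
#' Intensity-weighted co-occurrence between two channels:
#' \deqn{M1 = \frac{\sum_i R_i [G_i > t_G]}{\sum_i R_i} \quad
#'       (\text{over pixels with } R_i > t_R),}
#' and symmetrically for M2 (green weighted by red co-occurrence).  M1 is
#' invariant to rescaling the red channel (with its threshold rescaled
#' identically), and for binary images equals the overlap fraction
#' \eqn{|R \cap G| / |R|}.
#'
#' @param red,green nonnegative intensity matrices of identical shape.
#' @param thr_red,thr_green channel thresholds (default 0; pixels must
#'   exceed them strictly to count as positive).
#' @param mask optional logical matrix restricting the analysis.
#' @return List of class `coloc_result`: `M1`, `M2` in `[0, 1]`, the
#'   thresholds, and `n_pixels_used`.
#' @examples
#' r <- matrix(0, 8, 8); r[1:4, ] <- 1
#' g <- matrix(0, 8, 8); g[3:6, ] <- 1
#' manders_coefficients(r, g)$M1  # 0.5
#' @export
manders_coefficients <- function(red, green, thr_red = 0, thr_green = 0,
                                 mask = NULL) {
  check_image_pair(red, green, mask)
  if (thr_red < 0 || thr_green < 0) stop("thresholds must be nonnegative")
  r <- as.vector(red); g <- as.vector(green)
  if (!is.null(mask)) { r <- r[mask]; g <- g[mask] }
  rpos <- r > thr_red; gpos <- g > thr_green
  if (!any(rpos)) stop("no pixels above threshold in the red channel")
  if (!any(gpos)) stop("no pixels above threshold in the green channel")
  m1 <- sum(r[rpos & gpos]) / sum(r[rpos])
  m2 <- sum(g[gpos & rpos]) / sum(g[gpos])
  structure(list(M1 = m1, M2 = m2, thr_red = thr_red, thr_green = thr_green,
                 n_pixels_used = length(r)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Manders coefficients: M1 = %.4f, M2 = %.4f\n", x$M1, x$M2))
  cat(sprintf("  thresholds: red > %g, green > %g; %d pixels\n",
              x$thr_red, x$thr_green, x$n_pixels_used))
  invisible(x)
}

check_image_pair <- function(red, green, mask = NULL) {
  if (!is.matrix(red) || !is.matrix(green))
    stop("red and green must be matrices")
  if (!identical(dim(red), dim(green)))
    stop("red and green must have identical dimensions")
  if (any(!is.finite(red)) || any(!is.finite(green)))
    stop("intensities must be finite")
  if (any(red < 0) || any(green < 0)) stop("intensities must be nonnegative")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(red)))
      stop("mask must be a logical matrix matching the image dimensions")
  }
  invisible(TRUE)
}

#' Costes automatic colocalization threshold
#'
#' Implements the standard Costes (2004) procedure: an orthogonal
#' (principal-axis) regression \eqn{G = a + bR} defines a one-parameter
#' family of threshold pairs \eqn{(T, a + bT)}.  Candidate thresholds are
#' scanned downward from the red maximum; for each, the Pearson correlation
#' (population formula) of the pixels *below* both thresholds is computed,
#' and the largest \eqn{T} whose below-threshold population shows
#' correlation \eqn{\le 0} is accepted (a correlation of exactly zero
#' accepts).  Candidate sets with fewer than two pixels or zero variance in
#' either channel are skipped; if no candidate qualifies the minimum red
#' intensity is returned, excluding no pixel.
#'
#' Every distinct red intensity is used as a candidate when there are at
#' most 4096 distinct values; otherwise 256 quantization bins are used.
#'
#' @param red,green nonnegative intensity matrices of identical shape;
#'   neither constant, and positively correlated overall.
#' @param equal if `TRUE`, a single threshold is applied to both channels
#'   (the below-population is `R < T & G < T` and both returned thresholds
#'   equal `T`), mirroring analyses run with equivalent threshold values
#'   for both fluorophores.
#' @param mask optional logical matrix.
#' @return List with `thr_red`, `thr_green`, `regression` (`a`, `b`), and
#'   `correlation_below` at the accepted threshold.
#' @export
costes_threshold <- function(red, green, equal = FALSE, mask = NULL) {
  check_image_pair(red, green, mask)
  r <- as.vector(red); g <- as.vector(green)
  if (!is.null(mask)) { r <- r[mask]; g <- g[mask] }
  if (stats::var(r) == 0 || stats::var(g) == 0)
    stop("channels must be non-constant")
  if (pearson_pop(r, g) <= 0)
    stop("overall channel correlation is not positive; Costes threshold undefined")

  # orthogonal (major-axis) regression G = a + b R
  sxx <- stats::var(r); syy <- stats::var(g); sxy <- stats::cov(r, g)
  b <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  if (!is.finite(b)) stop("degenerate orthogonal regression")
  a <- mean(g) - b * mean(r)

  cand <- sort(unique(r), decreasing = TRUE)
  if (length(cand) > 4096) {
    cand <- sort(unique(stats::quantile(r, probs = seq(0, 1, length.out = 256),
                                        names = FALSE)), decreasing = TRUE)
  }
  accepted <- NA_real_; rho_acc <- NA_real_
  for (t in cand) {
    tg <- if (equal) t else a + b * t
    below <- r < t & g < tg
    if (sum(below) < 2) next
    rb <- r[below]; gb <- g[below]
    if (stats::var(rb) == 0 || stats::var(gb) == 0) next
    rho <- pearson_pop(rb, gb)
    if (rho <= 0) { accepted <- t; rho_acc <- rho; break }
  }
  if (is.na(accepted)) { accepted <- min(r); rho_acc <- NA_real_ }
  thr_g <- if (equal) accepted else a + b * accepted
  list(thr_red = accepted, thr_green = thr_g,
       regression = c(a = a, b = b),
       correlation_below = rho_acc)
}

# population-formula Pearson correlation (n denominator)
pearson_pop <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(sum((x - mx)^2) / n); sy <- sqrt(sum((y - my)^2) / n)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - mx) * (y - my)) / (n * sx * sy)
}

#' Optional image preprocessing pipeline
#'
#' Parameterized stand-in for a typical microscopy preprocessing chain
#' ahead of colocalization: grey top-hat style background subtraction
#' (local-minimum rolling window), percentile-clip contrast normalization
#' and 3x3 mean smoothing.  Every step is optional; the returned image
#' carries the applied steps as the `"preprocessing"` attribute so results
#' stay traceable to their provenance.
#'
#' @param img nonnegative intensity matrix.
#' @param background_radius window half-width (pixels) for the running
#'   background estimate; `NULL` skips background subtraction.
#' @param saturate_pct percent of pixels saturated at each end during
#'   contrast normalization; `NULL` skips normalization.
#' @param smooth logical; apply one pass of 3x3 mean smoothing.
#' @return Preprocessed matrix with attribute `"preprocessing"`.
#' @export
preprocess_channel <- function(img, background_radius = NULL,
                               saturate_pct = 0.35, smooth = TRUE) {
  check_image_pair(img, img)
  steps <- character(0)
  if (!is.null(background_radius)) {
    bg <- erode_min(img, background_radius)
    img <- pmax(img - bg, 0)
    steps <- c(steps, sprintf("background(min-window r=%d)", background_radius))
  }
  if (!is.null(saturate_pct)) {
    qs <- stats::quantile(img, c(saturate_pct / 100, 1 - saturate_pct / 100),
                          names = FALSE)
    if (qs[2] > qs[1]) {
      img <- pmin(pmax(img, qs[1]), qs[2])
      img <- (img - qs[1]) / (qs[2] - qs[1])
      steps <- c(steps, sprintf("normalize(saturate %.2f%%)", saturate_pct))
    }
  }
  if (isTRUE(smooth)) {
    img <- mean_filter3(img)
    steps <- c(steps, "smooth(3x3 mean)")
  }
  attr(img, "preprocessing") <- steps
  img
}

# running-minimum erosion over a (2r+1)^2 window (separable)
erode_min <- function(img, r) {
  f1 <- function(m) {
    out <- m
    for (k in seq_len(r)) {
      up <- rbind(m[-seq_len(k), , drop = FALSE],
                  m[rep(nrow(m), k), , drop = FALSE])
      dn <- rbind(m[rep(1, k), , drop = FALSE],
                  m[seq_len(nrow(m) - k), , drop = FALSE])
      out <- pmin(out, up, dn)
    }
    out
  }
  t(f1(t(f1(img))))
}

mean_filter3 <- function(img) {
  pad <- function(m) rbind(m[1, ], m, m[nrow(m), ])
  m <- pad(t(pad(t(img))))
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + m[di + seq_len(nr), dj + seq_len(nc)]
  acc / 9
}
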