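#' Mean residue ellipticity from raw CD ellipticity
#'
#' Converts a circular-dichroism signal in millidegrees to mean residue
#' ellipticity (deg cm^2 dmol^-1):
#' \deqn{MRE = \theta_{mdeg} / (10 \cdot path_{cm} \cdot c_{M} \cdot n_{res}),}
#' i.e. the molar ellipticity per peptide unit.  `n_residues` is the residue
#' count by default; pass `n_residues - 1` to normalize per peptide bond.
#'
#' @param theta_mdeg ellipticity in millidegrees (vectorized).
#' @param path_cm cuvette path length, cm; positive.
#' @param conc_molar protein molar concentration, M; positive.
#' @param n_residues residues per chain; positive.
#' @return MRE in deg cm^2 dmol^-1, linear in `theta_mdeg`.
#' @examples
#' mre_from_ellipticity(-20, 0.1, 41.6e-6, 107)  # ~ -4.49e3
#' @export
mre_from_ellipticity <- function(theta_mdeg, path_cm, conc_molar, n_residues) {
  if (!is.finite(path_cm) || path_cm <= 0) stop("path_cm must be positive")
  if (!is.finite(conc_molar) || conc_molar <= 0)
    stop("conc_molar must be positive")
  if (!is.finite(n_residues) || n_residues <= 0)
    stop("n_residues must be positive")
  theta_mdeg / (10 * path_cm * conc_molar * n_residues)
}

#' Normalize a melt curve to the unit interval
#'
#' Affine map of the signal so its minimum is 0 and maximum is 1; ordering
#' (and hence any transition shape) is preserved, and the result is invariant
#' to affine transformations of the input.
#'
#' @param temperature_C temperatures, strictly increasing.
#' @param signal ellipticity or any melt signal; must not be constant.
#' @return Data frame with columns `temperature_C`, `signal` (in `[0, 1]`).
#' @export
normalize_melt <- function(temperature_C, signal) {
  check_melt_xy(temperature_C, signal, min_points = 2L)
  r <- range(signal)
  if (diff(r) == 0) stop("cannot normalize a constant signal")
  data.frame(temperature_C = temperature_C,
             signal = (signal - r[1]) / diff(r))
}

check_melt_xy <- function(temperature_C, signal, min_points = 20L) {
  if (length(temperature_C) != length(signal))
    stop("temperature_C and signal must have equal length")
  if (length(temperature_C) < min_points)
    stop(sprintf("at least %d points are required", min_points))
  if (any(!is.finite(temperature_C)) || any(!is.finite(signal)))
    stop("inputs must be finite")
  if (any(diff(temperature_C) <= 0))
    stop("temperature_C must be strictly increasing")
  invisible(TRUE)
}

#' Fit a thermal melt with a multi-transition Boltzmann sigmoid
#'
#' Models the denaturation signal as a sum of Boltzmann sigmoids on a
#' baseline:
#' \deqn{y(T) = b_0 [+ b_1 T] + \sum_k a_k / (1 + e^{(T_{m,k} - T)/s_k}),}
#' with per-transition midpoint \eqn{T_m}, slope \eqn{s} (degC) and amplitude
#' \eqn{a_k \ge 0}.  Pre- and post-transition baselines are constant by
#' default (the data are typically normalized to `[0, 1]` first); sloping
#' baselines add the global linear term \eqn{b_1 T}.  A melt whose signal
#' decreases overall is flipped internally so amplitudes stay nonnegative.
#'
#' Transitions are reported in ascending \eqn{T_m}; the headline
#' `reported_tm` is the midpoint of the transition with the largest amplitude
#' (the one carrying the maximum normalized change in signal).  A midpoint
#' within 2 degC of either end of the scanned range is flagged unreliable.
#'
#' @param temperature_C temperatures, strictly increasing, at least 20
#'   points.
#' @param signal melt signal (raw mdeg or normalized).
#' @param n_transitions 1 or 2.
#' @param baseline `"constant"` (default) or `"sloping"`.
#' @param maxiter,ftol optimizer controls as in [fit_one_site()].
#' @return An object of class `melt_fit`: list with `transitions` (data frame
#'   `tm_C`, `slope_C`, `amplitude`, `amplitude_fraction`, sorted by
#'   `tm_C`), `reported_tm`, `n_transitions`, `baseline` coefficients,
#'   `converged`, `boundary_flag`, `residual_norm`, `data`, `fitted`,
#'   `flipped`.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `fitted`, `plot`.
#' @examples
#' m <- sim_melt(tm_C = 92, slope_C = 2, noise = 0)
#' fit <- fit_boltzmann_melt(m$temperature_C, m$signal, n_transitions = 1)
#' fit$reported_tm
#' @export
fit_boltzmann_melt <- function(temperature_C, signal, n_transitions = 2,
                               baseline = c("constant", "sloping"),
                               maxiter = 1024, ftol = 1e-10) {
  baseline <- match.arg(baseline)
  if (!n_transitions %in% c(1, 2)) stop("n_transitions must be 1 or 2")
  check_melt_xy(temperature_C, signal)
  tt <- temperature_C; y <- signal
  if (diff(range(y)) == 0) stop("flat melt curve: nothing to fit")

  flipped <- y[length(y)] < y[1]
  if (flipped) y <- -y
  k <- n_transitions

  # initialization: level crossings of the smoothed, normalized signal
  yn <- (y - min(y)) / diff(range(y))
  ys <- stats::filter(yn, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- yn[is.na(ys)]
  tm0 <- vapply(seq_len(k), function(j) {
    lev <- (j - 0.5) / k
    i <- which(ys >= lev)[1]
    if (is.na(i)) stats::quantile(tt, lev) else tt[max(i, 2)]
  }, numeric(1))
  tm0 <- sort(tm0)
  if (k == 2 && diff(tm0) < 2) tm0 <- tm0 + c(-2, 2)
  amp0 <- rep(diff(range(y)) / k, k)
  par <- c(b0 = min(y),
           if (baseline == "sloping") c(b1 = 0),
           stats::setNames(amp0, paste0("a", seq_len(k))),
           stats::setNames(tm0, paste0("tm", seq_len(k))),
           stats::setNames(rep(2, k), paste0("s", seq_len(k))))

  model_fn <- function(par, tvec) {
    out <- par[["b0"]]
    if (baseline == "sloping") out <- out + par[["b1"]] * tvec
    for (j in seq_len(k)) {
      out <- out + par[[paste0("a", j)]] /
        (1 + exp((par[[paste0("tm", j)]] - tvec) / par[[paste0("s", j)]]))
    }
    out
  }
  lower <- rep(-Inf, length(par)); upper <- rep(Inf, length(par))
  names(lower) <- names(upper) <- names(par)
  lower[paste0("a", seq_len(k))] <- 0
  lower[paste0("s", seq_len(k))] <- 1e-3
  lower[paste0("tm", seq_len(k))] <- min(tt)
  upper[paste0("tm", seq_len(k))] <- max(tt)

  fit <- minpack.lm::nls.lm(
    par = par, fn = function(p) y - model_fn(p, tt),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         ptol = 1e-12))
  p <- fit$par
  a <- vapply(seq_len(k), function(j) p[[paste0("a", j)]], numeric(1))
  tm <- vapply(seq_len(k), function(j) p[[paste0("tm", j)]], numeric(1))
  s <- vapply(seq_len(k), function(j) p[[paste0("s", j)]], numeric(1))
  ord <- order(tm)
  a <- a[ord]; tm <- tm[ord]; s <- s[ord]
  afrac <- if (sum(a) > 0) a / sum(a) else rep(NA_real_, k)
  transitions <- data.frame(tm_C = tm, slope_C = s, amplitude = a,
                            amplitude_fraction = afrac)
  reported <- tm[which.max(a)]
  boundary <- reported <= min(tt) + 2 || reported >= max(tt) - 2
  fitted_y <- model_fn(p, tt)
  if (flipped) fitted_y <- -fitted_y

  structure(list(transitions = transitions,
                 reported_tm = reported,
                 n_transitions = k,
                 baseline = c(b0 = unname(if (flipped) -p[["b0"]] else p[["b0"]]),
                              b1 = if (baseline == "sloping")
                                unname(if (flipped) -p[["b1"]] else p[["b1"]])
                              else 0),
                 baseline_mode = baseline,
                 converged = fit$info %in% 1:4,
                 boundary_flag = boundary,
                 residual_norm = sqrt(sum((signal - fitted_y)^2)),
                 data = data.frame(temperature_C = tt, signal = signal),
                 fitted = fitted_y,
                 flipped = flipped),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Boltzmann melt fit: %d transition(s), baseline %s%s\n",
              x$n_transitions, x$baseline_mode,
              if (x$flipped) " (signal decreasing, fit on flipped scale)" else ""))
  print(format(x$transitions, digits = digits), row.names = FALSE)
  cat(sprintf("Reported Tm (max-amplitude transition): %s degC%s\n",
              format(x$reported_tm, digits = digits),
              if (x$boundary_flag) "  [at scan boundary - unreliable]" else ""))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.melt_fit <- function(object, ...) {
  object  # printed representation already carries the full fit
}

#' @export
coef.melt_fit <- function(object, ...) {
  k <- object$n_transitions
  out <- object$baseline["b0"]
  if (object$baseline_mode == "sloping") out <- c(out, object$baseline["b1"])
  for (j in seq_len(k)) {
    out <- c(out,
             stats::setNames(object$transitions$amplitude[j], paste0("a", j)),
             stats::setNames(object$transitions$tm_C[j], paste0("tm", j)),
             stats::setNames(object$transitions$slope_C[j], paste0("s", j)))
  }
  out
}

#' @export
fitted.melt_fit <- function(object, ...) object$fitted

#' @export
residuals.melt_fit <- function(object, ...) object$data$signal - object$fitted

#' @export
predict.melt_fit <- function(object, temperature_C = NULL, ...) {
  if (is.null(temperature_C)) return(object$fitted)
  sgn <- if (object$flipped) -1 else 1
  out <- rep(object$baseline[["b0"]], length(temperature_C)) +
    object$baseline[["b1"]] * temperature_C
  for (j in seq_len(object$n_transitions)) {
    term <- object$transitions$amplitude[j] /
      (1 + exp((object$transitions$tm_C[j] - temperature_C) /
                 object$transitions$slope_C[j]))
    out <- out + sgn * term
  }
  out
}

#' @export
plot.melt_fit <- function(x, ..., xlab = "temperature (degC)",
                          ylab = "signal") {
  graphics::plot(x$data$temperature_C, x$data$signal, pch = 16, cex = 0.6,
                 xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$data$temperature_C, x$fitted, col = 2)
  graphics::abline(v = x$reported_tm, lty = 2, col = "grey40")
  invisible(x)
}
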