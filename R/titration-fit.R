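#' Fit a titration to the one-site ligand-depletion binding model
#'
#' Least-squares fit of the signal model
#' \deqn{S(L) = S_{free} + (S_{sat} - S_{free}) \, B(K_D, P, L) / P,}
#' where \eqn{B} is the exact (quadratic) bound-complex concentration of
#' [fraction_bound()] and \eqn{P} is the fixed concentration of the labeled
#' (depleted) species.  Works for increasing or decreasing signal; the MST
#' modality fits already-ratioed F/F0 values on the same model.
#'
#' Initialization follows the monotone-curve heuristic: \eqn{S_{free}} from
#' the first point, \eqn{S_{sat}} from the last, and \eqn{K_D} from the
#' titrant concentration at half the signal change.  Optimization is
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) with \eqn{K_D \ge 0}, a sum-of-
#' squares tolerance of 1e-10 and at most 2000 iterations; non-convergence is
#' reported, never silently ignored.
#'
#' If the fitted amplitude \eqn{|S_{sat} - S_{free}|} falls below
#' `noise_floor` (default: 3 times the residual standard deviation, or any
#' exactly constant signal) the curve carries no binding information: the fit
#' is flagged non-identifiable and no \eqn{K_D} is reported.
#'
#' @param titrant_uM titrant concentrations, uM; nonnegative, at least 5
#'   points. Sorted internally together with `signal`.
#' @param signal observed signal (fluorescence a.u., or F/F0 for MST).
#' @param labeled_conc_uM concentration of the labeled/depleted species, uM;
#'   positive.
#' @param modality one of `"fluorescein"`, `"mst"`, `"ans"`; metadata only.
#' @param noise_floor minimum identifiable amplitude on the signal scale;
#'   `NULL` for the residual-based default.
#' @param maxiter,ftol Levenberg-Marquardt iteration cap and sum-of-squares
#'   tolerance.
#' @return An object of class `binding_fit`: a list with elements `kd`
#'   (uM, `NA` when non-identifiable), `s_free`, `s_sat`, `stderr` (named,
#'   from the asymptotic covariance), `vcov`, `residual_norm`, `converged`,
#'   `identifiable`, `n`, `labeled_conc_uM`, `modality`, `data`, `fitted`.
#'   Methods: `print`, `summary`, `coef`, `vcov`, `predict`, `residuals`,
#'   `fitted`, `plot`, `simulate`.
#' @examples
#' curve <- sim_titration(preset = "fluorescein", kd_uM = 0.125, noise = 0)
#' fit <- fit_one_site(curve$titrant_uM, curve$signal, curve$labeled_conc_uM)
#' coef(fit)["kd"]  # recovers 0.125
#' @export
fit_one_site <- function(titrant_uM, signal, labeled_conc_uM,
                         modality = c("fluorescein", "mst", "ans"),
                         noise_floor = NULL, maxiter = 1024, ftol = 1e-10) {
  modality <- match.arg(modality)
  if (length(titrant_uM) != length(signal))
    stop("titrant_uM and signal must have equal length")
  if (length(titrant_uM) < 5) stop("at least 5 titration points are required")
  if (any(!is.finite(titrant_uM)) || any(titrant_uM < 0))
    stop("titrant_uM must be finite and nonnegative")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (!is.finite(labeled_conc_uM) || labeled_conc_uM <= 0)
    stop("labeled_conc_uM must be positive")

  ord <- order(titrant_uM)
  l <- titrant_uM[ord]; y <- signal[ord]
  p <- labeled_conc_uM
  n <- length(l)

  out <- list(labeled_conc_uM = p, modality = modality, n = n,
              data = data.frame(titrant_uM = l, signal = y),
              model = "one-site ligand depletion")
  class(out) <- "binding_fit"

  if (diff(range(y)) == 0) {
    out$kd <- NA_real_; out$s_free <- y[1]; out$s_sat <- y[1]
    out$stderr <- c(kd = NA_real_, s_free = NA_real_, s_sat = NA_real_)
    out$vcov <- NULL
    out$residual_norm <- 0; out$converged <- TRUE; out$identifiable <- FALSE
    out$fitted <- y
    return(out)
  }

  s_free0 <- y[1]; s_sat0 <- y[n]
  half <- (s_free0 + s_sat0) / 2
  kd0 <- stats::approx(y, l, xout = half, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- max(stats::median(l[l > 0]), 1e-6)

  resid_fn <- function(par) {
    fb <- fraction_bound(par[["kd"]], p, l) / p
    y - (par[["s_free"]] + (par[["s_sat"]] - par[["s_free"]]) * fb)
  }
  fit <- minpack.lm::nls.lm(
    par = c(kd = kd0, s_free = s_free0, s_sat = s_sat0),
    fn = resid_fn,
    lower = c(0, -Inf, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         ptol = 1e-12))
  par <- fit$par
  res <- resid_fn(par)
  dof <- n - 3L
  sigma2 <- if (dof > 0) sum(res^2) / dof else NA_real_
  vc <- tryCatch(sigma2 * solve(fit$hessian / 2), error = function(e) NULL)
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else
    rep(NA_real_, 3)
  names(se) <- names(par)

  amp <- abs(par[["s_sat"]] - par[["s_free"]])
  floor_ <- if (is.null(noise_floor)) {
    rsd <- if (dof > 0) sqrt(sigma2) else 0
    3 * rsd
  } else noise_floor
  identifiable <- amp > floor_

  out$kd <- if (identifiable) unname(par[["kd"]]) else NA_real_
  out$s_free <- unname(par[["s_free"]]); out$s_sat <- unname(par[["s_sat"]])
  out$stderr <- se
  out$vcov <- vc
  out$residual_norm <- sqrt(sum(res^2))
  out$converged <- fit$info %in% 1:4
  out$identifiable <- identifiable
  out$fitted <- y - res
  out
}

#' Fit an ANS-binding titration
#'
#' ANS (8-anilinonaphthalene-1-sulfonate) fluoresces on binding exposed
#' hydrophobic surface; titrating ANS into a fixed protein concentration
#' gives an increasing isotherm in which the *protein* is the depleted
#' partner.  This is [fit_one_site()] with the roles assigned accordingly:
#' P = protein sites (one per monomer), L = ANS.
#'
#' @param ans_uM ANS concentrations, uM.
#' @param net_signal background-subtracted net fluorescence intensities.
#' @param protein_conc_uM protein monomer concentration, uM; positive.
#' @param ... passed to [fit_one_site()].
#' @return A `binding_fit` (see [fit_one_site()]).
#' @export
fit_ans_titration <- function(ans_uM, net_signal, protein_conc_uM, ...) {
  fit_one_site(ans_uM, net_signal, labeled_conc_uM = protein_conc_uM,
               modality = "ans", ...)
}

#' Expected fluorescence decrease on diluting a protein-ligand mixture
#'
#' When a bound-ligand-proportional signal is diluted `factor`-fold together
#' with its protein (constant molar ratio), the expected fractional intensity
#' decrease at each step is
#' \deqn{D = 1 - B(K_D, P/f, L/f) / B(K_D, P, L),}
#' with \eqn{B} the depletion-model complex concentration.  In the
#' stoichiometric limit (\eqn{K_D \to 0}, ligand limiting) \eqn{D = 1 - 1/f};
#' in the weak-binding limit (\eqn{K_D \to \infty}) \eqn{B \propto PL} so
#' \eqn{D = 1 - 1/f^2}.  For a 2-fold dilution any finite \eqn{K_D > 0} with
#' ligand sub-stoichiometric therefore gives a decrease strictly between 50
#' and 75 percent.
#'
#' @param p_uM starting protein concentration, uM.
#' @param l_uM starting ligand concentration, uM.
#' @param kd_uM dissociation constant, uM.
#' @param factor dilution factor per step; must exceed 1.
#' @param n_steps number of successive dilutions; returns one decrease per
#'   step, each relative to the preceding state.
#' @return Numeric vector of length `n_steps`, fractional decreases in (0,1).
#' @examples
#' # 50 uM ANS + 0.5 mg/mL MCUb-NTD (41.63 uM), Kd 1.5 uM, three 2x dilutions
#' expected_dilution_decrease(41.63, 50, 1.5, factor = 2, n_steps = 3)
#' @export
expected_dilution_decrease <- function(p_uM, l_uM, kd_uM, factor = 2,
                                       n_steps = 1) {
  if (!is.finite(factor) || factor <= 1) stop("factor must exceed 1")
  stopifnot(n_steps >= 1)
  b_prev <- fraction_bound(kd_uM, p_uM, l_uM)
  if (b_prev <= 0) stop("no binding at the starting concentrations")
  d <- numeric(n_steps)
  p <- p_uM; l <- l_uM
  for (k in seq_len(n_steps)) {
    p <- p / factor; l <- l / factor
    b <- fraction_bound(kd_uM, p, l)
    d[k] <- 1 - b / b_prev
    b_prev <- b
  }
  d
}

# ---- binding_fit methods ----------------------------------------------------

#' @export
print.binding_fit <- function(x, digits = 4, ...) {
  cat(sprintf("One-site depletion binding fit (%s), %d points\n",
              x$modality, x$n))
  if (!x$identifiable) {
    cat("  non-identifiable: signal amplitude below noise floor; no Kd reported\n")
  } else {
    cat(sprintf("  Kd      %s uM (se %s)\n",
                format(x$kd, digits = digits),
                format(x$stderr[["kd"]], digits = 3)))
    cat(sprintf("  S_free  %s   S_sat  %s\n",
                format(x$s_free, digits = digits),
                format(x$s_sat, digits = digits)))
  }
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.binding_fit <- function(object, ...) {
  est <- c(kd = object$kd, s_free = object$s_free, s_sat = object$s_sat)
  tab <- cbind(Estimate = est, `Std. Error` = object$stderr[names(est)])
  structure(list(coefficients = tab,
                 labeled_conc_uM = object$labeled_conc_uM,
                 modality = object$modality,
                 residual_norm = object$residual_norm,
                 converged = object$converged,
                 identifiable = object$identifiable,
                 n = object$n),
            class = "summary.binding_fit")
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  cat(sprintf("One-site depletion binding fit (%s)\n", x$modality))
  cat(sprintf("Labeled species: %g uM; n = %d; residual norm %.4g\n",
              x$labeled_conc_uM, x$n, x$residual_norm))
  stats::printCoefmat(x$coefficients, na.print = "NA")
  if (!x$identifiable) cat("Flagged non-identifiable (flat signal).\n")
  if (!x$converged) cat("Optimizer did not converge.\n")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, s_free = object$s_free, s_sat = object$s_sat)
}

#' @export
vcov.binding_fit <- function(object, ...) object$vcov

#' @export
fitted.binding_fit <- function(object, ...) object$fitted

#' @export
residuals.binding_fit <- function(object, ...) {
  object$data$signal - object$fitted
}

#' Predicted signal from a binding fit
#'
#' @param object a `binding_fit`.
#' @param titrant_uM concentrations at which to evaluate the fitted model;
#'   defaults to the data grid.
#' @param ... unused.
#' @export
predict.binding_fit <- function(object, titrant_uM = NULL, ...) {
  if (is.null(titrant_uM)) titrant_uM <- object$data$titrant_uM
  kd <- if (is.na(object$kd)) 0 else object$kd
  fb <- fraction_bound(kd, object$labeled_conc_uM, titrant_uM) /
    object$labeled_conc_uM
  object$s_free + (object$s_sat - object$s_free) * fb
}

#' @export
plot.binding_fit <- function(x, ...,
                             xlab = "titrant (uM)", ylab = "signal") {
  graphics::plot(x$data$titrant_uM, x$data$signal, pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  grid_l <- seq(min(x$data$titrant_uM), max(x$data$titrant_uM),
                length.out = 200)
  graphics::lines(grid_l, predict(x, grid_l), col = 2)
  invisible(x)
}

#' Simulate new titrations from a fitted binding model
#'
#' @param object a `binding_fit`.
#' @param nsim number of simulated curves.
#' @param seed integer seed.
#' @param noise relative multiplicative noise (default 2 percent).
#' @param ... unused.
#' @return A list of data frames with columns `titrant_uM`, `signal`.
#' @export
simulate.binding_fit <- function(object, nsim = 1, seed = NULL,
                                 noise = 0.02, ...) {
  mu <- predict(object)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      data.frame(titrant_uM = object$data$titrant_uM,
                 signal = mu * (1 + stats::rnorm(length(mu), 0, noise)))
    })
  })
}
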