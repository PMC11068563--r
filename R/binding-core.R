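#' Bound-complex concentration under ligand depletion (Morrison model)
#'
#' Solves the 1:1 mass-action equilibrium exactly, without assuming free
#' ligand equals total ligand.  For total receptor \eqn{P}, total ligand
#' \eqn{L} and dissociation constant \eqn{K_D}, the complex concentration is
#' the smaller root of \eqn{B^2 - (P + L + K_D)B + PL = 0},
#' \deqn{B = \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4PL}}{2}.}
#' This is the regime relevant for tight binders, where the labeled species
#' concentration is comparable to \eqn{K_D} and the hyperbolic (Langmuir)
#' approximation is biased.
#'
#' The implementation uses the algebraically equivalent product form
#' \eqn{B = 2PL / (S + \sqrt{S^2 - 4PL})} with \eqn{S = P + L + K_D}, which
#' avoids catastrophic cancellation as \eqn{K_D \to 0}.  \code{kd = 0} is
#' handled analytically as \eqn{B = \min(P, L)} (stoichiometric limit).
#'
#' @param kd dissociation constant, uM. Scalar or vector; recycled.
#' @param p_tot total receptor (labeled/depleted species), uM.
#' @param l_tot total titrant (ligand), uM.
#' @return Bound complex concentration in uM, vectorized over the inputs;
#'   always in \eqn{[0, \min(P, L)]}.
#' @examples
#' fraction_bound(kd = 0.125, p_tot = 0.1, l_tot = 0.5)  # ~0.0772 uM
#' fraction_bound(0, 1, 2)                               # stoichiometric: 1
#' @seealso [fraction_bound_langmuir()] for the no-depletion limit.
#' @export
fraction_bound <- function(kd, p_tot, l_tot) {
  n <- max(length(kd), length(p_tot), length(l_tot))
  kd <- rep_len(kd, n); p <- rep_len(p_tot, n); l <- rep_len(l_tot, n)
  if (any(!is.finite(kd)) || any(!is.finite(p)) || any(!is.finite(l)))
    stop("all of kd, p_tot, l_tot must be finite")
  if (any(kd < 0) || any(p < 0) || any(l < 0))
    stop("kd, p_tot and l_tot must be nonnegative")
  b <- numeric(n)
  zero <- (p * l) == 0
  stoich <- !zero & kd == 0
  b[stoich] <- pmin(p[stoich], l[stoich])
  i <- !zero & !stoich
  if (any(i)) {
    s <- p[i] + l[i] + kd[i]
    disc <- s^2 - 4 * p[i] * l[i]
    disc[disc < 0] <- 0  # guard round-off
    b[i] <- 2 * p[i] * l[i] / (s + sqrt(disc))
  }
  pmin(b, pmin(p, l))
}

#' Fractional occupancy without ligand depletion (Langmuir isotherm)
#'
#' The classical hyperbolic saturation \eqn{\theta = L/(L + K_D)}, valid when
#' the receptor concentration is negligible relative to \eqn{K_D}.  It is the
#' \eqn{P \to 0} limit of [fraction_bound()] divided by \eqn{P}.
#'
#' @param kd dissociation constant, uM.
#' @param l_free free ligand concentration, uM.
#' @return Occupancy in \eqn{[0, 1]}, vectorized.
#' @export
fraction_bound_langmuir <- function(kd, l_free) {
  n <- max(length(kd), length(l_free))
  kd <- rep_len(kd, n); l <- rep_len(l_free, n)
  if (any(!is.finite(kd)) || any(!is.finite(l))) stop("inputs must be finite")
  if (any(kd < 0) || any(l < 0)) stop("kd and l_free must be nonnegative")
  if (any(kd == 0 & l == 0)) stop("occupancy undefined for kd = 0 and l_free = 0")
  l / (l + kd)
}

#' Protein species descriptor
#'
#' Bundles the constants needed to move between mass and molar concentration
#' scales: monomer mass and the mass-based extinction coefficient at 280 nm.
#'
#' @param name identifier, e.g. `"MCUb-NTD"`.
#' @param monomer_mass_kda theoretical monomer mass in kDa; must be positive.
#' @param ext_coeff_280 extinction coefficient at 280 nm in (mg/mL)^-1 cm^-1;
#'   must be positive.
#' @return An object of class `protein_spec`.
#' @examples
#' protein_spec("MCUb-NTD", 12.0098, 0.4280)
#' @export
protein_spec <- function(name, monomer_mass_kda, ext_coeff_280) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(monomer_mass_kda) || monomer_mass_kda <= 0)
    stop("monomer_mass_kda must be positive")
  if (!is.finite(ext_coeff_280) || ext_coeff_280 <= 0)
    stop("ext_coeff_280 must be positive")
  structure(list(name = name,
                 monomer_mass_kda = monomer_mass_kda,
                 ext_coeff_280 = ext_coeff_280),
            class = "protein_spec")
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("<protein_spec> %s: %.4f kDa, A280 %.4f (mg/mL)^-1 cm^-1\n",
              x$name, x$monomer_mass_kda, x$ext_coeff_280))
  invisible(x)
}

#' Built-in N-terminal domain constructs
#'
#' Reference constants for the MCU and MCUb matrix-facing N-terminal domains:
#' theoretical monomer masses of 13.8637 and 12.0098 kDa and 280-nm
#' extinction coefficients of 0.3693 and 0.4280 (mg/mL)^-1 cm^-1.
#'
#' @format A named list of two [protein_spec()] objects, `mcu_ntd` and
#'   `mcub_ntd`.
#' @export
ntd_constructs <- list(
  mcu_ntd  = protein_spec("MCU-NTD",  13.8637, 0.3693),
  mcub_ntd = protein_spec("MCUb-NTD", 12.0098, 0.4280)
)

#' Convert a mass concentration to molar units
#'
#' @param conc_mg_ml concentration in mg/mL; nonnegative.
#' @param spec a [protein_spec()].
#' @return Monomer concentration in uM: `conc / monomer_mass_kda * 1000`.
#' @examples
#' mgml_to_micromolar(0.81, ntd_constructs$mcub_ntd)  # ~67.4 uM
#' @export
mgml_to_micromolar <- function(conc_mg_ml, spec) {
  stopifnot(inherits(spec, "protein_spec"))
  if (any(!is.finite(conc_mg_ml)) || any(conc_mg_ml < 0))
    stop("conc_mg_ml must be finite and nonnegative")
  conc_mg_ml / spec$monomer_mass_kda * 1000
}

#' Convert 280-nm absorbance to mass concentration
#'
#' @param a280 absorbance at 280 nm; nonnegative.
#' @param spec a [protein_spec()].
#' @param path_cm cuvette path length in cm; positive (default 1).
#' @return Concentration in mg/mL: `a280 / (ext_coeff_280 * path_cm)`.
#' @export
a280_to_mgml <- function(a280, spec, path_cm = 1) {
  stopifnot(inherits(spec, "protein_spec"))
  if (any(!is.finite(a280)) || any(a280 < 0))
    stop("a280 must be finite and nonnegative")
  if (!is.finite(path_cm) || path_cm <= 0) stop("path_cm must be positive")
  a280 / (spec$ext_coeff_280 * path_cm)
}
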