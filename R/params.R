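# Idealized backbone geometry under the rigid-geometry hypothesis: bond
# lengths and bond angles fixed at standard stereochemistry values, trans
# peptide bond (omega = 180 deg) with optional Gaussian jitter, and fixed
# torsion magnitudes |phi|, |psi| whose signs are the combinatorial degrees
# of freedom of the instance.

#' Rigid-geometry parameters for the synthetic backbone generator
#'
#' Bond lengths (Angstrom), bond angles (degrees) and torsion settings used
#' to build idealized backbone conformations. Defaults are standard
#' stereochemistry values. The three angles around the amide nitrogen sum to
#' 360 degrees so the amide hydrogen is exactly in the peptide plane; with
#' `omega = 180` and `omega_jitter = 0` each peptide unit is exactly planar
#' and the positions of N and (first-occurrence) CA are forced by their
#' reference distances. `phi` and `psi` are torsion magnitudes: under the
#' discretization the sign of each torsion is chosen by an orientation bit,
#' so only the magnitudes enter the distance data.
#'
#' @param b_n_ca,b_ca_c,b_c_n,b_n_h,b_ca_ha Bond lengths N-CA, CA-C, C-N,
#'   N-H, CA-HA (Angstrom).
#' @param a_n_ca_c,a_ca_c_n,a_c_n_ca Backbone bond angles (degrees).
#' @param a_c_n_h Angle C-N-H (degrees); the angle H-N-CA is derived as
#'   `360 - a_c_n_ca - a_c_n_h` to keep the amide centre planar.
#' @param a_n_ca_ha,a_c_ca_ha Angles placing the alpha-hydrogen (degrees).
#' @param phi,psi Torsion magnitudes (degrees) about the N-CA and CA-C bonds;
#'   defaults are alpha-helical magnitudes. Must lie strictly inside
#'   (0, 180) so no extra collinearity is introduced.
#' @param omega Peptide torsion (degrees), 180 for a trans peptide.
#' @param omega_jitter Standard deviation (degrees) of Gaussian jitter added
#'   to `omega` per peptide bond; 0 gives exactly planar peptide units, about
#'   5 emulates the non-planarity of experimental structures.
#' @return A list of class `geometry_params`.
#' @export
geometry_params <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                            b_n_h = 1.01, b_ca_ha = 1.09,
                            a_n_ca_c = 111.0, a_ca_c_n = 117.2,
                            a_c_n_ca = 121.7, a_c_n_h = 119.0,
                            a_n_ca_ha = 108.5, a_c_ca_ha = 108.5,
                            phi = 57, psi = 47,
                            omega = 180, omega_jitter = 0) {
  p <- list(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n, b_n_h = b_n_h,
            b_ca_ha = b_ca_ha, a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n,
            a_c_n_ca = a_c_n_ca, a_c_n_h = a_c_n_h, a_n_ca_ha = a_n_ca_ha,
            a_c_ca_ha = a_c_ca_ha, phi = phi, psi = psi, omega = omega,
            omega_jitter = omega_jitter)
  bonds <- unlist(p[startsWith(names(p), "b_")])
  angs <- unlist(p[startsWith(names(p), "a_")])
  if (any(!is.finite(unlist(p))) || any(bonds <= 0))
    stop("invalid-argument: bond lengths must be positive and finite")
  if (any(angs <= 0 | angs >= 180))
    stop("invalid-argument: bond angles must lie in (0, 180) degrees")
  if (phi <= 0 || phi >= 180 || psi <= 0 || psi >= 180)
    stop("invalid-argument: torsion magnitudes must lie in (0, 180) degrees")
  if (omega_jitter < 0)
    stop("invalid-argument: omega_jitter must be non-negative")
  # H-N-CA angle completing a planar sp2 nitrogen
  p$a_h_n_ca <- 360 - a_c_n_ca - a_c_n_h
  if (p$a_h_n_ca <= 0 || p$a_h_n_ca >= 180)
    stop("invalid-argument: angles around N are inconsistent with a planar amide")
  class(p) <- "geometry_params"
  p
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Backbone geometry parameters (rigid-geometry hypothesis)\n")
  cat(sprintf("  bonds (A): N-CA %.3f  CA-C %.3f  C-N %.3f  N-H %.3f  CA-HA %.3f\n",
              x$b_n_ca, x$b_ca_c, x$b_c_n, x$b_n_h, x$b_ca_ha))
  cat(sprintf("  angles (deg): N-CA-C %.1f  CA-C-N %.1f  C-N-CA %.1f\n",
              x$a_n_ca_c, x$a_ca_c_n, x$a_c_n_ca))
  cat(sprintf("  torsions (deg): |phi| %.1f  |psi| %.1f  omega %.1f (jitter sd %.1f)\n",
              x$phi, x$psi, x$omega, x$omega_jitter))
  invisible(x)
}
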