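#' Physical constants used throughout the package
#'
#' GROMACS-style units are used internally: kJ/mol for energies, nm for
#' lengths, ps for times, amu for masses, K for temperatures. With these
#' units 1 amu nm^2 ps^-2 = 1 kJ/mol, so no unit conversion is needed in
#' the quasiharmonic machinery.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.008314462618 kJ mol^-1 K^-1.}
#'   \item{hbar}{Reduced Planck constant, 0.0635077993 kJ mol^-1 ps.}
#' }
#' @export
phys_const <- list(
  kB   = 0.008314462618,  # kJ/mol/K
  hbar = 0.0635077993     # kJ/mol * ps
)

# Standard backbone masses (amu) for mass-weighting.
.atom_masses <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999,
                  CB = 12.011, H = 1.008)

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
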