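#' Physical constants and model defaults
#'
#' Returns the physical constants of the coarse-grained model. All lengths are
#' in units of the bead diameter \eqn{\sigma} = 0.8 nm (the Kuhn length of a
#' polypeptide), all energies in units of \eqn{\epsilon = k_B T} at
#' T = 310 K, and all times in seconds.
#'
#' @param ... named overrides for individual constants. Unknown names are an
#'   error, so typos cannot silently fall back to defaults.
#'
#' @return A named list with elements:
#' \describe{
#'   \item{sigma_nm}{bead diameter in nm (0.8).}
#'   \item{temperature_K}{temperature (310).}
#'   \item{eps_kcal}{\eqn{k_B T} at `temperature_K`, in kcal/mol; the energy
#'     unit \eqn{\epsilon} used for all kcal/mol conversions.}
#'   \item{K0}{FENE spring constant, \eqn{\epsilon/\sigma^2} (5.833).}
#'   \item{R0}{FENE maximum bond extension, \eqn{\sigma} (2).}
#'   \item{l_B, kappa}{Bjerrum and Debye screening lengths, both \eqn{\sigma}
#'     (1); physiological-salt screening.}
#'   \item{elec_cutoff}{electrostatic cutoff in \eqn{\sigma} (6; the screened
#'     factor \eqn{e^{-6}} is below 0.0025).}
#'   \item{dG_empty}{free-energy penalty for opening an empty channel,
#'     \eqn{\epsilon} (3).}
#'   \item{D_nm2_s}{isotropic diffusion coefficient, nm\eqn{^2}/s (253).}
#'   \item{dt_s}{Langevin timestep, s (3e-7, i.e. 300 ns).}
#'   \item{tau_LG_s}{lateral-gate attempt timescale, s (5e-7, i.e. 500 ns).}
#'   \item{t_trans_s}{time to translate one bead (three residues), s (0.6,
#'     reproducing 5 residues/s).}
#'   \item{energy_cap}{cap on the soft-core potentials at zero separation,
#'     \eqn{\epsilon} (100).}
#'   \item{coil_penalty}{per-residue transfer-free-energy penalty for a
#'     non-hydrogen-bonded (coil) backbone, \eqn{\epsilon} (1.78).}
#'   \item{terminal_penalty}{transfer-free-energy penalty added to the charged
#'     N- and C-terminal beads, \eqn{\epsilon} (6).}
#' }
#' @examples
#' sec_constants()$t_trans_s           # 0.6 s per bead = 5 residues/s
#' sec_constants(dt_s = 6e-7)$dt_s     # override the timestep
#' @export
sec_constants <- function(...) {
  defaults <- list(
    sigma_nm = 0.8,
    temperature_K = 310,
    eps_kcal = 0.0019872041 * 310,
    K0 = 5.833,
    R0 = 2,
    l_B = 1,
    kappa = 1,
    elec_cutoff = 6,
    dG_empty = 3,
    D_nm2_s = 253.0,
    dt_s = 300e-9,
    tau_LG_s = 500e-9,
    t_trans_s = 0.6,
    energy_cap = 100,
    coil_penalty = 1.78,
    terminal_penalty = 6
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0("unknown constant(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  defaults
}

#' Convert between kcal/mol and the model energy unit
#'
#' The model energy unit is \eqn{\epsilon = k_B T} at 310 K
#' (0.61603 kcal/mol).
#'
#' @param x numeric vector of energies.
#' @param constants constants list from [sec_constants()].
#' @return numeric vector in the target unit.
#' @examples
#' kcal_to_eps(-1.25) * 3   # transfer free energy of an LLL bead, ~ -6.1 eps
#' @export
kcal_to_eps <- function(x, constants = sec_constants()) x / constants$eps_kcal

#' @rdname kcal_to_eps
#' @export
eps_to_kcal <- function(x, constants = sec_constants()) x * constants$eps_kcal

# diffusion coefficient in sigma^2/s
d_sigma2 <- function(constants = sec_constants()) {
  constants$D_nm2_s / constants$sigma_nm^2
}
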