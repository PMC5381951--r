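#' Water-octanol transfer free energy scale
#'
#' Per-residue water-to-octanol transfer free energies from the Wimley-White
#' pentapeptide partitioning scale, expressed in the model energy unit
#' \eqn{\epsilon = k_B T} at 310 K. Hydrophobic residues are negative
#' (favour the membrane), hydrophilic and charged residues positive. The
#' ionisable residues (D, E, K, R, H) use their charged-form values; the
#' model treats histidine as charge-neutral but keeps its charged-form
#' hydrophobicity.
#'
#' @param constants constants list from [sec_constants()]; sets the
#'   kcal/mol-to-\eqn{\epsilon} conversion.
#' @return A tibble with columns `residue` (one-letter code), `dg_kcal`
#'   (water-to-octanol transfer free energy, kcal/mol) and `dg_eps` (same, in
#'   \eqn{\epsilon}).
#' @examples
#' ww_scale() |> dplyr::filter(residue == "L")   # leucine: -1.25 kcal/mol
#' @export
ww_scale <- function(constants = sec_constants()) {
  tbl <- tibble(
    residue = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    dg_kcal = c(0.50, 1.81, 0.85, 3.64, -0.02, 0.77, 3.63, 1.15, 2.33, -1.12,
                -1.25, 2.80, -0.67, -1.71, 0.14, 0.46, 0.25, -2.09, -0.71, -0.46)
  )
  tbl$dg_eps <- kcal_to_eps(tbl$dg_kcal, constants)
  tbl
}

.ww_lookup <- function(constants = sec_constants()) {
  s <- ww_scale(constants)
  setNames(s$dg_eps, s$residue)
}

#' Per-residue transfer free energy
#'
#' Water-membrane transfer free energy of a single residue in \eqn{\epsilon}.
#' Residues whose backbone does not participate in intramolecular hydrogen
#' bonds (coil) pay an extra 1.78 \eqn{\epsilon}, the approximate cost of
#' partitioning a non-hydrogen-bonded peptide bond into the membrane.
#'
#' @param residue character vector of one-letter residue codes.
#' @param is_helix logical vector; `TRUE` for residues in hydrogen-bonded
#'   secondary structure (helix or strand), `FALSE` for coil.
#' @param constants constants list from [sec_constants()].
#' @return numeric vector of transfer free energies in \eqn{\epsilon}.
#' @examples
#' residue_tfe("L", TRUE)                        # ~ -2.03 eps
#' residue_tfe("Q", FALSE) - residue_tfe("Q", TRUE)   # +1.78 eps coil penalty
#' @export
residue_tfe <- function(residue, is_helix = TRUE, constants = sec_constants()) {
  residue <- toupper(residue)
  lk <- .ww_lookup(constants)
  bad <- setdiff(unique(residue), names(lk))
  if (length(bad)) {
    abort(paste0("unknown residue letter(s): ", paste(bad, collapse = ", ")))
  }
  g <- unname(lk[residue])
  g + ifelse(rep_len(is_helix, length(g)), 0, constants$coil_penalty)
}

# formal charge of residues: R,K +1; D,E -1; others (incl. H) 0
residue_charge <- function(residue) {
  residue <- toupper(residue)
  ifelse(residue %in% c("R", "K"), 1L,
         ifelse(residue %in% c("D", "E"), -1L, 0L))
}
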