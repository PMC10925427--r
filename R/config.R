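#' Bond-valence parameters
#'
#' Standard bond-valence parameters for metal--donor pairs used by
#' [bond_valence()]. The bond valence of a coordination bond of length
#' \eqn{d} is \eqn{\exp((R_0 - d)/b)}; for an ideal site the valences sum
#' to the metal's oxidation state.
#'
#' @param extra Optional tibble with columns `metal`, `donor`, `r0` appended
#'   to (and overriding) the built-in table, so additional metals can be
#'   configured.
#' @return A tibble with columns `metal`, `donor` (element symbol of the
#'   donor atom), `r0` (Angstrom) and `b` (Angstrom).
#' @export
#' @examples
#' bv_params()
bv_params <- function(extra = NULL) {
  base <- tibble::tribble(
    ~metal, ~donor, ~r0,
    "ZN", "O", 1.704,
    "ZN", "N", 1.77,
    "ZN", "S", 2.09
  )
  if (!is.null(extra)) {
    extra <- as_tibble(extra)
    base <- bind_rows(extra, base)
    base <- base[!duplicated(base[c("metal", "donor")]), ]
  }
  base$b <- 0.37
  base
}

#' Expected oxidation states by metal
#' @return Named numeric vector of oxidation states.
#' @export
oxidation_states <- function() c(ZN = 2)

#' Angular targets for zinc--donor--CB geometry
#'
#' Empirical target angles (degrees) for the Zn-donor-CB angle used by the
#' circle-scan placement strategies: 109 for cysteine SG, 100 for histidine
#' ND1, 155 for NE2. The ring carbons CE1/CD2 (eligible because of possible
#' ring mislabelling) take the midpoint of the two nitrogen targets.
#'
#' @return Named numeric vector keyed by atom role.
#' @export
angle_targets <- function() {
  c(SG = 109, ND1 = 100, NE2 = 155, CE1 = 128, CD2 = 128)
}

#' Atomic solvation parameter scale
#'
#' Per-atom-class hydrophobicity coefficients (cal mol^-1 A^-2) used by the
#' hydrophobicity-contrast and mean-solvation profiles. Carbon and sulfur
#' are hydrophobic (positive), polar nitrogen/oxygen hydrophilic (negative),
#' with stronger values for formally charged atoms.
#'
#' @return Named numeric vector with classes `C`, `N_O_neutral`,
#'   `O_charged`, `N_charged`, `S`.
#' @export
solvation_scale <- function() {
  c(C = 16, N_O_neutral = -6, O_charged = -24, N_charged = -50, S = 21)
}

#' Prediction configuration
#'
#' Bundles every tunable threshold of the prediction pipeline. Defaults are
#' the operating point of the method: a 2.4--4.5 A inter-ligand window, a
#' 2.400 A disulfide cutoff, a 2.5 A redundancy radius (preserving dinuclear
#' sites at 3--4 A), a 0.5 certainty threshold, and 2.5/4.0 A first/second
#' coordination spheres.
#'
#' @param distance_window Length-2 numeric, allowed inter-ligand atom
#'   distances (Angstrom).
#' @param disulfide_cutoff SG--SG distances below this are disulfides.
#' @param redundancy_threshold Predicted zincs closer than this are merged.
#' @param certainty_threshold Minimum certainty of a verified site.
#' @param first_sphere,second_sphere Coordination-sphere radii (Angstrom).
#' @param circle_radius Radius of the two-ligand placement locus circle.
#' @param bond_length Nominal zinc coordination bond length (Angstrom).
#' @param targets Angular targets, see [angle_targets()].
#' @param model Optional fitted ensemble (see [train_ensemble()]) used to
#'   verify two-residue sites.
#' @param reference_curves Optional reference profile curves (see
#'   [build_reference_curves()]) used to verify 3/4-residue sites.
#' @param chains Optional character vector restricting the search.
#' @param seed Integer seed recorded in reports.
#' @return A list of class `zn_config`.
#' @export
prediction_config <- function(distance_window = c(2.4, 4.5),
                              disulfide_cutoff = 2.400,
                              redundancy_threshold = 2.5,
                              certainty_threshold = 0.5,
                              first_sphere = 2.5,
                              second_sphere = 4.0,
                              circle_radius = 1.2,
                              bond_length = 2.1,
                              targets = angle_targets(),
                              model = NULL,
                              reference_curves = NULL,
                              chains = NULL,
                              seed = 1L) {
  stopifnot(
    length(distance_window) == 2, distance_window[1] < distance_window[2],
    disulfide_cutoff > 0, redundancy_threshold > 0,
    first_sphere > 0, second_sphere > first_sphere
  )
  structure(
    list(
      distance_window = distance_window,
      disulfide_cutoff = disulfide_cutoff,
      redundancy_threshold = redundancy_threshold,
      certainty_threshold = certainty_threshold,
      first_sphere = first_sphere,
      second_sphere = second_sphere,
      circle_radius = circle_radius,
      bond_length = bond_length,
      targets = targets,
      model = model,
      reference_curves = reference_curves,
      chains = chains,
      seed = as.integer(seed)
    ),
    class = "zn_config"
  )
}
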