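PROFILE_RADII <- seq(2, 7, by = 0.25)

# Assign each atom its solvation class. Charged classes are recognised from
# residue/atom-name rules: carboxylate oxygens of Glu/Asp (and C-terminal
# OXT) are charged O; Lys NZ and the arginine guanidinium nitrogens are
# charged N. Everything else maps by element.
solvation_class <- function(element, res_name, atom) {
  cls <- rep(NA_character_, length(element))
  cls[element == "C"] <- "C"
  cls[element == "S"] <- "S"
  charged_o <- (res_name == "GLU" & atom %in% c("OE1", "OE2")) |
    (res_name == "ASP" & atom %in% c("OD1", "OD2")) |
    atom == "OXT"
  charged_n <- (res_name == "LYS" & atom == "NZ") |
    (res_name == "ARG" & atom %in% c("NE", "NH1", "NH2"))
  cls[element == "O"] <- ifelse(charged_o[element == "O"], "O_charged", "N_O_neutral")
  cls[element == "N"] <- ifelse(charged_n[element == "N"], "N_charged", "N_O_neutral")
  cls
}

#' Atomic solvation parameter of atoms
#'
#' Maps each atom to its hydrophobicity coefficient (cal mol^-1 A^-2) on the
#' configured scale. Hydrogens contribute 0; metal atoms are excluded
#' (0 with a warning for any other unknown element).
#'
#' @param atoms Atom tibble (needs `element`, `res_name`, `atom`).
#' @param scale Named scale, see [solvation_scale()].
#' @return Numeric vector of per-atom values.
#' @export
solvation_parameter <- function(atoms, scale = solvation_scale()) {
  out <- numeric(nrow(atoms))
  el <- atoms$element
  known <- el %in% c("C", "N", "O", "S")
  cls <- solvation_class(el[known], atoms$res_name[known], atoms$atom[known])
  out[known] <- scale[cls]
  unknown <- !known & el != "H" & !(el %in% METAL_ELEMENTS)
  if (any(unknown)) {
    warn(paste(
      "no solvation parameter for element(s):",
      paste(unique(el[unknown]), collapse = ", "), "- treated as 0"
    ))
  }
  out
}

profile_atoms <- function(structure, scale) {
  a <- structure[!(structure$element %in% c("H", "D")) &
                   !(structure$element %in% METAL_ELEMENTS), ]
  a$dsigma <- solvation_parameter(a, scale)
  a
}

#' Hydrophobicity contrast at one radius
#'
#' Two-shell contrast around `center`: the sum of solvation parameters over
#' the outer shell (`R/2 < r <= R`) minus the sum over the inner ball
#' (`r <= R/2`). Positive when hydrophilic (negative-parameter) atoms fill
#' the inner shell and carbons the outer shell -- the signature of a buried
#' metal site. Metals and hydrogens are ignored.
#'
#' @param structure Atom tibble.
#' @param center Length-3 numeric.
#' @param radius Shell radius R (> 0).
#' @param scale Solvation scale.
#' @return The contrast value C(R).
#' @export
contrast_at <- function(structure, center, radius, scale = solvation_scale()) {
  stopifnot(radius > 0)
  a <- profile_atoms(structure, scale)
  if (nrow(a) == 0) return(0)
  r <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2)
  sum(a$dsigma[r > radius / 2 & r <= radius]) - sum(a$dsigma[r <= radius / 2])
}

#' Mean atomic solvation parameter at one radius
#'
#' Arithmetic mean of the solvation parameter over all (non-metal,
#' non-hydrogen) atoms within `radius` of `center`; 0 when the ball is
#' empty.
#'
#' @inheritParams contrast_at
#' @return Mean solvation parameter.
#' @export
mean_solvation_at <- function(structure, center, radius, scale = solvation_scale()) {
  stopifnot(radius > 0)
  a <- profile_atoms(structure, scale)
  if (nrow(a) == 0) return(0)
  r <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2)
  inside <- r <= radius
  if (!any(inside)) return(0)
  mean(a$dsigma[inside])
}

#' Radial hydrophobicity profile around a point
#'
#' Evaluates the hydrophobicity contrast C and the mean solvation parameter
#' at 21 radii from 2 to 7 Angstrom in 0.25 Angstrom steps around `center`
#' (typically a deduced zinc position).
#'
#' @inheritParams contrast_at
#' @return A 21-row tibble with columns `radius`, `c_value`, `mean_sigma`.
#' @export
hydro_profile <- function(structure, center, scale = solvation_scale()) {
  a <- profile_atoms(structure, scale)
  if (nrow(a) == 0) {
    return(tibble(radius = PROFILE_RADII, c_value = 0, mean_sigma = 0))
  }
  r <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2)
  cv <- vapply(PROFILE_RADII, function(R) {
    sum(a$dsigma[r > R / 2 & r <= R]) - sum(a$dsigma[r <= R / 2])
  }, numeric(1))
  ms <- vapply(PROFILE_RADII, function(R) {
    inside <- r <= R
    if (!any(inside)) 0 else mean(a$dsigma[inside])
  }, numeric(1))
  tibble(radius = PROFILE_RADII, c_value = cv, mean_sigma = ms)
}

#' Profile-correlation certainty score
#'
#' Pearson correlation between a site's C and mean-solvation curves and the
#' reference curves of its group, combined as the clamped arithmetic mean of
#' the two correlations. Constant (zero-variance) curves contribute a
#' correlation of 0.
#'
#' @param profile A [hydro_profile()] tibble.
#' @param reference A single group's reference curves: tibble with `radius`,
#'   `c_value`, `mean_sigma` on the same grid.
#' @return Certainty in `[0, 1]`.
#' @export
pearson_certainty <- function(profile, reference) {
  if (nrow(profile) != nrow(reference) ||
      any(abs(profile$radius - reference$radius) > 1e-9)) {
    abort("profile and reference must share the same radius grid")
  }
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
    cor(a, b)
  }
  r_c <- safe_cor(profile$c_value, reference$c_value)
  r_s <- safe_cor(profile$mean_sigma, reference$mean_sigma)
  clamp01((r_c + r_s) / 2)
}

#' Build group reference curves from validated sites
#'
#' Pointwise mean of the hydrophobicity profiles of validated sites, per
#' group (CH2/CH3/CH4). The result is the reference against which
#' [pearson_certainty()] scores predicted sites.
#'
#' @param sites A tibble with columns `structure` (list of atom tibbles),
#'   `center` (list of length-3 numerics) and `group`.
#' @param scale Solvation scale.
#' @return A tibble with columns `group`, `radius`, `c_value`, `mean_sigma`.
#' @export
build_reference_curves <- function(sites, scale = solvation_scale()) {
  sites <- as_tibble(sites)
  stopifnot(nrow(sites) >= 1)
  profs <- purrr::map2(sites$structure, sites$center, function(s, ctr) {
    hydro_profile(s, ctr, scale)
  })
  sites$prof <- profs
  out <- lapply(split(seq_len(nrow(sites)), sites$group), function(idx) {
    cv <- rowMeans(sapply(profs[idx], function(p) p$c_value))
    ms <- rowMeans(sapply(profs[idx], function(p) p$mean_sigma))
    tibble(radius = PROFILE_RADII, c_value = cv, mean_sigma = ms)
  })
  bind_rows(lapply(names(out), function(g) {
    mutate(out[[g]], group = g)
  }))[c("group", "radius", "c_value", "mean_sigma")]
}

#' Look up one group's reference curves
#'
#' @param refs Output of [build_reference_curves()].
#' @param group `"CH2"`, `"CH3"` or `"CH4"`.
#' @return The 21-row curve tibble for that group.
#' @export
reference_for_group <- function(refs, group) {
  hit <- refs[refs$group == group, ]
  if (nrow(hit) == 0) {
    abort(paste0("no reference curves for group ", group))
  }
  hit[c("radius", "c_value", "mean_sigma")]
}
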