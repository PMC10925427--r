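#' Bond valence of a metal--donor bond
#'
#' Empirical bond valence \eqn{\exp((R_0 - d)/b)} with tabulated \eqn{R_0}
#' per metal--donor pair and \eqn{b = 0.37} Angstrom. Vectorised over
#' `distance` and `donor_element`.
#'
#' @param distance Bond length(s) in Angstrom (> 0).
#' @param donor_element Donor element symbol(s): `"N"`, `"O"` or `"S"`.
#' @param metal Metal element symbol (default `"ZN"`).
#' @param params Parameter table, see [bv_params()].
#' @return Numeric valence(s) in valence units.
#' @export
#' @examples
#' bond_valence(2.09, "S")  # exactly 1 at d = R0
#' bond_valence(2.30, "S")
bond_valence <- function(distance, donor_element, metal = "ZN",
                         params = bv_params()) {
  if (any(distance <= 0)) abort("distance must be > 0")
  donor_element <- toupper(donor_element)
  idx <- match(
    paste(metal, donor_element),
    paste(params$metal, params$donor)
  )
  if (any(is.na(idx))) {
    bad <- unique(donor_element[is.na(idx)])
    abort(paste0(
      "no bond-valence parameters for ", metal, "-",
      paste(bad, collapse = "/"), "; extend bv_params()"
    ))
  }
  exp((params$r0[idx] - distance) / params$b[idx])
}

#' Collect the first coordination sphere around a point
#'
#' Finds every N/O/S donor atom within the first-sphere cutoff of `center`
#' and returns one bond-valence vector per donor. At most one atom per
#' residue contributes (the closest donor of each residue); hydrogens and
#' metal atoms are never donors; waters contribute their oxygen.
#'
#' @param structure An atom tibble.
#' @param center Numeric length-3 position (Angstrom).
#' @param cutoff First-sphere radius, default 2.5 Angstrom.
#' @param metal Metal element assumed at `center`.
#' @param params Bond-valence parameters.
#' @return A tibble with one row per donor: identity columns, `distance`,
#'   `valence`, the metal-to-donor unit vector (`ux`, `uy`, `uz`),
#'   `occupancy` and `b_factor`.
#' @export
coordination_sphere <- function(structure, center, cutoff = 2.5,
                                metal = "ZN", params = bv_params()) {
  don <- structure[structure$element %in% c("N", "O", "S"), ]
  if (nrow(don) == 0) return(empty_sphere())
  dx <- don$x - center[1]
  dy <- don$y - center[2]
  dz <- don$z - center[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- d <= cutoff & d > 1e-6
  don <- don[keep, ]
  if (nrow(don) == 0) return(empty_sphere())
  d <- d[keep]
  don$distance <- d
  don$ux <- dx[keep] / d
  don$uy <- dy[keep] / d
  don$uz <- dz[keep] / d
  don <- don |>
    group_by(.data$chain, .data$resseq, .data$icode) |>
    slice(which.min(.data$distance)) |>
    ungroup() |>
    arrange(.data$distance)
  don$valence <- bond_valence(don$distance, don$element, metal, params)
  don[c(
    "chain", "resseq", "icode", "res_name", "atom", "element",
    "distance", "valence", "ux", "uy", "uz", "occupancy", "b_factor"
  )]
}

empty_sphere <- function() {
  tibble(
    chain = character(), resseq = integer(), icode = character(),
    res_name = character(), atom = character(), element = character(),
    distance = numeric(), valence = numeric(),
    ux = numeric(), uy = numeric(), uz = numeric(),
    occupancy = numeric(), b_factor = numeric()
  )
}

#' Valence agreement score
#'
#' Agreement between the bond-valence sum \eqn{S = \sum V_i} and the
#' expected oxidation state: \eqn{Q_v = \min(S/V_{ox}, V_{ox}/S)}, 1 for a
#' perfect site, 0 when there are no bonds.
#'
#' @param valences Numeric vector of bond valences (>= 0).
#' @param v_ox Expected oxidation state (> 0).
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' q_valence(c(0.5, 0.5), 2)  # two-ligand optimum: 0.5
q_valence <- function(valences, v_ox) {
  if (v_ox <= 0) abort("v_ox must be > 0")
  if (any(valences < 0)) abort("valences must be >= 0")
  s <- sum(valences)
  if (s == 0) return(0)
  min(s / v_ox, v_ox / s)
}

#' Coordination-sphere completeness score
#'
#' One minus the normalised magnitude of the resultant bond-valence vector.
#' A complete, symmetric sphere cancels vectorially (score 1). Two
#' normalisations are provided: `"valence_sum"` divides the resultant by
#' \eqn{\sum V_i}; `"oxidation_state"` divides by \eqn{V_{ox}} and is the
#' convention under which the two-ligand optimum equals 0.71 (half of which
#' gives the 0.355 acceptance threshold used for two-ligand sites).
#'
#' @param sphere Donor tibble from [coordination_sphere()] (needs `valence`,
#'   `ux`, `uy`, `uz`).
#' @param normalization `"valence_sum"` or `"oxidation_state"`.
#' @param v_ox Expected oxidation state (used by `"oxidation_state"`).
#' @return Score clamped to `[0, 1]`.
#' @export
q_completeness <- function(sphere, normalization = c("valence_sum", "oxidation_state"),
                           v_ox = 2) {
  normalization <- match.arg(normalization)
  if (nrow(sphere) == 0) abort("q_completeness requires at least one donor")
  s <- sum(sphere$valence)
  if (s <= 0) abort("total bond valence must be > 0")
  resultant <- vnorm(c(
    sum(sphere$valence * sphere$ux),
    sum(sphere$valence * sphere$uy),
    sum(sphere$valence * sphere$uz)
  ))
  denom <- if (normalization == "valence_sum") s else v_ox
  clamp01(1 - resultant / denom)
}

#' Environmental agreement score
#'
#' Compares the metal's occupancy and B-factor with valence-weighted
#' averages over its donors: \eqn{O_e = \sum V_i O_i / \sum V_i},
#' \eqn{B_e = \sum V_i B_i / \sum V_i}, and
#' \deqn{Q_e = \min(2 \min(O_m, O_e), 1) \cdot
#'       \min\left(\frac{B_m O_m}{B_e O_e}, \frac{B_e O_e}{B_m O_m}\right).}
#'
#' @param o_m,b_m Metal occupancy (in `(0, 1]`) and B-factor (> 0).
#' @param sphere Donor tibble with `valence`, `occupancy`, `b_factor`.
#' @return Score in `[0, 1]`.
#' @export
q_environment <- function(o_m, b_m, sphere) {
  if (nrow(sphere) == 0) abort("q_environment requires at least one donor")
  if (o_m <= 0 || o_m > 1 || b_m <= 0) abort("o_m must be in (0,1] and b_m > 0")
  w <- sphere$valence
  o_e <- sum(w * sphere$occupancy) / sum(w)
  b_e <- sum(w * sphere$b_factor) / sum(w)
  if (o_e <= 0 || b_e <= 0) abort("donor occupancies/B-factors must be > 0")
  occ_term <- min(2 * min(o_m, o_e), 1)
  ratio <- (b_m * o_m) / (b_e * o_e)
  occ_term * min(ratio, 1 / ratio)
}

#' Validate a (modelled or predicted) metal site
#'
#' Assembles the first coordination sphere around `center` and computes the
#' valence, completeness and environment scores. Acceptance thresholds
#' depend on the ligand count: with three or more donors all three scores
#' must exceed 0.5 (half the four-ligand optimum); with exactly two donors
#' the thresholds are Qv > 0.25, Qc > 0.355 (oxidation-state normalisation)
#' and Qe > 0.5; with fewer than two donors the site fails.
#'
#' @param structure An atom tibble.
#' @param center Numeric length-3 metal position.
#' @param metal Metal element symbol.
#' @param o_m,b_m Metal occupancy and B-factor. When `NULL`, a modelled
#'   metal atom within 0.5 Angstrom of `center` is used if present;
#'   otherwise occupancy 1 and the environment B-factor are assumed.
#' @param cutoff First-sphere radius.
#' @param params Bond-valence parameters.
#' @return One-row tibble: `q_valence`, `q_completeness`, `q_environment`,
#'   `n_ligands`, `passed`.
#' @export
validate_site <- function(structure, center, metal = "ZN",
                          o_m = NULL, b_m = NULL, cutoff = 2.5,
                          params = bv_params()) {
  v_ox <- oxidation_states()[[metal]]
  if (is.null(v_ox)) abort(paste("no configured oxidation state for", metal))
  sphere <- coordination_sphere(structure, center, cutoff, metal, params)
  n <- nrow(sphere)
  if (is.null(o_m) || is.null(b_m)) {
    met <- structure[structure$element == metal & structure$is_hetero, ]
    if (nrow(met) > 0) {
      d <- sqrt((met$x - center[1])^2 + (met$y - center[2])^2 + (met$z - center[3])^2)
      if (min(d) < 0.5) {
        hit <- met[which.min(d), ]
        if (is.null(o_m)) o_m <- hit$occupancy
        if (is.null(b_m)) b_m <- hit$b_factor
      }
    }
    if (is.null(o_m)) o_m <- 1
    if (is.null(b_m)) {
      b_m <- if (n > 0) sum(sphere$valence * sphere$b_factor) / sum(sphere$valence) else 1
    }
  }
  if (n == 0) {
    return(tibble(
      q_valence = 0, q_completeness = 0, q_environment = 0,
      n_ligands = 0L, passed = FALSE
    ))
  }
  qv <- q_valence(sphere$valence, v_ox)
  qc <- q_completeness(
    sphere,
    normalization = if (n == 2) "oxidation_state" else "valence_sum",
    v_ox = v_ox
  )
  qe <- q_environment(max(min(o_m, 1), 1e-6), max(b_m, 1e-6), sphere)
  passed <- if (n >= 3) {
    qv > 0.5 && qc > 0.5 && qe > 0.5
  } else if (n == 2) {
    qv > 0.25 && qc > 0.355 && qe > 0.5
  } else {
    FALSE
  }
  tibble(
    q_valence = qv, q_completeness = qc, q_environment = qe,
    n_ligands = as.integer(n), passed = passed
  )
}

#' Validate every modelled metal in a structure
#'
#' Runs [validate_site()] at the position of each modelled (hetero) metal
#' ion of the requested element.
#'
#' @inheritParams validate_site
#' @return A tibble with one row per modelled metal: identity, position and
#'   the validation scores.
#' @export
validate_structure_metals <- function(structure, metal = "ZN", cutoff = 2.5,
                                      params = bv_params()) {
  met <- structure[structure$element == metal & structure$is_hetero, ]
  if (nrow(met) == 0) {
    return(tibble(
      chain = character(), resseq = integer(), icode = character(),
      x = numeric(), y = numeric(), z = numeric(),
      q_valence = numeric(), q_completeness = numeric(),
      q_environment = numeric(), n_ligands = integer(), passed = logical()
    ))
  }
  scores <- purrr::map(seq_len(nrow(met)), function(i) {
    validate_site(
      structure, c(met$x[i], met$y[i], met$z[i]), metal,
      o_m = met$occupancy[i], b_m = max(met$b_factor[i], 1e-6),
      cutoff = cutoff, params = params
    )
  })
  bind_rows(
    lapply(seq_len(nrow(met)), function(i) {
      bind_cols(
        met[i, c("chain", "resseq", "icode", "x", "y", "z")],
        scores[[i]]
      )
    })
  )
}

#' @importFrom dplyr bind_cols
NULL
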