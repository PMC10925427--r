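res_atoms_of <- function(structure, chain, resseq, icode) {
  structure[structure$chain == chain & structure$resseq == resseq &
              structure$icode == icode & !structure$is_hetero, ]
}

atom_position <- function(res, name) {
  hit <- res[res$atom == name, ]
  if (nrow(hit) == 0) return(NULL)
  c(hit$x[1], hit$y[1], hit$z[1])
}

# Minimise a scored locus circle: a coarse 0.1-degree scan (3600 points)
# followed by golden-section refinement around the best point. score_fn maps
# an n x 3 matrix of points to n scores.
scan_circle <- function(center, axis, radius, score_fn, n_steps = 3600) {
  w1 <- perp_vector(axis)
  w2 <- vunit(pracma_cross(axis, w1))
  point_at <- function(theta) {
    cbind(
      center[1] + radius * (cos(theta) * w1[1] + sin(theta) * w2[1]),
      center[2] + radius * (cos(theta) * w1[2] + sin(theta) * w2[2]),
      center[3] + radius * (cos(theta) * w1[3] + sin(theta) * w2[3])
    )
  }
  theta <- seq(0, 2 * pi, length.out = n_steps + 1)[-(n_steps + 1)]
  scores <- score_fn(point_at(theta))
  best <- which.min(scores)
  step <- 2 * pi / n_steps
  f <- function(th) score_fn(point_at(th))
  opt <- stats::optimize(
    f,
    interval = c(theta[best] - 1.5 * step, theta[best] + 1.5 * step),
    tol = 1e-12
  )
  drop(point_at(opt$minimum))
}

pracma_cross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Shared two-ligand circle placement: the zinc is restricted to the circle
# of radius `circle_radius` around the donor-pair midpoint in the plane
# perpendicular to the donor-donor segment, scored by squared deviation of
# each Zn-donor-CB angle from its per-role target. Locus points on the CB
# (proximal) side of a donor are rejected; if every point is rejected the
# constraint is relaxed to a continuous penalty.
place_pair_circle <- function(lig, structure, config) {
  stopifnot(nrow(lig) == 2)
  donors <- lapply(1:2, function(i) c(lig$x[i], lig$y[i], lig$z[i]))
  cbs <- lapply(1:2, function(i) {
    res <- res_atoms_of(structure, lig$chain[i], lig$resseq[i], lig$icode[i])
    atom_position(res, "CB")
  })
  e2 <- (donors[[1]] + donors[[2]]) / 2
  axis <- vunit(donors[[2]] - donors[[1]])
  if (any(vapply(cbs, is.null, logical(1)))) {
    return(list(position = e2, note = "missing CB; midpoint fallback"))
  }
  targets <- config$targets[lig$atom_role]
  angle_score <- function(pts) {
    total <- numeric(nrow(pts))
    for (i in 1:2) {
      u <- sweep(pts, 2, donors[[i]])  # donor -> locus point
      v <- cbs[[i]] - donors[[i]]
      ct <- (u %*% v) / (sqrt(rowSums(u^2)) * vnorm(v))
      ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
      total <- total + (ang - targets[i])^2
    }
    total
  }
  proximal_violation <- function(pts) {
    viol <- numeric(nrow(pts))
    for (i in 1:2) {
      u <- sweep(pts, 2, donors[[i]])
      v <- cbs[[i]] - donors[[i]]
      viol <- viol + pmax(0, drop(u %*% v))
    }
    viol
  }
  hard <- function(pts) {
    s <- angle_score(pts)
    s[proximal_violation(pts) > 0] <- Inf
    s
  }
  # Determine whether any locus point survives the distal-side test.
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  w1 <- perp_vector(axis)
  w2 <- vunit(pracma_cross(axis, w1))
  probe <- cbind(
    e2[1] + config$circle_radius * (cos(theta) * w1[1] + sin(theta) * w2[1]),
    e2[2] + config$circle_radius * (cos(theta) * w1[2] + sin(theta) * w2[2]),
    e2[3] + config$circle_radius * (cos(theta) * w1[3] + sin(theta) * w2[3])
  )
  if (all(proximal_violation(probe) > 0)) {
    score_fn <- function(pts) angle_score(pts) + 1e4 * proximal_violation(pts)
    note <- "distal-side constraint relaxed to penalty"
  } else {
    score_fn <- function(pts) angle_score(pts) + 1e6 * proximal_violation(pts)
    note <- NA_character_
  }
  pos <- scan_circle(e2, axis, config$circle_radius, score_fn)
  list(position = pos, note = note)
}

#' Two-cysteine (CC) zinc placement
#'
#' Places the zinc on the circle of radius 1.2 Angstrom around the SG--SG
#' midpoint, perpendicular to the SG--SG segment, at the point minimising
#' the squared deviation of both Zn-SG-CB angles from 109 degrees; points on
#' the CB side of either SG are rejected to avoid clashes.
#'
#' @param site One site row (with `ligands` list-column) or a ligand tibble.
#' @param structure The atom tibble the site came from (supplies CB atoms).
#' @param config A [prediction_config()].
#' @return A list with `position` (length-3 numeric), `strategy` and `note`.
#' @export
place_cc <- function(site, structure, config = prediction_config()) {
  lig <- site_ligands(site)
  res <- place_pair_circle(lig, structure, config)
  list(position = res$position, strategy = "a", note = res$note)
}

#' Cysteine--histidine (CH) zinc placement
#'
#' As [place_cc()], with the histidine angular target taken from
#' [angle_targets()] for the coordinating ring atom (100 degrees via ND1,
#' 155 via NE2).
#'
#' @inheritParams place_cc
#' @return A list with `position`, `strategy`, `note`.
#' @export
place_ch <- function(site, structure, config = prediction_config()) {
  lig <- site_ligands(site)
  his <- lig[lig$residue_kind == "HIS", ]
  for (i in seq_len(nrow(his))) {
    res <- res_atoms_of(structure, his$chain[i], his$resseq[i], his$icode[i])
    if (!all(HIS_RING_ROLES %in% res$atom)) {
      abort("placement error: histidine ring atoms missing")
    }
  }
  res <- place_pair_circle(lig, structure, config)
  list(position = res$position, strategy = "b", note = res$note)
}

#' Imidazole ring centroid
#'
#' Unweighted mean of the five ring atoms (CG, ND1, CD2, CE1, NE2) of a
#' histidine residue.
#'
#' @param res Atom tibble of one histidine residue.
#' @return Length-3 numeric centroid.
#' @export
ring_centroid <- function(res) {
  ring <- res[res$atom %in% HIS_RING_ATOMS, ]
  if (nrow(ring) < 5) abort("placement error: incomplete imidazole ring")
  c(mean(ring$x), mean(ring$y), mean(ring$z))
}

# Candidate zinc positions of one histidine ring: for each eligible ring
# atom, a point at `bond_length` from that atom along the centroid-to-atom
# ray (the lone-pair direction).
ring_candidates <- function(res, bond_length) {
  g <- ring_centroid(res)
  t(vapply(HIS_RING_ROLES, function(role) {
    p <- atom_position(res, role)
    if (is.null(p)) abort("placement error: incomplete imidazole ring")
    p + bond_length * vunit(p - g)
  }, numeric(3)))
}

#' Two-histidine (HH) zinc placement
#'
#' For each ring, four candidate zincs are generated on the centroid-to-atom
#' rays at the coordination bond length (2.1 Angstrom) beyond each eligible
#' ring atom; the closest cross-ring candidate pair is found and its
#' midpoint returned.
#'
#' @inheritParams place_cc
#' @return A list with `position`, `strategy`, `note`.
#' @export
place_hh <- function(site, structure, config = prediction_config()) {
  lig <- site_ligands(site)
  res1 <- res_atoms_of(structure, lig$chain[1], lig$resseq[1], lig$icode[1])
  res2 <- res_atoms_of(structure, lig$chain[2], lig$resseq[2], lig$icode[2])
  z <- ring_candidates(res1, config$bond_length)
  y <- ring_candidates(res2, config$bond_length)
  d <- sqrt(outer(z[, 1], y[, 1], "-")^2 + outer(z[, 2], y[, 2], "-")^2 +
              outer(z[, 3], y[, 3], "-")^2)
  idx <- which(d == min(d), arr.ind = TRUE)[1, ]
  list(
    position = (z[idx[1], ] + y[idx[2], ]) / 2,
    strategy = "c", note = NA_character_
  )
}

#' Three-histidine (HHH) zinc placement
#'
#' Applies the two-histidine strategy to each of the three His pairs and
#' returns the mean of the three pairwise placements.
#'
#' @inheritParams place_cc
#' @return A list with `position`, `strategy`, `note`.
#' @export
place_hhh <- function(site, structure, config = prediction_config()) {
  lig <- site_ligands(site)
  pairs <- utils::combn(3, 2, simplify = FALSE)
  pts <- lapply(pairs, function(p) {
    place_hh(lig[p, ], structure, config)$position
  })
  list(
    position = Reduce(`+`, pts) / 3,
    strategy = "d", note = NA_character_
  )
}

#' Mixed-composition CH3 zinc placement
#'
#' Places each of the three ligand pairs with the matching two-residue
#' strategy (CC, CH or HH), then takes a 2-of-3 majority vote: the pair of
#' pairwise candidates with the smallest mutual distance wins (cysteines are
#' more likely than histidines to sit in a rotamer unsuited to coordination,
#' so the outlier candidate is discarded) and the midpoint of the winning
#' pair is returned.
#'
#' @inheritParams place_cc
#' @return A list with `position`, `strategy`, `note`.
#' @export
place_ch3_mixed <- function(site, structure, config = prediction_config()) {
  lig <- site_ligands(site)
  pairs <- utils::combn(3, 2, simplify = FALSE)
  pts <- lapply(pairs, function(p) {
    sub <- lig[p, ]
    kind <- classify_subgroup(sub$residue_kind)
    switch(kind,
      CC = place_cc(sub, structure, config)$position,
      CH = place_ch(sub, structure, config)$position,
      HH = place_hh(sub, structure, config)$position
    )
  })
  d <- c(
    vdist(pts[[1]], pts[[2]]),
    vdist(pts[[1]], pts[[3]]),
    vdist(pts[[2]], pts[[3]])
  )
  winner <- list(c(1, 2), c(1, 3), c(2, 3))[[which.min(d)]]
  list(
    position = (pts[[winner[1]]] + pts[[winner[2]]]) / 2,
    strategy = "e", note = NA_character_
  )
}

#' Four-residue (CH4) zinc placement
#'
#' The centre (unweighted mean) of the four chosen coordinating atoms.
#'
#' @inheritParams place_cc
#' @return A list with `position`, `strategy`, `note`.
#' @export
place_ch4 <- function(site, structure, config = prediction_config()) {
  lig <- site_ligands(site)
  list(
    position = c(mean(lig$x), mean(lig$y), mean(lig$z)),
    strategy = "f", note = NA_character_
  )
}

site_ligands <- function(site) {
  has_lig <- if (is.data.frame(site)) "ligands" %in% names(site) else !is.null(site$ligands)
  if (has_lig) {
    lig <- if (is.data.frame(site$ligands)) site$ligands else site$ligands[[1]]
  } else {
    lig <- site
  }
  as_tibble(lig)
}

#' Place zinc ions for candidate sites
#'
#' Dispatches every candidate site to its subgroup-specific placement
#' strategy (a: CC, b: CH, c: HH, d: HHH, e: mixed CH3, f: CH4) and appends
#' the deduced zinc coordinates.
#'
#' @param sites Site tibble from [enumerate_sites()].
#' @param structure The atom tibble the sites came from.
#' @param config A [prediction_config()].
#' @return `sites` with columns `zn_x`, `zn_y`, `zn_z`, `strategy` and
#'   `placement_note` added.
#' @export
place_zinc <- function(sites, structure, config = prediction_config()) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0) {
    sites$zn_x <- numeric(0)
    sites$zn_y <- numeric(0)
    sites$zn_z <- numeric(0)
    sites$strategy <- character(0)
    sites$placement_note <- character(0)
    return(sites)
  }
  res <- lapply(seq_len(nrow(sites)), function(i) {
    row <- sites[i, ]
    if (is.na(row$subgroup)) abort("site must be classified before placement")
    switch(row$subgroup,
      CC = place_cc(row, structure, config),
      CH = place_ch(row, structure, config),
      HH = place_hh(row, structure, config),
      HHH = place_hhh(row, structure, config),
      CH3_mixed = place_ch3_mixed(row, structure, config),
      CH4 = place_ch4(row, structure, config),
      abort(paste("unknown subgroup:", row$subgroup))
    )
  })
  sites$zn_x <- map_dbl(res, ~ .x$position[1])
  sites$zn_y <- map_dbl(res, ~ .x$position[2])
  sites$zn_z <- map_dbl(res, ~ .x$position[3])
  sites$strategy <- vapply(res, function(r) r$strategy, character(1))
  sites$placement_note <- vapply(res, function(r) {
    if (is.null(r$note)) NA_character_ else r$note
  }, character(1))
  sites
}
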