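# A fine independent scan of the locus circle (no golden-section step),
# used as the exhaustive oracle for the two-ligand strategies.
oracle_circle_scan <- function(struct, site, config = prediction_config(),
                               n = 36000) {
  lig <- site$ligands[[1]]
  donors <- lapply(1:2, function(i) c(lig$x[i], lig$y[i], lig$z[i]))
  cbs <- lapply(1:2, function(i) {
    res <- struct[struct$chain == lig$chain[i] & struct$resseq == lig$resseq[i] &
                    !struct$is_hetero, ]
    cbrow <- res[res$atom == "CB", ]
    c(cbrow$x, cbrow$y, cbrow$z)
  })
  e2 <- (donors[[1]] + donors[[2]]) / 2
  axis <- (donors[[2]] - donors[[1]])
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w1 <- ref - sum(ref * axis) * axis
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(
    axis[2] * w1[3] - axis[3] * w1[2],
    axis[3] * w1[1] - axis[1] * w1[3],
    axis[1] * w1[2] - axis[2] * w1[1]
  )
  targets <- config$targets[lig$atom_role]
  best <- NULL
  best_score <- Inf
  for (theta in seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]) {
    p <- e2 + config$circle_radius * (cos(theta) * w1 + sin(theta) * w2)
    ok <- TRUE
    score <- 0
    for (i in 1:2) {
      u <- p - donors[[i]]
      v <- cbs[[i]] - donors[[i]]
      if (sum(u * v) > 0) ok <- FALSE
      ang <- acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      score <- score + (ang - targets[i])^2
    }
    if (ok && score < best_score) {
      best_score <- score
      best <- p
    }
  }
  best
}

placed_for <- function(fx, config = prediction_config()) {
  sites <- enumerate_sites(coordinating_atoms(fx$structure),
                           window = config$distance_window)
  place_zinc(sites, fx$structure, config)
}

recovery_error <- function(fx, config = prediction_config()) {
  pl <- placed_for(fx, config)
  expect_gt(nrow(pl), 0)
  min(sqrt((pl$zn_x - fx$zinc[1])^2 + (pl$zn_y - fx$zinc[2])^2 +
             (pl$zn_z - fx$zinc[3])^2))
}

test_that("every strategy recovers the true zinc within 0.15 A on noise-free fixtures", {
  for (sg in c("CC", "CH", "HH", "HHH", "CH3_mixed", "CH4")) {
    sep <- if (sg %in% c("CC", "CH", "HH")) tetra_sep() else 3.6
    fx <- make_site_structure(sg, ligand_separation = sep, shell = FALSE,
                              include_zinc = FALSE)
    expect_lt(recovery_error(fx), 0.15, label = sg)
  }
})

test_that("two-ligand placements agree with an exhaustive circle scan", {
  for (sg in c("CC", "CH")) {
    fx <- make_site_structure(sg, ligand_separation = tetra_sep(),
                              shell = FALSE, include_zinc = FALSE)
    pl <- placed_for(fx)
    pl <- pl[pl$subgroup == sg, ]
    oracle <- oracle_circle_scan(fx$structure, pl[1, ])
    got <- c(pl$zn_x[1], pl$zn_y[1], pl$zn_z[1])
    expect_lt(sqrt(sum((got - oracle)^2)), 0.05, label = sg)
  }
})

test_that("mirror-symmetric CC fixtures place the zinc in the symmetry plane", {
  fx <- make_site_structure("CC", ligand_separation = tetra_sep(),
                            shell = FALSE, include_zinc = FALSE)
  pl <- placed_for(fx)
  # fixture is mirror-symmetric about x = 0
  expect_lt(abs(pl$zn_x[1]), 1e-6)
})

test_that("locus points proximal to a CB are rejected (distal-side rule)", {
  fx <- make_site_structure("CC", ligand_separation = tetra_sep(),
                            shell = FALSE, include_zinc = FALSE)
  pl <- placed_for(fx)
  s <- fx$structure
  lig <- pl$ligands[[1]]
  p <- c(pl$zn_x[1], pl$zn_y[1], pl$zn_z[1])
  for (i in 1:2) {
    res <- s[s$chain == lig$chain[i] & s$resseq == lig$resseq[i], ]
    sg <- unlist(res[res$atom == "SG", c("x", "y", "z")])
    cb <- unlist(res[res$atom == "CB", c("x", "y", "z")])
    expect_lt(sum((p - sg) * (cb - sg)), 0)
  }
})

test_that("ring_centroid is the pentagon centre, translation-equivariant", {
  fx <- make_site_structure("HH", shell = FALSE, include_zinc = FALSE)
  res <- fx$structure[fx$structure$resseq == 10, ]
  g <- ring_centroid(res)
  ring <- res[res$atom %in% c("CG", "ND1", "CD2", "CE1", "NE2"), ]
  rc <- sqrt((ring$x - g[1])^2 + (ring$y - g[2])^2 + (ring$z - g[3])^2)
  # circumradius of a regular pentagon with 1.37 A edges
  expect_equal(rc, rep(1.37 / (2 * sin(36 * pi / 180)), 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  shifted <- res
  shifted$x <- shifted$x + 3
  expect_equal(ring_centroid(shifted), g + c(3, 0, 0), tolerance = 1e-12)
  expect_error(ring_centroid(res[res$atom != "CG", ]), "ring")
})

test_that("HH rays intersecting at a common point recover it exactly", {
  fx <- make_site_structure("HH", shell = FALSE, include_zinc = FALSE)
  pl <- placed_for(fx)
  # construction guarantees both NE2 rays pass through the origin at 2.1 A
  expect_lt(sqrt(pl$zn_x^2 + pl$zn_y^2 + pl$zn_z^2)[1], 1e-9)
  lig <- pl$ligands[[1]]
  d <- sqrt(lig$x^2 + lig$y^2 + lig$z^2)
  expect_equal(d, rep(2.1, 2), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("HHH placement averages the three pairwise placements", {
  fx <- make_site_structure("HHH", shell = FALSE, include_zinc = FALSE)
  sites <- enumerate_sites(coordinating_atoms(fx$structure))
  site <- sites[sites$subgroup == "HHH", ][1, ]
  lig <- site$ligands[[1]]
  pts <- lapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p) {
    place_hh(lig[p, ], fx$structure)$position
  })
  by_hand <- Reduce(`+`, pts) / 3
  got <- place_hhh(site, fx$structure)$position
  expect_equal(got, by_hand, tolerance = 1e-12)
})

test_that("CH3 majority vote takes the midpoint of the two closest candidates", {
  fx <- make_site_structure("CH3_mixed", shell = FALSE, include_zinc = FALSE)
  sites <- enumerate_sites(coordinating_atoms(fx$structure))
  site <- sites[sites$subgroup == "CH3_mixed", ][1, ]
  got <- place_ch3_mixed(site, fx$structure)$position
  # displace one Cys rotamer: the outlier pairwise candidate must be ignored
  s2 <- fx$structure
  cys_rows <- s2$res_name == "CYS" & s2$atom %in% c("CB", "SG")
  s2$x[cys_rows] <- s2$x[cys_rows] + 1.2
  sites2 <- enumerate_sites(coordinating_atoms(s2))
  sites2 <- sites2[sites2$subgroup %in% c("CH3_mixed", "HH"), ]
  if (any(sites2$subgroup == "CH3_mixed")) {
    site2 <- sites2[sites2$subgroup == "CH3_mixed", ][1, ]
    moved <- place_ch3_mixed(site2, s2)$position
    # the HH pair is untouched, so the vote should stay near the HH candidate
    hh_cand <- place_hh(site$ligands[[1]][2:3, ], fx$structure)$position
    expect_lt(sqrt(sum((moved - hh_cand)^2)), sqrt(sum((moved - got)^2)) + 1)
  }
  expect_equal(length(got), 3)
})

test_that("CH4 placement is the centroid of the four coordinating atoms", {
  lig <- tibble::tibble(
    chain = "A", resseq = 1:4, icode = "", res_name = "CYS",
    residue_kind = "CYS", atom = "SG", atom_role = "SG",
    x = c(1, 1, -1, -1), y = c(1, -1, 1, -1), z = c(1, -1, -1, 1)
  )
  got <- place_ch4(lig, NULL)$position
  expect_equal(got, c(0, 0, 0))
})

test_that("placements are rigid-motion equivariant to 1e-6 A", {
  r <- random_rotation(31)
  tr <- c(7.5, -3.2, 11)
  for (sg in c("CC", "HH", "HHH", "CH3_mixed", "CH4")) {
    sep <- if (sg %in% c("CC", "CH", "HH")) tetra_sep() else 3.6
    fx <- make_site_structure(sg, ligand_separation = sep, shell = FALSE,
                              include_zinc = FALSE)
    pl <- placed_for(fx)
    moved <- transform_structure(fx$structure, r, tr)
    pl2 <- place_zinc(enumerate_sites(coordinating_atoms(moved)), moved)
    expect_equal(nrow(pl2), nrow(pl))
    for (i in seq_len(nrow(pl))) {
      expected <- as.numeric(r %*% c(pl$zn_x[i], pl$zn_y[i], pl$zn_z[i]) + tr)
      got <- c(pl2$zn_x[i], pl2$zn_y[i], pl2$zn_z[i])
      expect_lt(sqrt(sum((got - expected)^2)), 1e-6, label = sg)
    }
  }
})

test_that("place_zinc dispatches each subgroup to its strategy", {
  strategies <- c(
    CC = "a", CH = "b", HH = "c", HHH = "d", CH3_mixed = "e", CH4 = "f"
  )
  for (sg in names(strategies)) {
    sep <- if (sg %in% c("CC", "CH", "HH")) tetra_sep() else 3.6
    fx <- make_site_structure(sg, ligand_separation = sep, shell = FALSE,
                              include_zinc = FALSE)
    pl <- placed_for(fx)
    expect_true(strategies[[sg]] %in% pl$strategy[pl$subgroup == sg],
                label = sg)
  }
})
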