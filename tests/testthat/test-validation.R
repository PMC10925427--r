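sphere_from <- function(valence, dirs, occupancy = 1, b_factor = 20) {
  tibble::tibble(
    chain = "A", resseq = seq_len(nrow(dirs)), icode = "",
    res_name = "CYS", atom = "SG", element = "S",
    distance = 2.1, valence = valence,
    ux = dirs[, 1], uy = dirs[, 2], uz = dirs[, 3],
    occupancy = occupancy, b_factor = b_factor
  )
}

two_dirs_109 <- function() {
  th <- 109.47122 * pi / 180
  rbind(c(0, 0, 1), c(sin(th), 0, cos(th)))
}

test_that("bond valence follows the exponential with tabulated parameters", {
  expect_equal(bond_valence(2.09, "S"), 1.0)
  expect_equal(bond_valence(2.30, "S"), exp((2.09 - 2.30) / 0.37))
  expect_equal(bond_valence(2.30, "S"), 0.56690, tolerance = 1e-4)
  expect_equal(bond_valence(2.10, "N"), exp((1.77 - 2.10) / 0.37))
  expect_equal(bond_valence(2.10, "N"), 0.40988, tolerance = 1e-4)
  expect_error(bond_valence(2.0, "P"), "parameters")
  expect_error(bond_valence(-1, "S"), "distance")
})

test_that("q_valence is the symmetric ratio to the oxidation state", {
  expect_equal(q_valence(c(1, 1), 2), 1.0)
  expect_equal(q_valence(c(0.5, 0.5), 2), 0.5)   # two-ligand optimum
  expect_equal(q_valence(c(1, 1, 1, 1), 2), 0.5) # overbonded mirror case
  expect_equal(q_valence(numeric(0), 2), 0)
  expect_error(q_valence(c(-0.1), 2), "valences")
})

test_that("q_completeness reproduces the two-ligand values under both normalizations", {
  sph <- sphere_from(c(0.5, 0.5), two_dirs_109())
  resultant <- 2 * 0.5 * cos(109.47122 / 2 * pi / 180)
  expect_equal(resultant, 0.5774, tolerance = 1e-4)
  expect_equal(q_completeness(sph, "valence_sum"), 1 - resultant / 1)
  expect_equal(q_completeness(sph, "oxidation_state", v_ox = 2),
               1 - resultant / 2)
  expect_equal(round(q_completeness(sph, "oxidation_state", v_ox = 2), 2), 0.71)
  # perfect tetrahedral cancellation
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  expect_equal(q_completeness(sphere_from(rep(0.5, 4), tet), "valence_sum"), 1.0)
  expect_error(q_completeness(sph[0, ]), "donor")
})

test_that("q_environment combines occupancy and B-factor agreement", {
  dirs <- two_dirs_109()
  expect_equal(q_environment(1, 20, sphere_from(c(0.5, 0.5), dirs, 1, 20)), 1.0)
  expect_equal(q_environment(1, 30, sphere_from(c(0.5, 0.5), dirs, 1, 15)), 0.5)
  # reduced metal occupancy: both factors engage (direct evaluation of the
  # adopted ratio-of-products form)
  expect_equal(q_environment(0.4, 20, sphere_from(c(0.5, 0.5), dirs, 1, 20)),
               min(2 * 0.4, 1) * min(0.4, 1 / 0.4))
  expect_error(q_environment(0, 20, sphere_from(c(0.5, 0.5), dirs)), "o_m")
})

test_that("coordination_sphere collects one closest N/O/S donor per residue", {
  fx <- make_site_structure("CH4", bond_length = 2.3, shell = FALSE,
                            include_zinc = FALSE)
  sph <- coordination_sphere(fx$structure, c(0, 0, 0))
  expect_equal(nrow(sph), 4)
  expect_equal(sph$valence, rep(bond_valence(2.3, "S"), 4), tolerance = 1e-9)
  # no donors in an empty region
  expect_equal(nrow(coordination_sphere(fx$structure, c(50, 50, 50))), 0)
  # carbon atoms are never donors
  carbon <- as_structure(tibble::tibble(
    atom = "CB", res_name = "ALA", chain = "A", resseq = 1L,
    x = 2, y = 0, z = 0, element = "C"
  ))
  expect_equal(nrow(coordination_sphere(carbon, c(0, 0, 0))), 0)
  # His contributes only its closest ring nitrogen
  hh <- make_site_structure("HH", shell = FALSE, include_zinc = FALSE)
  sph_hh <- coordination_sphere(hh$structure, c(0, 0, 0))
  expect_equal(nrow(sph_hh), 2)
  expect_true(all(sph_hh$atom == "NE2"))
})

test_that("validate_site applies coordination-number-dependent thresholds", {
  ideal <- make_site_structure("CH4", bond_length = 2.3, shell = FALSE)
  v <- validate_site(ideal$structure, c(0, 0, 0))
  s_tot <- 4 * bond_valence(2.3, "S")
  expect_equal(v$q_valence, min(s_tot / 2, 2 / s_tot))
  expect_equal(v$q_completeness, 1, tolerance = 1e-6)
  expect_equal(v$q_environment, 1, tolerance = 1e-6)
  expect_true(v$passed)

  # two-ligand thresholds are looser: a site just above them passes
  two <- make_site_structure("CC", ligand_separation = tetra_sep(2.45),
                             bond_length = 2.45, shell = FALSE)
  v2 <- validate_site(two$structure, c(0, 0, 0))
  expect_equal(v2$n_ligands, 2L)
  expect_true(v2$q_valence > 0.25 && v2$q_valence < 0.5)
  expect_true(v2$q_completeness > 0.355)
  expect_true(v2$passed)

  # single donor never passes
  one <- make_decoy_structure("sparse")$structure
  sg <- one[one$atom == "SG", ]
  v1 <- validate_site(one, c(sg$x + 2.1, sg$y, sg$z))
  expect_false(v1$passed)
})

test_that("validation scores stay in [0,1] under randomized geometries", {
  set.seed(99)
  for (trial in 1:1000) {
    n <- sample(2:6, 1)
    dirs <- matrix(rnorm(3 * n), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    sph <- sphere_from(
      runif(n, 0.05, 1.5), dirs,
      occupancy = runif(n, 0.3, 1), b_factor = runif(n, 5, 80)
    )
    qv <- q_valence(sph$valence, 2)
    qc <- q_completeness(sph, sample(c("valence_sum", "oxidation_state"), 1))
    qe <- q_environment(runif(1, 0.2, 1), runif(1, 5, 80), sph)
    expect_true(qv >= 0 && qv <= 1)
    expect_true(qc >= 0 && qc <= 1)
    expect_true(qe >= 0 && qe <= 1)
  }
})

test_that("q_completeness is rotation-invariant and q_valence permutation-invariant", {
  set.seed(5)
  dirs <- matrix(rnorm(9), 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  val <- c(0.3, 0.7, 0.5)
  sph <- sphere_from(val, dirs)
  r <- random_rotation(11)
  rot <- sphere_from(val, dirs %*% t(r))
  expect_equal(q_completeness(sph), q_completeness(rot), tolerance = 1e-10)
  perm <- sample(3)
  expect_equal(q_valence(val, 2), q_valence(val[perm], 2))
})

test_that("moving a donor radially outward never increases the valence sum", {
  base <- bond_valence(seq(2.0, 2.5, by = 0.05), "S")
  expect_true(all(diff(base) < 0))
})
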