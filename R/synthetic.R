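TETRA_DIRS <- rbind(
  c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)
) / sqrt(3)

# In-plane unit vector orthogonal to u, horizontal where possible (gives
# mirror-symmetric side-chain placement for two-ligand fixtures).
frame_w <- function(u) {
  h <- c(u[1], u[2], 0)
  if (vnorm(h) < 1e-9) return(perp_vector(u))
  h <- vunit(h)
  w <- h - sum(h * u) * u
  if (vnorm(w) < 1e-9) return(perp_vector(u))
  vunit(w)
}

# Ideal cysteine around a zinc at the origin: SG on direction u at the bond
# length, CB at 1.81 A from SG with a Zn-SG-CB angle of 109 degrees.
build_cys <- function(u, bond, chain, resseq) {
  w <- frame_w(u)
  v2 <- vunit(pracma_cross(u, w))
  ang <- 109 * pi / 180
  dvec <- cos(ang) * (-u) + sin(ang) * w
  sg <- bond * u
  cb <- sg + 1.81 * dvec
  t_ca <- cos(70 * pi / 180) * dvec + sin(70 * pi / 180) * v2
  ca <- cb + 1.53 * t_ca
  n <- ca + 1.46 * vunit(0.3 * dvec + 0.95 * v2)
  tibble(
    atom = c("N", "CA", "CB", "SG"),
    res_name = "CYS", chain = chain, resseq = resseq,
    x = c(n[1], ca[1], cb[1], sg[1]),
    y = c(n[2], ca[2], cb[2], sg[2]),
    z = c(n[3], ca[3], cb[3], sg[3]),
    element = c("N", "C", "C", "S")
  )
}

# Ideal histidine around a zinc at the origin: the coordinating ring atom
# (`role`) sits on direction u at the bond length and the ring centroid lies
# behind it on the same ray, so the centroid-to-atom lone-pair direction
# points exactly at the zinc. Regular pentagon with 1.37 A ring bonds.
build_his <- function(u, bond, chain, resseq, role = "NE2") {
  rc <- 1.37 / (2 * sin(36 * pi / 180))
  w <- frame_w(u)
  g <- (bond + rc) * u
  order_from <- function(start) {
    ring <- c("CG", "ND1", "CE1", "NE2", "CD2")  # cyclic: CG-ND1-CE1-NE2-CD2-CG
    cyc <- c("CG", "ND1", "CE1", "NE2", "CD2")
    i <- match(start, cyc)
    idx <- ((i - 1 + 0:4) %% 5) + 1
    cyc[idx]
  }
  names_cyc <- order_from(role)
  phi <- (0:4) * 72 * pi / 180
  pts <- lapply(phi, function(p) g + rc * (cos(p) * (-u) + sin(p) * w))
  ring <- tibble(
    atom = names_cyc,
    x = vapply(pts, `[`, numeric(1), 1),
    y = vapply(pts, `[`, numeric(1), 2),
    z = vapply(pts, `[`, numeric(1), 3)
  )
  cg <- unlist(ring[ring$atom == "CG", c("x", "y", "z")])
  cb <- cg + 1.50 * vunit(cg - g)
  v2 <- vunit(pracma_cross(u, w))
  ca <- cb + 1.53 * vunit(vunit(cb - g) + 0.8 * v2)
  n <- ca + 1.46 * v2
  out <- bind_rows(
    tibble(
      atom = c("N", "CA", "CB"),
      x = c(n[1], ca[1], cb[1]), y = c(n[2], ca[2], cb[2]),
      z = c(n[3], ca[3], cb[3])
    ),
    ring
  )
  out$res_name <- "HIS"
  out$chain <- chain
  out$resseq <- resseq
  out$element <- substr(out$atom, 1, 1)
  out
}

shell_points <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Surrounding atom shell giving a site-like (hydrophilic inner, carbon
# outer) or inverted hydrophobicity environment.
build_shell <- function(inverted = FALSE, start_resseq = 500, chain = "S") {
  r_carbon <- if (inverted) 3.2 else 5.9
  r_polar <- if (inverted) 6.0 else 3.3
  carbons <- shell_points(40, r_carbon)
  polars <- shell_points(6, r_polar)
  bind_rows(
    tibble(
      atom = "CB", res_name = "ALA", chain = chain,
      resseq = start_resseq + seq_len(nrow(carbons)) - 1L,
      x = carbons[, 1], y = carbons[, 2], z = carbons[, 3], element = "C"
    ),
    tibble(
      atom = "O", res_name = "GLY", chain = chain,
      resseq = start_resseq + 100L + seq_len(nrow(polars)) - 1L,
      x = polars[, 1], y = polars[, 2], z = polars[, 3], element = "O"
    )
  )
}

subgroup_kinds <- function(subgroup) {
  switch(subgroup,
    CC = c("CYS", "CYS"),
    CH = c("CYS", "HIS"),
    HH = c("HIS", "HIS"),
    HHH = c("HIS", "HIS", "HIS"),
    CH3_mixed = c("CYS", "HIS", "HIS"),
    CH4 = c("CYS", "CYS", "CYS", "CYS"),
    abort(paste("unknown subgroup:", subgroup))
  )
}

#' Generate a synthetic coordination-site structure
#'
#' Builds chemically plausible cysteine and/or histidine residues arranged
#' so the requested coordination geometry holds exactly around a known zinc
#' position at the origin: donors at the coordination bond length, ligand
#' pairs at the requested separation (two-residue sites) or ideal
#' tetrahedral directions (three/four residues), histidine imidazoles as
#' regular pentagons whose lone-pair rays point at the zinc. Optional
#' Gaussian positional noise and a surrounding hydrophobicity shell
#' (hydrophilic atoms inside, carbons outside) make the fixtures suitable
#' for every pipeline stage.
#'
#' @param subgroup One of `"CC"`, `"CH"`, `"HH"`, `"HHH"`, `"CH3_mixed"`,
#'   `"CH4"`.
#' @param bond_length Zinc--donor distance (default 2.1 Angstrom).
#' @param ligand_separation Donor--donor distance for two-residue sites
#'   (default 3.6 Angstrom, the empirical mean; ignored for 3/4-residue
#'   sites whose tetrahedral geometry fixes it).
#' @param noise_sd Per-coordinate Gaussian noise (Angstrom).
#' @param shell Add the surrounding hydrophobicity shell.
#' @param include_zinc Record the true zinc as a hetero atom (ground truth
#'   for evaluation fixtures).
#' @param his_role Ring atom through which histidines coordinate.
#' @param chain Chain identifier for the ligand residues; pass two values
#'   to build a cross-chain (interface) site.
#' @param seed Seed for the noise.
#' @return A list: `structure` (atom tibble), `zinc` (true position),
#'   `residues` (ligand residue table), `subgroup`.
#' @export
make_site_structure <- function(subgroup, bond_length = 2.1,
                                ligand_separation = 3.6, noise_sd = 0,
                                shell = TRUE, include_zinc = TRUE,
                                his_role = "NE2", chain = "A", seed = 1) {
  kinds <- subgroup_kinds(subgroup)
  n <- length(kinds)
  if (n == 2) {
    half <- asin(min(1, (ligand_separation / 2) / bond_length))
    dirs <- rbind(
      c(sin(half), 0, cos(half)),
      c(-sin(half), 0, cos(half))
    )
  } else {
    dirs <- TETRA_DIRS[seq_len(n), , drop = FALSE]
  }
  chains <- rep(chain, length.out = n)
  parts <- lapply(seq_len(n), function(i) {
    if (kinds[i] == "CYS") {
      build_cys(dirs[i, ], bond_length, chains[i], 10L * i)
    } else {
      build_his(dirs[i, ], bond_length, chains[i], 10L * i, role = his_role)
    }
  })
  atoms <- bind_rows(parts)
  if (shell) atoms <- bind_rows(atoms, build_shell(inverted = FALSE))
  if (noise_sd > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + rnorm(nrow(atoms), 0, noise_sd)
    atoms$y <- atoms$y + rnorm(nrow(atoms), 0, noise_sd)
    atoms$z <- atoms$z + rnorm(nrow(atoms), 0, noise_sd)
  }
  atoms$is_hetero <- FALSE
  if (include_zinc) {
    atoms <- bind_rows(atoms, tibble(
      atom = "ZN", res_name = "ZN", chain = "M", resseq = 900L,
      x = 0, y = 0, z = 0, element = "ZN", is_hetero = TRUE
    ))
  }
  list(
    structure = as_structure(atoms, id = paste0("synthetic_", subgroup)),
    zinc = c(0, 0, 0),
    residues = tibble(
      chain = chains, resseq = 10L * seq_len(n), res_name = kinds
    ),
    subgroup = subgroup
  )
}

#' Generate a decoy structure
#'
#' Decoys target the pipeline's exclusion rules: `"disulfide"` is a
#' cystine bridge (SG--SG about 2.05 Angstrom) that must yield no candidate
#' site; `"sparse"` is a lone cysteine; `"inverted_shell"` is a two-His
#' coordination geometry embedded in an inverted hydrophobicity environment
#' (carbons inside, polar atoms outside) that should be rejected by
#' verification.
#'
#' @param kind `"disulfide"`, `"sparse"` or `"inverted_shell"`.
#' @param seed Seed (reserved; decoys are deterministic).
#' @return A list with `structure` and `kind`.
#' @export
make_decoy_structure <- function(kind = c("disulfide", "sparse", "inverted_shell"),
                                 seed = 1) {
  kind <- match.arg(kind)
  atoms <- switch(kind,
    disulfide = bind_rows(
      build_cys(c(1, 0, 0), 1.025, "A", 10L),
      build_cys(c(-1, 0, 0), 1.025, "A", 20L)
    ),
    sparse = build_cys(c(0.6, 0.6, 0.529), 2.1, "A", 10L),
    inverted_shell = {
      half <- asin(min(1, (3.6 / 2) / 2.1))
      bind_rows(
        build_his(c(sin(half), 0, cos(half)), 2.1, "A", 10L),
        build_his(c(-sin(half), 0, cos(half)), 2.1, "A", 20L),
        build_shell(inverted = TRUE)
      )
    }
  )
  atoms$is_hetero <- FALSE
  list(
    structure = as_structure(atoms, id = paste0("decoy_", kind)),
    kind = kind
  )
}

#' Generate labelled synthetic feature sets
#'
#' Draws class-conditional 61-feature vectors mimicking the statistics of
#' real two-residue sites versus decoys: positives centre on the empirical
#' geometry (donor distance near 3.4 Angstrom, angles near the per-role
#' targets, a site-like hydrophobicity profile) with tight spread;
#' negatives are dispersed, with distorted angles and a flattened/inverted
#' profile. Subgroups are drawn with the empirical CC/CH/HH imbalance. The
#' two classes are separable by construction, so learner-recovery tests
#' have a known answer.
#'
#' @param n_pos,n_neg Class sizes (> 0).
#' @param seed Seed; the same seed reproduces the same table.
#' @return A tibble with `label` (1 = site, 0 = decoy), `subgroup`, and the
#'   61 feature columns of [feature_names()].
#' @export
make_labelled_features <- function(n_pos = 400, n_neg = 400, seed = 1) {
  stopifnot(n_pos > 0, n_neg > 0)
  set.seed(seed)
  roles <- c("SG", "ND1", "NE2", "CE1", "CD2")
  radii <- PROFILE_RADII
  draw <- function(n, positive) {
    subgroup <- sample(c("CC", "CH", "HH"), n, replace = TRUE,
                       prob = c(0.032, 0.137, 0.831))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      kinds <- switch(subgroup[i],
        CC = c("CYS", "CYS"), HH = c("HIS", "HIS"),
        CH = sample(c("CYS", "HIS"))
      )
      role <- ifelse(kinds == "CYS", "SG", sample(c("ND1", "NE2"), 2, replace = TRUE))
      target <- angle_targets()[role]
      onehot <- function(r) as.numeric(roles == r)
      if (positive) {
        geo <- c(
          rnorm(1, 3.4, 0.2), rnorm(1, 7.0, 0.8), rnorm(1, 5.5, 0.7),
          target[1] + 15 + rnorm(1, 0, 8), target[2] + 15 + rnorm(1, 0, 8),
          target[1] + rnorm(1, 0, 6), target[2] + rnorm(1, 0, 6)
        )
        cv <- 600 * stats::pnorm(radii, 5, 0.8) + rnorm(21, 0, 40)
        sv <- -5 + 13 * (radii - 2) / 5 + rnorm(21, 0, 1.5)
      } else {
        geo <- c(
          rnorm(1, 4.0, 0.5), rnorm(1, 8.5, 1.5), rnorm(1, 7.0, 1.3),
          target[1] + 15 + rnorm(1, 0, 30), target[2] + 15 + rnorm(1, 0, 30),
          target[1] + rnorm(1, 0, 30), target[2] + rnorm(1, 0, 30)
        )
        cv <- 100 - 300 * stats::pnorm(radii, 5, 1.2) + rnorm(21, 0, 60)
        sv <- 6 - 10 * (radii - 2) / 5 + rnorm(21, 0, 2)
      }
      rows[[i]] <- c(
        as.numeric(kinds[1] == "CYS"), onehot(role[1]),
        as.numeric(kinds[2] == "CYS"), onehot(role[2]),
        geo, cv, sv
      )
    }
    m <- do.call(rbind, rows)
    colnames(m) <- feature_names()
    out <- as_tibble(m)
    out$label <- as.integer(positive)
    out$subgroup <- subgroup
    out
  }
  out <- bind_rows(draw(n_pos, TRUE), draw(n_neg, FALSE))
  out[c("label", "subgroup", feature_names())]
}

#' Apply a rigid-body transform to a structure
#'
#' Utility for equivariance checks: rotates and translates every atom.
#'
#' @param structure Atom tibble.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric.
#' @return The transformed atom tibble.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure[c("x", "y", "z")]) %*% t(rotation)
  structure$x <- xyz[, 1] + translation[1]
  structure$y <- xyz[, 2] + translation[2]
  structure$z <- xyz[, 3] + translation[3]
  structure
}

#' Random rotation matrix
#'
#' @param seed Seed.
#' @return A 3x3 rotation matrix (determinant +1).
#' @export
random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
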