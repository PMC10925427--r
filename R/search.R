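HIS_RING_ROLES <- c("ND1", "NE2", "CE1", "CD2")
HIS_RING_ATOMS <- c("CG", "ND1", "CD2", "CE1", "NE2")

#' Candidate coordinating atoms
#'
#' Every side-chain atom eligible to coordinate zinc: SG from cysteine, and
#' ND1/NE2/CE1/CD2 from histidine (ring carbons are included because of
#' possible ring flips or mislabelling). Hetero records, waters and all
#' other residues are excluded; atoms from all selected chains are eligible
#' so protein-interface sites can be found.
#'
#' @param structure An atom tibble (alternate conformers should already be
#'   resolved with [primary_conformer()]).
#' @param chains Optional character vector of chain identifiers to search.
#' @return A tibble of eligible atoms with `residue_kind` and `atom_role`
#'   columns.
#' @export
coordinating_atoms <- function(structure, chains = NULL) {
  a <- structure[!structure$is_hetero, ]
  if (!is.null(chains)) a <- a[a$chain %in% chains, ]
  keep <- (a$res_name == "CYS" & a$atom == "SG") |
    (a$res_name == "HIS" & a$atom %in% HIS_RING_ROLES)
  a <- a[keep, ]
  a$residue_kind <- a$res_name
  a$atom_role <- a$atom
  a[c(
    "chain", "resseq", "icode", "res_name", "residue_kind", "atom",
    "atom_role", "x", "y", "z"
  )]
}

#' Disulfide test for a cysteine pair
#'
#' Two SG atoms closer than the disulfide cutoff are a disulfide bond, not a
#' metal site. The default cutoff 2.400 Angstrom is the upper confidence
#' bound of the disulfide SG--SG distance peak, see [disulfide_cutoff()].
#'
#' @param sg1,sg2 One-row atom tibbles (or lists) with `atom`, `x`, `y`,
#'   `z`; both must be SG atoms.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Logical flag.
#' @export
is_disulfide <- function(sg1, sg2, cutoff = disulfide_cutoff()) {
  if (!identical(sg1$atom, "SG") || !identical(sg2$atom, "SG")) {
    abort("is_disulfide expects two SG atoms")
  }
  vdist(c(sg1$x, sg1$y, sg1$z), c(sg2$x, sg2$y, sg2$z)) < cutoff
}

#' Disulfide distance cutoff
#'
#' Upper confidence bound of the disulfide SG--SG distance distribution,
#' \eqn{\mu + Z\sigma}: with the fitted peak (mean 2.058, sd 0.133 Angstrom)
#' and a two-tailed p = 0.01 Z-value of 2.575 this gives 2.400 Angstrom.
#'
#' @param mu,sigma Mean and standard deviation of the disulfide peak.
#' @param z Z-value of the confidence bound.
#' @return Cutoff in Angstrom.
#' @export
disulfide_cutoff <- function(mu = 2.058, sigma = 0.133, z = 2.575) {
  round(mu + z * sigma, 3)
}

#' Enumerate candidate zinc-binding sites
#'
#' Builds a residue-level compatibility graph over the eligible Cys/His
#' atoms: two residues are compatible when some allowed atom pair lies
#' within the distance window (and, for a Cys pair, is not a disulfide).
#' Fully compatible residue sets of size 2--4 are emitted; a residue set
#' that is a subset of an emitted larger set is suppressed, and cliques with
#' more than four residues contribute all their 4-subsets (downstream
#' certainty ranking and redundancy removal keep the best). For each site
#' one coordinating atom is chosen per residue (SG for Cys; for His the ring
#' atom minimising the summed distance to the other chosen atoms, iterated
#' to a fixed point), and the site is kept only if every pairwise
#' chosen-atom distance lies in the window.
#'
#' @param atoms Output of [coordinating_atoms()].
#' @param window Allowed inter-atom distance range (Angstrom).
#' @return A site tibble: `site_id`, `group` (CH2/CH3/CH4), `subgroup`,
#'   `cross_chain`, `n_residues` and a `ligands` list-column holding one
#'   chosen atom per residue.
#' @export
enumerate_sites <- function(atoms, window = c(2.4, 4.5)) {
  empty <- tibble(
    site_id = integer(), group = character(), subgroup = character(),
    cross_chain = logical(), n_residues = integer(), ligands = list()
  )
  if (nrow(atoms) == 0) return(empty)
  atoms$res_key <- residue_key(atoms$chain, atoms$resseq, atoms$icode)
  residues <- distinct(atoms[c("res_key", "residue_kind")])
  nres <- nrow(residues)
  if (nres < 2) return(empty)
  by_res <- split(atoms, atoms$res_key)[residues$res_key]

  compatible <- function(i, j) {
    ai <- by_res[[i]]
    aj <- by_res[[j]]
    d <- sqrt(outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
                outer(ai$z, aj$z, "-")^2)
    any(d >= window[1] & d <= window[2])
  }
  edges <- integer(0)
  for (i in seq_len(nres - 1)) {
    for (j in (i + 1):nres) {
      if (compatible(i, j)) edges <- c(edges, i, j)
    }
  }
  if (length(edges) == 0) return(empty)
  g <- igraph::make_graph(edges, n = nres, directed = FALSE)
  cliques <- igraph::max_cliques(g, min = 2)
  sets <- list()
  for (cl in cliques) {
    cl <- sort(as.integer(cl))
    if (length(cl) <= 4) {
      sets[[length(sets) + 1]] <- cl
    } else {
      subs <- utils::combn(cl, 4, simplify = FALSE)
      sets <- c(sets, subs)
    }
  }
  sets <- unique(sets)

  rows <- list()
  for (set in sets) {
    lig <- choose_site_atoms(by_res[set])
    if (is.null(lig)) next
    d <- as.matrix(stats::dist(lig[c("x", "y", "z")]))
    offd <- d[upper.tri(d)]
    if (any(offd < window[1]) || any(offd > window[2])) next
    kinds <- sort(lig$residue_kind)
    rows[[length(rows) + 1]] <- tibble(
      group = paste0("CH", nrow(lig)),
      subgroup = classify_subgroup(lig$residue_kind),
      cross_chain = length(unique(lig$chain)) > 1,
      n_residues = nrow(lig),
      ligands = list(lig[order(lig$chain, lig$resseq, lig$icode), ])
    )
  }
  if (length(rows) == 0) return(empty)
  out <- bind_rows(rows)
  out$site_id <- seq_len(nrow(out))
  out[c("site_id", "group", "subgroup", "cross_chain", "n_residues", "ligands")]
}

# One coordinating atom per residue: SG for Cys; for His start from the ring
# atom closest to the other residues and iterate the minimising choice to a
# fixed point (at most 3 passes).
choose_site_atoms <- function(res_atoms) {
  k <- length(res_atoms)
  centers <- t(vapply(res_atoms, function(a) c(mean(a$x), mean(a$y), mean(a$z)),
                      numeric(3)))
  pick <- integer(k)
  for (i in seq_len(k)) {
    a <- res_atoms[[i]]
    if (a$residue_kind[1] == "CYS") {
      idx <- which(a$atom_role == "SG")
      if (length(idx) == 0) return(NULL)
      pick[i] <- idx[1]
    } else {
      others <- centers[-i, , drop = FALSE]
      cost <- vapply(seq_len(nrow(a)), function(r) {
        sum(sqrt((others[, 1] - a$x[r])^2 + (others[, 2] - a$y[r])^2 +
                   (others[, 3] - a$z[r])^2))
      }, numeric(1))
      pick[i] <- which.min(cost)
    }
  }
  pos <- function() t(vapply(seq_len(k), function(i) {
    a <- res_atoms[[i]]
    c(a$x[pick[i]], a$y[pick[i]], a$z[pick[i]])
  }, numeric(3)))
  for (pass in 1:3) {
    changed <- FALSE
    p <- pos()
    for (i in seq_len(k)) {
      a <- res_atoms[[i]]
      if (a$residue_kind[1] == "CYS") next
      others <- p[-i, , drop = FALSE]
      cost <- vapply(seq_len(nrow(a)), function(r) {
        sum(sqrt((others[, 1] - a$x[r])^2 + (others[, 2] - a$y[r])^2 +
                   (others[, 3] - a$z[r])^2))
      }, numeric(1))
      best <- which.min(cost)
      if (best != pick[i]) {
        pick[i] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  bind_rows(lapply(seq_len(k), function(i) res_atoms[[i]][pick[i], ]))
}

#' Classify a candidate site into its subgroup
#'
#' Pairs are CC/CH/HH by residue kinds; triples are HHH or the mixed CH3
#' subgroup; quadruples are CH4.
#'
#' @param kinds Character vector of residue kinds (`"CYS"`/`"HIS"`), one per
#'   coordinating residue (2--4 entries).
#' @return Subgroup label: `"CC"`, `"CH"`, `"HH"`, `"HHH"`, `"CH3_mixed"`
#'   or `"CH4"`.
#' @export
classify_subgroup <- function(kinds) {
  n <- length(kinds)
  nc <- sum(kinds == "CYS")
  if (n == 2) {
    if (nc == 2) "CC" else if (nc == 1) "CH" else "HH"
  } else if (n == 3) {
    if (nc == 0) "HHH" else "CH3_mixed"
  } else if (n == 4) {
    "CH4"
  } else {
    abort("a candidate site has 2-4 residues")
  }
}
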