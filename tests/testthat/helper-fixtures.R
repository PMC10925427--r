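# Shared fixtures and independent oracles for the suite. Heavy objects
# (trained ensembles, reference curves) are built once per run and cached.

.cache <- new.env(parent = emptyenv())

tetra_sep <- function(bond = 2.1) 2 * bond * sin(109.47122 / 2 * pi / 180)

# A minimal structure of bare Cys residues (SG atoms only) at given SG
# positions -- enough for the candidate search.
bare_cys_structure <- function(sg_xyz, chain = "A") {
  n <- nrow(sg_xyz)
  as_structure(tibble::tibble(
    atom = "SG", res_name = "CYS", chain = chain,
    resseq = 10L * seq_len(n),
    x = sg_xyz[, 1], y = sg_xyz[, 2], z = sg_xyz[, 3], element = "S"
  ))
}

# Brute-force site enumeration oracle: all residue subsets of size 2-4 in
# which every residue pair has some eligible atom pair inside the window,
# with subsets of emitted (valid, size <= 4) supersets suppressed.
brute_force_sites <- function(atoms, window = c(2.4, 4.5)) {
  atoms$res_key <- paste(atoms$chain, atoms$resseq, atoms$icode)
  keys <- unique(atoms$res_key)
  n <- length(keys)
  by_res <- split(atoms, atoms$res_key)[keys]
  compat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      ai <- by_res[[i]]; aj <- by_res[[j]]
      d <- sqrt(outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
                  outer(ai$z, aj$z, "-")^2)
      compat[i, j] <- compat[j, i] <- any(d >= window[1] & d <= window[2])
    }
  }
  valid <- list()
  for (k in 2:min(4, n)) {
    for (set in utils::combn(n, k, simplify = FALSE)) {
      pairs <- utils::combn(set, 2, simplify = FALSE)
      if (all(vapply(pairs, function(p) compat[p[1], p[2]], logical(1)))) {
        valid[[length(valid) + 1]] <- set
      }
    }
  }
  keep <- vapply(seq_along(valid), function(i) {
    !any(vapply(seq_along(valid), function(j) {
      i != j && length(valid[[j]]) > length(valid[[i]]) &&
        all(valid[[i]] %in% valid[[j]])
    }, logical(1)))
  }, logical(1))
  lapply(valid[keep], function(set) sort(keys[set]))
}

site_keys <- function(sites) {
  lapply(sites$ligands, function(l) sort(paste(l$chain, l$resseq, l$icode)))
}

same_site_sets <- function(a, b) {
  norm <- function(x) sort(vapply(x, paste, character(1), collapse = "|"))
  identical(norm(a), norm(b))
}

# Exhaustive one-to-one assignment oracle for IoUR matching: the maximum
# number of pairs with IoUR >= threshold over all injective assignments.
brute_force_match_count <- function(p_sets, a_sets, threshold = 0.5) {
  np <- length(p_sets)
  na <- length(a_sets)
  m <- matrix(0, np, na)
  for (i in seq_len(np)) for (j in seq_len(na)) m[i, j] <- iour(p_sets[[i]], a_sets[[j]])
  best <- 0
  assign_next <- function(i, used, count) {
    if (i > np) {
      best <<- max(best, count)
      return(invisible())
    }
    assign_next(i + 1, used, count)
    for (j in seq_len(na)) {
      if (!used[j] && m[i, j] >= threshold) {
        used[j] <- TRUE
        assign_next(i + 1, used, count + 1)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1, rep(FALSE, na), 0)
  best
}

# Rank-based AUC, independent of the pROC implementation used internally.
rank_auc <- function(y, p) {
  r <- rank(p)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ensemble trained on the Gaussian labelled-feature generator (built once).
gauss_model <- function() {
  if (is.null(.cache$gauss_model)) {
    feats <- make_labelled_features(400, 400, seed = 2024)
    .cache$gauss_feats <- feats
    .cache$gauss_model <- train_ensemble(
      feats[feats$label == 1, ], feats[feats$label == 0, ], seed = 7
    )
  }
  .cache$gauss_model
}

gauss_feats <- function() {
  invisible(gauss_model())
  .cache$gauss_feats
}

# Feature rows encoded from generated structures (positives: noisy
# coordination fixtures; negatives: perturbed inverted-shell decoys).
encode_first_ch2 <- function(struct) {
  s <- enumerate_sites(coordinating_atoms(struct))
  s <- s[s$group == "CH2", ]
  if (nrow(s) == 0) return(NULL)
  pl <- place_zinc(s[1, ], struct)
  encode_features(pl, struct)
}

fixture_model <- function() {
  if (is.null(.cache$fixture_model)) {
    pos <- lapply(1:36, function(i) {
      sg <- c("CC", "CH", "HH")[1 + (i %% 3)]
      fx <- make_site_structure(
        sg, ligand_separation = 3.3 + 0.4 * ((i %% 5) / 4),
        noise_sd = 0.12, seed = i, include_zinc = FALSE
      )
      encode_first_ch2(fx$structure)
    })
    neg <- lapply(1:36, function(i) {
      st <- make_decoy_structure("inverted_shell")$structure
      set.seed(5000 + i)
      st$x <- st$x + rnorm(nrow(st), 0, 0.25)
      st$y <- st$y + rnorm(nrow(st), 0, 0.25)
      st$z <- st$z + rnorm(nrow(st), 0, 0.25)
      encode_first_ch2(st)
    })
    .cache$fixture_model <- train_ensemble(
      do.call(rbind, pos), do.call(rbind, neg), seed = 42
    )
  }
  .cache$fixture_model
}

fixture_refs <- function() {
  if (is.null(.cache$fixture_refs)) {
    entries <- list(
      list(g = "CH2", sub = "HH"), list(g = "CH3", sub = "HHH"),
      list(g = "CH3", sub = "CH3_mixed"), list(g = "CH4", sub = "CH4")
    )
    .cache$fixture_refs <- build_reference_curves(tibble::tibble(
      structure = lapply(entries, function(e) {
        make_site_structure(e$sub, include_zinc = FALSE)$structure
      }),
      center = replicate(length(entries), c(0, 0, 0), simplify = FALSE),
      group = vapply(entries, function(e) e$g, character(1))
    ))
  }
  .cache$fixture_refs
}

fixture_config <- function() {
  prediction_config(model = fixture_model(), reference_curves = fixture_refs())
}

vdist_test <- function(a, b) sqrt(sum((a - b)^2))

acc_fake_site <- function(x, certainty) {
  tibble::tibble(
    site_id = 1L, group = "CH4", subgroup = "CH4", cross_chain = FALSE,
    n_residues = 4L,
    ligands = list(tibble::tibble(
      chain = "A", resseq = 1:4, icode = "", res_name = "CYS",
      residue_kind = "CYS", atom = "SG", atom_role = "SG",
      x = x, y = 0, z = 0
    )),
    zn_x = x, zn_y = 0, zn_z = 0, strategy = "f",
    placement_note = NA_character_, certainty = certainty
  )
}
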