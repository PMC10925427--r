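test_that("feature encoding yields the documented 61-vector with valid one-hots", {
  fx <- make_site_structure("CH", ligand_separation = tetra_sep(),
                            include_zinc = FALSE)
  pl <- place_zinc(enumerate_sites(coordinating_atoms(fx$structure)),
                   fx$structure)
  pl <- pl[pl$group == "CH2", ][1, ]
  fv <- encode_features(pl, fx$structure)
  expect_length(fv, 61)
  expect_equal(names(fv), znsite:::feature_names())
  roles <- c("SG", "ND1", "NE2", "CE1", "CD2")
  expect_equal(sum(fv[paste0("lig1_", roles)]), 1)
  expect_equal(sum(fv[paste0("lig2_", roles)]), 1)
  # a CC site flags both ligands as Cys on SG
  cc <- make_site_structure("CC", ligand_separation = tetra_sep(),
                            include_zinc = FALSE)
  plc <- place_zinc(enumerate_sites(coordinating_atoms(cc$structure)),
                    cc$structure)[1, ]
  fvc <- encode_features(plc, cc$structure)
  expect_equal(unname(fvc[c("lig1_is_cys", "lig2_is_cys", "lig1_SG", "lig2_SG")]),
               c(1, 1, 1, 1))
})

test_that("encoding is invariant to input ligand order and deterministic", {
  fx <- make_site_structure("CH", ligand_separation = tetra_sep(),
                            include_zinc = FALSE)
  pl <- place_zinc(enumerate_sites(coordinating_atoms(fx$structure)),
                   fx$structure)
  pl <- pl[pl$group == "CH2", ][1, ]
  fv1 <- encode_features(pl, fx$structure)
  swapped <- pl
  swapped$ligands <- list(pl$ligands[[1]][2:1, ])
  fv2 <- encode_features(swapped, fx$structure)
  expect_identical(fv1, fv2)
  expect_identical(fv1, encode_features(pl, fx$structure))
})

test_that("negative-set construction screens metals and validation scores", {
  fx <- make_site_structure("CC", ligand_separation = tetra_sep(),
                            include_zinc = TRUE)
  pl <- place_zinc(enumerate_sites(coordinating_atoms(fx$structure)),
                   fx$structure)
  pl <- pl[pl$group == "CH2", ]
  # a modelled zinc sits at the placed position: excluded by the 4 A screen
  expect_equal(nrow(build_negative_set(fx$structure, pl)), 0)
  # no metal, and a geometry that fails Qv: included. At 4.4 A separation
  # every point of the placement locus lies beyond the 2.5 A first sphere of
  # both SG atoms, so the placed zinc has no donors and Qv = 0.
  weak <- make_site_structure("CC", bond_length = 2.3,
                              ligand_separation = 4.4,
                              include_zinc = FALSE)
  plw <- place_zinc(enumerate_sites(coordinating_atoms(weak$structure)),
                    weak$structure)
  plw <- plw[plw$group == "CH2", ]
  neg <- build_negative_set(weak$structure, plw)
  expect_equal(nrow(neg), nrow(plw))
  expect_true(all(neg$q_valence < 0.25 | neg$q_completeness < 0.355))
  # passing both criteria with no metal nearby: excluded
  good <- make_site_structure("CC", ligand_separation = tetra_sep(),
                              include_zinc = FALSE)
  plg <- place_zinc(enumerate_sites(coordinating_atoms(good$structure)),
                    good$structure)
  plg <- plg[plg$group == "CH2", ]
  expect_equal(nrow(build_negative_set(good$structure, plg)), 0)
})

test_that("the 3-of-5 vote and mean-probability certainty combine as stated", {
  cv <- znsite:::combine_votes(matrix(c(0.9, 0.9, 0.9, 0.1, 0.1), nrow = 1))
  expect_true(cv$is_positive)
  expect_equal(cv$certainty, 0.58)
  cv2 <- znsite:::combine_votes(matrix(c(1, 1, 0, 0, 0), nrow = 1))
  expect_false(cv2$is_positive)
  cv3 <- znsite:::combine_votes(matrix(rep(1, 5), nrow = 1))
  expect_true(cv3$is_positive)
  expect_equal(cv3$certainty, 1.0)
  # vote invariant to learner order
  p <- c(0.8, 0.6, 0.2, 0.9, 0.4)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(znsite:::combine_votes(matrix(p, 1))$is_positive,
               znsite:::combine_votes(matrix(p[perm], 1))$is_positive)
  expect_equal(znsite:::combine_votes(matrix(p, 1))$certainty,
               znsite:::combine_votes(matrix(p[perm], 1))$certainty)
})

test_that("training is deterministic for a fixed seed", {
  feats <- make_labelled_features(40, 40, seed = 3)
  pos <- feats[feats$label == 1, ]
  neg <- feats[feats$label == 0, ]
  m1 <- train_ensemble(pos, neg, seed = 5, cv_folds = 3)
  m2 <- train_ensemble(pos, neg, seed = 5, cv_folds = 3)
  expect_identical(m1$metadata$test_idx, m2$metadata$test_idx)
  expect_equal(glance(m1)$auc, glance(m2)$auc)
  probe <- as.matrix(as.data.frame(feats)[, znsite:::feature_names()])[1:5, ]
  expect_equal(ensemble_certainty(m1, probe)$certainty,
               ensemble_certainty(m2, probe)$certainty, tolerance = 1e-12)
})

test_that("all five learners emit probabilities and an ensemble tidy/glance", {
  m <- gauss_model()
  expect_s3_class(m, "zn_ensemble")
  expect_length(m$learners, 5)
  probe <- as.matrix(as.data.frame(gauss_feats())[, znsite:::feature_names()])[1:8, ]
  pr <- ensemble_certainty(m, probe)
  expect_true(all(pr$certainty >= 0 & pr$certainty <= 1))
  probs <- as.matrix(pr[paste0("p_", c("logistic", "tree", "mlp", "svm", "fcnn"))])
  expect_true(all(probs >= 0 & probs <= 1))
  td <- tidy(m)
  expect_true(all(c("learner", "cv_auc") %in% names(td)))
  gl <- glance(m)
  expect_true(all(c("auc", "ap", "precision", "recall") %in% names(gl)))
  # internal AUC agrees with an independent rank-based computation
  y <- c(rep(1, 4), rep(0, 4))
  p <- c(0.9, 0.8, 0.6, 0.4, 0.7, 0.3, 0.2, 0.1)
  expect_equal(znsite:::auc_score(y, p), rank_auc(y, p))
})
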