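feature_names <- function() {
  roles <- c("SG", "ND1", "NE2", "CE1", "CD2")
  c(
    paste0("lig1_", c("is_cys", roles)),
    paste0("lig2_", c("is_cys", roles)),
    "d_donor", "d_ca", "d_cb",
    "ang_ca1", "ang_ca2", "ang_cb1", "ang_cb2",
    paste0("c_", PROFILE_RADII),
    paste0("s_", PROFILE_RADII)
  )
}

#' Encode a two-residue site as a 61-feature vector
#'
#' The feature layout, in fixed order: per ligand (canonically ordered by
#' chain/resseq/icode) a cysteine flag and a 5-way one-hot of the
#' coordinating atom role (12 values); the coordinating-atom, CA--CA and
#' CB--CB distances (3); the four angles CA1-donor1-Zn, CA2-donor2-Zn,
#' CB1-donor1-Zn, CB2-donor2-Zn in degrees (4); and the 21 contrast plus 21
#' mean-solvation profile values around the placed zinc (42).
#'
#' @param site A placed CH2 site row (needs `ligands` and `zn_x/y/z`).
#' @param structure The atom tibble the site came from.
#' @param profile Optional precomputed [hydro_profile()] at the zinc
#'   position (computed if missing).
#' @param scale Solvation scale for the profile.
#' @return Named numeric vector of length 61.
#' @export
encode_features <- function(site, structure, profile = NULL,
                            scale = solvation_scale()) {
  lig <- site_ligands(site)
  if (nrow(lig) != 2) abort("encode_features expects a two-residue site")
  lig <- lig[order(lig$chain, lig$resseq, lig$icode), ]
  zn <- c(site$zn_x[1], site$zn_y[1], site$zn_z[1])
  if (any(!is.finite(zn))) abort("site must be placed before encoding")
  roles <- c("SG", "ND1", "NE2", "CE1", "CD2")
  lig_block <- function(i) {
    onehot <- as.numeric(roles == lig$atom_role[i])
    c(as.numeric(lig$residue_kind[i] == "CYS"), onehot)
  }
  pos <- lapply(1:2, function(i) c(lig$x[i], lig$y[i], lig$z[i]))
  ca <- cb <- vector("list", 2)
  for (i in 1:2) {
    res <- res_atoms_of(structure, lig$chain[i], lig$resseq[i], lig$icode[i])
    ca[[i]] <- atom_position(res, "CA")
    cb[[i]] <- atom_position(res, "CB")
    if (is.null(ca[[i]]) || is.null(cb[[i]])) {
      abort("encoding error: ligand residue lacks CA or CB")
    }
  }
  if (is.null(profile)) profile <- hydro_profile(structure, zn, scale)
  fv <- c(
    lig_block(1), lig_block(2),
    vdist(pos[[1]], pos[[2]]),
    vdist(ca[[1]], ca[[2]]),
    vdist(cb[[1]], cb[[2]]),
    vec_angle(ca[[1]], pos[[1]], zn),
    vec_angle(ca[[2]], pos[[2]], zn),
    vec_angle(cb[[1]], pos[[1]], zn),
    vec_angle(cb[[2]], pos[[2]], zn),
    profile$c_value,
    profile$mean_sigma
  )
  setNames(fv, feature_names())
}

#' Construct the classifier negative set
#'
#' Negative training examples are placed CH2 candidates that (a) have no
#' modelled metal ion within 4 Angstrom of the predicted zinc in their
#' structure and (b) fail the two-ligand validation criteria (Qc < 0.355 or
#' Qv < 0.25).
#'
#' @param structures List of atom tibbles, parallel to `candidates$structure_idx`
#'   (or a single structure used for all candidates).
#' @param candidates Placed CH2 site tibble; an optional `structure_idx`
#'   column indexes into `structures`.
#' @param metal_radius Exclusion radius around modelled metals.
#' @return The subset of `candidates` usable as negatives, with the
#'   two-ligand validation scores appended.
#' @export
build_negative_set <- function(structures, candidates, metal_radius = 4) {
  if (is.data.frame(structures)) structures <- list(structures)
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) return(candidates)
  idx <- candidates[["structure_idx"]]
  if (is.null(idx)) idx <- rep(1L, nrow(candidates))
  keep <- logical(nrow(candidates))
  qv <- qc <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- structures[[idx[i]]]
    zn <- c(candidates$zn_x[i], candidates$zn_y[i], candidates$zn_z[i])
    met <- s[s$is_hetero & s$element %in% METAL_ELEMENTS, ]
    if (nrow(met) > 0) {
      d <- sqrt((met$x - zn[1])^2 + (met$y - zn[2])^2 + (met$z - zn[3])^2)
      if (min(d) < metal_radius) next
    }
    sphere <- coordination_sphere(s, zn)
    if (nrow(sphere) == 0) {
      qv[i] <- 0
      qc[i] <- 0
      keep[i] <- TRUE
      next
    }
    qv[i] <- q_valence(sphere$valence, 2)
    qc[i] <- q_completeness(sphere, "oxidation_state", v_ox = 2)
    keep[i] <- qc[i] < 0.355 || qv[i] < 0.25
  }
  out <- candidates[keep, ]
  out$q_valence <- qv[keep]
  out$q_completeness <- qc[keep]
  out
}

make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

learner_grids <- function() {
  list(
    logistic = tibble(dummy = 1),
    tree = tibble(cp = c(0.001, 0.01, 0.05)),
    mlp = tidyr::expand_grid(size = c(4L, 8L), decay = c(0.01, 0.1)),
    svm = tibble(cost = c(0.5, 2, 8)),
    fcnn = tibble(size = 16L, decay = c(0.001, 0.01))
  )
}

fit_one <- function(kind, x, y, pars) {
  df <- data.frame(x)
  df$.y <- y
  switch(kind,
    logistic = suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial())
    ),
    tree = rpart::rpart(
      factor(.y) ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = pars$cp, minsplit = 10)
    ),
    mlp = nnet::nnet(
      x, y, size = pars$size, decay = pars$decay, maxit = 300,
      entropy = TRUE, trace = FALSE, MaxNWts = 5000
    ),
    svm = e1071::svm(
      x, factor(y), kernel = "radial", cost = pars$cost,
      probability = TRUE, scale = FALSE
    ),
    fcnn = nnet::nnet(
      x, y, size = pars$size, decay = pars$decay, maxit = 500,
      entropy = TRUE, trace = FALSE, MaxNWts = 5000
    )
  )
}

predict_one <- function(kind, fit, x) {
  df <- data.frame(x)
  p <- switch(kind,
    logistic = suppressWarnings(
      as.numeric(predict(fit, newdata = df, type = "response"))
    ),
    tree = {
      pr <- predict(fit, newdata = df, type = "prob")
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(df))
    },
    mlp = as.numeric(predict(fit, x)),
    fcnn = as.numeric(predict(fit, x)),
    svm = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      pr[, "1"]
    }
  )
  clamp01(p)
}

auc_score <- function(y, p) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = p,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

average_precision <- function(y, p) {
  ord <- order(-p)
  y <- y[ord]
  cum_tp <- cumsum(y)
  precision <- cum_tp / seq_along(y)
  sum(precision * y) / sum(y)
}

cv_select <- function(kind, x, y, grid, k = 10, seed = 1) {
  fold <- make_folds(y, k, seed)
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    preds <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      fit <- fit_one(kind, x[tr, , drop = FALSE], y[tr], grid[g, ])
      preds[!tr] <- predict_one(kind, fit, x[!tr, , drop = FALSE])
    }
    cv_auc[g] <- auc_score(y, preds)
  }
  best <- which.max(cv_auc)
  list(best = grid[best, ], cv = mutate(grid, cv_auc = cv_auc))
}

ensemble_kinds <- c("logistic", "tree", "mlp", "svm", "fcnn")

subgroup_of_features <- function(x) {
  flags <- x[, c("lig1_is_cys", "lig2_is_cys"), drop = FALSE]
  nc <- rowSums(flags)
  c("HH", "CH", "CC")[nc + 1]
}

#' Train the two-residue site verification ensemble
#'
#' Fits the five base learners (logistic regression, decision tree,
#' multilayer perceptron, radial-kernel SVM, and a larger feed-forward
#' network) on labelled 61-feature vectors. The data are split 70/30
#' stratified by label and CH2 subgroup (CC/CH/HH), features are
#' standardised on the training portion, and each learner's hyperparameters
#' are chosen by 10-fold cross-validated AUC over a small grid. Held-out
#' metrics (AUC, average precision, confusion matrix under the 3-of-5 vote)
#' are stored on the returned model.
#'
#' @param positives,negatives Data frames (or matrices) of 61 features, one
#'   row per site, columns named as in [feature_names()].
#' @param seed Integer seed governing the split, fold assignment and
#'   learner initialisation.
#' @param cv_folds Number of cross-validation folds.
#' @return An object of class `zn_ensemble`.
#' @export
train_ensemble <- function(positives, negatives, seed = 1, cv_folds = 10) {
  fn <- feature_names()
  pm <- as.matrix(as.data.frame(positives)[, fn])
  nm <- as.matrix(as.data.frame(negatives)[, fn])
  if (nrow(pm) == 0 || nrow(nm) == 0) abort("both classes must be non-empty")
  x <- rbind(pm, nm)
  y <- c(rep(1, nrow(pm)), rep(0, nrow(nm)))
  strata <- paste(y, subgroup_of_features(x))
  set.seed(seed)
  small <- names(which(table(strata) < 2))
  if (length(small) > 0) {
    warn("a subgroup stratum has < 2 members; falling back to a global split")
    strata <- as.character(y)
  }
  test_idx <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_test <- max(1, round(0.3 * length(idx)))
    if (length(idx) == 1) n_test <- 0
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  train_idx <- setdiff(seq_len(nrow(x)), test_idx)

  mu <- colMeans(x[train_idx, , drop = FALSE])
  sdv <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
  sdv[sdv < 1e-9] <- 1
  scale_x <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  xtr <- scale_x(x[train_idx, , drop = FALSE])
  ytr <- y[train_idx]
  xte <- scale_x(x[test_idx, , drop = FALSE])
  yte <- y[test_idx]

  grids <- learner_grids()
  learners <- list()
  cv_results <- list()
  for (kind in ensemble_kinds) {
    set.seed(seed + match(kind, ensemble_kinds))
    sel <- cv_select(kind, xtr, ytr, grids[[kind]], k = cv_folds, seed = seed)
    set.seed(seed + 100 + match(kind, ensemble_kinds))
    fit <- fit_one(kind, xtr, ytr, sel$best)
    learners[[kind]] <- list(kind = kind, fit = fit, params = sel$best)
    cv_results[[kind]] <- mutate(sel$cv, learner = kind)
  }
  model <- structure(
    list(
      learners = learners,
      scaling = list(mean = mu, sd = sdv),
      cv = bind_rows(cv_results),
      metadata = list(
        seed = seed, n_train = length(train_idx), n_test = length(test_idx),
        train_idx = train_idx, test_idx = test_idx
      )
    ),
    class = "zn_ensemble"
  )
  if (length(test_idx) > 0 && length(unique(yte)) == 2) {
    pred <- ensemble_certainty(model, xte, scaled = TRUE)
    vote_pos <- pred$is_positive
    tp <- sum(vote_pos & yte == 1)
    fp <- sum(vote_pos & yte == 0)
    fn_ <- sum(!vote_pos & yte == 1)
    tn <- sum(!vote_pos & yte == 0)
    model$holdout <- list(
      auc = auc_score(yte, pred$certainty),
      ap = average_precision(yte, pred$certainty),
      confusion = c(tp = tp, fp = fp, fn = fn_, tn = tn),
      metrics = classification_metrics(tp, fp, fn_, tn)
    )
  }
  model
}

#' Score sites with the ensemble
#'
#' Each base learner votes positive when its class probability exceeds 0.5;
#' a site is accepted when at least 3 of the 5 learners vote positive. The
#' certainty is the clamped mean of the five probabilities.
#'
#' @param model A fitted `zn_ensemble`.
#' @param features A named 61-vector, matrix or data frame of feature rows.
#' @param scaled Internal: set when `features` are already standardised.
#' @return A tibble with one row per site: `certainty`, `is_positive`,
#'   `votes`, and the five per-learner probabilities.
#' @export
ensemble_certainty <- function(model, features, scaled = FALSE) {
  if (!inherits(model, "zn_ensemble")) abort("model must be a fitted zn_ensemble")
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  x <- as.matrix(as.data.frame(features)[, feature_names(), drop = FALSE])
  if (!scaled) {
    x <- sweep(sweep(x, 2, model$scaling$mean), 2, model$scaling$sd, "/")
  }
  probs <- sapply(model$learners, function(l) predict_one(l$kind, l$fit, x))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  combine_votes(probs)
}

# Majority vote (3+ of 5 learners with probability > 0.5) and mean-probability
# certainty, from an n x 5 matrix of base-learner probabilities.
combine_votes <- function(probs) {
  votes <- rowSums(probs > 0.5)
  out <- tibble(
    certainty = clamp01(rowMeans(probs)),
    is_positive = votes >= 3,
    votes = as.integer(votes)
  )
  colnames(probs) <- paste0("p_", ensemble_kinds)
  bind_cols(out, as_tibble(probs))
}

#' @export
print.zn_ensemble <- function(x, ...) {
  cat("<zn_ensemble> five-learner majority-vote site classifier\n")
  cat("  learners:", paste(names(x$learners), collapse = ", "), "\n")
  cat("  training:", x$metadata$n_train, "sites; held out:", x$metadata$n_test, "\n")
  if (!is.null(x$holdout)) {
    cat(sprintf("  held-out AUC %.3f, AP %.3f\n", x$holdout$auc, x$holdout$ap))
  }
  invisible(x)
}

#' Tidy the cross-validation results of an ensemble
#'
#' @param x A `zn_ensemble`.
#' @param ... Unused.
#' @return Tibble of per-learner hyperparameter grids with CV AUC.
#' @exportS3Method generics::tidy
tidy.zn_ensemble <- function(x, ...) {
  as_tibble(x$cv)
}

#' One-row summary of an ensemble's held-out performance
#'
#' @param x A `zn_ensemble`.
#' @param ... Unused.
#' @return One-row tibble with AUC, average precision and the confusion
#'   counts and derived metrics of the 3-of-5 vote on the held-out split.
#' @exportS3Method generics::glance
glance.zn_ensemble <- function(x, ...) {
  if (is.null(x$holdout)) {
    return(tibble(auc = NA_real_, ap = NA_real_))
  }
  cm <- as.list(x$holdout$confusion)
  bind_cols(
    tibble(
      auc = x$holdout$auc, ap = x$holdout$ap,
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn
    ),
    x$holdout$metrics
  )
}
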