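#' Verify placed candidate sites
#'
#' Two-residue (CH2) sites are scored by the five-learner ensemble; three-
#' and four-residue sites by Pearson correlation of their hydrophobicity
#' profiles against the group reference curves. Sites whose certainty
#' exceeds the threshold are verified.
#'
#' @param placed Placed site tibble from [place_zinc()].
#' @param structure The atom tibble the sites came from.
#' @param model A fitted `zn_ensemble` (required when CH2 sites are present).
#' @param refs Reference curves from [build_reference_curves()] (required
#'   when CH3/CH4 sites are present).
#' @param threshold Certainty threshold (default 0.5).
#' @param scale Solvation scale.
#' @return `placed` with `certainty` and `verified` columns.
#' @export
verify_sites <- function(placed, structure, model = NULL, refs = NULL,
                         threshold = 0.5, scale = solvation_scale()) {
  placed <- as_tibble(placed)
  if (nrow(placed) == 0) {
    placed$certainty <- numeric(0)
    placed$verified <- logical(0)
    return(placed)
  }
  if (any(placed$group == "CH2") && is.null(model)) {
    abort("configuration error: CH2 sites present but no ensemble model supplied")
  }
  if (any(placed$group %in% c("CH3", "CH4")) && is.null(refs)) {
    abort("configuration error: CH3/CH4 sites present but no reference curves supplied")
  }
  certainty <- numeric(nrow(placed))
  for (i in seq_len(nrow(placed))) {
    zn <- c(placed$zn_x[i], placed$zn_y[i], placed$zn_z[i])
    if (placed$group[i] == "CH2") {
      fv <- encode_features(placed[i, ], structure, scale = scale)
      certainty[i] <- ensemble_certainty(model, fv)$certainty
    } else {
      prof <- hydro_profile(structure, zn, scale)
      ref <- reference_for_group(refs, placed$group[i])
      certainty[i] <- pearson_certainty(prof, ref)
    }
  }
  placed$certainty <- certainty
  placed$verified <- certainty > threshold
  placed
}

#' Remove redundant predicted zincs
#'
#' Sites are ranked by ligand count, then certainty, then chain/resseq of
#' the first ligand, and kept greedily: any lower-ranked site whose zinc
#' lies closer than the redundancy threshold (default 2.5 Angstrom) to an
#' already-kept zinc is dropped. Dinuclear sites (typically 3--4 Angstrom
#' apart) both survive.
#'
#' @param sites Placed site tibble with `certainty`.
#' @param threshold Redundancy radius in Angstrom.
#' @return The surviving subset, in rank order.
#' @export
remove_redundancy <- function(sites, threshold = 2.5) {
  sites <- as_tibble(sites)
  if (nrow(sites) <= 1) return(sites)
  first_lig <- bind_rows(lapply(sites$ligands, function(l) l[1, c("chain", "resseq")]))
  ord <- order(
    -sites$n_residues, -sites$certainty,
    first_lig$chain, first_lig$resseq
  )
  sites <- sites[ord, ]
  kept <- integer(0)
  for (i in seq_len(nrow(sites))) {
    zn <- c(sites$zn_x[i], sites$zn_y[i], sites$zn_z[i])
    if (length(kept) > 0) {
      d <- vapply(kept, function(k) {
        vdist(zn, c(sites$zn_x[k], sites$zn_y[k], sites$zn_z[k]))
      }, numeric(1))
      if (any(d < threshold)) next
    }
    kept <- c(kept, i)
  }
  sites[kept, ]
}

#' Auxiliary (non-Cys/His) ligands around a predicted zinc
#'
#' Finds N/O/S donor atoms from residues other than the site's own
#' coordinating Cys/His residues within the second coordination sphere of
#' the predicted zinc, labelled `"first"` (within the first-sphere radius)
#' or `"second"`. Glu/Asp carboxylate oxygens, backbone donors and waters
#' all qualify.
#'
#' @param structure Atom tibble.
#' @param site One placed site row.
#' @param first_sphere,second_sphere Sphere radii (default 2.5 / 4.0).
#' @return Tibble of auxiliary donor atoms with `distance` and `sphere`.
#' @export
annotate_second_sphere <- function(structure, site, first_sphere = 2.5,
                                   second_sphere = 4.0) {
  lig <- site_ligands(site)
  zn <- c(site$zn_x[1], site$zn_y[1], site$zn_z[1])
  don <- structure[structure$element %in% c("N", "O", "S"), ]
  own <- residue_key(don$chain, don$resseq, don$icode) %in%
    residue_key(lig$chain, lig$resseq, lig$icode)
  ch_side <- (don$res_name == "CYS" & don$atom == "SG") |
    (don$res_name == "HIS" & don$atom %in% HIS_RING_ROLES)
  don <- don[!own & !ch_side, ]
  if (nrow(don) == 0) return(mutate(don, distance = numeric(0), sphere = character(0)))
  d <- sqrt((don$x - zn[1])^2 + (don$y - zn[2])^2 + (don$z - zn[3])^2)
  keep <- d <= second_sphere
  don <- don[keep, ]
  don$distance <- d[keep]
  don$sphere <- ifelse(don$distance <= first_sphere, "first", "second")
  arrange(don, .data$distance)
}

#' Predict zinc-binding sites in a structure
#'
#' Runs the full chain: primary-conformer selection, Cys/His candidate-atom
#' collection, geometric site enumeration, subgroup-specific zinc placement,
#' hybrid verification (ensemble for CH2, profile correlation for CH3/CH4),
#' redundancy removal, and second-sphere annotation. Metals already
#' modelled in the input are validated with the bond-valence scores and
#' cross-referenced to predictions by IoUR.
#'
#' @param structure An atom tibble from [read_structure()].
#' @param config A [prediction_config()]; must carry `model` and/or
#'   `reference_curves` for the site groups present.
#' @return An object of class `zn_prediction`: a list with `verified`
#'   (surviving sites with certainty, auxiliary ligands and any matched
#'   experimental site), `rejected` (candidates with reasons),
#'   `experimental` (validation of modelled metals), and `config`.
#' @export
predict_structure <- function(structure, config = prediction_config()) {
  structure <- primary_conformer(structure)
  atoms <- coordinating_atoms(structure, chains = config$chains)
  candidates <- enumerate_sites(atoms, window = config$distance_window)
  placed <- place_zinc(candidates, structure, config)
  scored <- verify_sites(
    placed, structure,
    model = config$model, refs = config$reference_curves,
    threshold = config$certainty_threshold
  )
  rejected <- scored[!scored$verified, ]
  if (nrow(rejected) > 0) rejected$reason <- "certainty below threshold"
  verified <- remove_redundancy(
    scored[scored$verified, ],
    threshold = config$redundancy_threshold
  )
  if (nrow(verified) > 0) {
    verified$auxiliary <- lapply(seq_len(nrow(verified)), function(i) {
      annotate_second_sphere(
        structure, verified[i, ],
        first_sphere = config$first_sphere,
        second_sphere = config$second_sphere
      )
    })
  } else {
    verified$auxiliary <- list()
  }
  experimental <- validate_structure_metals(structure)
  if (nrow(experimental) > 0 && nrow(verified) > 0) {
    exp_sets <- lapply(seq_len(nrow(experimental)), function(i) {
      sph <- coordination_sphere(
        structure,
        c(experimental$x[i], experimental$y[i], experimental$z[i])
      )
      residue_key(sph$chain, sph$resseq, sph$icode)
    })
    mi <- match_iour(verified, exp_sets, threshold = 0.5)
    verified$matched_experimental <- NA_integer_
    verified$match_iour <- NA_real_
    verified$match_deviation <- NA_real_
    if (nrow(mi$pairs) > 0) {
      for (r in seq_len(nrow(mi$pairs))) {
        i <- mi$pairs$predicted[r]
        j <- mi$pairs$actual[r]
        verified$matched_experimental[i] <- j
        verified$match_iour[i] <- mi$pairs$iour[r]
        verified$match_deviation[i] <- vdist(
          c(verified$zn_x[i], verified$zn_y[i], verified$zn_z[i]),
          c(experimental$x[j], experimental$y[j], experimental$z[j])
        )
      }
    }
  }
  structure(
    list(
      verified = verified,
      rejected = rejected,
      experimental = experimental,
      config = config,
      structure_id = attr(structure, "id")
    ),
    class = "zn_prediction"
  )
}

#' @export
print.zn_prediction <- function(x, ...) {
  cat("<zn_prediction>", x$structure_id, "\n")
  cat("  verified sites:", nrow(x$verified), "\n")
  cat("  rejected candidates:", nrow(x$rejected), "\n")
  cat("  modelled metals validated:", nrow(x$experimental), "\n")
  invisible(x)
}

#' Tidy a prediction report
#'
#' One row per verified site with group, subgroup, ligand summary, zinc
#' position and certainty.
#'
#' @param x A `zn_prediction`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.zn_prediction <- function(x, ...) {
  v <- x$verified
  if (nrow(v) == 0) {
    return(tibble(
      site_id = integer(), group = character(), subgroup = character(),
      ligands = character(), zn_x = numeric(), zn_y = numeric(),
      zn_z = numeric(), certainty = numeric()
    ))
  }
  tibble(
    site_id = v$site_id,
    group = v$group,
    subgroup = v$subgroup,
    ligands = vapply(v$ligands, function(l) {
      paste0(l$chain, ":", substr(l$res_name, 1, 1), l$resseq, collapse = ",")
    }, character(1)),
    zn_x = v$zn_x, zn_y = v$zn_y, zn_z = v$zn_z,
    certainty = v$certainty,
    n_auxiliary = vapply(v$auxiliary, nrow, integer(1))
  )
}

#' One-row summary of a prediction report
#'
#' @param x A `zn_prediction`.
#' @param ... Unused.
#' @return One-row tibble of stage counts.
#' @exportS3Method generics::glance
glance.zn_prediction <- function(x, ...) {
  tibble(
    n_verified = nrow(x$verified),
    n_rejected = nrow(x$rejected),
    n_experimental = nrow(x$experimental),
    n_experimental_passed = sum(x$experimental$passed),
    mean_certainty = if (nrow(x$verified) > 0) mean(x$verified$certainty) else NA_real_
  )
}

#' Plot a prediction report
#'
#' A 2-D projection of the structure's atoms with predicted zincs overlaid,
#' sized by certainty.
#'
#' @param object A `zn_prediction`.
#' @param structure The atom tibble the prediction came from.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.zn_prediction <- function(object, structure = NULL, ...) {
  v <- object$verified
  p <- ggplot2::ggplot()
  if (!is.null(structure)) {
    p <- p + ggplot2::geom_point(
      data = structure,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey70", size = 0.5
    )
  }
  if (nrow(v) > 0) {
    p <- p + ggplot2::geom_point(
      data = v,
      ggplot2::aes(x = .data$zn_x, y = .data$zn_y, size = .data$certainty,
                   colour = .data$group)
    )
  }
  p + ggplot2::labs(
    x = "x (Å)", y = "y (Å)",
    title = paste("Predicted zinc sites:", object$structure_id)
  )
}

#' Plot a hydrophobicity profile
#'
#' @param object A [hydro_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot with both curves faceted.
#' @export
plot_hydro_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("c_value", "mean_sigma"),
                              names_to = "curve", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$radius, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "radius (Å)", y = NULL)
}
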