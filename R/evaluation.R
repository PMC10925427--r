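as_residue_set <- function(x) {
  if (is.character(x)) return(unique(x))
  x <- as_tibble(x)
  if (all(c("chain", "resseq") %in% names(x))) {
    icode <- if (is.null(x[["icode"]])) "" else x[["icode"]]
    return(unique(residue_key(x$chain, x$resseq, icode)))
  }
  abort("residue sets must be character keys or tibbles with chain/resseq")
}

#' Intersection-over-union ratio of two ligand-residue sets
#'
#' Residues are identified by (chain, resseq, icode). Both sets empty is
#' defined as 0.
#'
#' @param predicted,actual Character vectors of residue keys, or tibbles
#'   with `chain`, `resseq` (and optionally `icode`) columns.
#' @return Ratio in `[0, 1]`.
#' @export
#' @examples
#' iour(c("A:1:.", "A:2:."), c("A:1:.", "A:3:."))  # 1/3
iour <- function(predicted, actual) {
  p <- as_residue_set(predicted)
  a <- as_residue_set(actual)
  u <- length(union(p, a))
  if (u == 0) return(0)
  length(intersect(p, a)) / u
}

site_residue_sets <- function(sites) {
  if (is.list(sites) && !is.data.frame(sites)) {
    return(lapply(sites, as_residue_set))
  }
  sites <- as_tibble(sites)
  if (!is.null(sites[["ligands"]])) return(lapply(sites[["ligands"]], as_residue_set))
  if (!is.null(sites[["residues"]])) return(lapply(sites[["residues"]], as_residue_set))
  abort("site tables need a 'ligands' or 'residues' list-column")
}

#' Match predicted to actual sites by residue overlap
#'
#' Greedy one-to-one matching by descending IoUR: the best remaining
#' (prediction, actual) pair is matched while its IoUR meets the threshold.
#' Ties prefer the earlier (lowest-index) actual site. Matched pairs are
#' true positives; unmatched predictions false positives; unmatched actual
#' sites false negatives.
#'
#' @param predicted,actual Lists of residue sets, or site tibbles with a
#'   `ligands`/`residues` list-column.
#' @param threshold Minimum IoUR of a true positive (default 0.5).
#' @return A list with `pairs` (tibble of `predicted`, `actual` indices and
#'   `iour`), and counts `tp`, `fp`, `fn`.
#' @export
match_iour <- function(predicted, actual, threshold = 0.5) {
  p <- site_residue_sets(predicted)
  a <- site_residue_sets(actual)
  np <- length(p)
  na <- length(a)
  if (np == 0 || na == 0) {
    return(list(
      pairs = tibble(predicted = integer(), actual = integer(), iour = numeric()),
      tp = 0L, fp = np, fn = na
    ))
  }
  m <- matrix(0, np, na)
  for (i in seq_len(np)) {
    for (j in seq_len(na)) m[i, j] <- iour(p[[i]], a[[j]])
  }
  pairs <- list()
  avail_p <- rep(TRUE, np)
  avail_a <- rep(TRUE, na)
  repeat {
    mm <- m
    mm[!avail_p, ] <- -1
    mm[, !avail_a] <- -1
    best <- max(mm)
    if (best < threshold) break
    hits <- which(mm == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]  # lowest actual wins ties
    i <- hits[1, 1]
    j <- hits[1, 2]
    pairs[[length(pairs) + 1]] <- tibble(predicted = i, actual = j, iour = best)
    avail_p[i] <- FALSE
    avail_a[j] <- FALSE
  }
  pairs <- if (length(pairs) > 0) bind_rows(pairs) else
    tibble(predicted = integer(), actual = integer(), iour = numeric())
  list(
    pairs = pairs,
    tp = nrow(pairs),
    fp = as.integer(np - nrow(pairs)),
    fn = as.integer(na - nrow(pairs))
  )
}

#' Match predicted to actual sites by distance
#'
#' Distance-threshold matching: a prediction within `threshold` (default
#' 5 Angstrom) of its nearest actual site is a true positive; an actual site
#' with no prediction within the threshold is a false negative. Unmatched
#' predictions are clustered so that mutually close (within the threshold)
#' false predictions count as a single false positive.
#'
#' @param predicted,actual Tibbles (or matrices) with `x`, `y`, `z` columns
#'   (for placed-site tibbles, `zn_x/zn_y/zn_z` are also recognised).
#' @param threshold Matching radius in Angstrom.
#' @return A list with `pairs` (prediction index, nearest actual index,
#'   deviation) and counts `tp`, `fp`, `fn`.
#' @export
match_distance <- function(predicted, actual, threshold = 5) {
  coords <- function(s) {
    if (is.matrix(s)) return(s)
    s <- as_tibble(s)
    if (!is.null(s[["zn_x"]])) return(cbind(s$zn_x, s$zn_y, s$zn_z))
    cbind(s$x, s$y, s$z)
  }
  p <- coords(predicted)
  a <- coords(actual)
  np <- nrow(p)
  na <- nrow(a)
  if (np == 0) {
    return(list(
      pairs = tibble(predicted = integer(), actual = integer(), deviation = numeric()),
      tp = 0L, fp = 0L, fn = na
    ))
  }
  if (na == 0) {
    d_fp <- rep(TRUE, np)
    return(list(
      pairs = tibble(predicted = integer(), actual = integer(), deviation = numeric()),
      tp = 0L, fp = cluster_count(p, threshold), fn = 0L
    ))
  }
  d <- sqrt(outer(p[, 1], a[, 1], "-")^2 + outer(p[, 2], a[, 2], "-")^2 +
              outer(p[, 3], a[, 3], "-")^2)
  nearest <- apply(d, 1, which.min)
  dev <- d[cbind(seq_len(np), nearest)]
  is_tp <- dev <= threshold
  pairs <- tibble(
    predicted = which(is_tp),
    actual = nearest[is_tp],
    deviation = dev[is_tp]
  )
  covered <- apply(d <= threshold, 2, any)
  fp <- if (any(!is_tp)) cluster_count(p[!is_tp, , drop = FALSE], threshold) else 0L
  list(pairs = pairs, tp = as.integer(sum(is_tp)), fp = fp,
       fn = as.integer(sum(!covered)))
}

# Number of clusters among points when linking pairs closer than `radius`
# (mutually close false predictions count once).
cluster_count <- function(pts, radius) {
  n <- nrow(pts)
  if (n <= 1) return(as.integer(n))
  d <- as.matrix(stats::dist(pts))
  g <- igraph::graph_from_adjacency_matrix(d < radius, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::count_components(g))
}

#' Euclidean deviation between predicted and actual positions
#'
#' @param predicted,actual Length-3 numerics, or matrices/tibbles of
#'   positions (row-wise pairs).
#' @return Numeric deviation(s) in Angstrom.
#' @export
deviation <- function(predicted, actual) {
  if (is.null(dim(predicted))) return(vdist(predicted, actual))
  p <- as.matrix(predicted)
  a <- as.matrix(actual)
  sqrt(rowSums((p - a)^2))
}

#' Classification metrics from confusion counts
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), F1 = 2PR/(P+R), accuracy =
#' (TP+TN)/(TP+TN+FP+FN). Metrics with undefined (zero) denominators are
#' reported as `NA`, not 0.
#'
#' @param tp,fp,fn,tn Non-negative counts (`tn` may be `NA` when true
#'   negatives are undefined, as in structure-wide site detection).
#' @return One-row tibble with `recall`, `precision`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(tp, fp, fn, tn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  safe_div <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  f1 <- if (is.na(recall) || is.na(precision) || (precision + recall) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  accuracy <- if (is.na(tn)) NA_real_ else safe_div(tp + tn, tp + tn + fp + fn)
  tibble(recall = recall, precision = precision, f1 = f1, accuracy = accuracy)
}
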