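# Seven-dimensional feature mapping of an interacting protein pair.
#
# Weight features (units of the input network's edge weights):
#   F1  weight of the focal edge w_ij
#   F2  maximum neighbouring weight max w_xk, x in {i,j}, k outside the pair
#   F3  minimum neighbouring weight
#   F4  max over common neighbours k of min(w_ik, w_jk)
#   F5  max over common neighbours k of |w_ik - w_jk|   (default mode)
# Domain features (counts with multiplicity; unannotated protein -> 0):
#   F6  max(#domains of P_i, #domains of P_j)
#   F7  min(#domains of P_i, #domains of P_j)
#
# A heterodimer should show a strong focal edge (high F1) surrounded by weak
# neighbouring interactions (low F2-F4), and few domains (low F6/F7); pairs
# buried in larger complexes show strong common-neighbour edges instead.

FEATURE_NAMES <- paste0("F", 1:7)

#' Neighbourhood view of an interacting pair
#'
#' Collects the weights of all edges from either member of the pair to
#' proteins outside the pair, and, for each common neighbour `k`, the weight
#' pair `(w_ik, w_jk)`.  The focal edge itself is excluded.
#'
#' @param network a [ppi_network()]
#' @param a,b the two proteins; `{a,b}` must be a network edge
#' @return list with `neighbor_weights` (numeric, possibly empty) and
#'   `common` (data.frame `k`, `w_ik`, `w_jk`).
#' @export
neighborhood <- function(network, a, b) {
  if (!has_edge(network, a, b))
    stop("pair {", a, ", ", b, "} is not an edge of the network")
  na <- network$adj[[a]]; na <- na[names(na) != b]
  nb <- network$adj[[b]]; nb <- nb[names(nb) != a]
  common_ids <- intersect(names(na), names(nb))
  list(
    neighbor_weights = c(unname(na), unname(nb)),
    common = data.frame(k = common_ids,
                        w_ik = unname(na[common_ids]),
                        w_jk = unname(nb[common_ids]),
                        stringsAsFactors = FALSE)
  )
}

domain_count <- function(domains, protein) {
  comp <- domains[[protein]]
  if (is.null(comp)) 0L else sum(comp)
}

#' Compute the seven features for one interacting pair
#'
#' @inheritParams neighborhood
#' @param domains a [domain_annotation()]
#' @param f5_mode how the "maximum of differences between the neighbouring
#'   weights" is read: `"common_abs_diff"` (default) is the maximum over
#'   common neighbours of `|w_ik - w_jk|`; `"range"` is `F2 - F3`;
#'   `"inside_minus_min"` is `w_ij - F3`.  The alternatives are linear in
#'   F1-F3 and therefore redundant under a linear kernel; they are kept for
#'   comparison.
#' @return named numeric vector `F1..F7`.  Features F2-F5 default to 0 when
#'   no qualifying neighbour exists.
#' @export
compute_features <- function(network, domains, a, b,
                             f5_mode = c("common_abs_diff", "range",
                                         "inside_minus_min")) {
  f5_mode <- match.arg(f5_mode)
  nv <- neighborhood(network, a, b)
  f1 <- edge_weight(network, a, b)
  has_nb <- length(nv$neighbor_weights) > 0L
  f2 <- if (has_nb) max(nv$neighbor_weights) else 0
  f3 <- if (has_nb) min(nv$neighbor_weights) else 0
  has_common <- nrow(nv$common) > 0L
  f4 <- if (has_common) max(pmin(nv$common$w_ik, nv$common$w_jk)) else 0
  f5 <- switch(f5_mode,
    common_abs_diff = if (has_common) max(abs(nv$common$w_ik - nv$common$w_jk)) else 0,
    range = if (has_nb) f2 - f3 else 0,
    inside_minus_min = if (has_nb) f1 - f3 else 0)
  d <- c(domain_count(domains, a), domain_count(domains, b))
  stats::setNames(c(f1, f2, f3, f4, f5, max(d), min(d)), FEATURE_NAMES)
}

#' Compute the feature table for a set of pairs
#'
#' @inheritParams compute_features
#' @param pairs data.frame with columns `protein_a`, `protein_b` (e.g. from
#'   [build_dataset()]); a `label` column, if present, is carried through.
#' @return data.frame `protein_a`, `protein_b`, `F1..F7`[, `label`].
#' @export
feature_matrix <- function(network, domains, pairs,
                           f5_mode = c("common_abs_diff", "range",
                                       "inside_minus_min")) {
  f5_mode <- match.arg(f5_mode)
  feats <- t(vapply(seq_len(nrow(pairs)), function(i)
    compute_features(network, domains, pairs$protein_a[[i]],
                     pairs$protein_b[[i]], f5_mode),
    numeric(7L)))
  out <- cbind(pairs[c("protein_a", "protein_b")],
               as.data.frame(feats, stringsAsFactors = FALSE))
  if ("label" %in% names(pairs)) out$label <- pairs$label
  rownames(out) <- NULL
  out
}

#' Extract the numeric feature columns of a feature table
#'
#' @param features a feature table from [feature_matrix()] or a plain numeric
#'   matrix
#' @param feature_set which features to keep: a character vector of names or
#'   a shorthand like `"F1-5"`, `"F1-6"`, `"F1-5,7"`, `"F1-7"`.
#' @return numeric matrix with the selected feature columns.
#' @export
feature_columns <- function(features, feature_set = "F1-7") {
  keep <- parse_feature_set(feature_set)
  if (is.matrix(features)) return(features[, keep, drop = FALSE])
  as.matrix(features[keep])
}

parse_feature_set <- function(feature_set) {
  if (length(feature_set) > 1L || all(feature_set %in% FEATURE_NAMES)) {
    keep <- feature_set
  } else {
    spans <- strsplit(gsub("F", "", feature_set, fixed = TRUE), ",", fixed = TRUE)[[1]]
    keep <- unlist(lapply(spans, function(s) {
      r <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
      paste0("F", if (length(r) == 2L) seq(r[[1]], r[[2]]) else r)
    }))
  }
  if (!all(keep %in% FEATURE_NAMES))
    stop("unknown feature(s): ", paste(setdiff(keep, FEATURE_NAMES), collapse = ", "))
  keep
}

#' Per-feature min-max scaling fit on training rows
#'
#' Maps each training column onto [0, 1]; the same affine map is applied to
#' `apply_matrix` (values outside the training range are not clipped).
#' Constant training columns map to 0.
#'
#' @param train_matrix numeric matrix of training-fold feature rows
#' @param apply_matrix optional matrix to transform with the training fit
#' @return list with `train`, `apply` (or `NULL`) and the fitted `min` /
#'   `range` vectors.
#' @export
scale_features <- function(train_matrix, apply_matrix = NULL) {
  train_matrix <- as.matrix(train_matrix)
  if (nrow(train_matrix) == 0L) stop("train_matrix must be non-empty")
  mins <- apply(train_matrix, 2L, min)
  rng <- apply(train_matrix, 2L, max) - mins
  sc <- function(m) {
    m <- sweep(as.matrix(m), 2L, mins, "-")
    pos <- rng > 0
    m[, pos] <- sweep(m[, pos, drop = FALSE], 2L, rng[pos], "/")
    m[, !pos] <- 0
    m
  }
  list(train = sc(train_matrix),
       apply = if (is.null(apply_matrix)) NULL else sc(apply_matrix),
       min = mins, range = rng)
}
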