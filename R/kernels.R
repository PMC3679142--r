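# Domain-composition kernel over protein sets.
#
# Two proteins are equivalent when their domain multisets are identical
# (same domains, same count of each).  Two equal-sized protein sets are
# equivalent when some permutation matches their members into pairwise
# equivalent proteins.  The kernel is the indicator of this set equivalence;
# because the relation is an equivalence relation it partitions any example
# collection into classes, the Gram matrix is block-diagonal with all-ones
# blocks after reordering, and is therefore positive semidefinite.

#' Resolve a protein's domain composition
#'
#' @param domains a [domain_annotation()]
#' @param protein protein ID
#' @param unannotated how to treat proteins with no annotation:
#'   `"pseudo"` (default) assigns a unique pseudo-domain derived from the
#'   protein's own ID, so an unannotated protein is equivalent only to
#'   itself (keeps the relation reflexive without collapsing all
#'   unannotated proteins into one class); `"empty"` makes all unannotated
#'   proteins mutually equivalent via the empty multiset.
#' @return named integer vector of domain counts.
#' @export
domain_composition <- function(domains, protein,
                               unannotated = c("pseudo", "empty")) {
  unannotated <- match.arg(unannotated)
  comp <- domains[[protein]]
  if (!is.null(comp)) return(comp)
  if (unannotated == "pseudo")
    stats::setNames(1L, paste0("\x01unannotated:", protein))
  else stats::setNames(integer(0), character(0))
}

composition_string <- function(comp) {
  if (!length(comp)) return("")
  o <- order(names(comp))
  paste(names(comp)[o], comp[o], sep = ":", collapse = "|")
}

#' Protein equivalence: identical domain multisets
#'
#' @param comp_a,comp_b named integer vectors of domain counts (as returned
#'   by [domain_composition()])
#' @return logical
#' @export
protein_equivalent <- function(comp_a, comp_b) {
  composition_string(comp_a) == composition_string(comp_b)
}

#' Canonical key of a protein set's domain composition
#'
#' The multiset of per-protein canonical composition strings, sorted.  Two
#' protein sets are equivalent under permutation matching iff their keys are
#' equal.
#'
#' @param proteins character vector of protein IDs (a candidate complex)
#' @inheritParams domain_composition
#' @return single character key.
#' @export
set_composition_key <- function(proteins, domains,
                                unannotated = c("pseudo", "empty")) {
  unannotated <- match.arg(unannotated)
  per <- vapply(proteins, function(p)
    composition_string(domain_composition(domains, p, unannotated)), "")
  paste(sort(per), collapse = "\x02")
}

#' Protein-set equivalence under permutation matching
#'
#' True iff the two sets have equal size and some permutation of `set_y`
#' makes every protein of `set_x` pairwise equivalent to its image.
#' Computed via canonical sorted composition keys, which is exact: matching
#' two multisets elementwise is possible iff the multisets are equal.
#'
#' @param set_x,set_y character vectors of protein IDs
#' @inheritParams domain_composition
#' @return logical
#' @export
set_equivalent <- function(set_x, set_y, domains,
                           unannotated = c("pseudo", "empty")) {
  if (length(set_x) != length(set_y)) return(FALSE)
  unannotated <- match.arg(unannotated)
  set_composition_key(set_x, domains, unannotated) ==
    set_composition_key(set_y, domains, unannotated)
}

#' Domain composition kernel between two protein sets
#'
#' Indicator kernel: 1 when the sets are equivalent under permutation
#' matching of domain compositions, else 0.
#'
#' @inheritParams set_equivalent
#' @return 0 or 1.
#' @export
kdc <- function(set_x, set_y, domains, unannotated = c("pseudo", "empty")) {
  as.numeric(set_equivalent(set_x, set_y, domains, match.arg(unannotated)))
}

#' Kernel configuration
#'
#' @param alpha mixing parameter between the real-vector kernel on the
#'   features and the domain-composition kernel.  With the default
#'   `"convex"` form the combined kernel is
#'   `(1 - alpha) * <fx, fy> + alpha * Kdc`, `alpha` in `[0, 1]`; with
#'   `"additive"` it is `<fx, fy> + alpha * Kdc`, `alpha >= 0`.  Either way
#'   `alpha = 0` is the features-only linear kernel.
#' @param form `"convex"` (default) or `"additive"`
#' @param f5_mode passed to [compute_features()]
#' @param unannotated passed to [domain_composition()]
#' @return list of class `kernel_config`.
#' @export
kernel_config <- function(alpha = 0.6, form = c("convex", "additive"),
                          f5_mode = "common_abs_diff",
                          unannotated = "pseudo") {
  form <- match.arg(form)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha))
    stop("alpha must be a single number")
  if (form == "convex" && (alpha < 0 || alpha > 1))
    stop("convex combination requires alpha in [0, 1], got ", alpha)
  if (form == "additive" && alpha < 0)
    stop("additive combination requires alpha >= 0, got ", alpha)
  structure(list(alpha = alpha, form = form, f5_mode = f5_mode,
                 unannotated = unannotated), class = "kernel_config")
}

#' Combined kernel value for one example pair
#'
#' @param fx,fy numeric feature vectors (already scaled)
#' @param kdc_xy domain-composition kernel value in `{0, 1}`
#' @param config a [kernel_config()]
#' @return numeric kernel value.
#' @export
combined_kernel <- function(fx, fy, kdc_xy, config = kernel_config()) {
  lin <- sum(fx * fy)
  if (config$form == "convex")
    (1 - config$alpha) * lin + config$alpha * kdc_xy
  else lin + config$alpha * kdc_xy
}

#' Domain-composition Gram matrix over examples
#'
#' Groups examples by the canonical composition key of their protein set
#' (one key computation per example), then marks kernel value 1 within each
#' equivalence class — equivalent to, and tested against, the pairwise
#' permutation computation, but O(N log N) instead of O(N^2) matchings.
#'
#' @param examples data.frame with columns `protein_a`, `protein_b` (the
#'   size-2 candidate complexes)
#' @inheritParams domain_composition
#' @return N x N numeric 0/1 matrix.
#' @export
kdc_gram <- function(examples, domains, unannotated = c("pseudo", "empty")) {
  unannotated <- match.arg(unannotated)
  keys <- vapply(seq_len(nrow(examples)), function(i)
    set_composition_key(c(examples$protein_a[[i]], examples$protein_b[[i]]),
                        domains, unannotated), "")
  cls <- match(keys, unique(keys))
  outer(cls, cls, `==`) + 0
}

#' Combined Gram matrix over examples
#'
#' @param examples data.frame with `protein_a`, `protein_b`
#' @param features numeric matrix of (scaled) feature rows, one per example
#' @param domains a [domain_annotation()]
#' @param config a [kernel_config()]
#' @return symmetric N x N Gram matrix.
#' @export
build_gram <- function(examples, features, domains, config = kernel_config()) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(examples))
    stop("examples and feature rows are indexed inconsistently (",
         nrow(examples), " vs ", nrow(features), ")")
  lin <- tcrossprod(features)
  kd <- if (config$alpha > 0) kdc_gram(examples, domains, config$unannotated)
        else matrix(0, nrow(examples), nrow(examples))
  combine_grams(lin, kd, config)
}

combine_grams <- function(lin, kd, config) {
  if (config$form == "convex")
    (1 - config$alpha) * lin + config$alpha * kd
  else lin + config$alpha * kd
}
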