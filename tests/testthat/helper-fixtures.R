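# Shared fixtures and independent brute-force oracles.

# Build a ppi_network from "a b w" strings.
net_from <- function(...) {
  rows <- strsplit(c(...), " +")
  ppi_network(data.frame(a = vapply(rows, `[`, "", 1L),
                         b = vapply(rows, `[`, "", 2L),
                         weight = as.numeric(vapply(rows, `[`, "", 3L)),
                         stringsAsFactors = FALSE))
}

# The worked example: complex C1 = {A,B,C,D} with five of its six internal
# pairs interacting, and heterodimer C2 = {A,B} catalogued separately.
fig2_catalog <- function() complex_catalog(complexes = list(
  C1 = c("A", "B", "C", "D"), C2 = c("A", "B")))

fig2_network <- function() net_from(
  "A B 5", "A C 4", "B C 3", "B D 6", "C D 2")

# Brute-force dataset construction: apply the positive and negative rules
# literally to every unordered pair of proteins.
brute_dataset <- function(catalog, network) {
  prots <- sort(unique(c(unlist(catalog), network$vertices)))
  pos <- character(0); neg <- character(0)
  sizes <- lengths(catalog)
  if (length(prots) >= 2) for (i in seq_along(prots)[-length(prots)]) {
    for (j in seq((i + 1), length(prots))) {
      a <- prots[[i]]; b <- prots[[j]]
      if (!is_edge_of(network, a, b)) next
      pair <- c(a, b)
      as_dimer <- names(catalog)[vapply(catalog, function(m)
        length(m) == 2L && setequal(m, pair), logical(1))]
      if (length(as_dimer)) {
        proper <- any(vapply(catalog[setdiff(names(catalog), as_dimer)],
                             function(m) all(pair %in% m) && length(m) > 2L,
                             logical(1)))
        if (!proper) pos <- c(pos, paste(a, b))
        next  # a catalogued dimer pair is never a negative
      }
      in_large <- any(vapply(catalog[sizes > 2L], function(m)
        all(pair %in% m), logical(1)))
      if (in_large) neg <- c(neg, paste(a, b))
    }
  }
  list(positives = sort(pos), negatives = sort(neg))
}

is_edge_of <- function(network, a, b) {
  any(network$edges$a == min(a, b) & network$edges$b == max(a, b))
}

# Brute-force F1-F5 by scanning all edges of the graph.
brute_features_w <- function(network, a, b) {
  ed <- network$edges
  stopifnot(is_edge_of(network, a, b))
  f1 <- ed$weight[ed$a == min(a, b) & ed$b == max(a, b)]
  inc <- (ed$a %in% c(a, b) | ed$b %in% c(a, b)) &
    !(ed$a %in% c(a, b) & ed$b %in% c(a, b))
  nbw <- ed$weight[inc]
  f2 <- if (length(nbw)) max(nbw) else 0
  f3 <- if (length(nbw)) min(nbw) else 0
  others <- setdiff(unique(c(ed$a, ed$b)), c(a, b))
  f4 <- 0; f5 <- 0
  for (k in others) {
    wa <- ed$weight[(ed$a == min(a, k) & ed$b == max(a, k))]
    wb <- ed$weight[(ed$a == min(b, k) & ed$b == max(b, k))]
    if (length(wa) && length(wb)) {
      f4 <- max(f4, min(wa, wb))
      f5 <- max(f5, abs(wa - wb))
    }
  }
  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5)
}

# Random connected-ish weighted graph on <= n_max vertices.
random_network <- function(n_max = 10) {
  n <- sample(2:n_max, 1)
  prots <- sprintf("p%02d", seq_len(n))
  cmb <- utils::combn(prots, 2)
  keep <- runif(ncol(cmb)) < 0.5
  if (!any(keep)) keep[sample(ncol(cmb), 1)] <- TRUE
  ppi_network(data.frame(a = cmb[1, keep], b = cmb[2, keep],
                         weight = round(rlnorm(sum(keep), 1, 0.8), 3),
                         stringsAsFactors = FALSE))
}

# Random domain annotation over the given proteins.
random_domains <- function(proteins, vocab = 8, annotate_prob = 0.9) {
  comp <- list()
  for (p in proteins) {
    if (runif(1) > annotate_prob) next
    k <- sample(1:3, 1)
    d <- table(sample(sprintf("d%d", seq_len(vocab)), k, replace = TRUE))
    comp[[p]] <- stats::setNames(as.integer(d), names(d))
  }
  domain_annotation(comp)
}

# Set equivalence by explicit enumeration of all permutations (the
# definition, independent of the canonical-form implementation).
perm_set_equivalent <- function(set_x, set_y, domains, unannotated = "pseudo") {
  if (length(set_x) != length(set_y)) return(FALSE)
  comp <- function(p) domain_composition(domains, p, unannotated)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[[i]], rest)
    out
  }
  for (sigma in perms(set_y)) {
    if (all(vapply(seq_along(set_x), function(i)
      protein_equivalent(comp(set_x[[i]]), comp(sigma[[i]])), logical(1))))
      return(TRUE)
  }
  FALSE
}

# Tiny labelled feature table for classifier unit tests: 1-D separable toy
# embedded in the package's table layout.
toy_feature_table <- function(x, labels) {
  data.frame(protein_a = sprintf("a%02d", seq_along(x)),
             protein_b = sprintf("b%02d", seq_along(x)),
             F1 = x, F2 = 0, F3 = 0, F4 = 0, F5 = 0, F6 = 0, F7 = 0,
             label = labels, stringsAsFactors = FALSE)
}
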