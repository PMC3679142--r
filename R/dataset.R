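# Labelled-example construction from a complex catalogue and a weighted
# network.  Positives: catalogued size-2 complexes whose pair is a network
# edge and is not a proper subset of any other catalogued complex.
# Negatives: interacting pairs inside complexes of size > 2, excluding any
# pair that is itself a catalogued size-2 complex.

#' Select positive examples (heterodimeric complexes)
#'
#' A positive example is a catalogued complex of exactly two proteins whose
#' pair (i) is an edge of the interaction network and (ii) is not a proper
#' subset of any other catalogued complex.  An identically-membered
#' duplicate complex under another name does not disqualify a pair: equal
#' sets are not proper subsets.
#'
#' @param catalog a [complex_catalog()]
#' @param network a [ppi_network()]
#' @return data.frame with columns `protein_a`, `protein_b`, `label` (+1),
#'   `provenance` (source complex name), ordered lexicographically by pair.
#' @export
select_positives <- function(catalog, network) {
  sizes <- lengths(catalog)
  out <- empty_examples()
  for (nm in names(catalog)[sizes == 2L]) {
    pr <- catalog[[nm]]
    if (!has_edge(network, pr[[1]], pr[[2]])) next
    others <- catalog[setdiff(names(catalog), nm)]
    proper_subset <- any(vapply(others, function(members)
      length(members) > 2L && all(pr %in% members), logical(1)))
    if (proper_subset) next
    out <- rbind(out, data.frame(protein_a = pr[[1]], protein_b = pr[[2]],
                                 label = 1L, provenance = nm,
                                 stringsAsFactors = FALSE))
  }
  # identically-membered dimer complexes map to one example per pair
  if (nrow(out)) {
    key <- pair_key(out$protein_a, out$protein_b)
    if (anyDuplicated(key)) {
      prov <- tapply(out$provenance, key, paste, collapse = ";")
      out <- out[!duplicated(key), , drop = FALSE]
      out$provenance <- unname(prov[pair_key(out$protein_a, out$protein_b)])
    }
  }
  order_examples(out)
}

#' Select negative examples (pairs within larger complexes)
#'
#' Every unordered pair of proteins that co-occurs in at least one complex
#' of size greater than two and is an edge of the network, excluding any
#' pair that is itself a catalogued size-2 complex.  Pairs co-occurring in
#' several large complexes appear once, with provenance listing all of them.
#'
#' @inheritParams select_positives
#' @param positives ignored (negatives are defined by the catalogue alone;
#'   retained so the two selectors compose explicitly)
#' @return data.frame like [select_positives()] with `label` = -1.
#' @export
select_negatives <- function(catalog, network, positives = NULL) {
  sizes <- lengths(catalog)
  dimer_keys <- vapply(catalog[sizes == 2L],
                       function(pr) pair_key(pr[[1]], pr[[2]]), "")
  acc_key <- character(0); acc_a <- character(0); acc_b <- character(0)
  acc_src <- list()
  for (nm in names(catalog)[sizes > 2L]) {
    members <- catalog[[nm]]
    cmb <- utils::combn(members, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      if (!has_edge(network, a, b)) next
      k <- pair_key(a, b)
      if (k %in% dimer_keys) next
      hit <- match(k, acc_key)
      if (is.na(hit)) {
        acc_key <- c(acc_key, k)
        cp <- canonical_pair(a, b)
        acc_a <- c(acc_a, cp$a); acc_b <- c(acc_b, cp$b)
        acc_src[[length(acc_src) + 1L]] <- nm
      } else {
        acc_src[[hit]] <- c(acc_src[[hit]], nm)
      }
    }
  }
  if (!length(acc_key)) return(empty_examples())
  out <- data.frame(protein_a = acc_a, protein_b = acc_b, label = -1L,
                    provenance = vapply(acc_src, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  order_examples(out)
}

#' Build the full labelled dataset
#'
#' Concatenates [select_positives()] and [select_negatives()] and asserts
#' that the two sets are disjoint (they are by construction: a positive is a
#' size-2 complex, which the negative rule excludes).
#'
#' @inheritParams select_positives
#' @return data.frame of labelled examples; attribute `counts` holds
#'   `c(positive = ..., negative = ...)`.
#' @export
build_dataset <- function(catalog, network) {
  pos <- select_positives(catalog, network)
  neg <- select_negatives(catalog, network)
  if (nrow(pos) && nrow(neg)) {
    overlap <- intersect(pair_key(pos$protein_a, pos$protein_b),
                         pair_key(neg$protein_a, neg$protein_b))
    if (length(overlap))
      stop("internal consistency error: ", length(overlap),
           " pair(s) labelled both positive and negative")
  }
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  attr(out, "counts") <- c(positive = nrow(pos), negative = nrow(neg))
  out
}

empty_examples <- function() {
  data.frame(protein_a = character(0), protein_b = character(0),
             label = integer(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

order_examples <- function(df) {
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}
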