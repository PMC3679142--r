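# Synthetic benchmark generator.
#
# Emulates the structure the classifier exploits in a curated weighted PPI
# compendium: planted heterodimers (one strong internal edge, weak
# neighbourhood), planted larger complexes (dense strong internal
# subgraphs, whose member pairs are the hard negatives), right-skewed
# positive edge weights (log-normal, strong internal location versus weak
# background location), background proteins and edges, per-protein domain
# multisets, and a configurable fraction of heterodimer pairs that share an
# exact domain-composition class.  A sub-fraction of those sharing pairs is
# made "hard": both members also attach strongly to a common decoy
# neighbour, so their weight features mimic a larger complex and only the
# domain-composition kernel can recover them.

#' Synthetic benchmark configuration
#'
#' @param n_background_proteins background proteins not in any complex
#' @param n_heterodimers planted size-2 complexes (the positives)
#' @param n_large_complexes planted complexes of size 3-6 (their interacting
#'   member pairs are the negatives)
#' @param large_size_range inclusive size range of the large complexes
#' @param internal_meanlog,internal_sdlog log-normal location/spread of
#'   within-complex edge weights (strong)
#' @param background_meanlog,background_sdlog log-normal location/spread of
#'   background and attachment edge weights (weak)
#' @param internal_edge_prob probability that each within-large-complex pair
#'   is observed as an interaction
#' @param background_edge_prob edge probability among background proteins
#' @param attach_range inclusive range of weak background attachments per
#'   complex member (ignored when there are no background proteins)
#' @param domain_vocab_size number of distinct domain identifiers
#' @param domains_per_protein inclusive range of domains per protein (drawn
#'   with replacement, so repeated domains occur)
#' @param shared_composition_fraction fraction of heterodimer pairs placed
#'   in shared exact domain-composition classes
#' @param hard_fraction fraction of heterodimer pairs additionally given a
#'   strong common decoy neighbour (drawn from the sharing pairs, so the
#'   composition kernel can rescue them)
#' @param seed RNG seed; generation is deterministic given the config
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_background_proteins = 300L,
                             n_heterodimers = 40L,
                             n_large_complexes = 20L,
                             large_size_range = c(3L, 6L),
                             internal_meanlog = 3, internal_sdlog = 0.3,
                             background_meanlog = 0.5, background_sdlog = 0.5,
                             internal_edge_prob = 0.9,
                             background_edge_prob = 0.01,
                             attach_range = c(1L, 3L),
                             domain_vocab_size = 60L,
                             domains_per_protein = c(1L, 4L),
                             shared_composition_fraction = 0.3,
                             hard_fraction = 0.15,
                             seed = 1L) {
  cfg <- list(n_background_proteins = as.integer(n_background_proteins),
              n_heterodimers = as.integer(n_heterodimers),
              n_large_complexes = as.integer(n_large_complexes),
              large_size_range = as.integer(large_size_range),
              internal_meanlog = internal_meanlog,
              internal_sdlog = internal_sdlog,
              background_meanlog = background_meanlog,
              background_sdlog = background_sdlog,
              internal_edge_prob = internal_edge_prob,
              background_edge_prob = background_edge_prob,
              attach_range = as.integer(attach_range),
              domain_vocab_size = as.integer(domain_vocab_size),
              domains_per_protein = as.integer(domains_per_protein),
              shared_composition_fraction = shared_composition_fraction,
              hard_fraction = hard_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_background_proteins, n_heterodimers, n_large_complexes) < 0))
      stop("counts must be >= 0")
    if (internal_sdlog < 0 || background_sdlog < 0)
      stop("log-normal spreads must be >= 0")
    if (shared_composition_fraction < 0 || shared_composition_fraction > 1 ||
        hard_fraction < 0 || hard_fraction > 1)
      stop("fractions must lie in [0, 1]")
    if (shared_composition_fraction > 0 && n_heterodimers == 0L)
      stop("cannot share compositions across 0 heterodimers")
    if (round(hard_fraction * n_heterodimers) > 0 && n_background_proteins == 0L)
      stop("hard heterodimers need background proteins to serve as decoys")
    if (internal_edge_prob < 0 || internal_edge_prob > 1 ||
        background_edge_prob < 0 || background_edge_prob > 1)
      stop("edge probabilities must lie in [0, 1]")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic weighted PPI benchmark
#'
#' @param config a [synthetic_config()]
#' @return list with `network` ([ppi_network()]), `catalog`
#'   ([complex_catalog()]), `domains` ([domain_annotation()]) and `truth`
#'   (the intended labelled examples, in the layout of [build_dataset()]).
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  stopifnot(is(config, "synthetic_config"))
  with_seed(config$seed, generate_benchmark_impl(config))
}

generate_benchmark_impl <- function(cfg) {
  rln <- function(n, kind) {
    if (kind == "internal") rlnorm(n, cfg$internal_meanlog, cfg$internal_sdlog)
    else rlnorm(n, cfg$background_meanlog, cfg$background_sdlog)
  }
  bg <- if (cfg$n_background_proteins > 0)
    sprintf("bg%04d", seq_len(cfg$n_background_proteins)) else character(0)
  ea <- character(0); eb <- character(0); ew <- numeric(0)
  add_edges <- function(a, b, w) {
    ea <<- c(ea, a); eb <<- c(eb, b); ew <<- c(ew, w)
  }

  # --- planted heterodimers -----------------------------------------------
  catalog <- list()
  hd_a <- hd_b <- character(0)
  if (cfg$n_heterodimers > 0) {
    hd_a <- sprintf("hd%03da", seq_len(cfg$n_heterodimers))
    hd_b <- sprintf("hd%03db", seq_len(cfg$n_heterodimers))
    add_edges(hd_a, hd_b, rln(cfg$n_heterodimers, "internal"))
    for (i in seq_len(cfg$n_heterodimers))
      catalog[[sprintf("HD%03d", i)]] <- c(hd_a[[i]], hd_b[[i]])
  }

  # --- planted large complexes (dense strong subgraphs) -------------------
  lc_members <- list()
  if (cfg$n_large_complexes > 0) {
    sizes <- sample(seq(cfg$large_size_range[[1]], cfg$large_size_range[[2]]),
                    cfg$n_large_complexes, replace = TRUE)
    for (j in seq_len(cfg$n_large_complexes)) {
      members <- sprintf("lc%02d_%d", j, seq_len(sizes[[j]]))
      lc_members[[sprintf("LC%02d", j)]] <- members
      catalog[[sprintf("LC%02d", j)]] <- members
      cmb <- utils::combn(members, 2L)
      keep <- runif(ncol(cmb)) < cfg$internal_edge_prob
      if (any(keep))
        add_edges(cmb[1L, keep], cmb[2L, keep], rln(sum(keep), "internal"))
    }
  }

  # --- background edges and weak attachments ------------------------------
  if (length(bg) > 1L && cfg$background_edge_prob > 0) {
    cmb <- utils::combn(bg, 2L)
    keep <- runif(ncol(cmb)) < cfg$background_edge_prob
    if (any(keep))
      add_edges(cmb[1L, keep], cmb[2L, keep], rln(sum(keep), "background"))
  }
  complex_proteins <- unique(c(hd_a, hd_b, unlist(lc_members)))
  if (length(bg) > 0L && length(complex_proteins) > 0L) {
    for (p in complex_proteins) {
      k <- sample(seq(cfg$attach_range[[1]], cfg$attach_range[[2]]), 1L)
      k <- min(k, length(bg))
      if (k > 0L) add_edges(rep(p, k), sample(bg, k), rln(k, "background"))
    }
  }

  # --- composition-sharing classes and hard heterodimers ------------------
  n_hd <- cfg$n_heterodimers
  n_shared <- round(cfg$shared_composition_fraction * n_hd)
  n_hard <- round(cfg$hard_fraction * n_hd)
  shared_idx <- if (n_shared > 0) sort(sample(seq_len(n_hd), n_shared)) else integer(0)
  class_of <- integer(0)
  if (n_shared > 0) {
    # classes of ~6 pairs: enough same-class training mates that the
    # indicator kernel's dual-weight sum can outweigh a feature deficit
    n_classes <- max(1L, floor(n_shared / 6L))
    class_of <- rep(seq_len(n_classes), length.out = n_shared)
  }
  # hard pairs: drawn from the sharing classes first (at most half a class,
  # so every hard pair keeps easy classmates the kernel can lean on), any
  # excess from the remaining heterodimers
  hard_idx <- integer(0)
  if (n_hard > 0) {
    by_class <- split(seq_len(n_shared), class_of)
    take <- unlist(lapply(by_class, function(ix) ix[seq_len(max(0L, length(ix) %/% 2L))]))
    hard_idx <- shared_idx[sort(take[seq_len(min(n_hard, length(take)))])]
    extra <- n_hard - length(hard_idx)
    if (extra > 0) {
      pool <- setdiff(seq_len(n_hd), hard_idx)
      hard_idx <- sort(c(hard_idx, sample(pool, min(extra, length(pool)))))
    }
    for (i in hard_idx) {
      decoy <- sample(bg, 1L)
      add_edges(c(hd_a[[i]], hd_b[[i]]), rep(decoy, 2L), rln(2L, "internal"))
    }
  }

  # --- assemble network (dedupe duplicate draws, keep max weight) ---------
  network <- ppi_network(data.frame(a = ea, b = eb, weight = ew,
                                    stringsAsFactors = FALSE))

  # --- domain annotations -------------------------------------------------
  vocab <- sprintf("PFsyn%04d", seq_len(cfg$domain_vocab_size))
  draw_comp <- function() {
    k <- sample(seq(cfg$domains_per_protein[[1]], cfg$domains_per_protein[[2]]), 1L)
    dom <- sample(vocab, k, replace = TRUE)
    v <- table(dom)
    stats::setNames(as.integer(v), names(v))
  }
  proteins <- network$vertices
  comp <- stats::setNames(lapply(proteins, function(p) draw_comp()), proteins)
  if (n_shared > 0) {
    for (cl in unique(class_of)) {
      template_a <- draw_comp(); template_b <- draw_comp()
      for (pos_in_shared in which(class_of == cl)) {
        i <- shared_idx[[pos_in_shared]]
        # random role assignment exercises crossed permutation matching
        if (runif(1) < 0.5) {
          comp[[hd_a[[i]]]] <- template_a; comp[[hd_b[[i]]]] <- template_b
        } else {
          comp[[hd_a[[i]]]] <- template_b; comp[[hd_b[[i]]]] <- template_a
        }
      }
    }
  }
  domains <- domain_annotation(comp)

  # --- intended truth labels ----------------------------------------------
  pos <- if (n_hd > 0) data.frame(
    protein_a = pmin(hd_a, hd_b), protein_b = pmax(hd_a, hd_b),
    label = 1L, provenance = sprintf("HD%03d", seq_len(n_hd)),
    stringsAsFactors = FALSE) else empty_examples()
  negs <- empty_examples()
  for (nm in names(lc_members)) {
    cmb <- utils::combn(lc_members[[nm]], 2L)
    present <- vapply(seq_len(ncol(cmb)), function(j)
      has_edge(network, cmb[1L, j], cmb[2L, j]), logical(1))
    if (any(present)) {
      cp <- canonical_pair(cmb[1L, present], cmb[2L, present])
      negs <- rbind(negs, data.frame(protein_a = cp$a, protein_b = cp$b,
                                     label = -1L, provenance = nm,
                                     stringsAsFactors = FALSE))
    }
  }
  truth <- rbind(order_examples(pos), order_examples(negs))
  rownames(truth) <- NULL
  attr(truth, "hard_pairs") <- if (length(hard_idx))
    pair_key(hd_a[hard_idx], hd_b[hard_idx]) else character(0)

  list(network = network,
       catalog = complex_catalog(complexes = catalog),
       domains = domains,
       truth = truth)
}
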