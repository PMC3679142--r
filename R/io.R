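#' Construct a weighted PPI network from an edge table
#'
#' Vertices are opaque, case-sensitive protein identifiers; each unordered
#' pair of distinct proteins carries at most one positive finite weight,
#' interpreted as the reliability and strength of the interaction.
#'
#' @param edges data.frame with columns `a`, `b` (character protein IDs) and
#'   `weight` (positive finite numeric).  Self-loops are rejected; duplicate
#'   unordered pairs are collapsed to their maximum weight.
#' @return An object of class `ppi_network`: a list with the canonical edge
#'   table (`edges`, with `a < b` within each row), the vertex set
#'   (`vertices`), and an adjacency list (`adj`) mapping each protein to a
#'   named vector of neighbour weights.
#' @export
ppi_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "weight") %in% names(edges)))
  a <- as.character(edges$a)
  b <- as.character(edges$b)
  w <- as.numeric(edges$weight)
  if (any(a == b)) stop("self-loops are not allowed in a ppi_network")
  if (any(!is.finite(w) | w <= 0)) stop("edge weights must be positive and finite")
  cp <- canonical_pair(a, b)
  key <- paste(cp$a, cp$b, sep = "\x1f")
  if (anyDuplicated(key)) {
    w <- tapply(w, key, max)
    key <- names(w)
    parts <- strsplit(key, "\x1f", fixed = TRUE)
    cp <- list(a = vapply(parts, `[`, "", 1L), b = vapply(parts, `[`, "", 2L))
    w <- as.numeric(w)
  }
  ord <- order(cp$a, cp$b)
  ed <- data.frame(a = cp$a[ord], b = cp$b[ord], weight = w[ord],
                   stringsAsFactors = FALSE)
  structure(list(
    edges = ed,
    vertices = sort(unique(c(ed$a, ed$b))),
    adj = build_adjacency(ed),
    edge_index = stats::setNames(seq_len(nrow(ed)),
                                 paste(ed$a, ed$b, sep = "\x1f"))
  ), class = "ppi_network")
}

build_adjacency <- function(ed) {
  ends <- c(ed$a, ed$b)
  other <- c(ed$b, ed$a)
  w <- c(ed$weight, ed$weight)
  split_idx <- split(seq_along(ends), ends)
  lapply(split_idx, function(i) stats::setNames(w[i], other[i]))
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$vertices), "proteins,", nrow(x$edges), "weighted edges\n")
  invisible(x)
}

#' Edge weight lookup
#'
#' @param network a [ppi_network()]
#' @param a,b protein IDs (order irrelevant)
#' @return The edge weight, or `NA` if the pair is not an edge.
#' @export
edge_weight <- function(network, a, b) {
  i <- unname(network$edge_index[pair_key(a, b)])
  ifelse(is.na(i), NA_real_, network$edges$weight[i])
}

has_edge <- function(network, a, b) !is.na(network$edge_index[pair_key(a, b)])

# ---------------------------------------------------------------------------
# Delimited-text readers.  Dialect: tab, semicolon or comma, auto-detected on
# the first data row (whitespace as fallback); override with `delimiter`.
# ---------------------------------------------------------------------------

detect_delimiter <- function(line) {
  counts <- vapply(c("\t", ";", ","), function(d)
    length(gregexpr(d, line, fixed = TRUE)[[1]][gregexpr(d, line, fixed = TRUE)[[1]] > 0]),
    integer(1))
  if (all(counts == 0)) return("")   # read.table whitespace default
  names(counts)[which.max(counts)]
}

read_delimited <- function(path, delimiter = NULL, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: empty file: ", path)
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1]])
  tab <- utils::read.table(text = lines, sep = delimiter, header = FALSE,
                           colClasses = "character", fill = TRUE,
                           strip.white = TRUE, quote = "", comment.char = "")
  if (ncol(tab) < min_cols)
    stop("format error: expected at least ", min_cols, " columns in ", path)
  tab
}

#' Read a weighted PPI network from WI-PHI-style delimited text
#'
#' Each data row is `proteinA <sep> proteinB <sep> weight`.  Self-interaction
#' rows are dropped (and counted), duplicate unordered pairs are collapsed to
#' their maximum weight, and rows whose weight column is non-numeric (e.g. a
#' header) are skipped with a count, so files with or without headers parse
#' identically.
#'
#' @param path path to the edge table.
#' @param delimiter optional single-character field separator; by default
#'   tab/semicolon/comma are auto-detected on the first row, falling back to
#'   whitespace.
#' @return A [ppi_network()].  Attributes `n_self_dropped`, `n_skipped` and
#'   `n_collapsed` record dropped self-interactions, skipped non-numeric
#'   rows, and duplicate pairs collapsed.
#' @export
read_network <- function(path, delimiter = NULL) {
  tab <- read_delimited(path, delimiter, min_cols = 3L)
  a <- tab[[1]]; b <- tab[[2]]
  w <- suppressWarnings(as.numeric(tab[[3]]))
  skip <- is.na(w)
  n_skipped <- sum(skip)
  a <- a[!skip]; b <- b[!skip]; w <- w[!skip]
  if (length(w) == 0L) stop("format error: no parsable data rows in ", path)
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad))
    stop("format error: non-positive or non-finite weight at data row ", bad[[1]])
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; w <- w[!self]
  if (length(w) == 0L) stop("format error: all rows were self-interactions in ", path)
  key <- pair_key(a, b)
  n_collapsed <- sum(duplicated(key))
  if (n_collapsed > 0)
    message("read_network: collapsed ", n_collapsed,
            " duplicate pair row(s) to the maximum weight")
  net <- ppi_network(data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE))
  attr(net, "n_self_dropped") <- n_self
  attr(net, "n_skipped") <- n_skipped
  attr(net, "n_collapsed") <- n_collapsed
  net
}

#' Write a weighted PPI network as 3-column delimited text
#'
#' @param network a [ppi_network()]
#' @param path output path
#' @param delimiter field separator (default tab)
#' @export
write_network <- function(network, path, delimiter = "\t") {
  utils::write.table(network$edges, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a complex catalogue from CYC2008-style membership rows
#'
#' Each data row is `protein <sep> complex`.  Rows are grouped by complex
#' name; duplicate (protein, complex) rows are deduplicated with a warning;
#' complexes left with fewer than two distinct members are dropped with a
#' warning (a complex has at least two subunits by definition).
#'
#' @inheritParams read_network
#' @return An object of class `complex_catalog`: a named list of character
#'   vectors of member protein IDs.
#' @export
read_catalog <- function(path, delimiter = NULL) {
  tab <- read_delimited(path, delimiter, min_cols = 2L)
  complex_catalog(members = tab[[1]], complex = tab[[2]])
}

#' Construct a complex catalogue
#'
#' @param members character vector of protein IDs (ignored when `complexes`
#'   is given)
#' @param complex character vector of complex names, parallel to `members`
#' @param complexes alternatively, a named list of character member vectors
#' @return A `complex_catalog`: named list of character vectors, every
#'   complex with >= 2 distinct members.
#' @export
complex_catalog <- function(members = NULL, complex = NULL, complexes = NULL) {
  if (is.null(complexes)) {
    stopifnot(length(members) == length(complex))
    dup <- duplicated(paste(members, complex, sep = "\x1f"))
    if (any(dup))
      warning("dropping ", sum(dup), " duplicate (protein, complex) row(s)")
    complexes <- lapply(split(as.character(members)[!dup],
                              as.character(complex)[!dup]), unique)
  }
  if (length(complexes) &&
      (is.null(names(complexes)) || anyDuplicated(names(complexes))))
    stop("complex names must be present and unique")
  sizes <- lengths(complexes)
  if (any(sizes < 2L)) {
    warning("dropping ", sum(sizes < 2L), " singleton complex(es): ",
            paste(names(complexes)[sizes < 2L], collapse = ", "))
    complexes <- complexes[sizes >= 2L]
  }
  structure(lapply(complexes, function(x) sort(as.character(x))),
            class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat("complex_catalog:", length(x), "complexes (",
      sum(lengths(x) == 2L), "of size 2 )\n")
  invisible(x)
}

#' Read protein-domain annotations
#'
#' Each data row is `protein <sep> domain[ <sep> count]`.  A missing count
#' defaults to 1; counts accumulate across repeated rows, so a protein's
#' annotation is a multiset of domain identifiers.  Proteins absent from the
#' file are unannotated.
#'
#' @inheritParams read_network
#' @return An object of class `domain_annotation`: a named list mapping each
#'   protein ID to a named integer vector of domain counts (all >= 1).
#' @export
read_domains <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(domain_annotation(list()))
  delim <- if (is.null(delimiter)) detect_delimiter(lines[[1]]) else delimiter
  tab <- utils::read.table(text = lines, sep = delim, header = FALSE,
                           colClasses = "character", fill = TRUE,
                           strip.white = TRUE, quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("format error: expected at least 2 columns in ", path)
  cnt <- if (ncol(tab) >= 3L) {
    raw <- tab[[3]]
    v <- suppressWarnings(as.numeric(raw))
    v[is.na(v) & !nzchar(raw)] <- 1          # absent third field -> default 1
    v
  } else rep(1, nrow(tab))
  if (any(is.na(cnt)))
    stop("format error: unparseable domain count at data row ", which(is.na(cnt))[[1]])
  if (any(cnt <= 0 | cnt != round(cnt)))
    stop("format error: domain counts must be positive integers (row ",
         which(cnt <= 0 | cnt != round(cnt))[[1]], ")")
  df <- data.frame(protein = tab[[1]], domain = tab[[2]], count = as.integer(cnt),
                   stringsAsFactors = FALSE)
  comp <- lapply(split(df[c("domain", "count")], df$protein), function(d) {
    v <- tapply(d$count, d$domain, sum)
    stats::setNames(as.integer(v), names(v))
  })
  domain_annotation(comp)
}

#' Construct a domain annotation
#'
#' @param composition named list: protein ID -> named integer vector of
#'   domain counts (each >= 1).
#' @return A `domain_annotation`.
#' @export
domain_annotation <- function(composition = list()) {
  if (length(composition)) {
    if (is.null(names(composition))) stop("composition must be named by protein ID")
    composition <- lapply(composition, function(v) {
      if (any(v < 1L)) stop("domain counts must be >= 1")
      v <- stats::setNames(as.integer(v), names(v))
      v[order(names(v))]
    })
  }
  structure(composition, class = "domain_annotation")
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("domain_annotation:", length(x), "annotated proteins\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Intermediate artifacts: feature tables and Gram matrices.
# ---------------------------------------------------------------------------

#' Write / read a labelled feature table
#'
#' Delimited text with header `protein_a, protein_b, F1..F7, label`.
#'
#' @param features data.frame as returned by [feature_matrix()] (pair IDs,
#'   F1..F7, and optionally `label`)
#' @param path file path
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Write / read a Gram matrix with its example index
#'
#' The matrix is written as square delimited text; the example identifiers go
#' to a sidecar index file `<path>.idx`, one per row.
#'
#' @param gram square numeric matrix with row/column names
#' @param path file path for the matrix
#' @export
write_gram <- function(gram, path) {
  stopifnot(is.matrix(gram), nrow(gram) == ncol(gram))
  utils::write.table(gram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(if (is.null(rownames(gram))) as.character(seq_len(nrow(gram)))
             else rownames(gram), paste0(path, ".idx"))
  invisible(path)
}

#' @rdname write_gram
#' @export
read_gram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  ids <- readLines(paste0(path, ".idx"), warn = FALSE)
  if (length(ids) != nrow(m)) stop("index file does not match matrix dimension")
  dimnames(m) <- list(ids, ids)
  m
}
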