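# End-to-end wiring: read inputs -> build dataset -> featurize -> evaluate.
# The command-line entry point (inst/cli/hdimer) is a thin wrapper over
# these exported functions.

#' Run the full prediction pipeline on input files
#'
#' Reads the three input tables, constructs the labelled dataset, computes
#' the feature table, and either cross-validates one parameter setting or
#' runs the parameter grid.  Intermediates (dataset, feature table, Gram
#' matrix) are written to `out_dir` for auditability unless
#' `write_intermediates = FALSE`.
#'
#' @param network_path,catalog_path,domains_path input file paths (see
#'   [read_network()], [read_catalog()], [read_domains()])
#' @param out_dir output directory (created if missing); `NULL` disables all
#'   file output
#' @param kernel a [kernel_config()]
#' @param train a [training_config()]
#' @param cv a [cv_config()]
#' @param feature_set feature subset, e.g. `"F1-7"`
#' @param grid `NULL` for a single [cross_validate()], or a list with
#'   entries `alpha`, `c_plus`, `c_minus` (numeric grids) for
#'   [grid_search()]
#' @param scale min-max scale features per training fold
#' @param write_intermediates write dataset/features/Gram into `out_dir`
#' @param quiet suppress progress messages
#' @return data.frame with columns `feature_set, alpha, c_plus, c_minus,
#'   precision, recall, fmeasure` (one row per evaluated setting);
#'   attribute `dataset` holds the labelled examples.
#' @export
run_pipeline <- function(network_path, catalog_path, domains_path = NULL,
                         out_dir = NULL,
                         kernel = kernel_config(), train = training_config(),
                         cv = cv_config(), feature_set = "F1-7", grid = NULL,
                         scale = TRUE, write_intermediates = TRUE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[hdimer] ", ...)
  for (p in c(network_path, catalog_path, domains_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)

  say("reading network: ", network_path)
  network <- read_network(network_path)
  say(length(network$vertices), " proteins, ", nrow(network$edges),
      " edges (", attr(network, "n_self_dropped"), " self-interactions dropped, ",
      attr(network, "n_skipped"), " non-numeric rows skipped)")
  say("reading catalogue: ", catalog_path)
  catalog <- read_catalog(catalog_path)
  domains <- if (is.null(domains_path)) domain_annotation(list())
             else read_domains(domains_path)

  dataset <- build_dataset(catalog, network)
  cnt <- attr(dataset, "counts")
  say("dataset: ", cnt[["positive"]], " positives, ", cnt[["negative"]],
      " negatives")
  if (cnt[["positive"]] == 0L || cnt[["negative"]] == 0L)
    stop("dataset stage: need both classes to train (got ",
         cnt[["positive"]], " positives, ", cnt[["negative"]], " negatives)")

  features <- feature_matrix(network, domains, dataset,
                             f5_mode = kernel$f5_mode)

  if (!is.null(out_dir) && write_intermediates) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(dataset, file.path(out_dir, "dataset.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_feature_table(features, file.path(out_dir, "features.tsv"))
    sc <- scale_features(feature_columns(features, feature_set))
    gram <- build_gram(features, sc$train, domains, kernel)
    rownames(gram) <- paste(features$protein_a, features$protein_b, sep = "--")
    write_gram(gram, file.path(out_dir, "gram.tsv"))
  }

  results <- if (is.null(grid)) {
    res <- cross_validate(features, domains, kernel, train, cv, scale,
                          feature_set)
    data.frame(feature_set = paste(res$feature_set, collapse = ","),
               alpha = kernel$alpha, c_plus = train$c_plus,
               c_minus = train$c_minus,
               precision = res$mean[["precision"]],
               recall = res$mean[["recall"]],
               fmeasure = res$mean[["fmeasure"]])
  } else {
    grid_search(features, domains,
                alpha_grid = grid$alpha, cplus_grid = grid$c_plus,
                cminus_grid = grid$c_minus, cv = cv,
                form = kernel$form, scale = scale, feature_set = feature_set)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(out_dir, "results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("results written to ", file.path(out_dir, "results.tsv"))
  }
  attr(results, "dataset") <- dataset
  results
}

#' Write a synthetic benchmark to disk in the package's input formats
#'
#' @param config a [synthetic_config()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the list from [generate_benchmark()].
#' @export
write_benchmark <- function(config = synthetic_config(), out_dir) {
  bench <- generate_benchmark(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_network(bench$network, file.path(out_dir, "network.tsv"))
  cat_rows <- data.frame(
    protein = unlist(bench$catalog, use.names = FALSE),
    complex = rep(names(bench$catalog), lengths(bench$catalog)))
  utils::write.table(cat_rows, file.path(out_dir, "catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  dom_rows <- data.frame(
    protein = rep(names(bench$domains), lengths(bench$domains)),
    domain = unlist(lapply(bench$domains, names), use.names = FALSE),
    count = unlist(bench$domains, use.names = FALSE))
  utils::write.table(dom_rows, file.path(out_dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(bench$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(bench)
}

#' Compare parsed inputs against the published reference counts
#'
#' The curated yeast resources this package was designed around have known
#' sizes: 49,607 non-self weighted interactions, 172 size-2 complexes among
#' 408, and a rule-built dataset of 152 positive and 5,345 negative
#' examples.  Given locally available copies of those files (they are not
#' shipped), this reports observed versus expected counts so that reader
#' dialect or deduplication discrepancies can be diagnosed.
#'
#' @param network a [ppi_network()]
#' @param catalog a [complex_catalog()]
#' @param expected named numeric vector of expected counts
#' @return data.frame `quantity, observed, expected, match`.
#' @export
validate_reference_counts <- function(network, catalog,
                                      expected = c(network_pairs = 49607,
                                                   dimer_complexes = 172,
                                                   positives = 152,
                                                   negatives = 5345)) {
  dataset <- build_dataset(catalog, network)
  cnt <- attr(dataset, "counts")
  observed <- c(network_pairs = nrow(network$edges),
                dimer_complexes = sum(lengths(catalog) == 2L),
                positives = unname(cnt[["positive"]]),
                negatives = unname(cnt[["negative"]]))
  data.frame(quantity = names(expected),
             observed = unname(observed[names(expected)]),
             expected = unname(expected),
             match = unname(observed[names(expected)] == expected),
             stringsAsFactors = FALSE)
}
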