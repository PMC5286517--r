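#' Read a TSV edge list
#'
#' Parses a 2-column (unweighted) or 3-column (weighted) tab-separated
#' edge list. Every row must have exactly the expected number of fields;
#' weights must parse as reals in `[0, 1]`. Duplicate edges are collapsed
#' to a single edge keeping the maximum weight, with a warning.
#'
#' @param path File path.
#' @param weighted If `TRUE`, expect a third weight column.
#' @param header If `TRUE`, skip the first line.
#' @return `data.frame` with columns `from`, `to` and (if weighted)
#'   `weight`.
#' @export
read_edge_list <- function(path, weighted = FALSE, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
    if (weighted) out$weight <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (weighted) 3L else 2L
  bad <- which(lengths(fields) != want)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                 bad[1] + as.integer(header), path, want,
                 lengths(fields)[bad[1]]))
  }
  m <- do.call(rbind, fields)
  out <- data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
  if (weighted) {
    w <- suppressWarnings(as.numeric(m[, 3]))
    if (anyNA(w)) {
      stop(sprintf("non-numeric weight at line %d of %s",
                   which(is.na(w))[1] + as.integer(header), path))
    }
    if (any(w < 0 | w > 1)) {
      stop(sprintf("weight out of [0, 1] at line %d of %s",
                   which(w < 0 | w > 1)[1] + as.integer(header), path))
    }
    out$weight <- w
  }
  key <- paste(out$from, out$to, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edges collapsed (maximum weight kept) in ", path)
    if (weighted) {
      keep_w <- tapply(out$weight, key, max)
      out <- out[!duplicated(key), , drop = FALSE]
      out$weight <- unname(keep_w[paste(out$from, out$to, sep = "\r")])
    } else {
      out <- out[!duplicated(key), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Write an edge list as TSV
#'
#' @param edges `data.frame`; all columns are written tab-separated.
#' @param path Output path.
#' @param header Write column names as a first line (default `FALSE`).
#' @export
write_edge_list <- function(edges, path, header = FALSE) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of condition IDs and a first column of gene IDs.
#'
#' @param path File path.
#' @return Numeric matrix, genes x conditions.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expression table needs a gene column and >= 2 conditions")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene IDs in ", path)
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix with gene rownames and condition colnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Expand a GMT gene-set file into co-annotated gene pairs
#'
#' GMT format: one set per line, `name<TAB>description<TAB>member...`.
#' Returns the union over sets of all unordered within-set pairs. Sets
#' with fewer than two members are skipped with a warning.
#'
#' @param path GMT file path.
#' @return `data.frame` with columns `gene_a`, `gene_b` (deduplicated,
#'   `gene_a < gene_b`).
#' @export
expand_gmt_to_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pairs <- unlist(lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    members <- unique(f[-(1:2)])
    if (length(members) < 2) {
      warning(sprintf("gene set '%s' (line %d) has < 2 members; skipped",
                      f[1], i))
      return(character(0))
    }
    cmb <- utils::combn(sort(members), 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE)
  pairs_to_df(sort(unique(pairs)))
}

#' Write all files of a simulated benchmark
#'
#' Emits the five pipeline inputs of a [simulate_benchmark()] result (or
#' the network-level subset of a [simulate_weighted_grn()] result) in the
#' package's TSV formats, plus the ground-truth network for evaluation.
#'
#' @param bench Benchmark list.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- function(f) file.path(dir, f)
  if (!is.null(bench$expression)) {
    write_expression(bench$expression, p("expression.tsv"))
    writeLines(bench$tf_list, p("tf_list.txt"))
    write_edge_list(bench$binding, p("binding.tsv"))
    paths <- c(expression = p("expression.tsv"), tf_list = p("tf_list.txt"),
               binding = p("binding.tsv"))
  }
  if (!is.null(bench$network)) {
    write_edge_list(bench$network, p("network.tsv"))
    paths <- c(paths, network = p("network.tsv"))
  }
  write_edge_list(bench$cofn, p("cofunction.tsv"))
  write_edge_list(bench$gold$regulatory, p("gold_regulatory.tsv"))
  write_edge_list(bench$gold$cofunction, p("gold_cofunction.tsv"))
  write_edge_list(bench$truth, p("truth.tsv"))
  c(paths, cofn = p("cofunction.tsv"),
    gold_regulatory = p("gold_regulatory.tsv"),
    gold_cofunction = p("gold_cofunction.tsv"), truth = p("truth.tsv"))
}

# Default run configuration; unknown user keys are rejected.
default_config <- function() {
  list(
    expression = NULL, tf_list = NULL, binding = NULL, cofunction = NULL,
    gold_regulatory = NULL, gold_cofunction = NULL, out_dir = ".",
    keep_fraction = 0.05, n_trees = 1000, jaccard_threshold = 0.5,
    beta = 1, recall_anchor = "gold", lambda_range = c(0.001, 2.5),
    grid_resolution = c(10, 10),
    anneal = list(t0 = 1, cooling = 0.9, n_levels = 50, n_per_level = 4,
                  delta_f = 0.01),
    n_rounds = 100, fraction = 0.632, epsilon = 0.5, seed = 1
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unspecified settings with package
#' defaults, and rejects unknown keys.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file (e.g. a seed from
#'   the command line).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, user)
  stopifnot(cfg$keep_fraction > 0, cfg$keep_fraction <= 1,
            cfg$n_trees >= 1, cfg$beta > 0,
            cfg$jaccard_threshold >= 0, cfg$jaccard_threshold <= 1,
            cfg$n_rounds >= 1, cfg$fraction > 0, cfg$fraction < 1,
            cfg$epsilon >= 0, cfg$epsilon < 1)
  cfg
}

#' Run the full refinement pipeline from a configuration
#'
#' Executes initial-network inference (expression + binding), meta-network
#' construction, and the hold-out ensemble (which drives hyperparameter
#' learning, belief propagation and scoring), writing all artifacts and a
#' reproducibility manifest to `out_dir`.
#'
#' @param config Configuration list from [load_config()], or a path to a
#'   YAML file.
#' @return Invisibly, a list with `initial`, `modules`, `ensemble` and the
#'   written `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  for (key in c("expression", "tf_list", "binding", "cofunction",
                "gold_regulatory", "gold_cofunction")) {
    if (is.null(config[[key]])) stop("configuration is missing input: ", key)
    if (!file.exists(config[[key]])) {
      stop("input file not found (", key, "): ", config[[key]])
    }
  }
  message("[1/4] initial network: expression regression + binding intersection")
  expr <- preprocess_expression(read_expression(config$expression))
  tf_list <- readLines(config$tf_list)
  binding <- read_edge_list(config$binding)
  names(binding) <- c("regulator", "target")
  binding <- binding[binding$regulator != binding$target, , drop = FALSE]
  initial <- infer_initial_grn(expr, tf_list, binding,
                               keep_fraction = config$keep_fraction,
                               n_trees = config$n_trees, seed = config$seed)
  message(sprintf("      %d links retained", nrow(initial)))

  message("[2/4] meta network + spanning-tree modules")
  cofn <- read_edge_list(config$cofunction, weighted = TRUE)
  names(cofn) <- c("gene_a", "gene_b", "weight")
  meta <- build_meta_network(initial, cofn)
  modules <- extract_modules(meta, initial)
  message(sprintf("      %d meta edges, %d modules", nrow(meta),
                  length(modules)))

  message("[3/4] hold-out ensemble")
  gr <- read_edge_list(config$gold_regulatory)
  names(gr) <- c("regulator", "target")
  gc <- read_edge_list(config$gold_cofunction)
  names(gc) <- c("gene_a", "gene_b")
  gold <- list(regulatory = gr, cofunction = gc)
  ens <- run_ensemble(modules, gold, n_rounds = config$n_rounds,
                      fraction = config$fraction, epsilon = config$epsilon,
                      seed = config$seed,
                      hyperopt = list(lambda_range = config$lambda_range,
                                      resolution = config$grid_resolution,
                                      beta = config$beta,
                                      jaccard_threshold = config$jaccard_threshold,
                                      recall_anchor = config$recall_anchor,
                                      anneal = config$anneal))
  message(sprintf("      %d of %d links selected by the ensemble",
                  nrow(ens$final), nrow(initial)))

  message("[4/4] writing artifacts")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_edge_list(initial, p("initial_network.tsv"), header = TRUE)
  write_edge_list(module_links(modules), p("modules.tsv"), header = TRUE)
  write_edge_list(ens$final, p("final_network.tsv"), header = TRUE)
  write_edge_list(ens$likelihood, p("link_likelihood.tsv"), header = TRUE)
  write_edge_list(ens$rounds, p("rounds.tsv"), header = TRUE)
  manifest <- list(config = config,
                   versions = list(package = as.character(
                     utils::packageVersion("grnrefine")),
                     r = R.version.string),
                   counts = list(initial_links = nrow(initial),
                                 modules = length(modules),
                                 final_links = nrow(ens$final)))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(list(initial = initial, modules = modules, ensemble = ens,
                 paths = c(initial = p("initial_network.tsv"),
                           modules = p("modules.tsv"),
                           final = p("final_network.tsv"),
                           likelihood = p("link_likelihood.tsv"),
                           rounds = p("rounds.tsv"),
                           manifest = p("manifest.yaml"))))
}
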