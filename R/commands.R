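# Run configuration and the high-level commands that tie the stages into
# reproducible file-to-file runs; a thin command-line wrapper around these
# lives in inst/cli/bpfs.R.

#' Run configuration with documented defaults
#'
#' Collects every tunable of the pipeline in one validated list. Unknown
#' keys are rejected. Defaults: candidate-set size `t = 10`; `K = 50`
#' resamples of `fraction = 0.8` of the training samples; ranking length
#' and weight scale `N = 150`; unresolved-interaction probability
#' `p = 0.0088`; influence decay base 2; 10 bins for the
#' mutual-information seed; SVM box constraint 1; 4:1 train/test ratio.
#'
#' @param ... named overrides of any default field.
#' @return object of class `bpfs_config` (a named list).
#' @export
bpfs_config <- function(...) {
  cfg <- list(
    t = 10L, K = 50L, fraction = 0.8, N = 150L,
    p = 0.0088, decay_base = 2, no_path_influence = 0,
    n_bins = 10L, regularization = 1, standardize = FALSE,
    ratio = 0.8, seed = 1L,
    mode = "real_pathway",           # real_pathway | fully_connected | pathway_blind
    literal_delta_j_order = FALSE,
    retrain_per_candidate = FALSE,
    with_replacement = FALSE,
    seed_method = "mutual_information",
    total_genes = 20500L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (!cfg$mode %in% c("real_pathway", "fully_connected", "pathway_blind"))
    stop("mode must be real_pathway, fully_connected or pathway_blind")
  structure(cfg, class = "bpfs_config")
}

#' @export
print.bpfs_config <- function(x, ...) {
  cat("bpfs_config:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a key = value configuration file
#'
#' Plain-text lines `key = value` (or `key: value`); `#` starts a
#' comment. Values are parsed as logical/numeric where possible.
#'
#' @param path file path.
#' @return a [bpfs_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
    parsed <- suppressWarnings(as.numeric(val))
    if (!is.na(parsed)) val <- parsed
    else if (toupper(val) %in% c("TRUE", "FALSE")) val <- as.logical(val)
    over[[key]] <- val
  }
  do.call(bpfs_config, over)
}

# build the graph + mapping for the configured mode
.assemble_graph <- function(config, edges = NULL, membership = NULL,
                            mapping = NULL, fids) {
  map <- if (is.null(mapping)) identity_mapping(fids)
         else read_gene_mapping(mapping)
  miss <- setdiff(fids, names(map))
  if (length(miss)) {  # features absent from the mapping are unresolved
    map <- c(map, stats::setNames(rep("UNRESOLVED", length(miss)), miss))
  }
  genes <- setdiff(unique(unname(map)), "UNRESOLVED")
  g <- switch(config$mode,
    real_pathway = {
      if (is.null(edges)) stop("mode 'real_pathway' needs an edge list")
      consolidate(edges, extra_vertices = genes)
    },
    fully_connected = {
      if (is.null(membership)) stop("mode 'fully_connected' needs a membership table")
      fully_connected_graph(membership, all_genes = genes)
    },
    pathway_blind = {
      igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genes)
    })
  list(graph = g, mapping = map)
}

#' Run the complete selection pipeline on files
#'
#' Loads expression data, builds the configured interaction graph, runs
#' the resampled pathway-aware selection (a single direct selection when
#' `K = 1` and `fraction = 1`) and writes `ranking.tsv`,
#' `weight_matrix.tsv`, `candidate_log.jsonl` and `config.txt` under
#' `out_dir`. Identical config + seed reproduce identical outputs.
#'
#' @param expression,labels paths to the expression matrix and label
#'   table (see [load_expression()]).
#' @param out_dir output directory, created if needed.
#' @param config a [bpfs_config()].
#' @param edges edge-list path(s) (mode `real_pathway`).
#' @param membership membership TSV path (mode `fully_connected`).
#' @param mapping feature-to-gene mapping TSV path; `NULL` treats
#'   feature ids as gene ids.
#' @return the `bpfs_ensemble`, invisibly.
#' @export
cmd_select <- function(expression, labels, out_dir, config = bpfs_config(),
                       edges = NULL, membership = NULL, mapping = NULL) {
  data <- load_expression(expression, labels)
  gm <- .assemble_graph(config, edges, membership, mapping, feature_ids(data))
  model <- influence_model(decay_base = config$decay_base, p = config$p,
                           no_path_influence = config$no_path_influence)
  N <- min(config$N, n_features(data))
  ens <- run_ensemble(data, gm$graph, gm$mapping, model,
                      K = config$K, fraction = config$fraction, N = N,
                      t = config$t, seed = config$seed,
                      with_replacement = config$with_replacement,
                      regularization = config$regularization,
                      seed_method = config$seed_method,
                      n_bins = config$n_bins,
                      literal_delta_j_order = config$literal_delta_j_order,
                      retrain_per_candidate = config$retrain_per_candidate,
                      standardize = config$standardize)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ranking(ens, file.path(out_dir, "ranking.tsv"))
  write_weight_matrix(ens$matrix, file.path(out_dir, "weight_matrix.tsv"))
  logs <- lapply(ens$runs, `[[`, "log")
  con <- file(file.path(out_dir, "candidate_log.jsonl"), "w")
  for (k in seq_along(logs))
    writeLines(jsonlite::toJSON(list(subset = k, log = logs[[k]]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  close(con)
  writeLines(utils::capture.output(print(config)),
             file.path(out_dir, "config.txt"))
  invisible(ens)
}

#' Estimate the unresolved-interaction probability from an edge list
#'
#' Builds the consolidated graph, runs the edge-subsampling reachability
#' pipeline and writes the curve as TSV (s, average reachability, fitted
#' value) when `out` is given.
#'
#' @param edges edge-list path(s).
#' @param config a [bpfs_config()] (`total_genes` and `seed` are used).
#' @param fractions edge fractions to measure; default 0.1..1 by 0.1.
#' @param out optional path for the curve TSV.
#' @return list with `curve`, `p` and `p_reported` (see
#'   [reachability_pipeline()]).
#' @export
cmd_estimate_p <- function(edges, config = bpfs_config(),
                           fractions = seq(0.1, 1, by = 0.1), out = NULL) {
  g <- consolidate(edges)
  res <- reachability_pipeline(g, fractions = fractions,
                               total_genes = config$total_genes,
                               seed = config$seed)
  if (!is.null(out)) {
    utils::write.table(
      data.frame(s = res$curve$fractions,
                 reachability = res$curve$reachabilities,
                 fitted = res$curve$fitted),
      out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Evaluate a ranking: test accuracy versus number of features
#'
#' Splits the data 4:1 (stratified, or uses a stored split plan), trains
#' a linear SVM on the training samples restricted to the top-k ranked
#' features for each k in `ks`, and reports the accuracy on the held-out
#' test samples.
#'
#' @param ranking ranking TSV path (columns rank/feature/weight), a
#'   `bpfs_ensemble`, or a character vector of feature ids in rank
#'   order.
#' @param expression,labels data file paths.
#' @param config a [bpfs_config()] (`ratio`, `seed`, `regularization`).
#' @param ks numbers of top features to evaluate; values beyond the
#'   ranking length are truncated with a warning.
#' @param split optional split-plan TSV (see [write_split_plan()]).
#' @param out optional path for the accuracy table TSV.
#' @return data frame with columns `k` and `accuracy`.
#' @export
cmd_evaluate <- function(ranking, expression, labels,
                         config = bpfs_config(),
                         ks = c(1, 2, 5, 10, 20, 50), split = NULL,
                         out = NULL) {
  data <- load_expression(expression, labels)
  feats <- if (inherits(ranking, "bpfs_ensemble")) ranking$ranking$feature
    else if (is.character(ranking) && length(ranking) == 1 && file.exists(ranking))
      utils::read.table(ranking, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)$feature
    else as.character(ranking)
  plan <- if (is.null(split)) stratified_split(data, config$ratio, config$seed)
          else read_split_plan(split, data)
  train <- data[plan$train_indices, ]
  test <- data[plan$test_indices, ]
  if (any(ks > length(feats))) {
    warning("k values beyond the ranking length (", length(feats),
            ") truncated")
    ks <- unique(pmin(ks, length(feats)))
  }
  acc <- vapply(ks, function(k) {
    fs <- feats[seq_len(k)]
    fit <- e1071::svm(train$values[, fs, drop = FALSE],
                      factor(train$labels, levels = c(-1, 1)),
                      kernel = "linear", cost = config$regularization,
                      scale = FALSE)
    pred <- stats::predict(fit, test$values[, fs, drop = FALSE])
    mean(as.numeric(as.character(pred)) == test$labels)
  }, numeric(1))
  res <- data.frame(k = ks, accuracy = acc)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
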