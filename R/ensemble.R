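# Rank aggregation over resampled selections: each resample contributes a
# ranking row; a feature in 1-based column k of a row earns weight N - k,
# and weights are summed over rows to produce the final ranking.

#' Stack per-resample rankings into a weight matrix
#'
#' @param rankings list of K ordered feature-id vectors, each of length
#'   >= N.
#' @param N ranking length (columns of the matrix) and weight scale.
#' @return K x N character matrix of class `weight_matrix`; row i holds
#'   the first N features of ranking i.
#' @export
build_weight_matrix <- function(rankings, N) {
  if (length(rankings) < 1) stop("need at least one ranking")
  short <- which(vapply(rankings, length, integer(1)) < N)
  if (length(short))
    stop("ranking for subset ", short[1], " has fewer than N = ", N,
         " entries")
  m <- matrix(NA_character_, nrow = length(rankings), ncol = N)
  for (i in seq_along(rankings))
    m[i, ] <- as.character(rankings[[i]])[seq_len(N)]
  structure(m, class = c("weight_matrix", class(m)))
}

#' Aggregate weight of one feature across the matrix
#'
#' Sum over rows of N - k for each occurrence of the feature in (1-based)
#' column k; a feature at columns 3, 14 and 10 of three rows with N = 150
#' scores (150-3) + (150-14) + (150-10) = 423. Absent features score 0.
#'
#' @param matrix a `weight_matrix`.
#' @param feature feature id.
#' @return nonnegative integer weight.
#' @export
feature_weight <- function(matrix, feature) {
  N <- ncol(matrix)
  hits <- which(matrix == feature, arr.ind = TRUE)
  if (nrow(hits) == 0) return(0)
  sum(N - hits[, "col"])
}

#' Aggregate a weight matrix into a final ranking
#'
#' Features are ordered by total weight descending; ties break by the
#' best (smallest) column at which the feature ever appears, then by
#' feature id.
#'
#' @param matrix a `weight_matrix`.
#' @param output_count number of features to return; if it exceeds the
#'   number of distinct features, all are returned with a warning.
#' @return data frame with columns `rank`, `feature`, `weight`.
#' @export
aggregate_ranking <- function(matrix, output_count = ncol(matrix)) {
  N <- ncol(matrix)
  feats <- unique(as.character(matrix))
  cols <- col(matrix)
  weight <- vapply(feats, function(f) sum(N - cols[matrix == f]), numeric(1))
  best_col <- vapply(feats, function(f) min(cols[matrix == f]), numeric(1))
  ord <- order(-weight, best_col, feats)
  if (output_count > length(feats)) {
    warning("output_count = ", output_count, " exceeds ", length(feats),
            " distinct features; returning all")
    output_count <- length(feats)
  }
  keep <- ord[seq_len(output_count)]
  data.frame(rank = seq_len(output_count), feature = feats[keep],
             weight = unname(weight[keep]), stringsAsFactors = FALSE)
}

#' Resampled pathway-aware selection with rank aggregation
#'
#' Draws `K` stratified subsets of the samples ([bootstrap_subsets()]),
#' runs [bpfs_select()] for `N` features on each, stacks the K rankings
#' into a weight matrix and aggregates them into a final ranking. Running
#' the selection over perturbed training sets counters overfitting to any
#' single draw of the (few) samples.
#'
#' @param data an [expression_matrix()] (the training samples).
#' @param graph,mapping,model as in [bpfs_select()].
#' @param K number of resamples; default 50.
#' @param fraction samples per resample as a fraction; default 0.8.
#' @param N per-resample ranking length and weight scale; default 150.
#' @param t candidate-set size; default 10.
#' @param seed integer master seed (fans out to the resampling stage).
#' @param with_replacement passed to [bootstrap_subsets()].
#' @param ... further arguments to [bpfs_select()].
#' @return object of class `bpfs_ensemble`: list with `ranking` (data
#'   frame rank/feature/weight), `matrix` (the `weight_matrix`),
#'   `subsets`, and `runs` (the per-subset `bpfs_selection` objects).
#' @export
run_ensemble <- function(data, graph, mapping, model = influence_model(),
                         K = 50L, fraction = 0.8, N = 150L, t = 10L,
                         seed = 1L, with_replacement = FALSE, ...) {
  if (N > n_features(data))
    stop("N (", N, ") exceeds the number of features (", n_features(data), ")")
  subsets <- bootstrap_subsets(data, K = K, fraction = fraction,
                               seed = stage_seed(seed, 1),
                               with_replacement = with_replacement)
  runs <- lapply(seq_len(K), function(k) {
    tryCatch(
      bpfs_select(data[subsets[[k]], ], graph, mapping, model,
                  target_count = N, t = t, ...),
      error = function(e)
        stop("selection failed on subset ", k, ": ", conditionMessage(e)))
  })
  m <- build_weight_matrix(lapply(runs, `[[`, "selected"), N)
  structure(list(ranking = aggregate_ranking(m, output_count = N),
                 matrix = m, subsets = subsets, runs = runs,
                 K = K, fraction = fraction, N = N, seed = seed),
            class = "bpfs_ensemble")
}

#' @export
print.bpfs_ensemble <- function(x, ...) {
  cat(sprintf("bpfs_ensemble: K = %d resamples, N = %d; top features:\n",
              x$K, x$N))
  print(utils::head(x$ranking, 5), row.names = FALSE)
  invisible(x)
}

#' Write a weight matrix / final ranking as TSV
#' @param x a `weight_matrix` or the ranking data frame
#' @param path output path
#' @export
write_weight_matrix <- function(x, path) {
  utils::write.table(unclass(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
write_ranking <- function(x, path) {
  if (inherits(x, "bpfs_ensemble")) x <- x$ranking
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
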