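# The main pathway-aware forward-selection loop: seed feature, then
# repeatedly take the top-t candidates by marginal classification power and
# keep the one least redundant with the selected set on the pathway graph.

#' Choose the seed feature
#'
#' The first feature is selected on discriminative power alone: by default
#' the feature with maximum mutual information with the class label;
#' alternatively the feature with the best marginal classification power
#' against the empty selected set. Ties break by feature id.
#'
#' @param data an [expression_matrix()].
#' @param method `"mutual_information"` (default) or `"marginal_power"`.
#' @param n_bins bins for the mutual-information estimate.
#' @param regularization SVM box constraint for the marginal-power method.
#' @return a feature id.
#' @export
select_seed <- function(data, method = c("mutual_information", "marginal_power"),
                        n_bins = 10L, regularization = 1) {
  method <- match.arg(method)
  ids <- feature_ids(data)
  if (method == "mutual_information") {
    mi <- vapply(ids, function(f)
      mutual_information(data$values[, f], data$labels, n_bins = n_bins),
      numeric(1))
    ids[order(-mi, ids)][1]
  } else {
    fit0 <- fit_svm(data, character(0), regularization = regularization)
    rank_candidates(data, fit0, character(0), ids, t = 1L)$feature
  }
}

#' Pathway-aware forward feature selection
#'
#' Iteratively grows an ordered feature set. The seed feature is chosen by
#' [select_seed()] (the selected set being empty, redundancy plays no
#' role). Each subsequent round (i) refits the linear SVM on the current
#' selected set, (ii) ranks the remaining features by marginal
#' classification power and keeps the top `t` as candidates, and (iii)
#' selects the candidate with the smallest total influence from the
#' selected set on the interaction graph — the least biologically
#' redundant of the statistically strongest candidates. Influence ties
#' break by better marginal-power rank, then feature id. When fewer than
#' `t` features remain, all of them are candidates.
#'
#' @param data an [expression_matrix()].
#' @param graph interaction graph ([consolidate()],
#'   [fully_connected_graph()], or any named [igraph::igraph]).
#' @param mapping feature id -> gene id / `"UNRESOLVED"` (see
#'   [read_gene_mapping()]); every feature of `data` must appear.
#' @param model an [influence_model()].
#' @param target_count number of features to select, <= number of
#'   features.
#' @param t candidate-set size per round; default 10.
#' @param regularization SVM box constraint; default 1.
#' @param seed_method passed to [select_seed()].
#' @param n_bins bins for the mutual-information seed.
#' @param literal_delta_j_order,retrain_per_candidate passed to
#'   [rank_candidates()].
#' @param standardize center/scale features before SVM training.
#' @return object of class `bpfs_selection`: list with `selected` (ordered
#'   feature ids), `log` (per-iteration data frame of candidates with
#'   their delta J, total influence and the chosen flag), and the call
#'   parameters.
#' @export
bpfs_select <- function(data, graph, mapping, model = influence_model(),
                        target_count, t = 10L, regularization = 1,
                        seed_method = "mutual_information", n_bins = 10L,
                        literal_delta_j_order = FALSE,
                        retrain_per_candidate = FALSE,
                        standardize = FALSE) {
  ids <- feature_ids(data)
  if (target_count > length(ids))
    stop("target_count (", target_count, ") exceeds feature count (",
         length(ids), ")")
  if (t < 1) stop("`t` must be >= 1")
  miss <- setdiff(ids, names(mapping))
  if (length(miss))
    stop("mapping is missing feature id: ", miss[1])

  seed_f <- select_seed(data, method = seed_method, n_bins = n_bins,
                        regularization = regularization)
  selected <- seed_f
  log <- list(data.frame(iteration = 1L, feature = seed_f, delta_j = NA_real_,
                         tif = 0, chosen = TRUE, stringsAsFactors = FALSE))

  while (length(selected) < target_count) {
    it <- length(selected) + 1L
    available <- setdiff(ids, selected)
    fit <- tryCatch(
      fit_svm(data, selected, regularization = regularization,
              standardize = standardize),
      error = function(e)
        stop("SVM training failed at iteration ", it, " with |S| = ",
             length(selected), ": ", conditionMessage(e)))
    cand <- suppressWarnings(rank_candidates(
      data, fit, selected, available, t = min(t, length(available)),
      literal_delta_j_order = literal_delta_j_order,
      retrain_per_candidate = retrain_per_candidate))
    cand$tif <- vapply(cand$feature, function(m)
      total_influence(model, graph, mapping, m, selected), numeric(1))
    # minimum influence; ties by marginal-power rank (row order), then id
    pick <- order(cand$tif, seq_len(nrow(cand)), cand$feature)[1]
    cand$chosen <- seq_len(nrow(cand)) == pick
    cand$iteration <- it
    log[[it]] <- cand[, c("iteration", "feature", "delta_j", "tif", "chosen")]
    selected <- c(selected, cand$feature[pick])
  }
  structure(list(selected = selected,
                 log = do.call(rbind, log),
                 target_count = target_count, t = t,
                 regularization = regularization,
                 seed_method = seed_method),
            class = "bpfs_selection")
}

#' @export
print.bpfs_selection <- function(x, ...) {
  cat(sprintf("bpfs_selection: %d features (t = %d)\n",
              length(x$selected), x$t))
  n <- min(10, length(x$selected))
  cat("  ", paste(x$selected[seq_len(n)], collapse = ", "),
      if (length(x$selected) > n) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write a selection result as TSV (rank, feature, delta J, influence)
#' @param x a `bpfs_selection`
#' @param path output path
#' @export
write_selection <- function(x, path) {
  chosen <- x$log[x$log$chosen, ]
  out <- data.frame(rank = seq_along(x$selected), feature = x$selected,
                    delta_j = chosen$delta_j[match(x$selected, chosen$feature)],
                    tif = chosen$tif[match(x$selected, chosen$feature)])
  utils::write.table(format(out, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-iteration candidate log as JSON lines
#' @param x a `bpfs_selection`
#' @param path output path
#' @export
write_candidate_log <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (it in unique(x$log$iteration)) {
    rows <- x$log[x$log$iteration == it, ]
    writeLines(jsonlite::toJSON(
      list(iteration = it,
           candidates = rows[, c("feature", "delta_j", "tif", "chosen")]),
      auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}
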