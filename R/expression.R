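# Expression matrix container, tabular I/O, stratified splits and
# bootstrap-style resampling of the training samples.

#' Construct an expression matrix with binary class labels
#'
#' The central data container: a numeric samples x features matrix together
#' with a per-sample class label encoded -1/+1. Most functions in the
#' package take one of these as their first argument.
#'
#' @param values numeric matrix, samples in rows and features in columns;
#'   must carry unique rownames (sample ids) and colnames (feature ids).
#' @param labels per-sample class labels, any vector with exactly two
#'   distinct values; recoded to -1/+1 (the two values in sort order map to
#'   -1 and +1 respectively, unless already numeric -1/+1).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `labels` (named numeric vector of -1/+1).
#' @export
expression_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids")
  if (length(labels) != nrow(values))
    stop("length of `labels` (", length(labels), ") != number of samples (",
         nrow(values), ")")
  if (anyNA(values))
    stop("`values` contains missing entries; apply a missing policy first")
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2)
    stop("labels must take exactly two distinct values, got ", length(lv))
  if (setequal(lv, c("-1", "1"))) {
    y <- as.numeric(as.character(labels))
  } else {
    y <- ifelse(as.character(labels) == lv[2], 1, -1)
  }
  if (min(table(y)) < 2)
    stop("each class needs at least 2 samples")
  names(y) <- rownames(values)
  structure(list(values = values, labels = y), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("expression_matrix: %d samples x %d features (classes -1: %d, +1: %d)\n",
              nrow(x$values), ncol(x$values), tb[["-1"]], tb[["1"]]))
  invisible(x)
}

#' Number of samples / features
#' @param x an `expression_matrix`
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$values)

#' @rdname n_samples
#' @export
n_features <- function(x) ncol(x$values)

#' Feature identifiers of an expression matrix
#' @param x an `expression_matrix`
#' @return character vector of feature ids.
#' @export
feature_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by sample index
#' @param x an `expression_matrix`
#' @param i sample indices (integer or sample ids)
#' @param j optional feature indices or ids
#' @param ... unused
#' @param drop ignored; result is always a matrix
#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE], x$labels[i])
}

#' Read an expression matrix and labels from tabular text files
#'
#' The matrix file is TSV or CSV with a header row of feature ids and the
#' first column holding sample ids. The labels file has two columns:
#' sample id and class label. Samples whose label is absent from the labels
#' file are dropped. Missing values are resolved by `missing_policy`:
#' either the affected feature columns are removed, or missing cells are
#' replaced by the feature mean over observed samples.
#'
#' @param matrix_path path to the expression table.
#' @param labels_path path to the two-column label table.
#' @param missing_policy `"drop_feature"` (default) or `"mean_impute"`.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.csv` -> comma, otherwise tab).
#' @return an [expression_matrix()].
#' @export
load_expression <- function(matrix_path, labels_path,
                            missing_policy = c("drop_feature", "mean_impute"),
                            sep = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) stop("expression table needs >= 1 feature column")
  sample_ids <- raw[[1]]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in ", matrix_path, ": ",
         sample_ids[duplicated(sample_ids)][1])
  fids <- colnames(raw)[-1]
  if (anyDuplicated(fids))
    stop("duplicate feature id in ", matrix_path, ": ",
         fids[duplicated(fids)][1])
  vals <- matrix(NA_real_, nrow(raw), length(fids),
                 dimnames = list(sample_ids, fids))
  for (j in seq_along(fids)) {
    col <- raw[[j + 1]]
    blank <- is.na(col) | col == "" | toupper(col) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !blank)
    if (length(bad))
      stop("non-numeric value '", col[bad[1]], "' at row ", bad[1],
           " (sample ", sample_ids[bad[1]], "), column ", fids[j])
    vals[, j] <- num
  }
  lab_tab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                               stringsAsFactors = FALSE, quote = "\"",
                               comment.char = "")
  # tolerate a header line in the labels file
  if (nrow(lab_tab) > 0 && !lab_tab[1, 1] %in% sample_ids &&
      any(lab_tab[-1, 1] %in% sample_ids))
    lab_tab <- lab_tab[-1, , drop = FALSE]
  labels <- stats::setNames(as.character(lab_tab[[2]]), as.character(lab_tab[[1]]))
  keep <- sample_ids %in% names(labels)
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) < 4) stop("fewer than 4 labeled samples")
  if (anyNA(vals)) {
    if (missing_policy == "drop_feature") {
      vals <- vals[, colSums(is.na(vals)) == 0, drop = FALSE]
      if (ncol(vals) == 0) stop("all features removed by drop_feature policy")
    } else {
      for (j in which(colSums(is.na(vals)) > 0)) {
        m <- mean(vals[, j], na.rm = TRUE)
        if (is.nan(m)) m <- 0   # feature entirely missing
        vals[is.na(vals[, j]), j] <- m
      }
    }
  }
  expression_matrix(vals, labels[rownames(vals)])
}

#' Stratified train/test split
#'
#' Randomly partitions samples into train and test sets so that the
#' per-class proportions in each part stay within one sample of the
#' full-data proportions (largest-remainder apportionment per class).
#'
#' @param data an [expression_matrix()].
#' @param ratio train fraction, in (0, 1).
#' @param seed integer seed; the same seed always yields the same plan.
#' @return An object of class `split_plan`: list with integer vectors
#'   `train_indices` and `test_indices`, plus `seed` and `ratio`.
#' @export
stratified_split <- function(data, ratio = 0.8, seed = 1L) {
  if (!inherits(data, "expression_matrix")) stop("`data` must be an expression_matrix")
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1)
    stop("`ratio` must lie strictly between 0 and 1")
  y <- data$labels
  n_by_class <- table(y)
  if (min(n_by_class) < 2) stop("each class needs >= 2 samples to split")
  m <- round(ratio * length(y))
  quota <- stratified_quota(as.integer(n_by_class), m)
  names(quota) <- names(n_by_class)
  # keep at least one sample of each class on each side
  quota <- pmin(pmax(quota, 1L), as.integer(n_by_class) - 1L)
  train <- integer(0)
  with_seed(seed, {
    for (cl in names(n_by_class)) {
      idx <- which(as.character(y) == cl)
      train <- c(train, sample(idx, quota[[cl]]))
    }
  })
  train <- sort(train)
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_along(y), train),
                 seed = seed, ratio = ratio),
            class = "split_plan")
}

#' Write / read a split plan as two-column TSV (sample id, role)
#' @param plan a `split_plan`
#' @param data the `expression_matrix` the plan indexes
#' @param path output path
#' @export
write_split_plan <- function(plan, data, path) {
  ids <- rownames(data$values)
  role <- rep("test", length(ids))
  role[plan$train_indices] <- "train"
  utils::write.table(data.frame(sample_id = ids, role = role),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path, data) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ids <- rownames(data$values)
  role <- stats::setNames(tab$role, tab$sample_id)[ids]
  if (anyNA(role)) stop("split plan does not cover all samples")
  structure(list(train_indices = unname(which(role == "train")),
                 test_indices = unname(which(role == "test")),
                 seed = NA_integer_, ratio = mean(role == "train")),
            class = "split_plan")
}

#' Stratified sample subsets of the training data
#'
#' Draws `K` subsets, each containing `round(fraction * n)` samples taken
#' without replacement (by default) and stratified by class, for running
#' the selection loop on perturbed versions of the training data.
#'
#' @param data an [expression_matrix()].
#' @param K number of subsets, >= 1.
#' @param fraction fraction of samples per subset, in (0, 1].
#' @param seed integer seed; subsets are deterministic given the seed.
#' @param with_replacement draw with replacement instead (classical
#'   bootstrap); default `FALSE`, matching a literal "80% of the training
#'   data" reading.
#' @return list of `K` integer vectors of sample indices.
#' @export
bootstrap_subsets <- function(data, K = 50L, fraction = 0.8, seed = 1L,
                              with_replacement = FALSE) {
  if (K < 1) stop("`K` must be >= 1")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  y <- data$labels
  n_by_class <- table(y)
  m <- round(fraction * length(y))
  quota <- stratified_quota(as.integer(n_by_class), m)
  names(quota) <- names(n_by_class)
  if (any(quota == 0))
    stop("subset of size ", m, " would lose class ",
         names(quota)[quota == 0][1], " entirely")
  with_seed(seed, {
    lapply(seq_len(K), function(k) {
      out <- integer(0)
      for (cl in names(n_by_class)) {
        idx <- which(as.character(y) == cl)
        out <- c(out, sample(idx, quota[[cl]], replace = with_replacement))
      }
      sort(out)
    })
  })
}
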