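# Per-feature discriminative scores: mutual information for seeding the
# selection, and the linear-SVM dual objective with its fixed-multiplier
# marginal classification power for candidate ranking.

#' Plug-in mutual information between a feature and the class label
#'
#' Discretizes the feature values into `n_bins` bins (equal-width by
#' default, equal-frequency optionally), forms the empirical joint mass
#' of (bin, label) and returns
#' I(F, L) = sum psi(f, l) * log( psi(f, l) / (psi(f) psi(l)) )
#' in nats; 0 * log 0 terms contribute 0.
#'
#' @param values per-sample feature values.
#' @param labels per-sample class labels (-1/+1 or any two-valued vector).
#' @param n_bins number of bins, >= 1; default 10.
#' @param binning `"width"` (equal-width, default) or `"frequency"`
#'   (equal-frequency quantile bins).
#' @return nonnegative mutual information estimate in nats.
#' @export
mutual_information <- function(values, labels, n_bins = 10L,
                               binning = c("width", "frequency")) {
  binning <- match.arg(binning)
  if (length(values) != length(labels)) stop("length mismatch")
  if (length(values) < 2) stop("need at least 2 samples")
  if (length(unique(labels)) < 2) stop("labels are constant")
  if (n_bins < 1) stop("`n_bins` must be >= 1")
  rng <- range(values)
  if (rng[1] == rng[2] || n_bins == 1) {
    bins <- rep(1L, length(values))
  } else if (binning == "width") {
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bins <- cut(values, breaks = brk, include.lowest = TRUE, labels = FALSE)
  } else {
    brk <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(brk) < 2) bins <- rep(1L, length(values))
    else bins <- cut(values, breaks = brk, include.lowest = TRUE, labels = FALSE)
  }
  joint <- table(bins, labels) / length(values)
  pf <- rowSums(joint); pl <- colSums(joint)
  terms <- joint * log(joint / outer(pf, pl))
  max(0, sum(terms[joint > 0]))
}

#' Train a soft-margin linear SVM on a feature subset
#'
#' Solves the C-SVM dual with a linear kernel on the columns of `data`
#' named in `feature_subset` and reports the Lagrange multipliers together
#' with the dual objective
#' J = sum(alpha) - 1/2 * sum_ij alpha_i alpha_j y_i y_j x_i . x_j,
#' recomputed here directly from the returned multipliers. The quadratic
#' programme is solved by libsvm's sequential minimal optimization (via
#' \pkg{e1071}), which is deterministic for fixed inputs.
#'
#' An empty `feature_subset` is allowed as the selection loop's starting
#' state: the kernel is identically zero, the dual is maximized on the
#' boundary, and the multipliers are set to the balanced convention
#' alpha_i = C / n_class(y_i), which satisfies sum(alpha * y) = 0 and box
#' constraints (for unbalanced classes the larger class is capped at C and
#' the smaller rescaled).
#'
#' @param data an [expression_matrix()].
#' @param feature_subset character vector of feature ids (may be empty).
#' @param regularization box constraint C > 0; default 1.
#' @param standardize center/scale features before training; default
#'   `FALSE`.
#' @return object of class `svm_fit`: list with `alpha` (length-n vector),
#'   `objective` (dual J), `support_indices`, `regularization`,
#'   `features`, and `x` (the training submatrix actually used).
#' @export
fit_svm <- function(data, feature_subset, regularization = 1,
                    standardize = FALSE) {
  if (regularization <= 0) stop("`regularization` must be positive")
  y <- data$labels
  n <- length(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  feature_subset <- as.character(feature_subset)
  missing_f <- setdiff(feature_subset, feature_ids(data))
  if (length(missing_f)) stop("unknown feature id: ", missing_f[1])
  if (length(feature_subset) == 0) {
    ncl <- table(y)
    alpha <- regularization * (min(ncl) / ncl[as.character(y)])
    alpha <- as.numeric(alpha)
    return(structure(list(alpha = alpha, objective = sum(alpha),
                          support_indices = seq_len(n),
                          regularization = regularization,
                          features = character(0),
                          x = matrix(0, n, 0, dimnames = list(names(y), NULL))),
                     class = "svm_fit"))
  }
  x <- data$values[, feature_subset, drop = FALSE]
  if (standardize) x <- scale(x)
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = regularization, scale = FALSE)
  alpha <- numeric(n)
  alpha[fit$index] <- abs(fit$coefs)  # coefs are alpha_i * y_i
  ay <- alpha * y
  K <- tcrossprod(x)
  objective <- sum(alpha) - 0.5 * as.numeric(t(ay) %*% K %*% ay)
  structure(list(alpha = alpha, objective = objective,
                 support_indices = which(alpha > 0),
                 regularization = regularization,
                 features = feature_subset, x = x),
            class = "svm_fit")
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("svm_fit: %d features, %d/%d support vectors, J = %.6g, C = %g\n",
              length(x$features), length(x$support_indices), length(x$alpha),
              x$objective, x$regularization))
  invisible(x)
}

#' Primal weight of a candidate feature under fixed multipliers
#'
#' w_m = sum_i alpha_i y_i x_im, the weight the current dual solution
#' would place on feature m if its column were appended.
#' @noRd
candidate_weight <- function(data, fit, candidate) {
  sum(fit$alpha * data$labels * data$values[, candidate])
}

#' Marginal classification power of a candidate feature
#'
#' Change in the linear-SVM dual objective when the candidate's column is
#' appended to the selected set's kernel while the Lagrange multipliers
#' are held fixed at the current solution. Appending a column changes only
#' the quadratic term, so the change collapses to the closed form
#' delta J(m) = -1/2 * (sum_i alpha_i y_i x_im)^2, which is always <= 0;
#' its magnitude is the squared primal weight the current solution would
#' assign to the candidate, the standard SVM forward-selection relevance
#' score.
#'
#' @param data an [expression_matrix()].
#' @param fit an `svm_fit` trained on exactly `selected`.
#' @param selected feature ids the fit was trained on.
#' @param candidate candidate feature id, not in `selected`.
#' @return delta J, a nonpositive number.
#' @export
marginal_power <- function(data, fit, selected, candidate) {
  if (!identical(as.character(selected), fit$features))
    stop("`fit` was not trained on `selected`")
  if (candidate %in% selected) stop("candidate already selected")
  -0.5 * candidate_weight(data, fit, candidate)^2
}

#' Rank candidate features by marginal classification power
#'
#' Scores every available feature with the fixed-multiplier marginal
#' power and returns the top `t`. By default candidates are ordered by
#' |delta J| descending (squared candidate weight, largest first);
#' `literal_delta_j_order = TRUE` instead orders by the signed delta J
#' descending. With `retrain_per_candidate = TRUE` the SVM is refit on
#' `selected + candidate` and delta J is the true objective difference.
#' Ties are broken by feature id.
#'
#' @param data an [expression_matrix()].
#' @param fit `svm_fit` on `selected` (ignored when retraining).
#' @param selected feature ids already selected.
#' @param available candidate pool (character vector, non-empty).
#' @param t number of candidates to return; if `t` exceeds the pool all
#'   candidates are returned with a warning.
#' @param literal_delta_j_order rank by signed delta J instead of |delta J|.
#' @param retrain_per_candidate refit the SVM for every candidate.
#' @return data frame with columns `feature`, `delta_j`, `score`, ordered
#'   best first.
#' @export
rank_candidates <- function(data, fit, selected, available, t = 10L,
                            literal_delta_j_order = FALSE,
                            retrain_per_candidate = FALSE) {
  if (length(available) == 0) stop("`available` is empty")
  if (t < 1) stop("`t` must be >= 1")
  available <- as.character(available)
  if (retrain_per_candidate) {
    delta <- vapply(available, function(m) {
      fit_svm(data, c(as.character(selected), m),
              regularization = fit$regularization)$objective - fit$objective
    }, numeric(1))
  } else {
    w <- vapply(available, candidate_weight, numeric(1),
                data = data, fit = fit)
    delta <- -0.5 * w^2
  }
  score <- if (literal_delta_j_order) delta else abs(delta)
  ord <- order(-score, available)
  if (t > length(available)) {
    warning("t = ", t, " exceeds ", length(available),
            " available candidates; returning all")
    t <- length(available)
  }
  out <- data.frame(feature = available[ord], delta_j = unname(delta[ord]),
                    score = unname(score[ord]), stringsAsFactors = FALSE)
  out[seq_len(t), , drop = FALSE]
}
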