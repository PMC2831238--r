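# Edge-subsampling reachability analysis: estimates how much influence an
# unmappable feature is expected to exert, by extrapolating the average
# reachability of the interaction graph as missing interactions are added.

#' Randomly subsample the edges of a graph
#'
#' Retains `round(fraction * |E|)` edges chosen uniformly without
#' replacement; the vertex set is unchanged.
#'
#' @param graph an [igraph::igraph].
#' @param fraction fraction of edges to keep, in (0, 1].
#' @param seed integer seed; deterministic given the seed.
#' @return subsampled graph on the same vertices.
#' @export
subsample_edges <- function(graph, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  ne <- igraph::ecount(graph)
  keep <- round(fraction * ne)
  if (keep == ne) return(graph)
  drop_n <- ne - keep
  with_seed(seed, {
    drop <- sample(seq_len(ne), drop_n)
    igraph::delete_edges(graph, drop)
  })
}

#' Average reachability of a graph
#'
#' Mean, over vertices, of the number of OTHER vertices reachable from
#' each vertex. Within a connected component of size c every vertex
#' reaches c - 1 others, so this equals `sum(c_i * (c_i - 1)) / |V|` over
#' component sizes.
#'
#' @param graph an [igraph::igraph] with at least one vertex.
#' @return nonnegative real number.
#' @export
average_reachability <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("graph has no vertices")
  cs <- igraph::components(graph)$csize
  sum(cs * (cs - 1)) / igraph::vcount(graph)
}

#' Fit a saturating curve to reachability-vs-edge-fraction points
#'
#' Models the average reachability as a function of the percentage `s` of
#' interactions present with the converging geometric form
#' f(s) = A - B * q^s (A > 0, B > 0, 0 < q < 1), whose asymptote A is the
#' average reachability of the hypothetical completed pathway. The fit is
#' least squares: q is profiled on a grid plus golden-section refinement
#' (A and B are linear given q), then polished with `nls` when possible.
#'
#' @param fractions s values (percent of edges retained), strictly
#'   increasing, at least 4 points.
#' @param reachabilities observed average reachabilities, nonnegative.
#' @return object of class `reachability_curve`: list with `fractions`,
#'   `reachabilities`, `fit_params` (A, B, q), `fitted`, `residuals`, and
#'   `extrapolation_limit` (largest s observed).
#' @export
fit_reachability_curve <- function(fractions, reachabilities) {
  s <- as.numeric(fractions); r <- as.numeric(reachabilities)
  if (length(s) < 4) stop("need at least 4 points to fit the curve")
  if (any(diff(s) <= 0)) stop("`fractions` must be strictly increasing")
  if (any(r < 0)) stop("reachabilities must be nonnegative")

  # profile SSE over q: for fixed q the model is linear in (A, B)
  profile <- function(q) {
    X <- cbind(1, -q^s)
    cf <- tryCatch(qr.coef(qr(X), r), error = function(e) c(NA, NA))
    if (anyNA(cf)) return(list(sse = Inf, A = NA, B = NA))
    res <- r - X %*% cf
    list(sse = sum(res^2), A = cf[1], B = cf[2])
  }
  qs <- seq(0.0001, 0.9999, length.out = 400)
  sse <- vapply(qs, function(q) profile(q)$sse, numeric(1))
  i <- which.min(sse)
  lo <- qs[max(1, i - 1)]; hi <- qs[min(length(qs), i + 1)]
  opt <- stats::optimize(function(q) profile(q)$sse, c(lo, hi), tol = 1e-12)
  q <- opt$minimum
  pf <- profile(q)
  A <- pf$A; B <- pf$B

  # polish with full nonlinear least squares when the profiled solution is
  # in the interior of the admissible region
  if (is.finite(A) && B > 0) {
    # warnOnly + explicit SSE comparison below: a non-converged polish is
    # simply discarded in favour of the profiled solution
    fit <- tryCatch(suppressWarnings(
      stats::nls(r ~ A - B * q^s, start = list(A = A, B = B, q = q),
                 algorithm = "port",
                 lower = c(A = 1e-12, B = 1e-12, q = 1e-9),
                 upper = c(A = Inf, B = Inf, q = 1 - 1e-9),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (sum((r - (cf["A"] - cf["B"] * cf["q"]^s))^2) <= pf$sse + 1e-12) {
        A <- unname(cf["A"]); B <- unname(cf["B"]); q <- unname(cf["q"])
      }
    }
  }
  if (!is.finite(A) || !is.finite(B))
    stop("reachability curve fit failed to converge; inspect the input points")
  if (B < 0) { # monotone-decreasing data: clamp to the saturated fit
    A <- mean(r); B <- 0
  }
  fitted <- A - B * q^s
  structure(list(fractions = s, reachabilities = r,
                 fit_params = c(A = A, B = B, q = q),
                 fitted = fitted, residuals = r - fitted,
                 extrapolation_limit = max(s)),
            class = "reachability_curve")
}

#' Evaluate a fitted reachability curve
#' @param curve a `reachability_curve`
#' @param s edge-percentage value(s); `Inf` gives the asymptote A.
#' @return fitted average reachability f(s).
#' @export
predict_reachability <- function(curve, s) {
  p <- curve$fit_params
  ifelse(is.infinite(s), p[["A"]], p[["A"]] - p[["B"]] * p[["q"]]^s)
}

#' @export
print.reachability_curve <- function(x, ...) {
  p <- x$fit_params
  cat(sprintf("reachability_curve: f(s) = %.4g - %.4g * %.6g^s over s in [%g, %g]\n",
              p[["A"]], p[["B"]], p[["q"]], min(x$fractions), max(x$fractions)))
  cat(sprintf("  asymptote %.4g, residual SD %.4g\n", p[["A"]],
              stats::sd(x$residuals)))
  invisible(x)
}

#' Estimate the unresolved-interaction probability p
#'
#' p is the probability that an unmapped feature interacts with a
#' randomly chosen gene once the pathway is complete: the extrapolated
#' average reachability divided by the total number of genes, clamped to
#' \[0, 1\]. With the human consolidated pathway the extrapolation
#' saturates near 180 reachable genes, and with ~20,500 human genes this
#' gives p = 0.0088 (4-decimal presentation).
#'
#' @param curve a fitted `reachability_curve` (or a single number taken
#'   directly as the completed-pathway average reachability).
#' @param total_genes total number of genes in the organism (human:
#'   20500).
#' @param extrapolate_to s value at which to evaluate the fitted curve;
#'   `NULL` (default) uses the asymptote A.
#' @return p in \[0, 1\] (unrounded; round to 4 decimals for reports).
#' @export
estimate_p <- function(curve, total_genes, extrapolate_to = NULL) {
  if (total_genes <= 0) stop("`total_genes` must be positive")
  reach <- if (is.numeric(curve)) {
    curve
  } else if (is.null(extrapolate_to)) {
    curve$fit_params[["A"]]
  } else {
    predict_reachability(curve, extrapolate_to)
  }
  min(1, max(0, reach / total_genes))
}

#' Run the full reachability pipeline on a graph
#'
#' Builds edge-subsampled graphs at the requested fractions, measures the
#' average reachability of each, fits the saturating curve and estimates
#' p.
#'
#' @param graph the consolidated interaction graph.
#' @param fractions edge fractions (in (0, 1]) at which to measure;
#'   default 0.1 to 1 in steps of 0.1.
#' @param total_genes organism gene count used as the denominator.
#' @param seed integer master seed (one draw per fraction).
#' @param replicates subsampled replicates averaged per fraction.
#' @return list with `curve` (a `reachability_curve` whose fractions are
#'   in percent), `p`, and `p_reported` (rounded to 4 decimals).
#' @export
reachability_pipeline <- function(graph, fractions = seq(0.1, 1, by = 0.1),
                                  total_genes = 20500, seed = 1L,
                                  replicates = 3L) {
  reach <- vapply(seq_along(fractions), function(i) {
    mean(vapply(seq_len(replicates), function(rep) {
      average_reachability(
        subsample_edges(graph, fractions[i],
                        seed = stage_seed(seed, i * 131 + rep)))
    }, numeric(1)))
  }, numeric(1))
  curve <- fit_reachability_curve(fractions * 100, reach)
  p <- estimate_p(curve, total_genes)
  list(curve = curve, p = p, p_reported = round(p, 4))
}
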