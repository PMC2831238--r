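# Shared fixtures and independent oracles for cross-checking the graph and
# SVM computations. The oracles deliberately avoid igraph and the package's
# own code paths.

# small labeled expression matrix with controllable values
toy_expression <- function(values, labels) {
  vals <- as.matrix(values)
  rownames(vals) <- sprintf("s%d", seq_len(nrow(vals)))
  colnames(vals) <- sprintf("f%d", seq_len(ncol(vals)))
  expression_matrix(vals, labels)
}

# random Erdos-Renyi adjacency matrix on nv labeled vertices
random_adjacency <- function(nv, p_edge) {
  a <- matrix(0L, nv, nv)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p_edge)
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", seq_len(nv)), paste0("v", seq_len(nv)))
  a
}

graph_from_adjacency <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# all-pairs shortest hop distances by boolean matrix powers: the shortest
# path between i and j is the smallest k for which (A^k)_{ij} > 0
oracle_distances <- function(a) {
  nv <- nrow(a)
  d <- matrix(Inf, nv, nv, dimnames = dimnames(a))
  diag(d) <- 0
  A <- a > 0
  P <- A
  for (k in seq_len(max(1, nv - 1))) {
    newly <- P & is.infinite(d)
    d[newly] <- k
    P <- (P %*% A) > 0
  }
  d
}

# average count of OTHER vertices reachable from each vertex
oracle_average_reachability <- function(a) {
  d <- oracle_distances(a)
  mean(rowSums(is.finite(d)) - 1)
}

# literal dual-objective difference: J(S u {m}) - J(S) evaluated with the
# fixed multipliers of `fit`, both terms computed from their kernels
oracle_delta_j_literal <- function(data, fit, selected, candidate) {
  y <- data$labels
  ay <- fit$alpha * y
  xs <- data$values[, selected, drop = FALSE]
  xm <- data$values[, c(selected, candidate), drop = FALSE]
  j_s <- sum(fit$alpha) - 0.5 * as.numeric(t(ay) %*% tcrossprod(xs) %*% ay)
  j_sm <- sum(fit$alpha) - 0.5 * as.numeric(t(ay) %*% tcrossprod(xm) %*% ay)
  j_sm - j_s
}

# independent weight tally for rank aggregation
oracle_weights <- function(mat) {
  N <- ncol(mat)
  tally <- new.env()
  for (i in seq_len(nrow(mat))) for (k in seq_len(N)) {
    f <- mat[i, k]
    tally[[f]] <- (if (is.null(tally[[f]])) 0 else tally[[f]]) + (N - k)
  }
  unlist(as.list(tally))
}

# write a small expression + labels pair to temp files, returning paths
write_toy_files <- function(data, dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  tab <- data.frame(sample_id = rownames(data$values), data$values,
                    check.names = FALSE)
  write.table(tab, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(rownames(data$values), data$labels), lp,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  c(expression = ep, labels = lp)
}
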