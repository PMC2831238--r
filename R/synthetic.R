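# Synthetic two-class expression data with planted informative feature
# blocks, and matching modular interaction graphs, so every stage of the
# selection pipeline can be exercised with known ground truth.

#' Specification of a synthetic dataset
#'
#' Describes a two-class dataset in which `n_blocks` blocks of
#' `block_size` informative features each carry the same class signal and
#' are mutually correlated (redundant measurements of one biological
#' module), all remaining features are pure noise, and the companion
#' interaction graph connects each block as a module. A configurable
#' fraction of features is left unmappable to the graph.
#'
#' @param n_samples number of samples (split evenly between classes).
#' @param n_features total number of features.
#' @param n_blocks number of informative blocks.
#' @param block_size features per block (`n_blocks * block_size <=
#'   n_features`).
#' @param effect_size class-mean shift of informative features in units
#'   of the feature SD; default 1.5, a clearly detectable but noisy
#'   signal at ~100 samples.
#' @param within_block_correlation pairwise correlation of the noise
#'   component within a block, in \[0, 1); default 0.8.
#' @param unresolved_fraction fraction of features left unmappable to the
#'   graph; default 0.6, matching the share typically seen when mapping
#'   microarray probes onto curated pathway databases.
#' @param p_within probability of each intra-block edge beyond the
#'   spanning path; default 1 (blocks are cliques).
#' @param p_between probability of a background edge between resolved
#'   genes of different blocks (or noise genes); default 0.
#' @param seed integer seed; all generators are deterministic given it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 120L, n_features = 100L,
                           n_blocks = 5L, block_size = 4L,
                           effect_size = 1.5,
                           within_block_correlation = 0.8,
                           unresolved_fraction = 0.6,
                           p_within = 1, p_between = 0,
                           seed = 1L) {
  if (n_blocks * block_size > n_features)
    stop("n_blocks * block_size exceeds n_features")
  if (within_block_correlation < 0 || within_block_correlation >= 1)
    stop("`within_block_correlation` must be in [0, 1)")
  if (unresolved_fraction < 0 || unresolved_fraction > 1)
    stop("`unresolved_fraction` must be in [0, 1]")
  for (pr in c(p_within, p_between))
    if (pr < 0 || pr > 1) stop("edge probabilities must be in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 effect_size = effect_size,
                 within_block_correlation = within_block_correlation,
                 unresolved_fraction = unresolved_fraction,
                 p_within = p_within, p_between = p_between,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class expression matrix
#'
#' Labels are exactly balanced (for even `n_samples`). An informative
#' feature j in block b is generated as
#' `x_ij = y_i * effect/2 + sqrt(rho) * z_ib + sqrt(1 - rho) * e_ij`
#' with `z_ib` a per-sample block latent factor and `e_ij` independent
#' standard normal noise, so the noise component has unit variance, the
#' two class means differ by `effect_size`, and any two features of one
#' block have noise correlation `rho`. Remaining features are independent
#' standard normal.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (an [expression_matrix()]) and `blocks`
#'   (named integer vector, feature id -> block number, `NA` for noise
#'   features).
#' @export
generate_expression <- function(spec) {
  n <- spec$n_samples; P <- spec$n_features
  nb <- spec$n_blocks; bs <- spec$block_size
  rho <- spec$within_block_correlation
  fids <- sprintf("F%03d", seq_len(P))
  sids <- sprintf("S%03d", seq_len(n))
  y <- rep(c(-1, 1), length.out = n)
  blocks <- rep(NA_integer_, P)
  if (nb > 0) blocks[seq_len(nb * bs)] <- rep(seq_len(nb), each = bs)
  names(blocks) <- fids
  with_seed(spec$seed, {
    vals <- matrix(stats::rnorm(n * P), n, P, dimnames = list(sids, fids))
    if (nb > 0) {
      z <- matrix(stats::rnorm(n * nb), n, nb)
      for (j in which(!is.na(blocks))) {
        b <- blocks[j]
        vals[, j] <- y * spec$effect_size / 2 +
          sqrt(rho) * z[, b] + sqrt(1 - rho) * vals[, j]
      }
    }
  })
  list(data = expression_matrix(vals, y), blocks = blocks)
}

#' Generate the companion interaction graph and feature mapping
#'
#' Each informative block becomes a connected module: a spanning path
#' over its resolved members guarantees connectivity, and every further
#' intra-block pair is an edge with probability `p_within`. Background
#' edges between any other resolved pair appear with probability
#' `p_between`. A uniformly chosen `unresolved_fraction` of the features
#' is unmappable (`"UNRESOLVED"` in the mapping); all other features map
#' to a gene vertex (resolved noise features are isolated unless a
#' background edge touches them).
#'
#' @param spec a [synthetic_spec()].
#' @param feature_ids feature ids of the companion expression matrix.
#' @param blocks named block assignment as returned by
#'   [generate_expression()].
#' @return list with `graph` (an [igraph::igraph]) and `mapping` (named
#'   character vector, feature id -> gene id or `"UNRESOLVED"`).
#' @export
generate_pathway <- function(spec, feature_ids, blocks) {
  stopifnot(length(blocks) == length(feature_ids))
  P <- length(feature_ids)
  with_seed(stage_seed(spec$seed, 7L), {
    n_unres <- round(spec$unresolved_fraction * P)
    unres <- if (n_unres > 0) sample(feature_ids, n_unres) else character(0)
    mapping <- stats::setNames(paste0("g_", feature_ids), feature_ids)
    mapping[unres] <- "UNRESOLVED"
    resolved <- setdiff(feature_ids, unres)
    genes <- unname(mapping[resolved])
    edges <- matrix(character(0), ncol = 2)
    add <- function(a, b) rbind(edges, cbind(a, b))
    # intra-block: spanning path + extra pairs at p_within
    for (b in seq_len(max(c(0, blocks), na.rm = TRUE))) {
      members <- mapping[resolved][blocks[resolved] %in% b]
      members <- unname(members)
      if (length(members) >= 2) {
        edges <- add(members[-length(members)], members[-1])
        if (length(members) >= 3 && spec$p_within > 0) {
          pairs <- t(utils::combn(members, 2))
          keep <- stats::runif(nrow(pairs)) < spec$p_within
          edges <- rbind(edges, pairs[keep, , drop = FALSE])
        }
      }
    }
    # background edges between resolved genes of no shared block
    if (spec$p_between > 0 && length(genes) >= 2) {
      pairs <- t(utils::combn(genes, 2))
      fb <- blocks[resolved]
      same_block <- !is.na(fb[match(pairs[, 1], genes)]) &
        fb[match(pairs[, 1], genes)] == fb[match(pairs[, 2], genes)]
      same_block[is.na(same_block)] <- FALSE
      cross <- pairs[!same_block, , drop = FALSE]
      keep <- stats::runif(nrow(cross)) < spec$p_between
      edges <- rbind(edges, cross[keep, , drop = FALSE])
    }
    g <- if (nrow(edges) == 0) {
      igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genes)
    } else {
      igraph::simplify(igraph::graph_from_data_frame(
        data.frame(from = edges[, 1], to = edges[, 2]),
        directed = FALSE, vertices = genes))
    }
    list(graph = g, mapping = mapping)
  })
}

#' Generate a complete synthetic study (expression + graph + mapping)
#'
#' Convenience wrapper composing [generate_expression()] and
#' [generate_pathway()].
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data`, `blocks`, `graph`, `mapping`.
#' @export
generate_study <- function(spec) {
  expr <- generate_expression(spec)
  pw <- generate_pathway(spec, feature_ids(expr$data), expr$blocks)
  c(expr, pw)
}

#' Small apoptosis-signaling fixture graph
#'
#' A hand-built eight-gene subgraph of the human apoptosis/NF-kB
#' signaling neighbourhood used throughout the documentation and tests:
#' PKB/Akt touches CASP9, IKK and BAD directly; IKK activates NFkB; BAD
#' ties to Bcl-xl; RacGEF activates RAC which activates NFkB. All genes
#' are resolved (features are the gene names themselves).
#'
#' @return list with `graph` (an [igraph::igraph] on 8 vertices, 7
#'   edges) and `mapping` (identity).
#' @export
fig1_fixture <- function() {
  edges <- data.frame(
    from = c("PKB/Akt", "PKB/Akt", "IKK", "PKB/Akt", "BAD", "RacGEF", "RAC"),
    to   = c("CASP9",   "IKK",     "NFkB", "BAD",    "Bcl-xl", "RAC",  "NFkB"),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  list(graph = g, mapping = identity_mapping(igraph::V(g)$name))
}

#' Write a synthetic study to the tabular formats the loaders read
#'
#' Produces `expression.tsv`, `labels.tsv`, `edges.tsv` and
#' `mapping.tsv` under `dir`, round-trippable through
#' [load_expression()], [consolidate()] and [read_gene_mapping()].
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "expression.tsv")
  lp <- file.path(dir, "labels.tsv")
  gp <- file.path(dir, "edges.tsv")
  mp <- file.path(dir, "mapping.tsv")
  vals <- study$data$values
  tab <- data.frame(sample_id = rownames(vals), vals, check.names = FALSE)
  utils::write.table(tab, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(vals),
                                label = study$data$labels),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  el <- igraph::as_edgelist(study$graph)
  utils::write.table(as.data.frame(el), gp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(feature = names(study$mapping),
                                gene = unname(study$mapping)),
                     mp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(expression = ep, labels = lp, edges = gp, mapping = mp))
}
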