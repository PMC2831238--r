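# Consolidated gene-interaction graph: construction from edge lists or
# per-pathway membership, shortest-hop distances, influence factors and the
# probabilistic model for features that cannot be mapped to the pathway.

#' Build a consolidated interaction graph from edge tables
#'
#' Takes one or more edge tables (data frames, or paths to two-column TSV
#' files; three-column SIF-style rows "geneA interaction geneB" are
#' tolerated, the middle column is ignored) and returns their union as an
#' undirected simple graph: duplicate edges and self-loops are removed.
#'
#' @param edge_tables a data frame, a file path, or a list mixing both.
#' @param extra_vertices optional gene ids to include as isolated vertices
#'   (genes known to the pathway database but taking part in no
#'   interaction).
#' @return an undirected [igraph::igraph] with gene ids as vertex names.
#' @export
consolidate <- function(edge_tables, extra_vertices = character(0)) {
  if (!is.list(edge_tables) || is.data.frame(edge_tables))
    edge_tables <- list(edge_tables)
  pairs <- lapply(edge_tables, function(tab) {
    if (is.character(tab) && length(tab) == 1) {
      tab <- utils::read.table(tab, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE, quote = "\"",
                               comment.char = "#")
    }
    if (!is.data.frame(tab) || ncol(tab) < 2)
      stop("each edge table needs at least two columns (gene, gene)")
    # SIF tolerance: 3+ columns -> first and third are the genes
    if (ncol(tab) >= 3) tab <- tab[, c(1, 3)]
    data.frame(from = as.character(tab[[1]]), to = as.character(tab[[2]]),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, pairs)
  verts <- unique(c(edges$from, edges$to, as.character(extra_vertices)))
  if (length(verts) == 0) stop("empty edge union: no vertices")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Build the idealized per-pathway clique graph
#'
#' Each pathway becomes a clique (all member genes pairwise connected);
#' no edges join genes that share no pathway. Genes appearing in several
#' pathways receive every intra-pathway clique edge. Features without a
#' pathway assignment become isolated vertices (singleton pathways).
#'
#' @param membership two-column data frame (gene id, pathway id), one row
#'   per membership, or path to such a TSV.
#' @param all_genes optional gene ids guaranteed present as vertices even
#'   when unassigned.
#' @return an undirected [igraph::igraph]; the pathway assignment is kept
#'   in the graph attribute `"membership"`.
#' @export
fully_connected_graph <- function(membership, all_genes = character(0)) {
  if (is.character(membership) && length(membership) == 1)
    membership <- utils::read.table(membership, header = FALSE, sep = "\t",
                                    stringsAsFactors = FALSE)
  gene <- as.character(membership[[1]])
  pw <- as.character(membership[[2]])
  edges <- do.call(rbind, lapply(split(unique(data.frame(gene, pw)), pw),
    function(d) {
      gs <- sort(unique(d$gene))
      if (length(gs) < 2) return(NULL)
      t(utils::combn(gs, 2))
    }))
  verts <- unique(c(gene, as.character(all_genes)))
  if (length(verts) == 0) stop("no genes in membership")
  if (is.null(edges)) {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(verts)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]),
      directed = FALSE, vertices = verts)
    g <- igraph::simplify(g)
  }
  igraph::graph_attr(g, "membership") <- data.frame(gene = gene, pathway = pw,
                                                    stringsAsFactors = FALSE)
  g
}

#' Shortest-hop distance between two genes
#'
#' Length (number of edges) of the shortest path connecting two vertices
#' of the interaction graph; `Inf` when no path exists.
#'
#' @param graph an [igraph::igraph] with named vertices.
#' @param g1,g2 gene ids (vertex names).
#' @return a nonnegative number, `Inf` if the genes are disconnected.
#' @export
hop_distance <- function(graph, g1, g2) {
  vn <- igraph::V(graph)$name
  if (!g1 %in% vn) stop("unknown vertex: ", g1)
  if (!g2 %in% vn) stop("unknown vertex: ", g2)
  as.numeric(igraph::distances(graph, v = g1, to = g2)[1, 1])
}

#' Influence model for pairwise and unresolved-gene redundancy
#'
#' Bundles the parameters of the hop-decay influence metric: the decay
#' base b in IF = b^(1-d), the probability `p` that an unmapped feature
#' interacts with a randomly chosen gene, and the influence assigned to
#' disconnected resolved pairs.
#'
#' @param decay_base decay base, > 1; default 2 halves the influence per
#'   additional hop.
#' @param p expected unresolved-interaction probability in \[0, 1\];
#'   default 0.0088 (extrapolated average reachability of a completed
#'   human regulatory/signaling pathway over ~20,500 human genes; see
#'   [estimate_p()]).
#' @param no_path_influence influence contributed by a resolved pair with
#'   no connecting path; default 0.
#' @return object of class `influence_model`.
#' @export
influence_model <- function(decay_base = 2, p = 0.0088, no_path_influence = 0) {
  if (!is.numeric(decay_base) || decay_base <= 1)
    stop("`decay_base` must be > 1")
  if (!is.numeric(p) || p < 0 || p > 1) stop("`p` must be in [0, 1]")
  if (no_path_influence < 0) stop("`no_path_influence` must be >= 0")
  structure(list(decay_base = decay_base, p = p,
                 no_path_influence = no_path_influence),
            class = "influence_model")
}

#' Pairwise influence factor
#'
#' IF(g1, g2) = b^(1 - d) where d is the shortest-hop distance between the
#' genes and b the decay base: 1 for direct neighbours, halved (at b = 2)
#' for every extra hop. Disconnected pairs contribute
#' `model$no_path_influence` (default 0), preserving monotone decay.
#'
#' @param model an [influence_model()].
#' @param graph interaction graph.
#' @param g1,g2 distinct gene ids.
#' @return nonnegative influence value.
#' @export
influence_factor <- function(model, graph, g1, g2) {
  if (identical(g1, g2))
    stop("influence_factor is defined only for distinct genes")
  d <- hop_distance(graph, g1, g2)
  if (is.infinite(d)) return(model$no_path_influence)
  model$decay_base^(1 - d)
}

#' Read a feature-to-gene mapping table
#'
#' Two-column TSV: feature id, gene id or the literal `UNRESOLVED` for
#' features that cannot be mapped to the pathway.
#'
#' @param path file path, or a two-column data frame.
#' @return named character vector, feature id -> gene id / `"UNRESOLVED"`.
#' @export
read_gene_mapping <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "#")
  map <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  if (anyDuplicated(names(map)))
    stop("duplicate feature id in mapping: ",
         names(map)[duplicated(names(map))][1])
  map
}

#' Identity mapping for data whose feature ids are themselves gene ids
#' @param ids feature ids
#' @return named character vector mapping each id to itself.
#' @export
identity_mapping <- function(ids) stats::setNames(ids, ids)

# resolve a feature id through the mapping: returns the gene id, or NA when
# the feature is unresolved or absent from the mapping
.resolve <- function(mapping, feature) {
  g <- unname(mapping[feature])
  if (is.na(g) || toupper(g) == "UNRESOLVED") NA_character_ else g
}

#' Total influence of the selected set on a candidate feature
#'
#' Sum of pairwise influence factors between a candidate and every
#' already-selected feature, the redundancy score minimized at each
#' selection step. Features map to pathway genes through `mapping`;
#' features marked `UNRESOLVED` (or mapping to genes absent from the
#' graph) enter probabilistically: a resolved candidate receives
#' `p * |Q|` for the unresolved part Q of the selected set plus the exact
#' hop-decay sum over the resolved part, and an unresolved candidate
#' receives `p * |S|` for the whole selected set.
#'
#' @param model an [influence_model()].
#' @param graph interaction graph.
#' @param mapping named character vector, feature id -> gene id or
#'   `"UNRESOLVED"` (see [read_gene_mapping()]).
#' @param candidate candidate feature id (not in `selected`).
#' @param selected character vector of already-selected feature ids.
#' @return nonnegative total influence; 0 when `selected` is empty.
#' @export
total_influence <- function(model, graph, mapping, candidate, selected) {
  if (candidate %in% selected) stop("candidate already selected")
  if (length(selected) == 0) return(0)
  vn <- igraph::V(graph)$name
  cand_gene <- .resolve(mapping, candidate)
  if (!is.na(cand_gene) && !cand_gene %in% vn) cand_gene <- NA_character_
  if (is.na(cand_gene)) return(model$p * length(selected))
  sel_genes <- vapply(selected, .resolve, character(1), mapping = mapping)
  sel_genes[!sel_genes %in% vn] <- NA_character_
  n_unres <- sum(is.na(sel_genes))
  res_genes <- sel_genes[!is.na(sel_genes)]
  tif <- model$p * n_unres
  if (length(res_genes)) {
    d <- as.numeric(igraph::distances(graph, v = cand_gene, to = res_genes))
    contrib <- ifelse(is.infinite(d), model$no_path_influence,
                      ifelse(d == 0, model$decay_base,  # same gene, d = 0
                             model$decay_base^(1 - d)))
    tif <- tif + sum(contrib)
  }
  tif
}
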