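# Clonal architecture: minimal spanning tree over clone consensus genotypes,
# rooted at the all-zero germline genotype. Edge weights are genetic
# distances between consensus genotypes (Hamming by default). Kruskal's
# algorithm is implemented directly so ties are broken lexicographically by
# node label, making the tree deterministic.

#' Reduce a fitted mixture to clone consensus genotypes
#'
#' Thresholds each clone cluster's presence probabilities at 0.5 (inclusive)
#' to a 0/1 consensus genotype and appends an all-zero germline root so the
#' tree is rootable.
#'
#' @param model fitted [bmix()].
#' @param include cluster indices to keep as clones; defaults to all. Flagged
#'   doublet or poor clusters should be excluded here.
#' @param assay_class optional named `"snv"`/`"sv"` vector for per-clone
#'   mutation-class counts.
#' @param threshold consensus cut on theta (default 0.5, inclusive).
#' @return object of class `clone_nodes`: `genotypes` (nodes x assays 0/1
#'   matrix, first row `root`), `n_cells` (argmax assignment counts; 0 for
#'   the root), `n_snv`, `n_sv`.
#' @export
consensus_genotypes <- function(model, include = NULL, assay_class = NULL,
                                threshold = 0.5) {
  include <- include %||% seq_len(model$K)
  G <- (model$theta[include, , drop = FALSE] >= threshold) * 1L
  rownames(G) <- paste0("clone", include)
  G <- rbind(root = 0L, G)
  n_cells <- c(0L, vapply(include, function(k)
    sum(model$cluster == k), integer(1)))
  if (is.null(assay_class)) {
    assay_class <- setNames(rep(NA_character_, ncol(G)), colnames(G))
  }
  cls <- assay_class[colnames(G)]
  n_snv <- as.integer(G %*% (!is.na(cls) & cls == "snv"))
  n_sv <- as.integer(G %*% (!is.na(cls) & cls == "sv"))
  structure(list(genotypes = G,
                 n_cells = setNames(n_cells, rownames(G)),
                 n_snv = setNames(n_snv, rownames(G)),
                 n_sv = setNames(n_sv, rownames(G))),
            class = "clone_nodes")
}

#' @export
print.clone_nodes <- function(x, ...) {
  cat(sprintf("clone_nodes: %d nodes (incl. germline root), %d assays\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  df <- data.frame(n_cells = x$n_cells, n_mutations = rowSums(x$genotypes),
                   n_snv = x$n_snv, n_sv = x$n_sv)
  print(df)
  invisible(x)
}

# genetic distance between two binary genotypes
genotype_distance <- function(a, b, method = c("hamming", "jaccard")) {
  method <- match.arg(method)
  if (method == "hamming") return(hamming(a, b))
  u <- sum(a == 1 | b == 1)
  if (u == 0) return(0)
  1 - sum(a == 1 & b == 1) / u
}

#' Build the minimal spanning tree over clone genotypes
#'
#' Forms the complete graph on the nodes with genetic-distance edge weights
#' and extracts a minimum spanning tree with Kruskal's algorithm. Equal-weight
#' edges are taken in lexicographic `(label_a, label_b)` order, so the result
#' is deterministic. Duplicate genotypes are legal (weight-0 edges).
#'
#' @param nodes a `clone_nodes` object (see [consensus_genotypes()]) or a
#'   0/1 matrix of genotypes with row labels.
#' @param distance `"hamming"` (default) or `"jaccard"`.
#' @return object of class `clone_tree`: `nodes`, `edges` (data.frame
#'   `node_a`, `node_b`, `weight`), `total_weight`, `distance`.
#' @export
build_mst <- function(nodes, distance = c("hamming", "jaccard")) {
  distance <- match.arg(distance)
  G <- if (inherits(nodes, "clone_nodes")) nodes$genotypes else as.matrix(nodes)
  m <- nrow(G)
  if (m < 2L) stop("need at least 2 nodes for a spanning tree", call. = FALSE)
  labels <- rownames(G) %||% paste0("node", seq_len(m))
  pairs <- combn(m, 2L)
  w <- vapply(seq_len(ncol(pairs)), function(p)
    genotype_distance(G[pairs[1, p], ], G[pairs[2, p], ], distance),
    numeric(1))
  la <- labels[pairs[1, ]]; lb <- labels[pairs[2, ]]
  swap <- la > lb
  tmp <- la[swap]; la[swap] <- lb[swap]; lb[swap] <- tmp
  ord <- order(w, la, lb)

  # Kruskal with union-find
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  chosen <- integer(0)
  for (e in ord) {
    ra <- find(pairs[1, e]); rb <- find(pairs[2, e])
    if (ra != rb) {
      parent[ra] <- rb
      chosen <- c(chosen, e)
      if (length(chosen) == m - 1L) break
    }
  }
  edges <- data.frame(node_a = la[chosen], node_b = lb[chosen],
                      weight = w[chosen], stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    nodes = if (inherits(nodes, "clone_nodes")) nodes else
      structure(list(genotypes = G,
                     n_cells = setNames(rep(NA_integer_, m), labels),
                     n_snv = setNames(rep(NA_integer_, m), labels),
                     n_sv = setNames(rep(NA_integer_, m), labels)),
                class = "clone_nodes"),
    edges = edges,
    total_weight = sum(edges$weight),
    distance = distance
  ), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d nodes, %d edges, total %s weight %g\n",
              nrow(x$nodes$genotypes), nrow(x$edges), x$distance,
              x$total_weight))
  print(x$edges)
  invisible(x)
}

#' Convert a clone tree to an igraph object
#'
#' Node attributes `n_cells`, `n_snv`, `n_sv` are attached for export and
#' plotting.
#'
#' @param tree a `clone_tree`.
#' @return an igraph graph.
#' @export
as_igraph <- function(tree) {
  g <- igraph::graph_from_data_frame(
    tree$edges,
    directed = FALSE,
    vertices = data.frame(name = rownames(tree$nodes$genotypes),
                          n_cells = tree$nodes$n_cells,
                          n_snv = tree$nodes$n_snv,
                          n_sv = tree$nodes$n_sv)
  )
  igraph::E(g)$weight <- tree$edges$weight
  g
}

#' Write a clone tree to GraphML or DOT
#'
#' @param tree a `clone_tree`.
#' @param path output file.
#' @param format `"graphml"` (default) or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(tree), path, format = "graphml")
  } else {
    lab <- rownames(tree$nodes$genotypes)
    lines <- c("graph clone_tree {",
               sprintf("  \"%s\" [n_cells=%s, n_snv=%s, n_sv=%s];",
                       lab, tree$nodes$n_cells, tree$nodes$n_snv,
                       tree$nodes$n_sv),
               sprintf("  \"%s\" -- \"%s\" [label=%g, weight=%g];",
                       tree$edges$node_a, tree$edges$node_b,
                       tree$edges$weight, tree$edges$weight),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
#' @importFrom graphics plot
plot.clone_tree <- function(x, ...) {
  g <- as_igraph(x)
  sizes <- x$nodes$n_cells
  sizes[is.na(sizes)] <- 0
  igraph::plot.igraph(
    g,
    vertex.size = 15 + 30 * sizes / max(1, sum(sizes, na.rm = TRUE)),
    edge.label = igraph::E(g)$weight,
    ...
  )
  invisible(x)
}
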