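#' Construct a PPI network object
#'
#' A `csrw_network` is an undirected simple graph with a short label,
#' backed by an [igraph::igraph] plus a precomputed adjacency list for
#' fast neighbour lookups. Self-loops and duplicate edges are removed at
#' construction; isolated nodes are preserved.
#'
#' @param label Short string identifier for the network.
#' @param edges Two-column character matrix (or data frame) of endpoints;
#'   may have zero rows.
#' @param nodes Optional character vector of node ids; the union with all
#'   edge endpoints is used, so isolated nodes can be declared here.
#' @return An object of class `csrw_network` with fields `label`, `nodes`
#'   (character), `adj` (named list: node -> character vector of
#'   neighbours) and `graph` (the igraph).
#' @export
csrw_network <- function(label, edges = NULL, nodes = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (is.null(edges)) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) < 2L) stop("edges must have two columns")
    em <- em[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
  }
  # drop self-loops, dedup unordered pairs
  if (nrow(em) > 0L) {
    self <- em[, 1] == em[, 2]
    em <- em[!self, , drop = FALSE]
  }
  if (nrow(em) > 0L) {
    a <- pmin(em[, 1], em[, 2])
    b <- pmax(em[, 1], em[, 2])
    keep <- !duplicated(paste(a, b, sep = "\x1f"))
    a <- a[keep]; b <- b[keep]
    o <- order(a, b, method = "radix")   # canonical edge order
    em <- cbind(a[o], b[o])
  }
  all_nodes <- sort(unique(c(as.character(nodes), as.vector(em))))
  g <- igraph::make_empty_graph(n = length(all_nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_nodes)
  if (nrow(em) > 0L) g <- igraph::add_edges(g, t(em))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(vs) vs$name)
  names(adj) <- all_nodes
  structure(
    list(label = label, nodes = all_nodes, adj = adj, graph = g),
    class = "csrw_network"
  )
}

#' @export
print.csrw_network <- function(x, ...) {
  cat(sprintf("<csrw_network '%s': %d nodes, %d edges>\n",
              x$label, length(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}

#' Number of nodes in a network
#' @param net A `csrw_network`.
#' @return Integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Neighbours of a node
#' @param net A `csrw_network`.
#' @param v Node id (character).
#' @return Character vector of neighbour ids (possibly empty).
#' @export
neighbors_of <- function(net, v) {
  nb <- net$adj[[v]]
  if (is.null(nb)) stop(sprintf("node '%s' not in network '%s'", v, net$label))
  nb
}

#' Edge list of a network
#' @param net A `csrw_network`.
#' @return Two-column character matrix of unordered edges.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  storage.mode(el) <- "character"
  el
}

#' Bundle networks into an ordered set
#'
#' @param ... `csrw_network` objects, or a single list of them.
#' @return A `csrw_network_set`: named list of networks (by label) that
#'   preserves the given order. At least two networks with distinct
#'   labels are required.
#' @export
network_set <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && !inherits(nets[[1]], "csrw_network")) {
    nets <- nets[[1]]
  }
  ok <- vapply(nets, inherits, logical(1), "csrw_network")
  if (!all(ok)) stop("all elements must be csrw_network objects")
  labels <- vapply(nets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("network labels must be unique")
  if (length(nets) < 2L) stop("a network set needs at least 2 networks")
  names(nets) <- labels
  structure(nets, class = "csrw_network_set")
}

#' @export
print.csrw_network_set <- function(x, ...) {
  cat(sprintf("<csrw_network_set: %d networks [%s]>\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Labels of a network set
#' @param nets A `csrw_network_set`.
#' @return Character vector of labels in set order.
#' @export
set_labels <- function(nets) names(nets)

# Internal: canonical key of an unordered label pair, respecting set order.
pair_key <- function(u_label, v_label) paste(u_label, v_label, sep = "\x1f")

# Internal: key for a node pair within one network pair.
node_pair_key <- function(u, v) paste(u, v, sep = "\x1f")
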