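#' Construct a network alignment (set of equivalence classes)
#'
#' An alignment is a list of disjoint equivalence classes. Each class is
#' a data frame with columns `network` and `node`; a class may contain
#' several nodes from the same network (many-to-many alignment).
#'
#' @param classes List of data frames, each with character columns
#'   `network` and `node`.
#' @param networks Optional `csrw_network_set`; if given, every member
#'   must name a known network and an existing node in it.
#' @return A `csrw_alignment` object.
#' @export
alignment <- function(classes = list(), networks = NULL) {
  classes <- lapply(classes, function(cl) {
    cl <- as.data.frame(cl, stringsAsFactors = FALSE)
    stopifnot(all(c("network", "node") %in% names(cl)))
    data.frame(network = as.character(cl$network),
               node = as.character(cl$node), stringsAsFactors = FALSE)
  })
  members <- unlist(lapply(classes, function(cl)
    paste(cl$network, cl$node, sep = "|")), use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("duplicate member across classes: ",
         members[duplicated(members)][1])
  }
  if (!is.null(networks)) {
    for (cl in classes) {
      for (i in seq_len(nrow(cl))) {
        lab <- cl$network[i]
        if (!lab %in% names(networks)) {
          stop(sprintf("unknown network label '%s' in alignment", lab))
        }
        if (!cl$node[i] %in% networks[[lab]]$nodes) {
          stop(sprintf("node '%s' not in network '%s'", cl$node[i], lab))
        }
      }
    }
  }
  structure(list(classes = classes), class = "csrw_alignment")
}

#' @export
print.csrw_alignment <- function(x, ...) {
  sizes <- vapply(x$classes, nrow, integer(1))
  cat(sprintf("<csrw_alignment: %d classes, %d aligned nodes>\n",
              length(x$classes), sum(sizes)))
  invisible(x)
}

#' Number of equivalence classes
#' @param A A `csrw_alignment`.
#' @return Integer count of classes.
#' @export
n_classes <- function(A) length(A$classes)

# Internal: all cross-network node pairs induced by the classes of A.
# Returns a data frame (net1, node1, net2, node2) with each unordered
# pair once, ordered canonically by (network, node) of the two members.
induced_pairs <- function(A) {
  out <- vector("list", length(A$classes))
  for (k in seq_along(A$classes)) {
    cl <- A$classes[[k]]
    n <- nrow(cl)
    if (n < 2L) next
    idx <- utils::combn(n, 2)
    i <- idx[1, ]; j <- idx[2, ]
    cross <- cl$network[i] != cl$network[j]
    if (!any(cross)) next
    i <- i[cross]; j <- j[cross]
    # canonical member order: by (network, node)
    swap <- (cl$network[i] > cl$network[j]) |
      (cl$network[i] == cl$network[j] & cl$node[i] > cl$node[j])
    a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
    out[[k]] <- data.frame(
      net1 = cl$network[a], node1 = cl$node[a],
      net2 = cl$network[b], node2 = cl$node[b],
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(net1 = character(0), node1 = character(0),
                      net2 = character(0), node2 = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Internal: keys of induced pairs for set operations.
induced_pair_keys <- function(A) {
  p <- induced_pairs(A)
  paste(p$net1, p$node1, p$net2, p$node2, sep = "\x1f")
}
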