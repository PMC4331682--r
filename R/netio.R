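#' Read a network from a plain-text edge list
#'
#' Parses a whitespace-delimited edge list: the first two tokens of each
#' non-comment line are node ids (opaque, case-sensitive strings). Lines
#' starting with `#` and blank lines are ignored. Self-loops are dropped
#' with a warning; duplicate edges are deduplicated silently. An empty
#' file yields an empty network.
#'
#' @param path Path to the edge-list file.
#' @param label Network label to attach.
#' @return A [csrw_network()].
#' @export
read_network <- function(path, label) {
  if (!file.exists(path)) stop(sprintf("cannot read network file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(csrw_network(label))
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s' line %d: expected 2 node ids",
                 path, lineno[bad[1]]))
  }
  em <- t(vapply(toks, function(tk) tk[1:2], character(2)))
  n_self <- sum(em[, 1] == em[, 2])
  if (n_self > 0L) {
    warning(sprintf("%s: dropped %d self-loop(s)", path, n_self))
  }
  csrw_network(label, edges = em, nodes = unique(as.vector(em)))
}

#' Read a pairwise node-similarity table
#'
#' Each line holds `nodeU nodeV score`. Entries with score <= 0 are
#' discarded (their absence defines the non-similar set I); entries that
#' reference unknown nodes are discarded with a warning reporting the
#' count; duplicate (u, v) entries keep the maximum score.
#'
#' @param path Path to the 3-column similarity file.
#' @param netU,netV The two [csrw_network()]s the table refers to.
#' @return A [sim_table()]; errors if no positive, resolvable entry
#'   survives (M empty).
#' @export
read_similarity <- function(path, netU, netV) {
  if (!file.exists(path)) stop(sprintf("cannot read similarity file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no similar node pairs (M is empty)")
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s' line %d: expected nodeU nodeV score",
                 path, lineno[bad[1]]))
  }
  u <- vapply(toks, `[[`, character(1), 1L)
  v <- vapply(toks, `[[`, character(1), 2L)
  sc <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 3L)))
  if (anyNA(sc)) {
    stop(sprintf("parse error in '%s' line %d: non-numeric score",
                 path, lineno[which(is.na(sc))[1]]))
  }
  known <- u %in% netU$nodes & v %in% netV$nodes
  n_unknown <- sum(!known)
  if (n_unknown > 0L) {
    warning(sprintf("%s: discarded %d entr%s referencing unknown nodes",
                    path, n_unknown, if (n_unknown == 1L) "y" else "ies"))
  }
  u <- u[known]; v <- v[known]; sc <- sc[known]
  if (length(u) == 0L || all(sc <= 0)) stop("no similar node pairs (M is empty)")
  sim_table(netU$label, netV$label, u, v, sc)
}

#' Read a functional annotation table
#'
#' Each line holds `networkLabel nodeId functionLabel`. A node annotated
#' more than once keeps the last entry (with a warning). An empty file
#' yields an empty map.
#'
#' @param path Path to the 3-column annotation file.
#' @return A `csrw_annmap`: map from (network, node) to function label.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read annotation file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(annotation_map(character(0), character(0), character(0)))
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in '%s' line %d: expected network node function",
                 path, lineno[bad[1]]))
  }
  net <- vapply(toks, `[[`, character(1), 1L)
  node <- vapply(toks, `[[`, character(1), 2L)
  fun <- vapply(toks, `[[`, character(1), 3L)
  key <- paste(net, node, sep = "\x1f")
  ndup <- sum(duplicated(key))
  if (ndup > 0L) {
    warning(sprintf("%s: %d node(s) annotated more than once; keeping last",
                    path, ndup))
  }
  annotation_map(net, node, fun)
}

#' Build an annotation map in memory
#'
#' @param network,node,fun Parallel character vectors; later entries for
#'   the same (network, node) override earlier ones.
#' @return A `csrw_annmap`.
#' @export
annotation_map <- function(network, node, fun) {
  key <- paste(as.character(network), as.character(node), sep = "\x1f")
  map <- stats::setNames(as.character(fun), key)
  map <- map[!duplicated(names(map), fromLast = TRUE)]
  structure(list(map = map), class = "csrw_annmap")
}

#' @export
print.csrw_annmap <- function(x, ...) {
  cat(sprintf("<csrw_annmap: %d annotated nodes, %d distinct labels>\n",
              length(x$map), length(unique(x$map))))
  invisible(x)
}

# Internal: vectorized annotation lookup; NA where unannotated.
ann_lookup <- function(ann, network, node) {
  unname(ann$map[paste(network, node, sep = "\x1f")])
}

# Internal: serialize one class as sorted "net|node" member tokens.
class_tokens <- function(cl) {
  sort(paste(cl$network, cl$node, sep = "|"), method = "radix")
}

#' Write an alignment to a cluster file
#'
#' One equivalence class per line, members serialized as
#' `<networkLabel>|<nodeId>` and separated by tabs. Classes are ordered
#' by descending size, ties by lexicographic first member; members
#' within a class are sorted lexicographically. UTF-8, Unix newlines.
#'
#' @param A A [alignment()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_alignment <- function(A, path) {
  stopifnot(inherits(A, "csrw_alignment"))
  toks <- lapply(A$classes, class_tokens)
  sizes <- vapply(toks, length, integer(1))
  first <- vapply(toks, function(x) x[1], character(1))
  o <- order(-sizes, first, method = "radix")
  lines <- vapply(toks[o], paste, character(1), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an alignment from a cluster file
#'
#' Exact inverse of [write_alignment()] on its own output.
#'
#' @param path Path to the cluster file.
#' @param networks A `csrw_network_set`; member labels and nodes are
#'   validated against it.
#' @return A [alignment()].
#' @export
read_alignment <- function(path, networks) {
  if (!file.exists(path)) stop(sprintf("cannot read alignment file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  classes <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    has_sep <- grepl("|", toks, fixed = TRUE)
    if (!all(has_sep)) {
      stop(sprintf("parse error in '%s' line %d: member '%s' lacks '|'",
                   path, i, toks[!has_sep][1]))
    }
    net <- sub("\\|.*$", "", toks)
    node <- sub("^[^|]*\\|", "", toks)
    if (anyDuplicated(toks)) {
      stop(sprintf("parse error in '%s' line %d: duplicate member '%s'",
                   path, i, toks[duplicated(toks)][1]))
    }
    data.frame(network = net, node = node, stringsAsFactors = FALSE)
  })
  alignment(classes, networks = networks)
}
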