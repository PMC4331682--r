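#' Write a network as a plain-text edge list
#'
#' One `u v` line per edge, lexicographically sorted. Isolated nodes are
#' written as self-loop lines `x x`: [read_network()] drops the loop
#' (with its usual warning) but keeps the node, so the round trip is
#' lossless.
#'
#' @param net A [csrw_network()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_network <- function(net, path) {
  el <- network_edges(net)
  iso <- setdiff(net$nodes, unique(as.vector(el)))
  lines <- sort(c(paste(el[, 1], el[, 2]), paste(iso, iso)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a similarity table as 3-column text
#'
#' @param sim A [sim_table()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_similarity <- function(sim, path) {
  lines <- sprintf("%s %s %.10g", sim$u, sim$v, sim$score)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write an annotation map as 3-column text
#'
#' @param ann A `csrw_annmap`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(ann, path) {
  keys <- names(ann$map)
  parts <- strsplit(keys, "\x1f", fixed = TRUE)
  net <- vapply(parts, `[[`, character(1), 1L)
  node <- vapply(parts, `[[`, character(1), 2L)
  lines <- sort(sprintf("%s %s %s", net, node, unname(ann$map)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
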