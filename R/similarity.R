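#' Construct a node-similarity table for one network pair
#'
#' Holds the strictly positive node-similarity scores s(u, v) between two
#' networks (typically BLAST bit scores). The positive support of the
#' table is the match set M of the context-sensitive random walk;
#' zero-score pairs are simply absent. Duplicate (u, v) entries keep the
#' maximum score; entries are stored sorted lexicographically by (u, v).
#'
#' @param u_label,v_label Labels of the two networks.
#' @param u,v Character vectors of node ids (same length).
#' @param score Numeric vector of strictly positive scores.
#' @return A `csrw_simtab` with fields `u_label`, `v_label`, `u`, `v`,
#'   `score`.
#' @export
sim_table <- function(u_label, v_label, u, v, score) {
  stopifnot(length(u) == length(v), length(v) == length(score))
  u <- as.character(u); v <- as.character(v); score <- as.numeric(score)
  keep <- score > 0
  u <- u[keep]; v <- v[keep]; score <- score[keep]
  if (length(u) == 0L) stop("no similar node pairs (M is empty)")
  key <- node_pair_key(u, v)
  if (anyDuplicated(key)) {
    score <- tapply(score, key, max)
    uv <- do.call(rbind, strsplit(names(score), "\x1f", fixed = TRUE))
    u <- uv[, 1]; v <- uv[, 2]; score <- as.numeric(score)
  }
  o <- order(u, v, method = "radix")
  structure(
    list(u_label = u_label, v_label = v_label,
         u = u[o], v = v[o], score = score[o]),
    class = "csrw_simtab"
  )
}

#' @export
print.csrw_simtab <- function(x, ...) {
  cat(sprintf("<csrw_simtab %s-%s: |M| = %d>\n",
              x$u_label, x$v_label, length(x$u)))
  invisible(x)
}

#' Transpose view of a similarity table
#'
#' `sim_transpose(t)(v, u)` equals `t(u, v)`: the (V, U) view of a (U, V)
#' table.
#'
#' @param sim A `csrw_simtab`.
#' @return A `csrw_simtab` with the roles of the two networks swapped.
#' @export
sim_transpose <- function(sim) {
  sim_table(sim$v_label, sim$u_label, sim$v, sim$u, sim$score)
}

# Internal: named numeric lookup of scores by "u\x1fv" key.
sim_lookup <- function(sim) {
  stats::setNames(sim$score, node_pair_key(sim$u, sim$v))
}

#' Number of similar node pairs (|M|)
#' @param sim A `csrw_simtab`.
#' @return Integer size of the positive support.
#' @export
n_pairs <- function(sim) length(sim$u)
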