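#' Parameters of the greedy alignment construction
#'
#' @param n_max Maximum number of members per equivalence class.
#'   Default 10.
#' @param min_score Candidates with score <= `min_score` are dropped
#'   before ranking. Default 0 (every positive-score candidate
#'   eligible).
#' @return A `csrw_align_params` list.
#' @export
align_params <- function(n_max = 10L, min_score = 0) {
  stopifnot(n_max >= 2)
  structure(list(n_max = as.integer(n_max), min_score = min_score),
            class = "csrw_align_params")
}

#' Pool and rank candidate node pairs across all network pairs
#'
#' Collects every positive-score entry of every correspondence table
#' into a single list sorted by descending score; ties are broken
#' lexicographically by (network pair labels, u, v) so the ranking is
#' deterministic.
#'
#' @param cs A `csrw_corr_set`.
#' @param params An [align_params()]; entries with score <=
#'   `min_score` are excluded.
#' @return Data frame with columns `net_u`, `u`, `net_v`, `v`, `score`,
#'   sorted as described. Errors if no candidate survives.
#' @export
rank_pairs <- function(cs, params = align_params()) {
  rows <- lapply(cs$tables, function(tab) {
    tr <- Matrix::summary(methods::as(tab$C, "TsparseMatrix"))
    keep <- tr$x > params$min_score
    if (!any(keep)) return(NULL)
    data.frame(
      net_u = tab$a, u = rownames(tab$C)[tr$i[keep]],
      net_v = tab$b, v = colnames(tab$C)[tr$j[keep]],
      score = tr$x[keep], stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no candidate pairs above min_score")
  out <- do.call(rbind, rows)
  o <- order(-out$score, out$net_u, out$net_v, out$u, out$v,
             method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy construction of the multiple network alignment
#'
#' Scans the candidate list in the given order (highest correspondence
#' score first when produced by [rank_pairs()]) and grows equivalence
#' classes: a pair of two unassigned nodes founds a new class; a pair
#' with exactly one assigned node adds the other node to that class if
#' the class is below `n_max` members; a pair whose nodes are both
#' assigned is skipped (classes are never merged). The result is a
#' heuristic maximum-expected-accuracy alignment when scores approximate
#' posterior alignment probabilities.
#'
#' @param ranked Data frame as returned by [rank_pairs()].
#' @param networks A `csrw_network_set` (used to validate members).
#' @param params An [align_params()].
#' @return A [alignment()]; every class has between 2 and `n_max`
#'   members and classes are pairwise disjoint.
#' @export
build_alignment <- function(ranked, networks, params = align_params()) {
  n_max <- params$n_max
  assigned <- new.env(parent = emptyenv(), hash = TRUE)
  cls_net <- list(); cls_node <- list()
  nc <- 0L
  for (r in seq_len(nrow(ranked))) {
    ku <- paste(ranked$net_u[r], ranked$u[r], sep = "\x1f")
    kv <- paste(ranked$net_v[r], ranked$v[r], sep = "\x1f")
    au <- assigned[[ku]]; av <- assigned[[kv]]
    if (is.null(au) && is.null(av)) {
      nc <- nc + 1L
      cls_net[[nc]] <- c(ranked$net_u[r], ranked$net_v[r])
      cls_node[[nc]] <- c(ranked$u[r], ranked$v[r])
      assigned[[ku]] <- nc; assigned[[kv]] <- nc
    } else if (is.null(av)) {
      if (length(cls_node[[au]]) < n_max) {
        cls_net[[au]] <- c(cls_net[[au]], ranked$net_v[r])
        cls_node[[au]] <- c(cls_node[[au]], ranked$v[r])
        assigned[[kv]] <- au
      }
    } else if (is.null(au)) {
      if (length(cls_node[[av]]) < n_max) {
        cls_net[[av]] <- c(cls_net[[av]], ranked$net_u[r])
        cls_node[[av]] <- c(cls_node[[av]], ranked$u[r])
        assigned[[ku]] <- av
      }
    }
    # both assigned (same or different classes): skip, never merge
  }
  classes <- lapply(seq_len(nc), function(k)
    data.frame(network = cls_net[[k]], node = cls_node[[k]],
               stringsAsFactors = FALSE))
  alignment(classes, networks = networks)
}

#' End-to-end multiple network alignment
#'
#' Runs the whole pipeline: per-pair context-sensitive random walk
#' scoring, selective consistency transformation, and greedy class
#' construction.
#'
#' @param networks A `csrw_network_set`.
#' @param sims List of [sim_table()]s, one per unordered network pair.
#' @param wparams A [walk_params()].
#' @param pparams A [pct_params()].
#' @param aparams An [align_params()].
#' @param complete Require a similarity table for every unordered
#'   network pair (default); `FALSE` tolerates skipped pairs.
#' @return List with `alignment` (the [alignment()]), `scores` (the
#'   post-PCT `csrw_corr_set`) and `pair_info` (data frame of per-pair
#'   |M|, lambda, iterations, dangling counts).
#' @export
align_networks <- function(networks, sims,
                           wparams = walk_params(),
                           pparams = pct_params(),
                           aparams = align_params(),
                           complete = TRUE) {
  ps <- list()
  info <- list()
  for (sim in sims) {
    netU <- networks[[sim$u_label]]
    netV <- networks[[sim$v_label]]
    if (is.null(netU) || is.null(netV)) {
      stop(sprintf("similarity table (%s, %s) references unknown network",
                   sim$u_label, sim$v_label))
    }
    res <- pair_correspondence(netU, netV, sim, wparams)
    ps[[length(ps) + 1L]] <- res
    info[[length(info) + 1L]] <- data.frame(
      pair = paste(sim$u_label, sim$v_label, sep = "-"),
      m = n_pairs(sim), lambda = res$lambda,
      iterations = res$iterations,
      dangling = sum(res$chain$dangling), stringsAsFactors = FALSE
    )
  }
  cs <- correspondence_set(networks, ps, complete = complete)
  cs <- apply_selective_pct(cs, pparams)
  ranked <- rank_pairs(cs, aparams)
  A <- build_alignment(ranked, networks, aparams)
  list(alignment = A, scores = cs, pair_info = do.call(rbind, info))
}
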