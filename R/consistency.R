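#' Parameters of the probabilistic consistency transformation
#'
#' @param alpha Intra-network mixing weight: weight kept by the raw
#'   scores when blending with neighbourhood-averaged scores. Default
#'   0.9.
#' @param beta Cross-network mixing weight: weight kept by the raw
#'   scores when blending with evidence composed through third networks.
#'   Default 0.8.
#' @param lambda_t Restart-probability gate: pairs whose reduced product
#'   graph is fragmented (lambda > lambda_t) skip the transformation
#'   entirely, since consistency propagation assumes well-connected
#'   product graphs. Default 0.7.
#' @return A `csrw_pct_params` list.
#' @export
pct_params <- function(alpha = 0.9, beta = 0.8, lambda_t = 0.7) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            lambda_t >= 0, lambda_t <= 1)
  structure(list(alpha = alpha, beta = beta, lambda_t = lambda_t),
            class = "csrw_pct_params")
}

#' Bundle per-pair correspondence scores for a network set
#'
#' Collects one [pair_correspondence()] result per unordered network
#' pair into sparse score matrices keyed by the pair's canonical order
#' (the order of the network set).
#'
#' @param networks A `csrw_network_set`.
#' @param pair_scores List of `csrw_pair_scores`, one per unordered pair
#'   of networks in the set (either orientation).
#' @param complete Require a table for every unordered pair (default);
#'   set `FALSE` to allow pairs to be absent (e.g. skipped because their
#'   match set was empty).
#' @return A `csrw_corr_set`: `networks` plus per-pair entries holding
#'   the score matrix `C` (rows = nodes of the first network, columns =
#'   nodes of the second), the M-support pattern and `lambda`.
#' @export
correspondence_set <- function(networks, pair_scores, complete = TRUE) {
  stopifnot(inherits(networks, "csrw_network_set"))
  labels <- names(networks)
  tables <- list()
  for (ps in pair_scores) {
    ch <- ps$chain
    iu <- match(ch$u_label, labels); iv <- match(ch$v_label, labels)
    if (is.na(iu) || is.na(iv)) {
      stop(sprintf("pair (%s, %s) references unknown network",
                   ch$u_label, ch$v_label))
    }
    flip <- iu > iv
    a <- if (flip) ch$v_label else ch$u_label
    b <- if (flip) ch$u_label else ch$v_label
    ra <- if (flip) ch$pairs$v else ch$pairs$u
    rb <- if (flip) ch$pairs$u else ch$pairs$v
    C <- Matrix::sparseMatrix(
      i = match(ra, networks[[a]]$nodes),
      j = match(rb, networks[[b]]$nodes),
      x = ps$c,
      dims = c(n_nodes(networks[[a]]), n_nodes(networks[[b]])),
      dimnames = list(networks[[a]]$nodes, networks[[b]]$nodes)
    )
    tables[[pair_key(a, b)]] <- list(
      a = a, b = b, C = C,
      support = methods::as(methods::as(C != 0, "nMatrix"), "CsparseMatrix"),
      lambda = ps$lambda
    )
  }
  if (complete) {
    expected <- utils::combn(labels, 2)
    for (k in seq_len(ncol(expected))) {
      if (is.null(tables[[pair_key(expected[1, k], expected[2, k])]])) {
        stop(sprintf("missing correspondence table for pair (%s, %s)",
                     expected[1, k], expected[2, k]))
      }
    }
  }
  structure(list(networks = networks, tables = tables),
            class = "csrw_corr_set")
}

#' @export
print.csrw_corr_set <- function(x, ...) {
  cat(sprintf("<csrw_corr_set: %d networks, %d pair tables>\n",
              length(x$networks), length(x$tables)))
  invisible(x)
}

# Internal: score matrix for pair (U, V) in the requested orientation.
corr_matrix <- function(cs, u_label, v_label) {
  tab <- cs$tables[[pair_key(u_label, v_label)]]
  if (!is.null(tab)) return(tab$C)
  tab <- cs$tables[[pair_key(v_label, u_label)]]
  if (is.null(tab)) stop(sprintf("no table for pair (%s, %s)", u_label, v_label))
  Matrix::t(tab$C)
}

# Internal: is a table present for the unordered pair (U, V)?
has_pair <- function(cs, u_label, v_label) {
  !is.null(cs$tables[[pair_key(u_label, v_label)]]) ||
    !is.null(cs$tables[[pair_key(v_label, u_label)]])
}

# Internal: sparse row-normalized adjacency of a network (isolated rows 0).
row_norm_adj <- function(net) {
  A <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(x = inv) %*% A
}

#' Intra-network neighbourhood smoothing of a score matrix
#'
#' Blends each pair score with the average score of the neighbouring
#' pairs: `C' = alpha * C + (1 - alpha) * A_U C A_V'`, where `A_X` is the
#' row-normalized adjacency of network X. The result is restricted to
#' the given support pattern (by default the nonzero pattern of `C`), so
#' smoothing never grows the candidate set.
#'
#' @param C Sparse nonnegative score matrix (nodes of U x nodes of V).
#' @param netU,netV The two networks (node order must match `C`).
#' @param alpha Mixing weight in \[0, 1\].
#' @param support Optional sparse pattern matrix marking the entries to
#'   keep.
#' @return Smoothed sparse matrix with the same dimensions.
#' @export
intra_network_smoothing <- function(C, netU, netV, alpha, support = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (is.null(support)) {
    support <- methods::as(methods::as(C != 0, "nMatrix"), "CsparseMatrix")
  }
  AU <- row_norm_adj(netU)
  AV <- row_norm_adj(netV)
  out <- alpha * C + (1 - alpha) * (AU %*% C %*% Matrix::t(AV))
  restrict_support(out, support)
}

# Internal: zero out entries outside the support pattern.
restrict_support <- function(M, support) {
  M * methods::as(support, "dMatrix")
}

#' Cross-network consistency transformation
#'
#' Propagates correspondence evidence through third networks: for each
#' pair (U, V), `C'' = beta * C' + (1 - beta) * mean_W C'(U,W) C'(W,V)`
#' over all other networks W, restricted to the original support of
#' (U, V). With only two networks the transformation is the identity.
#'
#' @param cs A `csrw_corr_set`.
#' @param beta Mixing weight in \[0, 1\].
#' @return A `csrw_corr_set` with transformed tables.
#' @export
cross_network_pct <- function(cs, beta) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  labels <- names(cs$networks)
  if (length(labels) == 2L || beta == 1) return(cs)
  out <- cs
  for (key in names(cs$tables)) {
    tab <- cs$tables[[key]]
    others <- setdiff(labels, c(tab$a, tab$b))
    others <- others[vapply(others, function(w)
      has_pair(cs, tab$a, w) && has_pair(cs, w, tab$b), logical(1))]
    if (length(others) == 0L) next
    comp <- NULL
    for (w in others) {
      term <- corr_matrix(cs, tab$a, w) %*% corr_matrix(cs, w, tab$b)
      comp <- if (is.null(comp)) term else comp + term
    }
    comp <- comp / length(others)
    out$tables[[key]]$C <-
      restrict_support(beta * tab$C + (1 - beta) * comp, tab$support)
  }
  out
}

#' Selectively apply the consistency transformation
#'
#' Network pairs whose restart probability exceeds `lambda_t` are passed
#' through untouched (their product graph is too fragmented for
#' consistency propagation to help); the remaining pairs receive
#' intra-network smoothing followed by the cross-network transformation.
#' Cross-network terms read the stage-one tables: gated pairs contribute
#' their raw scores.
#'
#' @param cs A `csrw_corr_set` with per-pair `lambda` recorded.
#' @param params A [pct_params()].
#' @return A transformed `csrw_corr_set`.
#' @export
apply_selective_pct <- function(cs, params = pct_params()) {
  labels <- names(cs$networks)
  gated <- vapply(cs$tables, function(t) t$lambda > params$lambda_t, logical(1))
  stage1 <- cs
  for (key in names(cs$tables)) {
    if (gated[[key]]) next
    tab <- cs$tables[[key]]
    stage1$tables[[key]]$C <- intra_network_smoothing(
      tab$C, cs$networks[[tab$a]], cs$networks[[tab$b]],
      params$alpha, support = tab$support
    )
  }
  if (length(labels) == 2L) return(stage1)
  stage2 <- cross_network_pct(stage1, params$beta)
  for (key in names(cs$tables)) {
    if (gated[[key]]) stage2$tables[[key]] <- cs$tables[[key]]
  }
  stage2
}
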