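#' Parameters of the context-sensitive random walk
#'
#' @param K Percentile (in percent) used by the restart-probability rule:
#'   lambda is the node fraction held by the `floor(K/100 * C)` smallest
#'   connected components of the reduced product graph. Default 99.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Iteration cap of the power iteration.
#' @param override_lambda Optional fixed restart probability in \[0, 1\];
#'   when set, the component rule is skipped.
#' @return A `csrw_walk_params` list.
#' @export
walk_params <- function(K = 99, tol = 1e-10, max_iter = 1000L,
                        override_lambda = NULL) {
  stopifnot(K > 0, K <= 100, tol > 0, max_iter >= 1)
  if (!is.null(override_lambda)) {
    stopifnot(override_lambda >= 0, override_lambda <= 1)
  }
  structure(list(K = K, tol = tol, max_iter = as.integer(max_iter),
                 override_lambda = override_lambda),
            class = "csrw_walk_params")
}

#' Similar neighbouring pairs of a match state
#'
#' For a walker at (u_c, v_c), the set N(u_c, v_c) of neighbouring node
#' pairs with positive similarity: all (u_i, v_j) with u_i a neighbour of
#' u_c, v_j a neighbour of v_c, and (u_i, v_j) in M. When non-empty the
#' walker makes a simultaneous (match) move into this set; otherwise it
#' falls back to an individual walk on one network.
#'
#' @param u,v Current position: node in `netU`, node in `netV`.
#' @param netU,netV The two networks.
#' @param sim The [sim_table()] for this network pair.
#' @return Data frame with columns `u`, `v`, `score`, sorted by (u, v);
#'   zero rows if the set is empty.
#' @export
neighbor_pair_set <- function(u, v, netU, netV, sim) {
  nu <- neighbors_of(netU, u)
  nv <- neighbors_of(netV, v)
  if (length(nu) == 0L || length(nv) == 0L) {
    return(data.frame(u = character(0), v = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  cand_u <- rep(nu, times = length(nv))
  cand_v <- rep(nv, each = length(nu))
  sc <- sim_lookup(sim)[node_pair_key(cand_u, cand_v)]
  hit <- !is.na(sc)
  out <- data.frame(u = cand_u[hit], v = cand_v[hit],
                    score = as.numeric(sc[hit]), stringsAsFactors = FALSE)
  out[order(out$u, out$v, method = "radix"), , drop = FALSE]
}

#' Build the reduced transition structure of the CSRW
#'
#' Constructs the row-stochastic matrix `P~` over the match set M (node
#' pairs with positive similarity), the similarity-proportional restart
#' distribution `s`, and the restart probability `lambda`.
#'
#' Rows are built per state (u_c, v_c): when the similar neighbouring
#' set is non-empty the row is the similarity-proportional match move
#' (all targets lie in M, so reduction leaves it untouched). Otherwise
#' the walker performs an individual walk: mass |U|/(|U|+|V|) is spread
#' uniformly over the neighbours of u_c (paired with v_c) and mass
#' |V|/(|U|+|V|) over the neighbours of v_c; targets outside M are then
#' removed and the surviving row renormalized. A state whose entire row
#' is removed (or whose nodes have no usable neighbours) is flagged
#' dangling and its row replaced by the restart distribution.
#'
#' @param netU,netV The two networks.
#' @param sim The [sim_table()] for the pair; must be non-empty.
#' @param params A [walk_params()].
#' @return A `csrw_chain`: list with `u_label`, `v_label`, `pairs` (data
#'   frame of M-pairs in lexicographic order), `P` (sparse dgCMatrix),
#'   `s`, `lambda`, `dangling` (logical), `support` (2-column integer
#'   matrix of pre-substitution transitions, used by the lambda rule).
#' @export
build_reduced_chain <- function(netU, netV, sim, params = walk_params()) {
  stopifnot(inherits(sim, "csrw_simtab"))
  if (n_pairs(sim) == 0L) stop("no similar node pairs (M is empty)")
  m <- n_pairs(sim)
  pairs <- data.frame(u = sim$u, v = sim$v, stringsAsFactors = FALSE)
  score <- sim$score
  idx_map <- stats::setNames(seq_len(m), node_pair_key(pairs$u, pairs$v))
  nU <- n_nodes(netU); nV <- n_nodes(netV)
  wU <- nU / (nU + nV); wV <- nV / (nU + nV)

  ii <- vector("list", m); jj <- vector("list", m); xx <- vector("list", m)
  dangling <- logical(m)
  for (st in seq_len(m)) {
    uc <- pairs$u[st]; vc <- pairs$v[st]
    nu <- netU$adj[[uc]]; nv <- netV$adj[[vc]]
    tgt <- integer(0); w <- numeric(0)
    if (length(nu) > 0L && length(nv) > 0L) {
      cand_u <- rep(nu, times = length(nv))
      cand_v <- rep(nv, each = length(nu))
      hit <- idx_map[node_pair_key(cand_u, cand_v)]
      hit <- hit[!is.na(hit)]
      if (length(hit) > 0L) {          # match move (Eq 6)
        tgt <- unname(hit)
        w <- score[tgt]
      }
    }
    if (length(tgt) == 0L) {           # individual walk (Eqs 7a/7b)
      if (length(nu) > 0L) {
        hu <- idx_map[node_pair_key(nu, rep(vc, length(nu)))]
        hu <- hu[!is.na(hu)]
        if (length(hu) > 0L) {
          tgt <- c(tgt, unname(hu))
          w <- c(w, rep(wU / length(nu), length(hu)))
        }
      }
      if (length(nv) > 0L) {
        hv <- idx_map[node_pair_key(rep(uc, length(nv)), nv)]
        hv <- hv[!is.na(hv)]
        if (length(hv) > 0L) {
          tgt <- c(tgt, unname(hv))
          w <- c(w, rep(wV / length(nv), length(hv)))
        }
      }
    }
    if (length(tgt) == 0L) {
      dangling[st] <- TRUE
    } else {
      ii[[st]] <- rep.int(st, length(tgt))
      jj[[st]] <- tgt
      xx[[st]] <- w / sum(w)
    }
  }
  i <- as.integer(unlist(ii)); j <- as.integer(unlist(jj))
  x <- as.numeric(unlist(xx))
  support <- cbind(from = i, to = j)
  s <- score / sum(score)
  if (any(dangling)) {                 # dangling rows -> restart distribution
    dstates <- which(dangling)
    i <- c(i, rep(dstates, each = m))
    j <- c(j, rep.int(seq_len(m), length(dstates)))
    x <- c(x, rep(s, times = length(dstates)))
  }
  P <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, m))
  chain <- structure(
    list(u_label = sim$u_label, v_label = sim$v_label, pairs = pairs,
         P = P, s = s, lambda = NA_real_, dangling = dangling,
         support = support, params = params),
    class = "csrw_chain"
  )
  chain$lambda <- if (is.null(params$override_lambda)) {
    compute_restart_lambda(chain, params$K)
  } else {
    params$override_lambda
  }
  chain
}

#' @export
print.csrw_chain <- function(x, ...) {
  cat(sprintf(
    "<csrw_chain %s-%s: |M| = %d, lambda = %.4g, %d dangling>\n",
    x$u_label, x$v_label, nrow(x$pairs), x$lambda, sum(x$dangling)))
  invisible(x)
}

#' Restart probability from reduced-product-graph fragmentation
#'
#' Builds the undirected support graph of the pre-substitution reduced
#' chain (dangling states contribute no edges), finds its connected
#' components, and returns the fraction of M-states contained in the
#' `floor(K/100 * C)` smallest components of the `C` found. A single
#' well-connected component gives lambda = 0; complete fragmentation
#' into singletons gives lambda close to 1 (restart at almost every
#' step).
#'
#' @param chain A `csrw_chain` (the `lambda` field is ignored).
#' @param K Percentile in percent, see [walk_params()].
#' @return Restart probability in \[0, 1\].
#' @export
compute_restart_lambda <- function(chain, K = 99) {
  m <- nrow(chain$pairs)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(chain$support) > 0L) {
    g <- igraph::add_edges(g, t(chain$support))
  }
  comp <- igraph::components(g)
  C <- comp$no
  sizes <- as.integer(comp$csize)
  # deterministic order: ascending size, ties by smallest member index
  first_member <- vapply(seq_len(C), function(k)
    min(which(comp$membership == k)), integer(1))
  o <- order(sizes, first_member)
  k <- floor(K / 100 * C)
  if (k == 0L) return(0)
  sum(sizes[o][seq_len(k)]) / m
}

#' Stationary distribution of the reduced chain
#'
#' Power iteration started at the restart distribution `s`. The iteration
#' is run on the half-lazy chain (I + P~)/2, which has the same
#' stationary distribution as P~ but is aperiodic by construction, so the
#' iterates converge geometrically even when P~ is periodic; for a
#' reducible P~ the limit is the start-dependent projection of `s`, which
#' keeps the output deterministic and restart-consistent.
#'
#' @param chain A `csrw_chain` with row-stochastic `P`.
#' @param params A [walk_params()]; `tol` is the L1 tolerance on
#'   successive iterates, `max_iter` the cap.
#' @return Numeric probability vector over the M-states (sums to 1) with
#'   attribute `iterations`.
#' @export
stationary_distribution <- function(chain, params = chain$params) {
  P <- chain$P
  rs <- Matrix::rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("internal error: reduced transition matrix is not row-stochastic")
  }
  x <- chain$s
  it <- 0L
  repeat {
    xn <- 0.5 * x + 0.5 * as.vector(x %*% P)
    it <- it + 1L
    d <- sum(abs(xn - x))
    x <- xn
    if (d < params$tol || it >= params$max_iter) break
  }
  x <- x / sum(x)
  attr(x, "iterations") <- it
  x
}

#' Correspondence scores from stationary distribution and restart vector
#'
#' The final node correspondence score vector is the convex combination
#' `c = lambda * s + (1 - lambda) * pi`, blending normalized node
#' similarity with the long-run match-state occupancy of the walk.
#'
#' @param pi Stationary distribution over M-states.
#' @param s Restart distribution over the same states.
#' @param lambda Restart probability in \[0, 1\].
#' @return Numeric score vector summing to 1.
#' @export
correspondence_scores <- function(pi, s, lambda) {
  if (length(pi) != length(s)) stop("pi and s must have the same length")
  if (is.na(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  lambda * s + (1 - lambda) * as.numeric(pi)
}

#' Full correspondence computation for one network pair
#'
#' Convenience driver: builds the reduced chain, computes the stationary
#' distribution and the final correspondence scores.
#'
#' @param netU,netV The two networks.
#' @param sim The [sim_table()] for the pair.
#' @param params A [walk_params()].
#' @return A `csrw_pair_scores` list: `chain`, `pi`, `c`, `lambda`,
#'   `iterations`.
#' @export
pair_correspondence <- function(netU, netV, sim, params = walk_params()) {
  chain <- build_reduced_chain(netU, netV, sim, params)
  pi <- stationary_distribution(chain, params)
  cc <- correspondence_scores(pi, chain$s, chain$lambda)
  structure(
    list(chain = chain, pi = as.numeric(pi), c = cc, lambda = chain$lambda,
         iterations = attr(pi, "iterations")),
    class = "csrw_pair_scores"
  )
}
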